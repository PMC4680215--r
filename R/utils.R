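# Internal helpers shared across modules. Sequences are handled as plain
# uppercase character scalars; the canonical internal alphabet for all
# pairing logic is RNA (T mapped to U on entry).

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.to_rna <- function(x) chartr("acgtuT", "ACGUUU", x)

.to_dna <- function(x) chartr("acgtuU", "ACGTTT", x)

#' @noRd
.validate_residues <- function(x, id = "sequence") {
  x <- toupper(x)
  if (!nzchar(x)) {
    stop("empty sequence for record '", id, "'", call. = FALSE)
  }
  bad <- gsub("[ACGTU]", "", x)
  if (nzchar(bad)) {
    stop("illegal residue(s) '", substr(bad, 1, 5), "' in record '", id, "'",
         call. = FALSE)
  }
  if (grepl("T", x, fixed = TRUE) && grepl("U", x, fixed = TRUE)) {
    stop("record '", id, "' mixes T and U; alphabet must be DNA or RNA",
         call. = FALSE)
  }
  x
}

.infer_alphabet <- function(x) {
  # T forces DNA; otherwise RNA, the package's canonical internal alphabet
  # (covers sequences with neither T nor U)
  if (grepl("T", x, fixed = TRUE)) "DNA" else "RNA"
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's
# .Random.seed afterwards so simulators never perturb user randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}
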