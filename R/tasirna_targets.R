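# tasiRNA target prediction: the same duplex machinery applied guide-by-guide
# across an mRNA library, with per-target site multiplicity.

#' Predict mRNA targets of tasiRNAs
#'
#' Applies [find_target_sites()] to every (tasiRNA, mRNA) pair and keeps
#' pairs with at least one qualifying site. Overlapping candidate sites on
#' one mRNA are collapsed to the best-scoring one, so multiplicity counts
#' discrete non-overlapping sites (dual-site targets such as the
#' tasiR-ARF / ARF3/-4 configuration yield multiplicity 2).
#'
#' @param tasirnas Named character vector of tasiRNA sequences, or a data
#'   frame with columns `id` and `seq` (e.g. [read_fasta()] output).
#' @param mrnas Named character vector of mRNA sequences, or a data frame
#'   with columns `id` and `seq`.
#' @param max_penalty Penalty cutoff (default 4, as in [find_target_sites()];
#'   override independently if looser tasiRNA rules are wanted).
#' @param weights A [duplex_weights()] configuration.
#' @return A data frame of predicted sites with columns `tasirna_name`,
#'   `target_id`, `start`, `end`, `penalty`, `cleavable`, `window`,
#'   `states`, sorted by (`tasirna_name`, `target_id`, `start`). Zero rows
#'   when nothing qualifies.
#' @export
predict_targets <- function(tasirnas, mrnas, max_penalty = 4,
                            weights = duplex_weights()) {
  tasirnas <- .as_named_seqs(tasirnas)
  mrnas <- .as_named_seqs(mrnas)
  out <- list()
  for (tn in names(tasirnas)) {
    for (mn in names(mrnas)) {
      if (nchar(mrnas[[mn]]) < nchar(tasirnas[[tn]])) next
      sites <- find_target_sites(tasirnas[[tn]], mrnas[[mn]],
                                 max_penalty = max_penalty,
                                 transcript_id = mn, weights = weights)
      if (nrow(sites) == 0) next
      sites$tasirna_name <- tn
      out[[length(out) + 1L]] <- sites
    }
  }
  if (length(out) == 0) {
    return(data.frame(tasirna_name = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      penalty = numeric(0), cleavable = logical(0),
                      window = character(0), states = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- data.frame(tasirna_name = res$tasirna_name,
                    target_id = res$transcript_id,
                    start = res$start, end = res$end,
                    penalty = res$penalty, cleavable = res$cleavable,
                    window = res$window, states = res$states,
                    stringsAsFactors = FALSE)
  res <- res[order(res$tasirna_name, res$target_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_named_seqs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    x <- stats::setNames(x$seq, x$id)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("sequences must be named", call. = FALSE)
  }
  as.list(x)
}

#' Per-target site multiplicity
#'
#' @param predictions Output of [predict_targets()].
#' @return A data frame with one row per (tasiRNA, target) pair and columns
#'   `tasirna_name`, `target_id`, `multiplicity`, sorted deterministically
#'   by (`tasirna_name`, `target_id`).
#' @export
multiplicity_report <- function(predictions) {
  if (nrow(predictions) == 0) {
    return(data.frame(tasirna_name = character(0), target_id = character(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(predictions$tasirna_name, predictions$target_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    tasirna_name = vapply(parts, `[`, character(1), 1),
    target_id = vapply(parts, `[`, character(1), 2),
    multiplicity = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$tasirna_name, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
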