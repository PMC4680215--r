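#' Read sequences from a FASTA file
#'
#' Parses a FASTA file (via [Biostrings::readBStringSet]) into a data frame
#' with one row per record. Residues are upper-cased and validated against
#' the nucleotide alphabet; the alphabet of each record is inferred from its
#' residue set (`T` implies DNA, otherwise RNA, the canonical internal
#' alphabet).
#' A record containing both `T` and `U` is an error.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (full header text), `seq`
#'   (upper-case residues) and `alphabet` (`"DNA"` or `"RNA"`), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA header (empty) in ", path, call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    .validate_residues(gsub("[ \t]", "", seqs[[i]]), ids[[i]])
  }, character(1))
  data.frame(
    id = ids,
    seq = seqs,
    alphabet = vapply(seqs, .infer_alphabet, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' Emits UNIX newlines and 60-column sequence wrapping.
#'
#' @param seqs A data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    x <- stats::setNames(seqs$seq, seqs$id)
  } else {
    x <- seqs
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read raw small-RNA reads from a FASTQ file
#'
#' Quality strings are ignored; only identifiers and residues are kept.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `id`, `seq` and `alphabet`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  seqs <- as.character(set)
  ids <- names(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    .validate_residues(seqs[[i]], ids[[i]])
  }, character(1))
  data.frame(
    id = ids,
    seq = seqs,
    alphabet = vapply(seqs, .infer_alphabet, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reverse-complement a nucleotide sequence
#'
#' Watson-Crick complement, reversed, in the same alphabet as the input
#' (a sequence containing `U` complements to RNA, otherwise to DNA).
#'
#' @param seq A character scalar of nucleotides.
#' @return The reverse complement, upper-cased.
#' @examples
#' reverse_complement("AUGC")  # "GCAU"
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  seq <- .validate_residues(seq)
  if (.infer_alphabet(seq) == "RNA") {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
}

#' Hamming distance between equal-length sequences
#'
#' Positions are compared after mapping `T` to `U`, so a DNA and an RNA
#' rendering of the same molecule are at distance zero.
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming("TCTTGACCTTGTAAGATCCCG", "TCTTGACCTTGTAAGACCTTT")  # 4
#' @export
hamming <- function(a, b) {
  a <- .to_rna(.validate_residues(a))
  b <- .to_rna(.validate_residues(b))
  if (nchar(a) != nchar(b)) {
    stop("hamming distance requires equal lengths (", nchar(a), " vs ",
         nchar(b), ")", call. = FALSE)
  }
  sum(.chars(a) != .chars(b))
}

#' Collapse raw reads to unique sequences with multiplicities
#'
#' @param raw Character vector of read sequences (upper-cased on entry).
#' @return A data frame with columns `seq` and `count`, sorted by descending
#'   count then lexicographically. Total count mass equals `length(raw)`.
#'   An empty input yields a zero-row frame.
#' @export
collapse_reads <- function(raw) {
  if (length(raw) == 0) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  raw <- vapply(raw, .validate_residues, character(1), USE.NAMES = FALSE)
  tab <- table(raw)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read count-collapsed reads from FASTA
#'
#' Headers are expected to carry the read multiplicity in a suffix matched by
#' `count_pattern` (first capture group), following the common sRNA-seq
#' `id_xN` convention.
#'
#' @param path Path to a collapsed FASTA file.
#' @param count_pattern Regular expression with one capture group yielding
#'   the integer count. Default matches a `_xN` suffix.
#' @return A data frame with columns `seq` and `count`, in descending-count
#'   then lexicographic order.
#' @export
read_collapsed_fasta <- function(path, count_pattern = "_x(\\d+)$") {
  fa <- read_fasta(path)
  m <- regexec(count_pattern, fa$id)
  hit <- regmatches(fa$id, m)
  bad <- lengths(hit) < 2
  if (any(bad)) {
    stop("header '", fa$id[bad][1], "' does not match count pattern '",
         count_pattern, "'", call. = FALSE)
  }
  counts <- as.integer(vapply(hit, `[`, character(1), 2))
  if (any(counts < 1)) stop("read counts must be >= 1", call. = FALSE)
  out <- data.frame(seq = fa$seq, count = counts, stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ seq, data = out, FUN = sum)
  agg <- agg[order(-agg$count, agg$seq), c("seq", "count"), drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write count-collapsed reads as FASTA
#'
#' @param reads Data frame with columns `seq` and `count`.
#' @param path Output path.
#' @param prefix Header prefix; record i becomes `<prefix><i>_x<count>`.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "read") {
  stopifnot(is.data.frame(reads), all(c("seq", "count") %in% names(reads)))
  ids <- sprintf("%s%d_x%d", prefix, seq_len(nrow(reads)), reads$count)
  write_fasta(stats::setNames(reads$seq, ids), path)
}

#' Read 5'-end tag positions from TSV
#'
#' @param path Tab-separated file with columns `target_id`, `position`,
#'   `count` (header row required).
#' @return A data frame of degradome tags.
#' @export
read_tags_tsv <- function(path) {
  tags <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "position", "count")
  if (!all(need %in% names(tags))) {
    stop("tag TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tags$count < 1) || any(tags$position < 1)) {
    stop("tag positions and counts must be positive", call. = FALSE)
  }
  tags
}

#' Write a data frame as TSV with UNIX newlines
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
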