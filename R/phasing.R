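# 21-nt phase register enumeration from the cleavage coordinate, read
# assignment, and the phasing enrichment statistic.

#' Enumerate plus-strand phase registers
#'
#' Tiles complete phase-length windows 5'-ward from the cleavage site: the
#' highest-index register ends at `cleavage_5p_end` (the transcript position
#' immediately 5' of the scissile bond) and each preceding register abuts
#' it. Windows that would start before `region_start` are dropped, not
#' clipped. Registers are named 5'D1+, 5'D2+, ... in 5'->3' transcript
#' order, so 5'D1+ is farthest from the cleavage site.
#'
#' @param cleavage_5p_end Transcript position immediately 5' of the
#'   scissile bond (the 3' end of the upstream cleavage fragment).
#' @param region_start First transcript position available for phasing
#'   (typically one past the 5' site's end).
#' @param phase Phase length in nt (default 21).
#' @param transcript Optional transcript sequence; when given, each
#'   register's 21-mer is recorded.
#' @return A data frame with columns `index`, `name`, `strand`, `start`,
#'   `end` and `sequence` (NA without a transcript); zero rows when the
#'   region is shorter than one phase length.
#' @examples
#' nrow(enumerate_registers(481, 313))  # 8
#' @export
enumerate_registers <- function(cleavage_5p_end, region_start, phase = 21L,
                                transcript = NULL) {
  cleavage_5p_end <- as.integer(cleavage_5p_end)
  region_start <- as.integer(region_start)
  phase <- as.integer(phase)
  stopifnot(phase >= 1L)
  if (region_start > cleavage_5p_end) {
    stop("region_start must not exceed cleavage_5p_end", call. = FALSE)
  }
  m <- (cleavage_5p_end - region_start + 1L) %/% phase
  if (m < 1L) {
    return(data.frame(index = integer(0), name = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  k <- seq_len(m)
  start <- cleavage_5p_end - (m - k + 1L) * phase + 1L
  end <- start + phase - 1L
  sequence <- rep(NA_character_, m)
  if (!is.null(transcript)) {
    transcript <- .to_rna(.validate_residues(transcript))
    if (max(end) > nchar(transcript)) {
      stop("registers extend past the transcript end", call. = FALSE)
    }
    sequence <- substring(transcript, start, end)
  }
  data.frame(index = k, name = sprintf("5'D%d+", k), strand = "+",
             start = start, end = end, sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Minus-strand duplex partners of plus-strand registers
#'
#' Each phased duplex carries a 2-nt 3' overhang, so the minus-strand
#' partner of a plus register `[s, e]` is the reverse complement of the
#' plus-strand window `[s + overhang, e + overhang]`. Partners whose shifted
#' window would run past the transcript end are dropped. Coordinates in the
#' output are the plus-strand coordinates of the shifted window.
#'
#' @param plus_registers Output of [enumerate_registers()].
#' @param transcript Transcript sequence (plus strand).
#' @param overhang Duplex 3'-overhang offset in nt (default 2).
#' @return A data frame like [enumerate_registers()] with `strand` `"-"`
#'   and names 5'Dk-.
#' @export
minus_strand_registers <- function(plus_registers, transcript, overhang = 2L) {
  transcript <- .to_rna(.validate_residues(transcript))
  overhang <- as.integer(overhang)
  s <- plus_registers$start + overhang
  e <- plus_registers$end + overhang
  keep <- s >= 1L & e <= nchar(transcript)
  out <- data.frame(
    index = plus_registers$index[keep],
    name = sprintf("5'D%d-", plus_registers$index[keep]),
    strand = rep("-", sum(keep)),
    start = s[keep], end = e[keep],
    sequence = vapply(which(keep), function(i) {
      reverse_complement(substring(transcript, s[i], e[i]))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Assign small-RNA reads to phase registers
#'
#' A read is in-phase for a register iff its sequence (with `T` mapped to
#' `U`) is identical to that register's 21-mer — exact matching, as used
#' when phased species are searched in an sRNA library. Reads that match
#' the phasing region as an exact substring at any other offset (either
#' strand) are off-phase; reads matching neither are ignored. Counts are
#' reported both raw (sum of collapsed multiplicities) and collapsed
#' (distinct sequences).
#'
#' @param reads A data frame with columns `seq` and `count` (e.g. from
#'   [collapse_reads()] or [read_collapsed_fasta()]), or a character vector
#'   of raw reads which is collapsed first.
#' @param registers Register table: typically the row-bind of
#'   [enumerate_registers()] (with sequences) and
#'   [minus_strand_registers()].
#' @param transcript Transcript sequence.
#' @param region_start,region_end Bounds of the phasing region used for the
#'   off-phase substring test; default to the span of `registers`.
#' @return A list of class `phasing_table`: `counts` (register table plus
#'   `raw_count` and `collapsed_count`), `off_phase_raw`,
#'   `off_phase_collapsed`, `total_raw`, `total_collapsed` (region-mapped
#'   totals), `region_length`, and `phasing_p` (NA until
#'   [phasing_pvalue()] is applied).
#' @export
assign_reads <- function(reads, registers, transcript,
                         region_start = NULL, region_end = NULL) {
  if (!is.data.frame(reads)) reads <- collapse_reads(reads)
  stopifnot(nrow(registers) >= 1, all(!is.na(registers$sequence)))
  transcript <- .to_rna(.validate_residues(transcript))
  if (is.null(region_start)) region_start <- min(registers$start)
  if (is.null(region_end)) region_end <- max(registers$end)
  region <- substring(transcript, region_start, region_end)
  region_rc <- reverse_complement(region)
  seqs <- vapply(reads$seq, function(s) .to_rna(.validate_residues(s)),
                 character(1), USE.NAMES = FALSE)
  hit <- match(seqs, registers$sequence)
  raw <- integer(nrow(registers))
  col <- integer(nrow(registers))
  inphase <- !is.na(hit)
  if (any(inphase)) {
    raw_t <- tapply(reads$count[inphase], hit[inphase], sum)
    col_t <- table(hit[inphase])
    raw[as.integer(names(raw_t))] <- as.integer(raw_t)
    col[as.integer(names(col_t))] <- as.integer(col_t)
  }
  off <- !inphase &
    (vapply(seqs, grepl, logical(1), x = region, fixed = TRUE) |
     vapply(seqs, grepl, logical(1), x = region_rc, fixed = TRUE))
  counts <- cbind(registers,
                  data.frame(raw_count = raw, collapsed_count = col))
  structure(list(
    counts = counts,
    off_phase_raw = sum(reads$count[off]),
    off_phase_collapsed = sum(off),
    total_raw = sum(raw) + sum(reads$count[off]),
    total_collapsed = sum(col) + sum(off),
    region_length = as.integer(region_end - region_start + 1L),
    region_start = as.integer(region_start),
    region_end = as.integer(region_end),
    phasing_p = NA_real_
  ), class = "phasing_table")
}

#' Phasing enrichment probability
#'
#' Tail probability of seeing at least the observed number of in-phase
#' reads if region-mapped reads started at uniformly random positions.
#' With `K = floor(region_length / phase)` in-phase start positions out of
#' `region_length`, the in-phase read count under the null is binomial with
#' success probability `K / region_length` (approximately `1/phase`), and
#' the reported value is the upper tail at the observed count. The paper's
#' workflow reports raw counts only; this statistic is an additive
#' convenience and is flagged as such in written output.
#'
#' @param table A [assign_reads()] result.
#' @param region_length Length of the phasing region in nt (defaults to the
#'   region recorded in `table`).
#' @param phase Phase length (default 21).
#' @return A probability in `[0, 1]`; 1.0 when no reads map to the region.
#'   Store it into the table's `phasing_p` field to have it appear in
#'   printed and written output.
#' @export
phasing_pvalue <- function(table, region_length = table$region_length,
                           phase = 21L) {
  stopifnot(inherits(table, "phasing_table"))
  n <- table$total_raw
  if (n == 0) return(1.0)
  x <- sum(table$counts$raw_count)
  K <- region_length %/% phase
  p0 <- K / region_length
  stats::pbinom(x - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' @export
print.phasing_table <- function(x, ...) {
  cat("Phase-register read assignment (region ", x$region_start, "-",
      x$region_end, ", ", x$region_length, " nt)\n", sep = "")
  print(x$counts[, c("name", "strand", "start", "end", "raw_count",
                     "collapsed_count")], row.names = FALSE)
  cat(sprintf("off-phase: %d raw / %d collapsed; region-mapped total: %d raw\n",
              x$off_phase_raw, x$off_phase_collapsed, x$total_raw))
  if (!is.na(x$phasing_p)) {
    cat(sprintf("phasing enrichment p = %.3g\n", x$phasing_p))
  }
  invisible(x)
}

#' Write a phasing table as TSV
#'
#' Columns mirror a per-register abundance table (name, strand, start, end,
#' sequence, raw_count, collapsed_count), followed by comment lines with
#' the off-phase and total tallies and, when computed, the enrichment
#' statistic (marked as a package addition, not a primary observable).
#'
#' @param table A [assign_reads()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phasing_tsv <- function(table, path) {
  stopifnot(inherits(table, "phasing_table"))
  cols <- c("name", "strand", "start", "end", "sequence",
            "raw_count", "collapsed_count")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(table$counts[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  writeLines(sprintf("# off_phase_raw=%d off_phase_collapsed=%d total_raw=%d total_collapsed=%d",
                     table$off_phase_raw, table$off_phase_collapsed,
                     table$total_raw, table$total_collapsed), con)
  if (!is.na(table$phasing_p)) {
    writeLines(sprintf("# phasing_p=%.6g (binomial enrichment; additional statistic, not a primary observable)",
                       table$phasing_p), con)
  }
  invisible(path)
}
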