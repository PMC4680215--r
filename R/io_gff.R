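# Minimal GFF3 emission for site and register annotations. The format here
# is write-only and flat (one feature per row, no hierarchy), so the
# 9-column text layout is emitted directly.

.gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

.gff3_lines <- function(seqid, source, type, start, end, score, strand,
                        attrs) {
  sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
          seqid, source, type, start, end, score, strand, attrs)
}

#' Write target sites as GFF3
#'
#' One `miRNA_target_site` feature per site, with `penalty`, `cleavable`
#' and (when cleavable) `scissile` attributes; the score column carries the
#' duplex penalty.
#'
#' @param sites Output of [find_target_sites()] or [predict_targets()].
#' @param path Output path.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_sites_gff3 <- function(sites, path, source = "tasiphase") {
  seqid <- if ("transcript_id" %in% names(sites)) sites$transcript_id
           else sites$target_id
  id <- sprintf("site%d", seq_len(nrow(sites)))
  attrs <- sprintf("ID=%s;penalty=%s;cleavable=%s", id,
                   format(sites$penalty, trim = TRUE),
                   tolower(sites$cleavable))
  if ("cleavage_5p" %in% names(sites)) {
    has <- !is.na(sites$cleavage_5p)
    attrs[has] <- sprintf("%s;scissile=%d_%d", attrs[has],
                          sites$cleavage_5p[has], sites$cleavage_3p[has])
  }
  if ("tasirna_name" %in% names(sites)) {
    attrs <- sprintf("%s;guide=%s", attrs, .gff3_escape(sites$tasirna_name))
  }
  lines <- .gff3_lines(.gff3_escape(seqid), source, "miRNA_target_site",
                       sites$start, sites$end,
                       format(sites$penalty, trim = TRUE), "+", attrs)
  writeLines(c("##gff-version 3", lines), path, sep = "\n")
  invisible(path)
}

#' Write phase registers as GFF3
#'
#' One `tasiRNA` feature per register (plus- or minus-strand), carrying the
#' register name and 21-mer in its attributes.
#'
#' @param registers Output of [enumerate_registers()] and/or
#'   [minus_strand_registers()].
#' @param path Output path.
#' @param seqid Transcript identifier for the seqid column.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_registers_gff3 <- function(registers, path, seqid = "transcript",
                                 source = "tasiphase") {
  attrs <- sprintf("ID=%s;Name=%s", .gff3_escape(registers$name),
                   .gff3_escape(registers$name))
  has_seq <- !is.na(registers$sequence)
  attrs[has_seq] <- sprintf("%s;sequence=%s", attrs[has_seq],
                            registers$sequence[has_seq])
  lines <- .gff3_lines(.gff3_escape(seqid), source, "tasiRNA",
                       registers$start, registers$end, ".",
                       registers$strand, attrs)
  writeLines(c("##gff-version 3", lines), path, sep = "\n")
  invisible(path)
}
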