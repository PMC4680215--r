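# Mapping 5'-end tags (RLM-RACE clones / degradome reads) onto predicted
# duplexes to locate the observed scissile bond and its clone support.

#' Map 5'-end tags to a cleavage position
#'
#' Collects tags whose 5' position falls within the duplex window extended
#' by `flank` nt on both sides, takes the modal tag position as the
#' observed cleavage signature (the tag's first nucleotide is the 5' end of
#' the 3' cleavage fragment, so a tag at position `t` marks a bond between
#' `t - 1` and `t`), and converts it to guide-relative numbering: the bond
#' sits between the target nucleotides opposite guide positions `i + 1`
#' and `i`, with `i = end - t + 1`. The canonical slicer signature is
#' `(10, 11)`. Ties on the modal count are broken toward the canonical
#' bond, then toward the 3'-most transcript position.
#'
#' @param tags Data frame of tags with columns `target_id`, `position`
#'   (1-based transcript coordinate of the tag's first nucleotide) and
#'   `count` (see [read_tags_tsv()]). Rows whose `target_id` differs from
#'   the site's transcript are ignored.
#' @param site A single target site (one row of [find_target_sites()]
#'   output).
#' @param flank Window extension in nt (default 5).
#' @return A list of class `cleavage_report`: `site`, `tag_position`,
#'   `bond` (transcript position pair), `guide_relative` (pair `(i, i+1)`),
#'   `canonical` (is it `(10, 11)`?), `supporting_fraction` (modal count /
#'   total in-window tag count), `n_tags`, and `supported` (`FALSE` when no
#'   tag falls in the window; then fraction is 0 and positions are NA).
#' @export
map_tags <- function(tags, site, flank = 5L) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- as.list(site)
  }
  flank <- as.integer(flank)
  keep <- tags$target_id == site$transcript_id &
    tags$position >= site$start - flank &
    tags$position <= site$end + flank
  tags <- tags[keep, , drop = FALSE]
  empty <- structure(list(site = site, tag_position = NA_integer_,
                          bond = c(NA_integer_, NA_integer_),
                          guide_relative = c(NA_integer_, NA_integer_),
                          canonical = FALSE, supporting_fraction = 0,
                          n_tags = 0L, supported = FALSE),
                     class = "cleavage_report")
  if (nrow(tags) == 0) return(empty)
  per_pos <- tapply(tags$count, tags$position, sum)
  pos <- as.integer(names(per_pos))
  cnt <- as.integer(per_pos)
  total <- sum(cnt)
  best <- which(cnt == max(cnt))
  if (length(best) > 1) {
    canonical_pos <- site$end - 9L  # tag position of the (10,11) bond
    if (canonical_pos %in% pos[best]) {
      best <- best[pos[best] == canonical_pos]
    } else {
      best <- best[which.max(pos[best])]
    }
  }
  t <- pos[best[1]]
  i <- as.integer(site$end) - t + 1L
  structure(list(
    site = site,
    tag_position = t,
    bond = c(t - 1L, t),
    guide_relative = c(i, i + 1L),
    canonical = identical(c(i, i + 1L), c(10L, 11L)),
    supporting_fraction = cnt[best[1]] / total,
    n_tags = total,
    supported = TRUE
  ), class = "cleavage_report")
}

#' @export
print.cleavage_report <- function(x, ...) {
  if (!x$supported) {
    cat("Cleavage report: no tags within the duplex window (unsupported)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Cleavage between transcript positions %d/%d (opposite guide positions %d/%d)%s\n",
    x$bond[1], x$bond[2], x$guide_relative[1], x$guide_relative[2],
    if (x$canonical) " [canonical]" else ""))
  cat(sprintf("  supported by %.1f%% of %d tags in window\n",
              100 * x$supporting_fraction, x$n_tags))
  invisible(x)
}

#' Tabulate cleavage reports
#'
#' @param reports A list of [map_tags()] results.
#' @return A data frame with one row per report (target, bond coordinates,
#'   guide-relative bond, canonical flag, supporting fraction, tag total).
#' @export
cleavage_report_table <- function(reports) {
  if (inherits(reports, "cleavage_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      target_id = r$site$transcript_id,
      site_start = r$site$start, site_end = r$site$end,
      tag_position = r$tag_position,
      bond_5p = r$bond[1], bond_3p = r$bond[2],
      guide_pos_5p = r$guide_relative[1],
      guide_pos_3p = r$guide_relative[2],
      canonical = r$canonical,
      supporting_fraction = r$supporting_fraction,
      n_tags = r$n_tags, supported = r$supported,
      stringsAsFactors = FALSE
    )
  }))
}
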