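# Plant small-RNA target-site discovery and scoring: ungapped antiparallel
# duplexes, psRNATarget-style penalty weights with G:U wobble, central-WC
# cleavability, and two-hit locus detection.

# Pair-state classification under antiparallel pairing, vectorized over
# equal-shape character arrays of RNA residues.
.pair_state <- function(g, t) {
  wc <- (g == "A" & t == "U") | (g == "U" & t == "A") |
        (g == "G" & t == "C") | (g == "C" & t == "G")
  gu <- (g == "G" & t == "U") | (g == "U" & t == "G")
  out <- rep("MISMATCH", length(g))
  dim(out) <- dim(g)
  out[gu] <- "GU"
  out[wc] <- "WC"
  out
}

.state_abbrev <- c(WC = "W", GU = "G", MISMATCH = "M")

#' Duplex scoring weights
#'
#' The penalty of a guide:target duplex is
#' \eqn{\sum_i w(\mathrm{state}_i) \cdot m(i)} where `w` is 0 for a
#' Watson-Crick pair, `gu` for a G:U wobble, `mismatch` otherwise, and the
#' positional multiplier `m` is `core_multiplier` inside the seed/core
#' region (guide positions `core_start`..`core_end`) and 1 elsewhere.
#' Defaults follow the widely used plant target-recognition rules
#' (mismatch 1, G:U 0.5, doubled over positions 2-13).
#'
#' @param mismatch,gu,wc Per-state weights.
#' @param core_start,core_end Guide positions (1-based from the guide 5' end)
#'   whose weights are multiplied.
#' @param core_multiplier Multiplier applied inside the core region.
#' @return A list of class `duplex_weights`.
#' @export
duplex_weights <- function(mismatch = 1, gu = 0.5, wc = 0,
                           core_start = 2L, core_end = 13L,
                           core_multiplier = 2) {
  structure(list(mismatch = mismatch, gu = gu, wc = wc,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end),
                 core_multiplier = core_multiplier),
            class = "duplex_weights")
}

#' Build a guide:target duplex
#'
#' Pairs a small-RNA guide (5'->3') against a same-length target window
#' (5'->3' on the transcript) in antiparallel orientation: guide position
#' `i` faces target-window position `L - i + 1`. Each guide position is
#' classified as `WC` (A:U or G:C), `GU` (G:U wobble, either orientation),
#' or `MISMATCH`. `T` and `U` are interchangeable.
#'
#' @param guide Guide sequence, 5'->3'.
#' @param window Target window, 5'->3', same length as `guide`.
#' @return A list of class `duplex` with elements `guide`, `window` (both
#'   RNA, upper-case) and `states` (character vector indexed by guide
#'   position).
#' @examples
#' d <- build_duplex("UCUUGACCUUGUAAGAUCCC", "AGGGUCUUGCAAGGUCAAGA")
#' which(d$states == "GU")        # 12 17
#' which(d$states == "MISMATCH")  # 20
#' @export
build_duplex <- function(guide, window) {
  guide <- .to_rna(.validate_residues(guide))
  window <- .to_rna(.validate_residues(window))
  if (nchar(guide) != nchar(window)) {
    stop("guide and target window must have equal lengths (ungapped model)",
         call. = FALSE)
  }
  g <- .chars(guide)
  t <- rev(.chars(window))  # t[i] faces guide position i
  structure(list(guide = guide, window = window,
                 states = .pair_state(g, t)),
            class = "duplex")
}

#' Score a duplex with plant target-penalty rules
#'
#' @param duplex A [build_duplex()] result.
#' @param weights A [duplex_weights()] configuration.
#' @return Non-negative numeric penalty; 0 for perfect complementarity.
#' @examples
#' score_duplex(build_duplex("UCUUGACCUUGUAAGAUCCC",
#'                           "AGGGUCUUGCAAGGUCAAGA"))  # 2.5
#' @export
score_duplex <- function(duplex, weights = duplex_weights()) {
  stopifnot(inherits(duplex, "duplex"))
  L <- length(duplex$states)
  w <- c(WC = weights$wc, GU = weights$gu, MISMATCH = weights$mismatch)
  m <- rep(1, L)
  core <- seq_len(L) >= weights$core_start & seq_len(L) <= weights$core_end
  m[core] <- weights$core_multiplier
  sum(unname(w[duplex$states]) * m)
}

#' Is a duplex competent for slicing?
#'
#' Slicing by the silencing complex requires an undistorted center: guide
#' positions 9-11 must all be strict Watson-Crick pairs. A G:U wobble at
#' any of these positions counts as non-cleavable.
#'
#' @param duplex A [build_duplex()] result with guide length >= 11.
#' @return `TRUE` or `FALSE`.
#' @export
assess_cleavability <- function(duplex) {
  stopifnot(inherits(duplex, "duplex"))
  if (length(duplex$states) < 11) {
    stop("cleavability requires a guide of length >= 11", call. = FALSE)
  }
  all(duplex$states[9:11] == "WC")
}

#' Transcript coordinates of the scissile bond
#'
#' For a guide bound at transcript positions `[start, end]` (guide position
#' `i` opposite transcript position `end - i + 1`), the scissile bond lies
#' between the transcript nucleotides opposite guide positions 11 and 10,
#' i.e. between positions `end - 10` and `end - 9`.
#'
#' @param site A single target site (one row of [find_target_sites()] output,
#'   or any list with fields `end` and `cleavable`).
#' @return Integer vector `c(p, p + 1)` flanking the scissile bond.
#' @examples
#' cleavage_coordinate(list(end = 21, cleavable = TRUE))   # 11 12
#' cleavage_coordinate(list(end = 491, cleavable = TRUE))  # 481 482
#' @export
cleavage_coordinate <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- as.list(site)
  }
  if (!isTRUE(site$cleavable)) {
    stop("cleavage coordinate is undefined for a non-cleavable site",
         call. = FALSE)
  }
  p <- as.integer(site$end) - 10L
  c(p, p + 1L)
}

# Score every guide-length window of the transcript at once. Returns a data
# frame with one row per window start.
.scan_all_windows <- function(guide, transcript, weights) {
  g <- .chars(guide)
  tc <- .chars(transcript)
  L <- length(g)
  n <- length(tc) - L + 1L
  # window start s places guide position i opposite transcript position
  # s + L - i (antiparallel)
  idx <- outer(seq_len(n), L - seq_len(L), `+`)
  tm <- matrix(tc[idx], nrow = n)
  gm <- matrix(rep(g, each = n), nrow = n)
  st <- .pair_state(gm, tm)
  w <- c(WC = weights$wc, GU = weights$gu, MISMATCH = weights$mismatch)
  m <- rep(1, L)
  core <- seq_len(L) >= weights$core_start & seq_len(L) <= weights$core_end
  m[core] <- weights$core_multiplier
  wm <- matrix(unname(w[st]), nrow = n)
  penalty <- as.vector(wm %*% m)
  cleavable <- if (L >= 11) {
    rowSums(st[, 9:11, drop = FALSE] == "WC") == 3L
  } else {
    rep(FALSE, n)
  }
  states <- apply(matrix(unname(.state_abbrev[st]), nrow = n), 1,
                  paste, collapse = "")
  data.frame(start = seq_len(n), end = seq_len(n) + L - 1L,
             penalty = penalty, cleavable = cleavable,
             states = states, stringsAsFactors = FALSE)
}

#' Find small-RNA complementary sites on a transcript
#'
#' Scores every guide-length window with [score_duplex()] rules, keeps
#' windows with penalty at or below `max_penalty`, and resolves groups of
#' mutually overlapping qualifying windows to the single lowest-penalty
#' window per group (ties broken leftmost). Set `resolve_overlaps = FALSE`
#' to obtain all qualifying windows.
#'
#' @param guide Guide sequence, 5'->3'.
#' @param transcript Transcript sequence, 5'->3' (plus strand).
#' @param max_penalty Penalty cutoff (default 4).
#' @param transcript_id Identifier recorded in the output.
#' @param weights A [duplex_weights()] configuration.
#' @param resolve_overlaps Collapse overlapping qualifying windows?
#' @return A data frame of target sites sorted by `start` with columns
#'   `transcript_id`, `start`, `end` (1-based inclusive, plus strand),
#'   `penalty`, `cleavable`, `cleavage_5p`, `cleavage_3p` (NA when not
#'   cleavable), `window` and `states` (one of `W`/`G`/`M` per guide
#'   position, 5'->3' along the guide).
#' @export
find_target_sites <- function(guide, transcript, max_penalty = 4,
                              transcript_id = "transcript",
                              weights = duplex_weights(),
                              resolve_overlaps = TRUE) {
  guide <- .to_rna(.validate_residues(guide))
  transcript <- .to_rna(.validate_residues(transcript))
  if (nchar(transcript) < nchar(guide)) {
    stop("transcript is shorter than the guide", call. = FALSE)
  }
  hits <- .scan_all_windows(guide, transcript, weights)
  hits <- hits[hits$penalty <= max_penalty, , drop = FALSE]
  if (nrow(hits) > 0 && resolve_overlaps) {
    hits <- hits[order(hits$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, hits$start[-1] > cummax(hits$end)[-nrow(hits)]))
    keep <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(i) {
      i[which.min(hits$penalty[i])]  # first minimum = leftmost on ties
    }), use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
  }
  tc <- .chars(transcript)
  window <- vapply(seq_len(nrow(hits)), function(i) {
    paste(tc[hits$start[i]:hits$end[i]], collapse = "")
  }, character(1))
  out <- data.frame(
    transcript_id = rep(transcript_id, nrow(hits)),
    start = hits$start, end = hits$end,
    penalty = hits$penalty, cleavable = hits$cleavable,
    cleavage_5p = ifelse(hits$cleavable, hits$end - 10L, NA_integer_),
    cleavage_3p = ifelse(hits$cleavable, hits$end - 9L, NA_integer_),
    window = window, states = hits$states,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Detect a two-hit tasiRNA trigger locus
#'
#' Searches the transcript for exactly two qualifying guide sites — the
#' two-hit configuration of TAS3-family transcripts, which carry dual
#' miR390 complementary sites with slicing confined to one of them. By
#' default the 3' site is the phase-setting (cleaved) site and the locus is
#' reported only when that site is slicing-competent; `phase_anchor = "5p"`
#' anchors phasing at the 5' site instead, for TAS families processed from
#' the other end.
#'
#' @inheritParams find_target_sites
#' @param phase_anchor Which site sets the phase: `"3p"` (default) or `"5p"`.
#' @return A list of class `two_hit_locus` with elements `five_prime_site`,
#'   `three_prime_site` (one-row data frames), `inter_site_span` (nt strictly
#'   between the sites), `region_start`, `cleavage_5p_end` (last transcript
#'   position 5' of the scissile bond) and `phase_anchor`; or `NULL` when
#'   fewer than two qualifying sites exist or the anchored site is not
#'   cleavable. More than two qualifying sites triggers a warning and the
#'   two lowest-penalty sites are kept.
#' @export
detect_two_hit <- function(guide, transcript, max_penalty = 4,
                           transcript_id = "transcript",
                           weights = duplex_weights(),
                           phase_anchor = c("3p", "5p")) {
  phase_anchor <- match.arg(phase_anchor)
  sites <- find_target_sites(guide, transcript, max_penalty,
                             transcript_id, weights)
  if (nrow(sites) < 2) return(NULL)
  if (nrow(sites) > 2) {
    warning(nrow(sites), " qualifying sites found; keeping the two with ",
            "lowest penalty", call. = FALSE)
    keep <- order(sites$penalty, sites$start)[1:2]
    sites <- sites[sort(keep), , drop = FALSE]
  }
  five <- sites[1, , drop = FALSE]
  three <- sites[2, , drop = FALSE]
  anchored <- if (phase_anchor == "3p") three else five
  if (!anchored$cleavable) return(NULL)
  bond <- cleavage_coordinate(anchored)
  if (phase_anchor == "3p") {
    region_start <- five$end + 1L
    cleavage_5p_end <- bond[1]
  } else {
    # phase runs 3'-ward from the 5'-site bond toward the 3' site
    region_start <- bond[2]
    cleavage_5p_end <- three$start - 1L
  }
  structure(list(
    five_prime_site = five,
    three_prime_site = three,
    inter_site_span = three$start - five$end - 1L,
    region_start = as.integer(region_start),
    cleavage_5p_end = as.integer(cleavage_5p_end),
    phase_anchor = phase_anchor
  ), class = "two_hit_locus")
}

#' @export
print.two_hit_locus <- function(x, ...) {
  cat("Two-hit small-RNA trigger locus on '",
      x$five_prime_site$transcript_id, "'\n", sep = "")
  cat(sprintf("  5' site: %d-%d  penalty %.2f  cleavable: %s\n",
              x$five_prime_site$start, x$five_prime_site$end,
              x$five_prime_site$penalty, x$five_prime_site$cleavable))
  cat(sprintf("  3' site: %d-%d  penalty %.2f  cleavable: %s\n",
              x$three_prime_site$start, x$three_prime_site$end,
              x$three_prime_site$penalty, x$three_prime_site$cleavable))
  cat(sprintf("  inter-site span: %d nt; phase region starts at %d, ends at %d\n",
              x$inter_site_span, x$region_start, x$cleavage_5p_end))
  invisible(x)
}
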