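# Synthetic TAS-like loci, phased small-RNA read sets, and 5'-tag sets with
# complete ground truth. Every simulator is deterministic for a fixed seed
# and restores the caller's RNG state.

#' Generate a synthetic two-hit TAS locus
#'
#' Builds a uniform-random RNA backbone and implants two guide-complementary
#' windows in the two-hit architecture: a 3' site that is a perfect reverse
#' complement of the guide (penalty 0, slicing-competent) and a 5' site
#' carrying exactly one mismatch opposite guide position 10 (the central
#' mismatch that blocks slicing at the 5' site of TAS3-family transcripts).
#' Site placement is chosen so that exactly `n_registers` complete
#' phase-length windows fit between the 5' site's end and the 3'-site
#' scissile bond.
#'
#' @param seed Integer seed; the same seed reproduces the locus exactly.
#' @param guide Guide (miRNA) sequence, 5'->3'; length >= 11.
#' @param backbone_length Transcript length in nt (>= `2 * guide length +
#'   n_registers * phase`).
#' @param n_registers Number of complete plus-strand registers to fit.
#' @param phase Phase length (default 21).
#' @return A list of class `tas_locus`: `transcript`, `transcript_id`,
#'   `guide`, `truth_sites` (two-row site table in [find_target_sites()]
#'   layout, 5' then 3'), `truth_registers`, `region_start`, `region_end`
#'   (= `cleavage_5p_end`), `cleavage_5p_end`, `phase` and `seed`.
#' @export
make_tas_locus <- function(seed, guide, backbone_length = 600L,
                           n_registers = 8L, phase = 21L) {
  guide <- .to_rna(.validate_residues(guide))
  gl <- nchar(guide)
  backbone_length <- as.integer(backbone_length)
  n_registers <- as.integer(n_registers)
  phase <- as.integer(phase)
  stopifnot(gl >= 11L, n_registers >= 1L)
  if (backbone_length < 2L * gl + n_registers * phase) {
    stop("backbone_length must be at least 2*guide + n_registers*phase nt",
         call. = FALSE)
  }
  # geometry: 5' site [s5, e5]; region starts at e5+1; scissile 5' end at
  # e5 + n*phase; 3' site ends 10 nt past the bond (guide position 11
  # opposite the bond's 5' flank)
  s5_max <- backbone_length - gl + 1L - n_registers * phase - 10L
  if (s5_max < 1L) stop("infeasible geometry for the requested locus",
                        call. = FALSE)
  with_seed(seed, {
    s5 <- if (s5_max == 1L) 1L else sample.int(s5_max, 1L)
    backbone <- sample(c("A", "C", "G", "U"), backbone_length, replace = TRUE)
  })
  e5 <- s5 + gl - 1L
  cleavage_5p_end <- e5 + n_registers * phase
  e3 <- cleavage_5p_end + 10L
  s3 <- e3 - gl + 1L
  w3 <- .chars(reverse_complement(guide))
  w5 <- w3
  # guide position 10 faces window position gl - 9; a residue identical to
  # the guide base can never pair (no WC, no G:U), giving exactly one
  # central mismatch
  w5[gl - 9L] <- .chars(guide)[10L]
  backbone[s5:e5] <- w5
  backbone[s3:e3] <- w3
  transcript <- paste(backbone, collapse = "")
  mk_site <- function(start, end, id) {
    win <- substring(transcript, start, end)
    d <- build_duplex(guide, win)
    cleav <- assess_cleavability(d)
    data.frame(transcript_id = id, start = start, end = end,
               penalty = score_duplex(d), cleavable = cleav,
               cleavage_5p = if (cleav) end - 10L else NA_integer_,
               cleavage_3p = if (cleav) end - 9L else NA_integer_,
               window = win,
               states = paste(.state_abbrev[d$states], collapse = ""),
               stringsAsFactors = FALSE)
  }
  id <- "synthetic_TAS"
  truth_sites <- rbind(mk_site(s5, e5, id), mk_site(s3, e3, id))
  truth_registers <- enumerate_registers(cleavage_5p_end, e5 + 1L,
                                         phase = phase,
                                         transcript = transcript)
  structure(list(
    transcript = transcript, transcript_id = id, guide = guide,
    truth_sites = truth_sites, truth_registers = truth_registers,
    region_start = e5 + 1L, region_end = cleavage_5p_end,
    cleavage_5p_end = cleavage_5p_end, phase = phase, seed = seed
  ), class = "tas_locus")
}

#' Simulate phased small-RNA reads from a synthetic locus
#'
#' Draws `depth` reads. With probability `in_phase_fraction` a register is
#' drawn from a geometric-weight distribution (weight proportional to
#' `abundance_decay` raised to the distance from `peak_register`) and its
#' exact 21-mer is emitted — from the minus strand (the duplex partner
#' shifted by `overhang`) with probability `minus_strand_fraction`, else
#' from the plus strand. Otherwise an off-phase read is emitted: a
#' phase-length substring of the phasing region starting at a uniformly
#' drawn non-register offset (offsets whose substring would coincide with a
#' register 21-mer are excluded so truth counts are exact under exact
#' matching). Abundances mimic real phased loci: a few dominant registers
#' near the 3' end of the array and many near-zero ones.
#'
#' @param locus A [make_tas_locus()] result.
#' @param depth Total number of reads.
#' @param in_phase_fraction Probability a read is a register 21-mer.
#' @param abundance_decay Geometric decay of register weight with distance
#'   from the peak register (in (0, 1]; 1 = uniform).
#' @param minus_strand_fraction Probability an in-phase read comes from the
#'   minus strand.
#' @param peak_register Index of the most abundant register; default
#'   `max(1, m - 2)` (mid-3' dominance).
#' @param overhang Duplex 3'-overhang offset for minus-strand partners.
#' @param seed Integer seed.
#' @return A list of class `sim_reads`: `reads` (collapsed data frame with
#'   `seq`, `count`), `truth_counts` (data frame `name`, `count` over plus
#'   and minus register names), `off_phase_truth`, `registers` (plus and
#'   minus register table used), and `params`.
#' @export
simulate_phased_reads <- function(locus, depth = 1000L,
                                  in_phase_fraction = 0.9,
                                  abundance_decay = 0.5,
                                  minus_strand_fraction = 0.3,
                                  peak_register = NULL,
                                  overhang = 2L, seed = 1L) {
  stopifnot(inherits(locus, "tas_locus"),
            in_phase_fraction >= 0, in_phase_fraction <= 1,
            abundance_decay > 0, abundance_decay <= 1)
  plus <- locus$truth_registers
  minus <- minus_strand_registers(plus, locus$transcript, overhang)
  m <- nrow(plus)
  if (is.null(peak_register)) peak_register <- max(1L, m - 2L)
  wts <- abundance_decay ^ abs(seq_len(m) - peak_register)
  wts <- wts / sum(wts)
  phase <- locus$phase
  region_starts <- locus$region_start:(locus$region_end - phase + 1L)
  off_ok <- !(region_starts %in% plus$start)
  # also exclude offsets whose 21-mer happens to equal a register sequence
  cand <- region_starts[off_ok]
  cand_seq <- substring(locus$transcript, cand, cand + phase - 1L)
  cand <- cand[!(cand_seq %in% c(plus$sequence, minus$sequence))]
  with_seed(seed, {
    n_in <- stats::rbinom(1L, depth, in_phase_fraction)
    reg_idx <- if (n_in > 0) sample.int(m, n_in, replace = TRUE, prob = wts)
               else integer(0)
    use_minus <- if (n_in > 0) {
      stats::runif(n_in) < minus_strand_fraction & reg_idx %in% minus$index
    } else logical(0)
    n_off <- depth - n_in
    off_pos <- if (n_off > 0 && length(cand) > 0) {
      cand[sample.int(length(cand), n_off, replace = TRUE)]
    } else integer(0)
  })
  in_names <- ifelse(use_minus, sprintf("5'D%d-", reg_idx),
                     sprintf("5'D%d+", reg_idx))
  all_regs <- rbind(plus, minus)
  seq_of <- stats::setNames(all_regs$sequence, all_regs$name)
  in_seqs <- unname(seq_of[in_names])
  off_seqs <- if (length(off_pos)) {
    substring(locus$transcript, off_pos, off_pos + phase - 1L)
  } else character(0)
  truth <- table(factor(in_names, levels = all_regs$name))
  structure(list(
    reads = collapse_reads(c(in_seqs, off_seqs)),
    truth_counts = data.frame(name = names(truth), count = as.integer(truth),
                              stringsAsFactors = FALSE),
    off_phase_truth = length(off_seqs),
    registers = all_regs,
    params = list(depth = depth, in_phase_fraction = in_phase_fraction,
                  abundance_decay = abundance_decay,
                  minus_strand_fraction = minus_strand_fraction,
                  peak_register = peak_register, overhang = overhang,
                  seed = seed)
  ), class = "sim_reads")
}

#' Simulate 5'-end (degradome/RLM-RACE) tags around a cleavage site
#'
#' Places `round((1 - noise_fraction) * depth)` tags at the bond shifted by
#' `bond_offset` nt (in the 3' transcript direction) from the canonical
#' scissile position, and the remainder uniformly within the duplex window
#' extended by `flank`.
#'
#' @param site A single cleavable target site (one row of
#'   [find_target_sites()] output), or any site when `bond_offset` is given
#'   explicitly.
#' @param depth Total tag count.
#' @param noise_fraction Fraction of tags placed uniformly at random.
#' @param bond_offset Offset of the true bond from canonical; `+1`
#'   reproduces a cleavage between guide positions 9 and 10.
#' @param flank Window extension used for noise placement (default 5).
#' @param seed Integer seed.
#' @return A data frame of tags (`target_id`, `position`, `count`)
#'   aggregated by position.
#' @export
simulate_degradome_tags <- function(site, depth = 50L, noise_fraction = 0,
                                    bond_offset = 0L, flank = 5L, seed = 1L) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- as.list(site)
  }
  if (!isTRUE(site$cleavable) && missing(bond_offset)) {
    stop("site is not cleavable; supply bond_offset explicitly",
         call. = FALSE)
  }
  true_tag <- as.integer(site$end) - 9L + as.integer(bond_offset)
  n_sig <- round((1 - noise_fraction) * depth)
  n_noise <- depth - n_sig
  window <- (site$start - flank):(site$end + flank)
  noise_pos <- with_seed(seed, {
    if (n_noise > 0) window[sample.int(length(window), n_noise,
                                       replace = TRUE)] else integer(0)
  })
  pos <- c(rep(true_tag, n_sig), noise_pos)
  per <- table(pos)
  data.frame(target_id = site$transcript_id,
             position = as.integer(names(per)),
             count = as.integer(per), stringsAsFactors = FALSE)
}

#' Simulate an mRNA carrying implanted tasiRNA target sites
#'
#' Implants `n_sites` non-overlapping reverse-complement windows of the
#' tasiRNA at seeded random positions separated by at least `min_gap` nt,
#' emulating dual-site targets such as ARF3/-4.
#'
#' @param seed Integer seed.
#' @param tasirna Guide sequence whose perfect complement is implanted.
#' @param length mRNA length (>= `n_sites * (guide + min_gap)`).
#' @param n_sites Number of sites (0 allowed: plain random backbone).
#' @param min_gap Minimum nt between consecutive sites.
#' @return A list: `id`, `seq` (the mRNA) and `truth_sites` (data frame
#'   `start`, `end` of implants in 5'->3' order; zero rows for
#'   `n_sites = 0`).
#' @export
simulate_target_mrna <- function(seed, tasirna, length = 2000L,
                                 n_sites = 2L, min_gap = 20L) {
  tasirna <- .to_rna(.validate_residues(tasirna))
  gl <- nchar(tasirna)
  length <- as.integer(length)
  n_sites <- as.integer(n_sites)
  if (length < n_sites * (gl + min_gap)) {
    stop("mRNA too short for ", n_sites, " sites with the requested gap",
         call. = FALSE)
  }
  with_seed(seed, {
    backbone <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
    starts <- integer(0)
    if (n_sites > 0) {
      # distribute the free slack among the n_sites + 1 gaps
      free <- length - n_sites * gl - (n_sites - 1L) * min_gap
      slack <- as.integer(stats::rmultinom(1L, free,
                                           rep(1, n_sites + 1L)))
      starts <- cumsum(c(1L + slack[1],
                         if (n_sites > 1)
                           rep(gl + min_gap, n_sites - 1L) +
                             slack[2:n_sites] else integer(0)))
    }
  })
  w <- .chars(reverse_complement(tasirna))
  for (s in starts) backbone[s:(s + gl - 1L)] <- w
  list(
    id = sprintf("synthetic_mRNA_seed%d", as.integer(seed)),
    seq = paste(backbone, collapse = ""),
    truth_sites = data.frame(start = starts, end = starts + gl - 1L)
  )
}
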