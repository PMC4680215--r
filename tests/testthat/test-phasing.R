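test_that("register enumeration from the dual-site coordinates yields 8", {
  # 5' site ends at 312, scissile bond at 481/482 on the 3' site
  regs <- enumerate_registers(cleavage_5p_end = 481, region_start = 313)
  expect_equal(nrow(regs), 8)
  expect_equal(regs$name, sprintf("5'D%d+", 1:8))
  expect_equal(regs$start[8], 461L)
  expect_equal(regs$end[8], 481L)
  expect_equal(regs$start[1], 314L)  # incomplete leading window dropped
})

test_that("register count follows the floor formula and edge cases", {
  expect_equal(nrow(enumerate_registers(42, 1)), 2)   # region of 42 nt
  expect_equal(nrow(enumerate_registers(20, 1)), 0)   # shorter than phase
  expect_error(enumerate_registers(10, 20), "region_start")
  set.seed(91)
  for (i in 1:50) {
    rs <- sample(1:500, 1)
    ce <- rs + sample(0:300, 1)
    ph <- sample(c(21L, 24L), 1)
    m <- nrow(enumerate_registers(ce, rs, phase = ph))
    expect_equal(m, (ce - rs + 1L) %/% ph)
  }
})

test_that("plus-strand registers tile contiguously and end at the bond", {
  set.seed(92)
  for (i in 1:20) {
    rs <- sample(1:100, 1)
    ce <- rs + 21L * sample(1:9, 1) + sample(0:20, 1)
    regs <- enumerate_registers(ce, rs)
    if (nrow(regs) == 0) next
    expect_equal(regs$end[nrow(regs)], ce)
    expect_true(all(diff(regs$start) == 21L))
    expect_true(all(regs$end - regs$start + 1L == 21L))
    expect_true(all(regs$start[-1] == regs$end[-nrow(regs)] + 1L))
    expect_gte(regs$start[1], rs)
  }
})

test_that("register sequences are cut from the transcript", {
  loc <- make_tas_locus(seed = 103, guide = test_guide, n_registers = 5)
  regs <- loc$truth_registers
  expect_equal(nrow(regs), 5)
  expect_equal(regs$sequence,
               substring(loc$transcript, regs$start, regs$end))
})

test_that("minus-strand partners apply the duplex overhang offset", {
  set.seed(93)
  tr <- random_rna(80)
  plus <- data.frame(index = 1L, name = "5'D1+", strand = "+",
                     start = 10L, end = 30L,
                     sequence = substr(tr, 10, 30))
  minus2 <- minus_strand_registers(plus, tr, overhang = 2)
  expect_equal(minus2$sequence, reverse_complement(substr(tr, 12, 32)))
  expect_equal(minus2$name, "5'D1-")
  minus0 <- minus_strand_registers(plus, tr, overhang = 0)
  expect_equal(minus0$sequence, reverse_complement(substr(tr, 10, 30)))
  # partner running past the transcript end is dropped, not clipped
  plus_edge <- plus
  plus_edge$start <- 60L; plus_edge$end <- 80L
  plus_edge$sequence <- substr(tr, 60, 80)
  expect_equal(nrow(minus_strand_registers(plus_edge, tr, overhang = 2)), 0)
})

test_that("simulated minus-strand reads all match a minus register", {
  loc <- make_tas_locus(seed = 104, guide = test_guide)
  sim <- simulate_phased_reads(loc, depth = 500, in_phase_fraction = 1,
                               minus_strand_fraction = 1, seed = 5)
  minus <- minus_strand_registers(loc$truth_registers, loc$transcript)
  expect_true(all(sim$reads$seq %in%
                    c(minus$sequence, loc$truth_registers$sequence)))
  expect_gt(sum(sim$reads$seq %in% minus$sequence), 0)
})

test_that("assign_reads separates in-phase, off-phase and foreign reads", {
  loc <- make_tas_locus(seed = 105, guide = test_guide)
  regs <- rbind(loc$truth_registers,
                minus_strand_registers(loc$truth_registers, loc$transcript))
  # pure in-phase simulation: zero off-phase, counts equal truth
  sim <- simulate_phased_reads(loc, depth = 800, in_phase_fraction = 1,
                               seed = 6)
  pt <- assign_reads(sim$reads, regs, loc$transcript,
                     loc$region_start, loc$region_end)
  expect_s3_class(pt, "phasing_table")
  expect_equal(pt$off_phase_raw, 0L)
  got <- setNames(pt$counts$raw_count, pt$counts$name)
  want <- setNames(sim$truth_counts$count, sim$truth_counts$name)
  expect_equal(got[names(want)], want)
  expect_equal(pt$total_raw, 800L)

  # a register sequence with one mismatch is off-phase under exact matching
  mm <- regs$sequence[1]
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "U"), substr(mm, 5, 5))[1]
  one_off <- assign_reads(data.frame(seq = mm, count = 3L), regs,
                          loc$transcript, loc$region_start, loc$region_end)
  expect_equal(sum(one_off$counts$raw_count), 0L)
  # not a substring of the region on either strand -> ignored entirely
  expect_true(one_off$off_phase_raw %in% c(0L, 3L))

  # an off-register substring of the region is off-phase
  off_seq <- substr(loc$transcript, loc$region_start + 3L,
                    loc$region_start + 23L)
  off <- assign_reads(data.frame(seq = off_seq, count = 2L), regs,
                      loc$transcript, loc$region_start, loc$region_end)
  expect_equal(off$off_phase_raw, 2L)
  expect_equal(sum(off$counts$raw_count), 0L)

  # a read from elsewhere on the transcript maps nowhere
  foreign <- substr(loc$transcript, 1, 21)
  f <- assign_reads(data.frame(seq = foreign, count = 5L), regs,
                    loc$transcript, loc$region_start, loc$region_end)
  expect_equal(f$total_raw, 0L)
})

test_that("assign_reads reports raw and collapsed tallies", {
  loc <- make_tas_locus(seed = 106, guide = test_guide)
  regs <- loc$truth_registers
  reads <- data.frame(seq = c(regs$sequence[1], regs$sequence[2]),
                      count = c(10L, 1L))
  pt <- assign_reads(reads, regs, loc$transcript,
                     loc$region_start, loc$region_end)
  expect_equal(pt$counts$raw_count[1:2], c(10L, 1L))
  expect_equal(pt$counts$collapsed_count[1:2], c(1L, 1L))
  expect_equal(pt$total_raw, 11L)
  expect_equal(pt$total_collapsed, 2L)
})

test_that("parameter recovery: dominant register is true at high depth", {
  loc <- make_tas_locus(seed = 107, guide = test_guide)
  regs <- rbind(loc$truth_registers,
                minus_strand_registers(loc$truth_registers, loc$transcript))
  sim <- simulate_phased_reads(loc, depth = 1500, in_phase_fraction = 0.85,
                               seed = 8)
  pt <- assign_reads(sim$reads, regs, loc$transcript,
                     loc$region_start, loc$region_end)
  got <- setNames(pt$counts$raw_count, pt$counts$name)
  want <- setNames(sim$truth_counts$count, sim$truth_counts$name)
  expect_equal(got[names(want)], want)  # exact under exact matching
  top <- pt$counts$name[which.max(pt$counts$raw_count)]
  expect_true(top %in% sim$truth_counts$name[sim$truth_counts$count > 0])
  expect_equal(pt$off_phase_raw, sim$off_phase_truth)
})

test_that("phasing p-value follows the stated edge cases", {
  loc <- make_tas_locus(seed = 108, guide = test_guide, n_registers = 8)
  regs <- loc$truth_registers
  expect_equal(loc$region_end - loc$region_start + 1L, 168L)
  # zero mapped reads -> 1.0
  empty <- assign_reads(data.frame(seq = "ACGUACGUACGUACGUACGUA",
                                   count = 1L)[0, ], regs,
                        loc$transcript, loc$region_start, loc$region_end)
  expect_equal(phasing_pvalue(empty), 1.0)
  # 100 reads all at in-phase positions in a 168-nt region
  allin <- assign_reads(
    data.frame(seq = regs$sequence[1:4], count = c(40L, 30L, 20L, 10L)),
    regs, loc$transcript, loc$region_start, loc$region_end)
  expect_equal(allin$total_raw, 100L)
  expect_lt(phasing_pvalue(allin, region_length = 168L), 1e-30)
})

test_that("phasing p-value is monotone in the in-phase count", {
  # fixed totals, increasing in-phase reads -> non-increasing p
  p <- vapply(0:50, function(x) {
    tab <- structure(list(counts = data.frame(raw_count = x),
                          total_raw = 50L, region_length = 168L),
                     class = "phasing_table")
    phasing_pvalue(tab)
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-12))
  expect_equal(p[1], 1.0)
})

test_that("phasing p-value is calibrated under the uniform null", {
  loc <- make_tas_locus(seed = 109, guide = test_guide)
  regs <- rbind(loc$truth_registers,
                minus_strand_registers(loc$truth_registers, loc$transcript))
  n_ok <- 0L
  for (s in 1:100) {
    sim <- simulate_phased_reads(loc, depth = 60, in_phase_fraction = 0.05,
                                 seed = 1000L + s)
    pt <- assign_reads(sim$reads, regs, loc$transcript,
                       loc$region_start, loc$region_end)
    if (phasing_pvalue(pt) > 0.05) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 90L)
})

test_that("phasing TSV and register GFF3 writers emit the table layout", {
  loc <- make_tas_locus(seed = 110, guide = test_guide)
  regs <- rbind(loc$truth_registers,
                minus_strand_registers(loc$truth_registers, loc$transcript))
  sim <- simulate_phased_reads(loc, depth = 300, seed = 9)
  pt <- assign_reads(sim$reads, regs, loc$transcript,
                     loc$region_start, loc$region_end)
  pt$phasing_p <- phasing_pvalue(pt)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_phasing_tsv(pt, tsv)
  lines <- readLines(tsv)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("name", "strand", "start", "end", "sequence",
                 "raw_count", "collapsed_count"))
  expect_equal(sum(!startsWith(lines, "#")) - 1L, nrow(regs))
  expect_true(any(grepl("^# phasing_p=", lines)))

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_registers_gff3(regs, gff, seqid = loc$transcript_id)
  glines <- readLines(gff)
  expect_equal(glines[1], "##gff-version 3")
  body <- strsplit(glines[-1], "\t")
  expect_true(all(lengths(body) == 9))
  expect_true(all(vapply(body, `[`, character(1), 3) == "tasiRNA"))
  expect_setequal(vapply(body, `[`, character(1), 7), c("+", "-"))
})
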