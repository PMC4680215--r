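# Independent brute-force oracle for duplex scoring and window scanning.
# Deliberately shares no code with the package: per-position loops and a
# literal pair table, used to cross-check the vectorized scanner.

oracle_state <- function(g, t) {
  # g, t: single RNA characters; guide base vs the transcript base it faces
  wc <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
  gu <- c(GU = TRUE, UG = TRUE)
  key <- paste0(g, t)
  if (isTRUE(wc[key])) "WC" else if (isTRUE(gu[key])) "GU" else "MISMATCH"
}

oracle_score_window <- function(guide, window) {
  # guide and window as RNA character scalars, equal length, antiparallel
  gc <- strsplit(guide, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  L <- length(gc)
  pen <- 0
  states <- character(L)
  for (i in seq_len(L)) {
    st <- oracle_state(gc[i], wc[L - i + 1])
    states[i] <- st
    w <- switch(st, WC = 0, GU = 0.5, MISMATCH = 1)
    if (i >= 2 && i <= 13) w <- w * 2
    pen <- pen + w
  }
  list(penalty = pen, states = states,
       cleavable = L >= 11 && all(states[9:11] == "WC"))
}

oracle_scan <- function(guide, transcript, max_penalty) {
  L <- nchar(guide)
  n <- nchar(transcript) - L + 1
  rows <- list()
  for (s in seq_len(n)) {
    win <- substr(transcript, s, s + L - 1)
    sc <- oracle_score_window(guide, win)
    if (sc$penalty <= max_penalty) {
      rows[[length(rows) + 1]] <- data.frame(
        start = as.integer(s), end = as.integer(s + L - 1),
        penalty = sc$penalty, cleavable = sc$cleavable)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      penalty = numeric(0), cleavable = logical(0)))
  }
  do.call(rbind, rows)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A miR390-like 21-mer used as the standard guide across synthetic tests.
test_guide <- "AAGCUCAGGAGGGAUAGCGCC"
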