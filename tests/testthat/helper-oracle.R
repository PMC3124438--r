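# Independent brute-force oracle for the wraparound aligner: fitting
# alignment of the segment against an explicitly unrolled repetition of the
# motif (free leading/trailing text, penalized internal gaps), unrolled
# until the score stabilizes.
oracle_wrap_score <- function(segment, motif, match = 2, mismatch = 3,
                              indel = 5) {
  s <- strsplit(segment, "")[[1]]
  n <- length(s)
  m <- nchar(motif)
  fit <- function(units) {
    Tn <- n + units * m
    text <- strsplit(strrep(motif, ceiling(Tn / m)), "")[[1]][seq_len(Tn)]
    dp <- matrix(-Inf, n + 1, Tn + 1)
    dp[1, ] <- 0
    for (i in seq_len(n)) {
      dp[i + 1, 1] <- dp[i, 1] - indel
      for (t in seq_len(Tn)) {
        sc <- if (s[i] == text[t] && s[i] != "N") match else -mismatch
        dp[i + 1, t + 1] <- max(dp[i, t] + sc, dp[i, t + 1] - indel,
                                dp[i + 1, t] - indel)
      }
    }
    max(dp[n + 1, ])
  }
  best <- fit(1)
  units <- 2
  stable <- 0
  repeat {
    nxt <- fit(units)
    if (nxt <= best) stable <- stable + 1 else stable <- 0
    if (stable >= 2) return(best)
    best <- max(best, nxt)
    units <- units + 1
  }
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Reverse complement for plain strings (test-side, independent of package
# internals).
rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Score-maximal boundaries of a planted tandem array, computed by an
# exhaustive Smith-Waterman of the planted window (truth interval plus a
# short flank) against the explicitly unrolled planted motif — a
# brute-force, traceback-by-origin local DP fully independent of the
# package's wraparound implementation. Returns boundaries in read
# coordinates.
effective_truth_bounds <- function(read, tr_start, tr_end, motif,
                                   flank = 15L, match = 2, mismatch = 3,
                                   indel = 5) {
  w_start <- max(1L, tr_start - flank)
  w_end <- min(nchar(read), tr_end + flank)
  s <- strsplit(substr(read, w_start, w_end), "")[[1]]
  n <- length(s)
  m <- nchar(motif)
  Tn <- n + 2L * m
  text <- strsplit(strrep(motif, ceiling(Tn / m) + 1), "")[[1]][seq_len(Tn)]
  dp <- matrix(0, n + 1, Tn + 1)
  org <- matrix(rep(1:(n + 1), Tn + 1), n + 1, Tn + 1)  # segment start + 1
  best <- 0; bi <- 1L; borg <- 1L
  for (i in 2:(n + 1)) {
    for (t in 2:(Tn + 1)) {
      sc <- if (s[i - 1] == text[t - 1] && s[i - 1] != "N") match else -mismatch
      v_diag <- dp[i - 1, t - 1] + sc
      v_up <- dp[i - 1, t] - indel
      v_left <- dp[i, t - 1] - indel
      v <- max(0, v_diag, v_up, v_left)
      dp[i, t] <- v
      org[i, t] <- if (v == 0) i
      else if (v == v_diag) {
        if (dp[i - 1, t - 1] == 0) i - 1 else org[i - 1, t - 1]
      } else if (v == v_up) org[i - 1, t]
      else org[i, t - 1]
      if (v > best) { best <- v; bi <- i; borg <- org[i, t] }
    }
  }
  c(start = w_start + borg - 1L, end = w_start + bi - 2L)
}
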