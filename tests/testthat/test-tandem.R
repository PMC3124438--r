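test_that("wraparound alignment scores the textbook cases", {
  expect_equal(wraparound_align("AGAGAG", "AG")$score, 12)
  a <- wraparound_align("AGAGCG", "AG")
  expect_equal(a$score, 7)               # 5 matches - 1 mismatch = 10 - 3
  expect_equal(a$purity, 5 / 6)
  # indels: AG AG A G -> one deletion relative to (AGA)xN
  expect_equal(wraparound_align("AGAG", "AG")$score, 8)
  # empty motif rejected
  expect_error(wraparound_align("ACGT", ""), "non-empty")
})

test_that("wraparound DP equals the exhaustive unrolled oracle", {
  set.seed(42)
  for (k in 1:500) {
    seg <- random_dna_str(sample(5:30, 1))
    motif <- random_dna_str(sample(2:6, 1))
    expect_equal(wraparound_align(seg, motif)$score,
                 oracle_wrap_score(seg, motif),
                 info = paste(seg, motif))
  }
})

test_that("candidate scan covers planted perfect arrays", {
  set.seed(7)
  for (k in 1:200) {
    d <- sample(1:6, 1)
    copies <- ceiling(12 / d) + sample(0:10, 1)
    array <- strrep(substr("ACGTAC", 1, d), copies)
    array <- substr(array, 1, max(12, d * 2))
    left <- random_dna_str(sample(10:80, 1))
    right <- random_dna_str(sample(10:80, 1))
    seq <- paste0(left, array, right)
    cands <- find_candidate_periods(seq, detector_params())
    a_start <- nchar(left) + 1
    a_end <- nchar(left) + nchar(array)
    covering <- cands[cands$period == d & cands$start <= a_start &
                        cands$end >= a_end, ]
    expect_gt(nrow(covering), 0)
  }
})

test_that("homopolymers and simple arrays are called with exact stats", {
  arr <- call_tandem_arrays(strrep("AG", 30))
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 2)
  expect_equal(arr$score, 120)
  expect_equal(arr$purity, 1)
  expect_equal(arr$copy_number, 30)
  # 12 copies (24 bp) scores 48 < 50: filtered under defaults
  expect_equal(nrow(call_tandem_arrays(strrep("AG", 12))), 0)
  # but survives an explicit min_score = 24
  low <- detector_params(min_score = 24)
  expect_equal(nrow(call_tandem_arrays(strrep("AG", 12), low)), 1)
  # 60-bp homopolymer: candidate period 1, called
  hp <- call_tandem_arrays(paste0(random_dna_str(30), strrep("A", 60),
                                  random_dna_str(30)))
  expect_true(any(hp$period == 1 & hp$motif == "A"))
})

test_that("purity filter removes at 0.55 and keeps above", {
  arrays <- data.frame(purity = c(0.55, 0.551, 0.9, 0.2),
                       id = 1:4)
  kept <- filter_by_purity(arrays, detector_params())
  expect_equal(kept$id, c(2, 3))
})

test_that("reported arrays re-score to their reported score", {
  set.seed(13)
  reads <- vapply(1:10, function(i) {
    paste0(random_dna_str(60), strrep("ACT", 25), random_dna_str(60))
  }, character(1))
  names(reads) <- paste0("r", 1:10)
  arr <- scan_tandem_arrays(reads)
  expect_gt(nrow(arr), 0)
  for (i in seq_len(nrow(arr))) {
    seg <- substr(reads[[arr$read_id[i]]], arr$start[i], arr$end[i])
    re <- wraparound_align(seg, arr$motif[i])
    expect_equal(re$score, arr$score[i])
  }
})

test_that("raising min_score never increases the number of arrays", {
  set.seed(19)
  read <- paste0(random_dna_str(100), strrep("AAG", 20), random_dna_str(50),
                 strrep("AC", 14), random_dna_str(100))
  counts <- vapply(c(24, 50, 80, 120), function(ms) {
    nrow(call_tandem_arrays(read, detector_params(min_score = ms)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is symmetric under reverse complement", {
  set.seed(23)
  for (k in 1:10) {
    read <- paste0(random_dna_str(80), strrep("AGT", 25), random_dna_str(40),
                   strrep("TC", 20), random_dna_str(80))
    fwd <- call_tandem_arrays(read)
    rev <- call_tandem_arrays(rc(read))
    expect_equal(nrow(fwd), nrow(rev))
    n <- nchar(read)
    mirrored <- data.frame(start = n - rev$end + 1, end = n - rev$start + 1,
                           period = rev$period,
                           canonical = rev$canonical_motif)
    mirrored <- mirrored[order(mirrored$start), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$end, mirrored$end)
    expect_equal(fwd$period, mirrored$period)
    expect_equal(fwd$canonical_motif, mirrored$canonical)
  }
})

test_that("same-period arrays never overlap by more than one unit", {
  set.seed(29)
  for (k in 1:10) {
    read <- paste0(strrep("CT", 38), random_dna_str(12), strrep("CA", 14),
                   random_dna_str(60), strrep("AAT", 30))
    arr <- call_tandem_arrays(read)
    if (nrow(arr) < 2) next
    for (i in 1:(nrow(arr) - 1)) for (j in (i + 1):nrow(arr)) {
      if (arr$period[i] != arr$period[j]) next
      ov <- min(arr$end[i], arr$end[j]) - max(arr$start[i], arr$start[j]) + 1
      expect_lte(ov, max(arr$period[i], arr$period[j]))
    }
  }
})

test_that("adjacent compound arrays are reported separately", {
  # (CT)38 ... 12 bp ... (CA)14, the classic compound locus layout
  read <- paste0(random_dna_str(30), strrep("CT", 38), random_dna_str(12),
                 strrep("CA", 14), random_dna_str(30))
  arr <- call_tandem_arrays(read)
  expect_setequal(arr$canonical_motif, c("AG", "AC"))
  expect_equal(nrow(arr), 2)
})

test_that("alignments do not cross runs of >= 2 N", {
  read <- paste0(strrep("AG", 20), "NN", strrep("AG", 20))
  arr <- call_tandem_arrays(read)
  expect_equal(nrow(arr), 2)
  expect_true(all(arr$end <= 40 | arr$start >= 43))
})

test_that("mutated planted arrays are recovered near their boundaries", {
  set.seed(31)
  recovered <- 0; total <- 0
  for (k in 1:60) {
    motif <- c("AG", "AAT", "AC", "AAG", "ACGT")[sample(5, 1)]
    copies <- ceiling(60 / nchar(motif))
    pure <- strrep(motif, copies)
    mut <- strsplit(pure, "")[[1]]
    nmut <- rbinom(1, length(mut), 0.1)
    if (nmut > 0) {
      pos <- sample(length(mut), nmut)
      mut[pos] <- vapply(mut[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    array <- paste(mut, collapse = "")
    left <- random_dna_str(60); right <- random_dna_str(60)
    read <- paste0(left, array, right)
    arr <- call_tandem_arrays(read)
    total <- total + 1
    a_start <- nchar(left) + 1; a_end <- nchar(left) + nchar(array)
    eff <- effective_truth_bounds(read, a_start, a_end, motif)
    hit <- arr[arr$canonical_motif %in% canonical_motif(motif) &
                 abs(arr$start - eff["start"]) <= nchar(motif) &
                 abs(arr$end - eff["end"]) <= nchar(motif), ]
    if (nrow(hit) > 0) recovered <- recovered + 1
  }
  expect_gte(recovered / total, 0.9)
})

test_that("masking replaces array spans with N", {
  reads <- c(r1 = paste0("ACGTACGTAC", strrep("AG", 30), "ACGTACGTAC"))
  arr <- scan_tandem_arrays(reads)
  masked <- mask_tandem_arrays(reads, arr)
  expect_equal(substr(masked[["r1"]], arr$start[1], arr$end[1]),
               strrep("N", arr$end[1] - arr$start[1] + 1))
  expect_equal(substr(masked[["r1"]], 1, 10), "ACGTACGTAC")
})

test_that("GFF3 round-trips coordinates and attributes", {
  reads <- c(r1 = paste0(strrep("ACT", 30), random_dna_str(50)))
  arr <- scan_tandem_arrays(reads)
  f <- tempfile(fileext = ".gff3")
  write_tandem_gff3(arr, f)
  gr <- rtracklayer::import(f)
  expect_equal(GenomicRanges::start(gr), arr$start)
  expect_equal(GenomicRanges::end(gr), arr$end)
  expect_equal(as.integer(gr$period), arr$period)
  unlink(f)
})

test_that("malformed sequences are rejected", {
  expect_error(call_tandem_arrays("ACGU"), "non-ACGTN")
  expect_error(call_tandem_arrays(""), "non-empty")
})
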