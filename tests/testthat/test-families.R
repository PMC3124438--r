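# Shared synthetic read set with two planted families (built once; reused
# across the family-pipeline tests below).
fam_sim <- local({
  cfg <- sim_config(n_reads = 180, seed = 101,
                    planted_ssrs = list(ssr_plant("AG", 40, 0.02,
                                                  n_loci = 10)),
                    planted_families = list(
                      family_plant("famA", 500, 25, 0.05),
                      family_plant("famB", 300, 22, 0.10)))
  sim <- simulate_reads(cfg)
  arr <- scan_tandem_arrays(sim$reads)
  masked <- mask_tandem_arrays(sim$reads, arr)
  fp <- family_params()
  hits <- allpairs_search(masked, fp, arr)
  list(sim = sim, arrays = arr, masked = masked, hits = hits, fp = fp)
})

test_that("all-vs-all search finds planted homology and is symmetric", {
  hits <- fam_sim$hits
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$read_a != hits$read_b))
  expect_true(all(hits$identity >= fam_sim$fp$min_hit_identity))
  expect_true(all(hits$end_a - hits$start_a + 1 >=
                    fam_sim$fp$min_hit_length))
  # symmetry: every (a, b) hit has its (b, a) mirror
  key <- paste(hits$read_a, hits$read_b, hits$start_a, hits$end_a,
               hits$start_b, hits$end_b)
  mirror <- paste(hits$read_b, hits$read_a, hits$start_b, hits$end_b,
                  hits$start_a, hits$end_a)
  expect_true(all(mirror %in% key))
  # planted 500-bp element shared by two reads is covered >= 80%
  fam <- fam_sim$sim$truth[fam_sim$sim$truth$label == "famA", ]
  covered <- 0
  for (i in seq_len(nrow(fam))) {
    h <- hits[hits$read_a == fam$read_id[i] &
                hits$start_a <= fam$end[i] & hits$end_a >= fam$start[i], ]
    if (nrow(h) == 0) next
    span <- sum(pmin(h$end_a, fam$end[i]) - pmax(h$start_a, fam$start[i]) + 1)
    if (max(pmin(h$end_a, fam$end[i]) - pmax(h$start_a, fam$start[i]) + 1) >=
          0.8 * (fam$end[i] - fam$start[i] + 1)) covered <- covered + 1
  }
  expect_gte(covered / nrow(fam), 0.9)
})

test_that("random background reads produce no hits at default floors", {
  set.seed(111)
  reads <- vapply(1:60, function(i) random_dna_str(500, 0.46), character(1))
  names(reads) <- paste0("bg", 1:60)
  hits <- allpairs_search(reads, family_params())
  expect_equal(nrow(hits), 0)
})

test_that("identical reads give a full-length cross-pair hit only", {
  s <- random_dna_str(400, 0.46)
  reads <- c(a = s, b = s)
  hits <- allpairs_search(reads, family_params())
  expect_true(all(hits$read_a != hits$read_b))
  expect_gte(max(hits$end_a - hits$start_a + 1), 395)
})

test_that("elements aggregate agreeing hits and keep distinct loci apart", {
  fp <- family_params()
  hits <- data.frame(
    read_a = rep("r1", 3), read_b = c("r2", "r3", "r4"),
    start_a = c(100, 105, 95), end_a = c(400, 408, 402),
    start_b = 1, end_b = 301, orientation = "same",
    identity = 0.9, score = 100, stringsAsFactors = FALSE)
  el <- define_elements(hits, fp)
  el1 <- el[el$read_id == "r1", ]
  expect_equal(nrow(el1), 1)
  expect_equal(el1$start, 100)   # median endpoint
  expect_equal(el1$end, 402)
  # far-apart intervals stay separate
  hits2 <- rbind(hits, data.frame(read_a = "r1", read_b = "r5",
                                  start_a = 600, end_a = 900, start_b = 1,
                                  end_b = 301, orientation = "same",
                                  identity = 0.9, score = 100))
  el2 <- define_elements(hits2, fp)
  expect_equal(nrow(el2[el2$read_id == "r1", ]), 2)
})

test_that("planted families are recovered with accurate counts and consensi", {
  fp <- fam_sim$fp
  fams <- cluster_families(define_elements(fam_sim$hits, fp),
                           fam_sim$hits, fp)
  fams <- filter_families(fams, fp)
  expect_equal(nrow(fams$families), 2)
  counts <- sort(fams$families$count)
  expect_lte(abs(counts[1] - 22) / 22, 0.1)   # famB: 22 copies +- 10%
  expect_lte(abs(counts[2] - 25) / 25, 0.1)   # famA: 25 copies +- 10%
  fams <- build_consensus(fams, fam_sim$sim$reads, fp)
  fams <- curate_families(fams, fam_sim$sim$reads, fam_sim$hits, fp)
  # consensus within 5% of the planted truth (>= 95% identity)
  for (fid in fams$families$family_id) {
    cons <- fams$consensus[[fid]]
    pid <- max(vapply(fam_sim$sim$family_consensi, function(tc) {
      max(Biostrings::pid(Biostrings::pairwiseAlignment(cons, tc,
                                                        type = "local")),
          Biostrings::pid(Biostrings::pairwiseAlignment(cons, rc(tc),
                                                        type = "local")))
    }, numeric(1)))
    expect_gte(pid, 95)
  }
  # element disjointness: total family bp never exceeds the survey
  acct <- family_accounting(fams, sum(nchar(fam_sim$sim$reads)), 0.01)
  expect_lte(acct$total$total_length, sum(nchar(fam_sim$sim$reads)))
})

test_that("clustering is invariant to read input order", {
  fp <- fam_sim$fp
  base <- filter_families(
    cluster_families(define_elements(fam_sim$hits, fp), fam_sim$hits, fp), fp)
  perm_hits <- fam_sim$hits[rev(seq_len(nrow(fam_sim$hits))), ]
  perm <- filter_families(
    cluster_families(define_elements(perm_hits, fp), perm_hits, fp), fp)
  sig <- function(f) {
    m <- f$elements[order(f$elements$read_id, f$elements$start),
                    c("read_id", "start", "end")]
    rownames(m) <- NULL
    list(counts = sort(f$families$count), members = m)
  }
  expect_equal(sig(base), sig(perm))
})

test_that("count filter keeps 20 and drops 19, monotonically", {
  fams <- structure(list(
    families = data.frame(family_id = c("F1", "F2", "F3"),
                          count = c(25, 20, 19)),
    elements = data.frame(element_id = 1:64,
                          read_id = paste0("r", 1:64),
                          start = 1L, end = 100L,
                          family_id = rep(c("F1", "F2", "F3"), c(25, 20, 19)),
                          orientation = "+"),
    consensus = character(0)), class = "repeat_families")
  kept <- filter_families(fams, family_params())
  expect_setequal(kept$families$family_id, c("F1", "F2"))
  stricter <- filter_families(fams, family_params(min_family_count = 25))
  expect_true(all(stricter$families$family_id %in% kept$families$family_id))
  empty <- filter_families(fams, family_params(min_family_count = 99))
  expect_equal(nrow(empty$families), 0)
})

test_that("consensus of identical copies is exact with alphabetical ties", {
  s <- random_dna_str(200, 0.5)
  reads <- c(a = s, b = s, c = s)
  fams <- structure(list(
    families = data.frame(family_id = "F1", count = 3),
    elements = data.frame(element_id = 1:3, read_id = c("a", "b", "c"),
                          start = 1L, end = 200L, family_id = "F1",
                          orientation = "+"),
    consensus = character(0)), class = "repeat_families")
  fams <- build_consensus(fams, reads, family_params())
  expect_equal(fams$consensus[["F1"]], s)
  # 50/50 split at one column resolves to the alphabetically first base
  s2 <- s; substr(s2, 50, 50) <- "A"
  s3 <- s; substr(s3, 50, 50) <- "T"
  reads2 <- c(a = s2, b = s2, c = s3, d = s3)
  fams2 <- structure(list(
    families = data.frame(family_id = "F1", count = 4),
    elements = data.frame(element_id = 1:4,
                          read_id = c("a", "b", "c", "d"),
                          start = 1L, end = 200L, family_id = "F1",
                          orientation = "+"),
    consensus = character(0)), class = "repeat_families")
  fams2 <- build_consensus(fams2, reads2, family_params())
  expect_equal(substr(fams2$consensus[["F1"]], 50, 50), "A")
})

test_that("curation merges an artificially split family and is idempotent", {
  fp <- fam_sim$fp
  fams <- filter_families(
    cluster_families(define_elements(fam_sim$hits, fp), fam_sim$hits, fp),
    fp)
  fams <- build_consensus(fams, fam_sim$sim$reads, fp)
  # artificially split the largest family into two halves
  big <- fams$families$family_id[which.max(fams$families$count)]
  el <- fams$elements
  members <- which(el$family_id == big)
  el$family_id[members[seq_len(floor(length(members) / 2))]] <- "SPLIT"
  fams$elements <- el
  fam <- as.data.frame(table(el$family_id), stringsAsFactors = FALSE)
  names(fam) <- c("family_id", "count")
  fams$families <- fam
  fams <- build_consensus(fams, fam_sim$sim$reads, fp)
  n_before <- nrow(fams$families)
  cur <- curate_families(fams, fam_sim$sim$reads, fam_sim$hits, fp)
  expect_equal(nrow(cur$families), n_before - 1)   # halves re-merged
  # unrelated families stay apart, and curation is a fixed point
  cur2 <- curate_families(cur, fam_sim$sim$reads, fam_sim$hits, fp)
  expect_equal(sort(cur$families$count), sort(cur2$families$count))
})

test_that("exclusion screening sets aside rRNA-like consensi", {
  rrna <- random_dna_str(400, 0.55)
  fams <- structure(list(
    families = data.frame(family_id = c("F1", "F2"), count = c(3, 3)),
    elements = data.frame(element_id = 1:6,
                          read_id = paste0("r", 1:6), start = 1L,
                          end = 150L,
                          family_id = rep(c("F1", "F2"), each = 3),
                          orientation = "+"),
    consensus = c(F1 = substr(rrna, 51, 250),
                  F2 = random_dna_str(200, 0.45))),
    class = "repeat_families")
  f <- tempfile(fileext = ".fasta")
  write_reads_fasta(c(rRNA_18S = rrna), f)
  scr <- screen_exclusion(fams, f)
  expect_equal(scr$excluded$families$family_id, "F1")
  expect_equal(scr$kept$families$family_id, "F2")
  # no exclusion file: everything kept
  scr0 <- screen_exclusion(fams, NULL)
  expect_equal(scr0$kept$families$family_id, c("F1", "F2"))
  expect_error(screen_exclusion(fams, tempfile()), "not found")
  unlink(f)
})

test_that("internal tandem scan reports unit and copies of embedded arrays", {
  set.seed(121)
  unit <- random_dna_str(21, 0.5)
  cons <- paste0(random_dna_str(60), strrep(unit, 20),
                 substr(unit, 1, round(0.4 * 21)), random_dna_str(60))
  scan <- internal_tandem_scan(cons)
  expect_true(any(scan$unit == 21 & abs(scan$copies - 20.4) <= 0.5))
  # exact doubling reports 2.0 copies (flanks chosen so the score-maximal
  # alignment cannot absorb them: the unit has no T, the flanks are all T)
  unit2 <- paste(sample(c("A", "C", "G"), 30, replace = TRUE), collapse = "")
  cons2 <- paste0(strrep("T", 40), strrep(unit2, 2), strrep("T", 40))
  scan2 <- internal_tandem_scan(cons2)
  expect_true(any(scan2$unit == 30 & scan2$copies == 2.0))
  # tandem-free random consensi stay empty
  empty_hits <- 0
  for (k in 1:5) {
    if (nrow(internal_tandem_scan(random_dna_str(300, 0.46))) == 0)
      empty_hits <- empty_hits + 1
  }
  expect_gte(empty_hits, 4)
})

test_that("family accounting extrapolates copies by the sampling fraction", {
  fams <- structure(list(
    families = data.frame(family_id = "F1", count = 400),
    elements = data.frame(element_id = 1:400,
                          read_id = paste0("r", 1:400), start = 1L,
                          end = 500L, family_id = "F1", orientation = "+"),
    consensus = c(F1 = "ACGT")), class = "repeat_families")
  acct <- family_accounting(fams, surveyed_bp = 1.1e7,
                            sampling_fraction = 0.0045)
  expect_equal(acct$per_family$extrapolated_copies, 400 / 0.0045)
  expect_gt(acct$per_family$extrapolated_copies, 80000)
  # a single family spanning the whole survey is 100% of it
  one <- structure(list(
    families = data.frame(family_id = "F1", count = 1),
    elements = data.frame(element_id = 1L, read_id = "r1", start = 1L,
                          end = 1000L, family_id = "F1", orientation = "+"),
    consensus = c(F1 = "ACGT")), class = "repeat_families")
  expect_equal(family_accounting(one, 1000, 1)$total$genome_fraction_pct,
               100)
  expect_error(family_accounting(one, 1000, 0), "sampling_fraction")
})

test_that("category totals reproduce combined-fraction arithmetic", {
  cats <- c(non_ltr = 643931, penelope = 378442, ltr = 157441,
            dna_transposon = 14817, viral = 2399849, unknown = 1285643,
            microsatellite = 807927)
  tot <- repeat_category_totals(cats, 11114786)
  expect_equal(tot$total_bp, 5688050)
  expect_equal(round(tot$total_pct, 2), 51.18)
  expect_equal(round(tot$per_category$pct[5], 2), 21.59)
})
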