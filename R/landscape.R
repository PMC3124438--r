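#' Per-motif microsatellite summary
#'
#' Aggregates called tandem arrays into one row per canonical motif class:
#' locus counts, number and percentage of reads carrying at least one locus
#' of the class (a read is counted once per class), summed bases and their
#' percentage of the surveyed length, maximum / mean / SD locus length,
#' mean repeat number (mean length / unit), relative abundance (RA%, class
#' bases over all microsatellite bases) and relative frequency (RF%, class
#' loci over all loci). RA and RF each sum to 100 over classes.
#'
#' @param arrays data.frame of tandem arrays (a `canonical_motif` column is
#'   filled from `motif` where missing).
#' @param total_reads Number of reads surveyed.
#' @param surveyed_bp Total surveyed length in bp.
#' @return data.frame sorted by unit length then label, with columns
#'   `motif`, `unit`, `counts`, `n_fes`, `pct_fes`, `bases`, `pct_bases`,
#'   `max_length`, `mean_length`, `std_length`, `mean_repeat_no`, `ra_pct`,
#'   `rf_pct`. Full precision is retained; round for display.
#' @export
summarize_by_motif <- function(arrays, total_reads, surveyed_bp) {
  if (surveyed_bp <= 0) stop("surveyed_bp must be positive")
  if (nrow(arrays) == 0) stop("no arrays to summarize")
  cm <- arrays$canonical_motif
  if (is.null(cm)) cm <- rep(NA_character_, nrow(arrays))
  fix <- is.na(cm)
  cm[fix] <- canonical_motif(arrays$motif[fix])
  len <- arrays$end - arrays$start + 1
  total_loci <- nrow(arrays)
  total_bases <- sum(len)
  rows <- lapply(split(seq_len(total_loci), cm), function(ix) {
    l <- len[ix]
    m <- cm[ix[1]]
    data.frame(
      motif = m, unit = nchar(m), counts = length(ix),
      n_fes = length(unique(arrays$read_id[ix])),
      bases = sum(l), max_length = max(l), mean_length = mean(l),
      std_length = if (length(l) > 1) sd(l) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_fes <- out$n_fes / total_reads * 100
  out$pct_bases <- out$bases / surveyed_bp * 100
  out$mean_repeat_no <- out$mean_length / out$unit
  out$ra_pct <- out$bases / total_bases * 100
  out$rf_pct <- out$counts / total_loci * 100
  out <- out[order(out$unit, out$motif),
             c("motif", "unit", "counts", "n_fes", "pct_fes", "bases",
               "pct_bases", "max_length", "mean_length", "std_length",
               "mean_repeat_no", "ra_pct", "rf_pct")]
  rownames(out) <- NULL
  out
}

#' Microsatellite density
#'
#' Kilobases of surveyed sequence per microsatellite locus, reported to two
#' decimals (e.g. one locus per 1.32 kb).
#'
#' @param total_loci Number of loci.
#' @param surveyed_bp Surveyed length, bp.
#' @return kb per locus (2 decimals).
#' @export
microsat_density <- function(total_loci, surveyed_bp) {
  if (total_loci <= 0) stop("density undefined: no loci")
  round(surveyed_bp / total_loci / 1000, 2)
}

# Length-class bins: L1 12-20, L2 21-40, ..., L10 181-200, L11 > 200 bp.
length_class_edges <- c(12, 21, 41, 61, 81, 101, 121, 141, 161, 181, 201, Inf)
length_class_labels <- paste0("L", 1:11)

#' Locus length-class histogram
#'
#' Assigns each locus to one of the 11 length classes (L1: 12-20 bp,
#' L2: 21-40, L3: 41-60, ..., L10: 181-200, L11: > 200 bp) per motif class.
#'
#' @param arrays data.frame of tandem arrays.
#' @return data.frame with `motif` and integer columns `L1`..`L11`; bin
#'   totals equal the motif's locus count.
#' @export
length_class_histogram <- function(arrays) {
  len <- arrays$end - arrays$start + 1
  if (any(len < 12))
    stop("locus length below the 12-bp detector floor")
  cm <- arrays$canonical_motif
  fix <- is.na(cm)
  cm[fix] <- canonical_motif(arrays$motif[fix])
  bin <- cut(len, breaks = c(length_class_edges[-length(length_class_edges)] - 0.5, Inf),
             labels = length_class_labels, right = FALSE)
  tab <- table(cm, bin)
  out <- data.frame(motif = rownames(tab), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame.matrix(tab))
  rownames(out) <- NULL
  out
}

#' Survey-level microsatellite landscape report
#'
#' Combines the per-motif table with survey totals: total loci, total
#' microsatellite bp and their percentage of the surveyed length, density
#' (kb per locus), mean locus length, and the A/T content of the
#' microsatellite base pairs (computed over the actual locus spans when
#' `reads` is supplied, else over the consensus units weighted by length).
#'
#' @param arrays data.frame of tandem arrays.
#' @param total_reads Number of reads surveyed.
#' @param surveyed_bp Surveyed length, bp.
#' @param reads Optional named read vector for exact A/T content.
#' @return List of class `landscape_report` with elements `per_motif`,
#'   `per_unit`, `total_loci`, `total_bases`, `genome_pct`, `density_kb`,
#'   `mean_locus_length`, `at_content_pct`, `pct_reads_with_ssr`.
#' @export
landscape_report <- function(arrays, total_reads, surveyed_bp, reads = NULL) {
  per_motif <- summarize_by_motif(arrays, total_reads, surveyed_bp)
  per_unit <- do.call(rbind, lapply(split(per_motif, per_motif$unit),
    function(g) data.frame(unit = g$unit[1], counts = sum(g$counts),
                           bases = sum(g$bases), rf_pct = sum(g$rf_pct),
                           ra_pct = sum(g$ra_pct))))
  rownames(per_unit) <- NULL
  len <- arrays$end - arrays$start + 1
  at <- if (!is.null(reads)) {
    reads <- as_read_vector(reads)
    spans <- substring(reads[arrays$read_id], arrays$start, arrays$end)
    counts <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(spans))[, c("A", "C", "G", "T"), drop = FALSE])
    100 * (counts["A"] + counts["T"]) / sum(counts)
  } else {
    atm <- vapply(strsplit(arrays$motif, ""), function(ch)
      mean(ch %in% c("A", "T")), numeric(1))
    100 * weighted.mean(atm, len)
  }
  structure(list(
    per_motif = per_motif, per_unit = per_unit,
    total_loci = nrow(arrays), total_bases = sum(len),
    genome_pct = sum(len) / surveyed_bp * 100,
    density_kb = microsat_density(nrow(arrays), surveyed_bp),
    mean_locus_length = sum(len) / nrow(arrays),
    at_content_pct = unname(at),
    pct_reads_with_ssr = length(unique(arrays$read_id)) / total_reads * 100),
    class = "landscape_report")
}

#' @export
print.landscape_report <- function(x, ...) {
  cat(sprintf("Microsatellite landscape: %d loci, %d bp (%.2f%% of survey)\n",
              x$total_loci, x$total_bases, x$genome_pct))
  cat(sprintf("  density: 1 per %.2f kb; mean locus length %.1f bp; A/T %.1f%%\n",
              x$density_kb, x$mean_locus_length, x$at_content_pct))
  cat(sprintf("  reads with >=1 locus: %.1f%%\n", x$pct_reads_with_ssr))
  cat("Top motifs by RF%:\n")
  pm <- x$per_motif[order(-x$per_motif$rf_pct), ]
  print(head(pm[, c("motif", "counts", "bases", "mean_length", "ra_pct",
                    "rf_pct")], 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare microsatellite landscapes of two sequence partitions
#'
#' Computes per-motif relative abundance within each partition (e.g.
#' genomic reads vs transcribed sequences) and the microsatellite bp per Mb
#' of each partition.
#'
#' @param arrays_a,arrays_b Array tables of the two partitions.
#' @param surveyed_a,surveyed_b Surveyed lengths, bp.
#' @return List with `ra_table` (motif, ra_pct_a, ra_pct_b, delta) and
#'   `bp_per_mb` (named numeric of length 2).
#' @export
compare_partitions <- function(arrays_a, surveyed_a, arrays_b, surveyed_b) {
  if (nrow(arrays_a) == 0 || nrow(arrays_b) == 0)
    stop("both partitions must contain at least one array")
  ra <- function(arr) {
    cm <- arr$canonical_motif
    fix <- is.na(cm)
    cm[fix] <- canonical_motif(arr$motif[fix])
    len <- arr$end - arr$start + 1
    tapply(len, cm, sum) / sum(len) * 100
  }
  ra_a <- ra(arrays_a); ra_b <- ra(arrays_b)
  motifs <- sort(union(names(ra_a), names(ra_b)))
  get0 <- function(v, m) ifelse(m %in% names(v), v[m], 0)
  tab <- data.frame(motif = motifs,
                    ra_pct_a = as.numeric(get0(ra_a, motifs)),
                    ra_pct_b = as.numeric(get0(ra_b, motifs)))
  tab$delta <- tab$ra_pct_a - tab$ra_pct_b
  bp_per_mb <- c(
    a = sum(arrays_a$end - arrays_a$start + 1) / surveyed_a * 1e6,
    b = sum(arrays_b$end - arrays_b$start + 1) / surveyed_b * 1e6)
  list(ra_table = tab, bp_per_mb = bp_per_mb)
}

#' Write the landscape report tables
#'
#' Writes the per-motif table (the standard survey column set), the
#' per-unit aggregates and the length-class histogram as TSV files.
#'
#' @param report A [landscape_report()] object.
#' @param arrays The array table the report was built from.
#' @param dir Output directory.
#' @param header Optional comment lines for provenance.
#' @return The directory, invisibly.
#' @export
write_landscape_tsv <- function(report, arrays, dir, header = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    con <- file(file.path(dir, name), "w")
    on.exit(close(con), add = TRUE)
    for (h in header) writeLines(paste0("# ", h), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pm <- report$per_motif
  num <- vapply(pm, is.numeric, logical(1))
  pm[num] <- lapply(pm[num], function(x) round(x, 2))
  wr(pm, "motif_summary.tsv")
  wr(report$per_unit, "unit_summary.tsv")
  wr(length_class_histogram(arrays), "length_classes.tsv")
  invisible(dir)
}
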