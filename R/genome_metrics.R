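#' Read a flow-cytometry fluorescence histogram
#'
#' Two-column whitespace- or comma-separated text: channel index and event
#' count per channel.
#'
#' @param file Path to the histogram file.
#' @return data.frame with `channel` and `count`, class `flow_histogram`.
#' @export
read_flow_histogram <- function(file) {
  raw <- readLines(file)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  parts <- strsplit(trimws(raw), "[,[:space:]]+")
  df <- data.frame(channel = as.numeric(vapply(parts, `[`, "", 1)),
                   count = as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(df)) stop("malformed histogram file: ", file)
  flow_histogram(df$channel, df$count)
}

#' Construct a flow histogram object
#' @param channel Integer channel (fluorescence bin) indices.
#' @param count Non-negative event counts per channel.
#' @return data.frame of class `flow_histogram`.
#' @export
flow_histogram <- function(channel, count) {
  if (any(count < 0)) stop("counts must be non-negative")
  df <- data.frame(channel = channel, count = count)
  df <- df[order(df$channel), ]
  rownames(df) <- NULL
  class(df) <- c("flow_histogram", "data.frame")
  df
}

#' Simulate a G1-peak fluorescence histogram
#'
#' Gaussian fluorescence about a G1 peak position with a given coefficient
#' of variation, binned into integer channels; emulates a typical
#' acquisition of a few thousand nuclei.
#'
#' @param peak_channel True G1 peak position (channels).
#' @param cv Coefficient of variation of the fluorescence (default 0.03).
#' @param n_events Number of nuclei (default 5000; typical acquisitions
#'   record 3000-10000).
#' @param n_channels Number of channels (default 1024).
#' @return A [flow_histogram()] object.
#' @export
simulate_flow_histogram <- function(peak_channel, cv = 0.03, n_events = 5000,
                                    n_channels = 1024) {
  x <- round(rnorm(n_events, peak_channel, cv * peak_channel))
  x <- pmin(pmax(x, 1), n_channels)
  tab <- tabulate(x, nbins = n_channels)
  flow_histogram(seq_len(n_channels), tab)
}

#' Locate the G1 peak of a flow histogram
#'
#' Smooths the histogram with a centered moving average and takes the mode;
#' the sub-channel peak position is the count-weighted centroid of the
#' contiguous region at or above half the smoothed peak height (FWHM
#' region). If a second local maximum within 5% of the peak height exists
#' outside that region, the histogram is flagged as multimodal and an
#' explicit `gate` (channel range) is required.
#'
#' @param hist A [flow_histogram()] object.
#' @param smoothing_window Moving-average window in channels (odd; 5).
#' @param gate Optional `c(lo, hi)` channel range to restrict the search.
#' @return Peak position in (fractional) channels.
#' @export
detect_g1_peak <- function(hist, smoothing_window = 5, gate = NULL) {
  stopifnot(inherits(hist, "flow_histogram"))
  if (sum(hist$count) < 500)
    stop("too few events (< 500) for peak detection")
  df <- hist
  if (!is.null(gate)) {
    df <- df[df$channel >= gate[1] & df$channel <= gate[2], ]
    if (nrow(df) == 0) stop("gate excludes all channels")
  }
  if (sum(df$count > 0) == 1)
    return(df$channel[df$count > 0])
  k <- max(1L, as.integer(smoothing_window))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(df$count, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  mode_i <- which.max(sm)
  half <- sm[mode_i] / 2
  lo <- mode_i; while (lo > 1 && sm[lo - 1] >= half) lo <- lo - 1
  hi <- mode_i; while (hi < length(sm) && sm[hi + 1] >= half) hi <- hi + 1
  # multimodality: another local max within 5% of the peak, outside the FWHM
  is_locmax <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE)
  rival <- which(is_locmax & sm >= 0.95 * sm[mode_i])
  rival <- rival[rival < lo | rival > hi]
  if (length(rival) > 0 && is.null(gate))
    stop("multimodal histogram (two peaks within 5% height); ",
         "supply an explicit gate")
  weighted.mean(df$channel[lo:hi], df$count[lo:hi])
}

#' Estimate genome size from a fluorescence ratio
#'
#' The 1C DNA content is the ratio of the sample G1 peak to the standard G1
#' peak times the standard's DNA content (default: human lymphocyte,
#' 3.50 pg per nucleus). Two base-pair conversions are offered:
#' `"reference"` (default) scales the reference genome length by the same
#' ratio (default 3.0e9 bp for human); `"pg"` converts picograms at
#' 0.978e9 bp/pg.
#'
#' @param sample_peak,standard_peak G1 peak positions (channels).
#' @param standard_pg DNA content of the standard, pg/nucleus (3.50).
#' @param reference_bp Reference genome length for the ratio conversion
#'   (3.0e9).
#' @param bp_from `"reference"` or `"pg"`.
#' @return List of class `genome_size_estimate`: `ratio`, `pg_per_nucleus`,
#'   `bp_haploid`, `standard_pg`, `reference_bp`.
#' @examples
#' estimate_genome_size(722, 1000)$pg_per_nucleus  # 2.527
#' @export
estimate_genome_size <- function(sample_peak, standard_peak,
                                 standard_pg = 3.50, reference_bp = 3.0e9,
                                 bp_from = c("reference", "pg")) {
  bp_from <- match.arg(bp_from)
  if (sample_peak <= 0 || standard_peak <= 0)
    stop("peak positions must be positive")
  ratio <- sample_peak / standard_peak
  pg <- ratio * standard_pg
  bp <- if (bp_from == "reference") ratio * reference_bp else pg * 0.978e9
  structure(list(ratio = ratio, pg_per_nucleus = pg, bp_haploid = bp,
                 standard_pg = standard_pg, reference_bp = reference_bp),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Genome size: ratio %.3f of standard -> %.2f pg/nucleus, %.3g bp haploid\n",
              x$ratio, x$pg_per_nucleus, x$bp_haploid))
  invisible(x)
}

#' Library coverage in haploid genome equivalents
#'
#' @param n_clones Number of clones in the library.
#' @param insert_bp Mean insert size, bp (nominal 40 kb for fosmids).
#' @param genome_bp Haploid genome size, bp.
#' @return Fold coverage (n_clones * insert_bp / genome_bp).
#' @examples
#' round(library_coverage(288000, 40000, 2.17e9), 1)  # 5.3
#' @export
library_coverage <- function(n_clones, insert_bp, genome_bp) {
  if (genome_bp <= 0) stop("genome size must be positive")
  if (n_clones <= 0 || insert_bp <= 0)
    stop("clone count and insert size must be positive")
  as.numeric(n_clones) * as.numeric(insert_bp) / as.numeric(genome_bp)
}

#' Gene count and density from a coding fraction
#'
#' Given the fraction of the survey matching coding sequence and a gene
#' size range, extrapolates the genome-wide gene count
#' (coding_fraction * genome_bp / gene_size) and gene density
#' (genome_bp / count) at both bounds.
#'
#' @param coding_fraction Fraction of surveyed reads/bases with coding
#'   similarity, in (0, 1).
#' @param genome_bp Haploid genome size, bp.
#' @param gene_size_lo,gene_size_hi Gene size bounds, bp (lo <= hi).
#' @return List with `count` (at hi..lo gene size: `count_lo` is the
#'   count at `gene_size_hi`) and `density_kb` per gene.
#' @examples
#' gene_metrics(0.048, 2.17e9, 7000, 10000)$count_hi  # 14880
#' @export
gene_metrics <- function(coding_fraction, genome_bp, gene_size_lo,
                         gene_size_hi = gene_size_lo) {
  if (coding_fraction <= 0 || coding_fraction >= 1)
    stop("coding_fraction must be in (0, 1)")
  if (gene_size_lo > gene_size_hi) stop("gene_size_lo must be <= gene_size_hi")
  if (gene_size_lo <= 0) stop("gene sizes must be positive")
  count_hi <- coding_fraction * genome_bp / gene_size_lo  # small genes -> many
  count_lo <- coding_fraction * genome_bp / gene_size_hi
  list(count_lo = count_lo, count_hi = count_hi,
       density_kb_lo = genome_bp / count_hi / 1000,
       density_kb_hi = genome_bp / count_lo / 1000)
}

#' GC content of a read set
#'
#' (G + C) / (A + C + G + T) * 100 over all reads; N and other ambiguity
#' codes are excluded from the denominator.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param what `"gc"` (default) or `"at"` for the complementary fraction.
#' @return GC (or A/T) percentage.
#' @export
gc_content <- function(reads, what = c("gc", "at")) {
  what <- match.arg(what)
  reads <- as_read_vector(reads)
  if (length(reads) == 0) stop("empty read set")
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(reads))[, c("A", "C", "G", "T"), drop = FALSE])
  tot <- sum(counts)
  if (tot == 0) stop("no unambiguous bases in read set")
  num <- if (what == "gc") counts["C"] + counts["G"] else counts["A"] + counts["T"]
  unname(num / tot * 100)
}

#' Mean masked fraction across repeat databases
#'
#' Ratio arithmetic over externally masked lengths: each masked length is
#' divided by the surveyed length and the resulting percentages averaged
#' (e.g. interspersed-repeat fractions masked against two different repeat
#' databases).
#'
#' @param masked_bp Numeric vector of masked lengths, bp.
#' @param surveyed_bp Surveyed length, bp.
#' @return Mean masked percentage.
#' @export
masked_fraction <- function(masked_bp, surveyed_bp) {
  if (surveyed_bp <= 0) stop("surveyed_bp must be positive")
  mean(masked_bp / surveyed_bp) * 100
}

#' Survey summary statistics
#'
#' @param reads Named character vector or `DNAStringSet` of survey reads.
#' @param genome_bp Haploid genome size, bp.
#' @param n_clones,insert_bp Library size and insert length for coverage.
#' @param coding_fraction,gene_size_lo,gene_size_hi Optional gene-count
#'   inputs (see [gene_metrics()]).
#' @return List of class `survey_summary`: `n_reads`, `surveyed_bp`,
#'   `gc_pct`, `mean_read_length`, `coverage_fold`, `sampling_fraction`,
#'   and (when coding inputs are given) the [gene_metrics()] fields.
#' @export
survey_summary <- function(reads, genome_bp, n_clones = NULL,
                           insert_bp = 40000, coding_fraction = NULL,
                           gene_size_lo = 7000, gene_size_hi = 10000) {
  reads <- as_read_vector(reads)
  surveyed_bp <- sum(nchar(reads))
  out <- list(n_reads = length(reads), surveyed_bp = surveyed_bp,
              gc_pct = gc_content(reads),
              mean_read_length = surveyed_bp / length(reads),
              sampling_fraction = surveyed_bp / genome_bp)
  if (!is.null(n_clones))
    out$coverage_fold <- library_coverage(n_clones, insert_bp, genome_bp)
  if (!is.null(coding_fraction))
    out <- c(out, gene_metrics(coding_fraction, genome_bp, gene_size_lo,
                               gene_size_hi))
  structure(out, class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("Survey: %d reads, %d bp (mean %.0f bp), GC %.2f%%\n",
              x$n_reads, x$surveyed_bp, x$mean_read_length, x$gc_pct))
  cat(sprintf("  sampling fraction %.3g", x$sampling_fraction))
  if (!is.null(x$coverage_fold))
    cat(sprintf("; library coverage %.1fx", x$coverage_fold))
  cat("\n")
  if (!is.null(x$count_lo))
    cat(sprintf("  gene count %.0f-%.0f (density 1 per %.0f-%.0f kb)\n",
                x$count_lo, x$count_hi, x$density_kb_lo, x$density_kb_hi))
  invisible(x)
}
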