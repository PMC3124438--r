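#' Tandem-repeat detector parameters
#'
#' Alignment weights and reporting filters for the wraparound-alignment
#' tandem-repeat caller. Defaults follow the classic microsatellite-survey
#' parameterization: match/mismatch/indel weights {2, 3, 5}, minimum
#' alignment score 50, minimum array length 12 bp, arrays with percent
#' matches (purity) at or below 55% discarded, unit sizes 1-6 bp.
#'
#' Note that with weights {2, 3, 5} a perfect 12-bp array scores only 24,
#' so the score and length floors are independent AND-filters: at the
#' default `min_score = 50` the effective floor for a perfect array is
#' 25 bp. Set `min_score = 24` to realize a literal 12-bp floor.
#'
#' @param match_weight Score added per matching column (default 2).
#' @param mismatch_penalty Score subtracted per mismatching column (3).
#' @param indel_penalty Score subtracted per gap column (5).
#' @param min_score Minimum alignment score to report an array (50).
#' @param min_array_length Minimum array span in bp (12).
#' @param min_purity Arrays with purity less than or equal to this are
#'   removed (0.55; retention is strictly greater).
#' @param max_unit Largest repeat unit searched, bp (6).
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(match_weight = 2, mismatch_penalty = 3,
                            indel_penalty = 5, min_score = 50,
                            min_array_length = 12, min_purity = 0.55,
                            max_unit = 6) {
  p <- list(match_weight = match_weight, mismatch_penalty = mismatch_penalty,
            indel_penalty = indel_penalty, min_score = min_score,
            min_array_length = min_array_length, min_purity = min_purity,
            max_unit = as.integer(max_unit))
  for (f in c("match_weight", "mismatch_penalty", "indel_penalty")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) config_stop(f, "must be positive")
  }
  if (p$min_purity <= 0 || p$min_purity >= 1)
    config_stop("min_purity", "must be in (0, 1)")
  if (p$max_unit < 1) config_stop("max_unit", "must be >= 1")
  if (p$min_array_length < 2)
    config_stop("min_array_length", "must be >= 2")
  class(p) <- "detector_params"
  p
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1)
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-ACGTN characters")
  sequence
}

# Internal: split a sequence at runs of >= 2 N into (offset, subsequence)
# pieces; alignments never cross such runs.
split_on_n_runs <- function(sequence) {
  m <- gregexpr("N{2,}", sequence)[[1]]
  if (m[1] == -1) return(data.frame(offset = 0L, seq = sequence))
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  keep_start <- c(1L, ends + 1L)
  keep_end <- c(starts - 1L, nchar(sequence))
  ok <- keep_end >= keep_start
  data.frame(offset = keep_start[ok] - 1L,
             seq = substring(sequence, keep_start[ok], keep_end[ok]))
}

#' Find candidate tandem periods in a sequence
#'
#' Fast scan preceding the wraparound alignment: for every candidate period
#' d (1..max_unit) the base identity of positions i and i+d is tallied in
#' sliding windows; windows whose match density reaches one half trigger a
#' candidate, and overlapping triggered windows are merged into one
#' candidate interval per period. Any perfect array of length at least
#' `min_array_length` is guaranteed to receive a covering candidate.
#' Runs of two or more N are never crossed.
#'
#' @param sequence A single uppercase ACGTN string.
#' @param params A [detector_params()] object.
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `period`.
#' @export
find_candidate_periods <- function(sequence, params = detector_params()) {
  sequence <- check_sequence(sequence)
  pieces <- split_on_n_runs(sequence)
  out <- list()
  for (pi in seq_len(nrow(pieces))) {
    seg <- pieces$seq[pi]
    off <- pieces$offset[pi]
    n <- nchar(seg)
    for (d in seq_len(params$max_unit)) {
      if (n < d + 2) next
      v <- .dist_match_cpp(seg, d)
      w <- min(max(12L, 2L * d), length(v))
      if (w < 2) next
      trigger <- ceiling(w / 2)
      cs <- c(0L, cumsum(v))
      nw <- length(v) - w + 1L
      counts <- cs[(w + 1L):(w + nw)] - cs[1:nw]
      q <- which(counts >= trigger)
      if (length(q) == 0) next
      # merge triggered window starts separated by <= w into runs, then
      # trim each run to the first/last actual match so the candidate does
      # not overshoot into flanking sequence
      brk <- which(diff(q) > w)
      run_start <- q[c(1L, brk + 1L)]
      run_end <- q[c(brk, length(q))]
      st <- en <- integer(length(run_start))
      for (ri in seq_along(run_start)) {
        span <- run_start[ri]:min(run_end[ri] + w - 1L, length(v))
        hitpos <- span[v[span] == 1L]
        st[ri] <- hitpos[1]
        en[ri] <- min(hitpos[length(hitpos)] + d, n)
      }
      keep <- (en - st + 1L) >= params$min_array_length
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        start = st[keep] + off, end = en[keep] + off, period = d)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$period), , drop = FALSE]
}

#' Wraparound alignment of a segment against a cyclic motif
#'
#' Aligns a DNA segment against an unbounded tandem repetition of `motif`
#' by wraparound dynamic programming: +match per matching column, -mismatch
#' per mismatching column, -indel per gap column, with the motif free to
#' start and end at any phase. In global mode the whole segment is aligned;
#' in local mode the best-scoring sub-segment is reported.
#'
#' @param segment DNA string to align.
#' @param motif Repeat unit (length >= 1).
#' @param params A [detector_params()] object supplying the weights.
#' @param local If TRUE, report the best local sub-segment alignment.
#' @return List with `score`, `purity` (matches / aligned columns),
#'   `indel_fraction` (gap columns / aligned columns), `start`, `end`
#'   (1-based inclusive aligned span within `segment`), and the raw
#'   `matches`, `mismatches`, `gaps` counts.
#' @examples
#' wraparound_align("AGAGAG", "AG")$score   # 12
#' wraparound_align("AGAGCG", "AG")$score   # 7
#' @export
wraparound_align <- function(segment, motif, params = detector_params(),
                             local = FALSE) {
  segment <- check_sequence(segment)
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) < 1)
    stop("motif must be a single non-empty string")
  motif <- toupper(motif)
  r <- .wrap_align_cpp(segment, motif, params$match_weight,
                       params$mismatch_penalty, params$indel_penalty, local)
  cols <- r$matches + r$mismatches + r$gaps
  list(score = r$score,
       purity = if (cols > 0) r$matches / cols else 0,
       indel_fraction = if (cols > 0) r$gaps / cols else 0,
       start = r$start, end = r$end,
       matches = r$matches, mismatches = r$mismatches, gaps = r$gaps)
}

# Internal: majority consensus unit of period d over a core interval,
# phase 0 anchored at `start`. Only positions confirming the periodicity
# (base equal to the base d ahead) vote, so flanking sequence inside a
# wide candidate window cannot pollute the unit; phases left without votes
# fall back to all positions. Ties break alphabetically.
phase_consensus <- function(sequence, start, end, d) {
  seg <- substr(sequence, start, end)
  chars <- strsplit(seg, "", fixed = TRUE)[[1]]
  phase <- (seq_along(chars) - 1L) %% d
  v <- .dist_match_cpp(seg, d)
  voters <- logical(length(chars))
  if (length(v) > 0) {
    idx <- which(v == 1L)
    voters[idx] <- TRUE
    voters[idx + d] <- TRUE
  }
  if (!any(voters)) voters[] <- TRUE
  unit <- vapply(0:(d - 1L), function(ph) {
    sel <- voters & phase == ph
    if (!any(sel)) sel <- phase == ph
    tab <- table(factor(chars[sel], levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]  # which.max takes the first (alphabetical) max
  }, character(1))
  paste(unit, collapse = "")
}

empty_arrays <- function() {
  data.frame(read_id = character(0), start = integer(0), end = integer(0),
             period = integer(0), motif = character(0),
             canonical_motif = character(0), copy_number = numeric(0),
             score = numeric(0), purity = numeric(0),
             indel_fraction = numeric(0), stringsAsFactors = FALSE)
}

#' Call tandem arrays in a single read
#'
#' Runs the candidate-period scan, derives a majority consensus unit per
#' candidate, finds the optimal local wraparound alignment of the candidate
#' region against the cyclic unit, and reports arrays passing the score,
#' length and purity filters. Overlapping calls are resolved greedily:
#' highest score first, ties to the smaller period then the leftmost start;
#' a call is dropped if it overlaps an accepted call by more than one
#' repeat unit, so adjacent compound arrays of distinct motifs are reported
#' separately, never merged.
#'
#' @param read DNA string (a single read or consensus sequence).
#' @param params A [detector_params()] object.
#' @param read_id Identifier stored in the output.
#' @return data.frame with one row per array: `read_id`, `start`, `end`
#'   (1-based inclusive), `period`, `motif` (consensus unit), a
#'   `canonical_motif` label (NA for periods > 6), `copy_number`
#'   (span / period), `score`, `purity`, `indel_fraction`.
#' @export
call_tandem_arrays <- function(read, params = detector_params(),
                               read_id = "read") {
  read <- check_sequence(read)
  cands <- find_candidate_periods(read, params)
  if (nrow(cands) == 0) return(empty_arrays())
  n <- nchar(read)

  # Extract the best local wraparound alignment within a candidate core,
  # then recurse on the flanking remainders so adjacent distinct-motif
  # arrays sharing one candidate window are each reported.
  extract <- function(cstart, cend, d, depth) {
    if (depth > 4 || cend - cstart + 1 < max(params$min_array_length, d + 1))
      return(NULL)
    margin <- d + 4L
    wstart <- max(1L, cstart - margin)
    wend <- min(n, cend + margin)
    # never let the alignment window cross a run of >= 2 N
    wpieces <- split_on_n_runs(substr(read, wstart, wend))
    if (nrow(wpieces) > 1) {
      wpieces$abs_start <- wstart + wpieces$offset
      wpieces$abs_end <- wpieces$abs_start + nchar(wpieces$seq) - 1L
      hit <- which(wpieces$abs_start <= cstart & wpieces$abs_end >= cstart)
      if (length(hit) == 0) return(NULL)
      wstart <- wpieces$abs_start[hit[1]]
      wend <- min(wpieces$abs_end[hit[1]], wend)
      if (wend - wstart + 1 < params$min_array_length) return(NULL)
    }
    unit <- phase_consensus(read, max(cstart, wstart), min(cend, wend), d)
    if (grepl("N", unit)) return(NULL)
    aln <- wraparound_align(substr(read, wstart, wend), unit, params,
                            local = TRUE)
    if (aln$end < aln$start || aln$score < params$min_score) return(NULL)
    a_start <- wstart + aln$start - 1L
    a_end <- wstart + aln$end - 1L
    # interruption check: a sustained stretch of low distance-d match
    # density inside the span is a spacer between two distinct arrays,
    # not array interior; split there and treat the halves separately
    if (a_end - a_start + 1 >= 2 * params$min_array_length + 12) {
      vv <- .dist_match_cpp(substr(read, a_start, a_end), d)
      if (length(vv) >= 12) {
        cs <- c(0L, cumsum(vv))
        wc <- cs[13:length(cs)] - cs[1:(length(cs) - 12L)]
        bad <- which(wc <= 3L)
        if (length(bad) > 0) {
          split_at <- a_start + bad[1] + 5L   # centre of the weak window
          return(rbind(extract(cstart, split_at, d, depth + 1L),
                       extract(split_at + 1L, cend, d, depth + 1L)))
        }
      }
    }
    # report the unit rotated to the phase of the aligned span start
    unit_rot <- rotate_chr(unit, (a_start - cstart) %% d)
    p <- primitive_period(unit_rot)
    if (p < d) unit_rot <- substr(unit_rot, 1, p)
    row <- data.frame(
      read_id = read_id, start = a_start, end = a_end, period = p,
      motif = unit_rot,
      canonical_motif = if (p <= 6) canonical_motif(unit_rot) else NA_character_,
      copy_number = (a_end - a_start + 1) / p,
      score = aln$score, purity = aln$purity,
      indel_fraction = aln$indel_fraction, stringsAsFactors = FALSE)
    rbind(row,
          extract(cstart, a_start - 2L, d, depth + 1),
          extract(a_end + 2L, cend, d, depth + 1))
  }

  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    rows[[i]] <- extract(cands$start[i], cands$end[i], cands$period[i], 1L)
  }
  arr <- do.call(rbind, rows)
  if (is.null(arr) || nrow(arr) == 0) return(empty_arrays())
  arr <- arr[arr$score >= params$min_score &
               (arr$end - arr$start + 1) >= params$min_array_length &
               arr$copy_number >= 1.9, , drop = FALSE]
  arr <- filter_by_purity(arr, params)
  if (nrow(arr) == 0) return(empty_arrays())
  # drop exact duplicates (same span called at several candidate periods)
  arr <- arr[order(arr$start, arr$end, arr$period), , drop = FALSE]
  arr <- arr[!duplicated(arr[, c("start", "end", "period")]), , drop = FALSE]
  # greedy overlap resolution
  ord <- order(-arr$score, arr$period, arr$start)
  arr <- arr[ord, , drop = FALSE]
  kept <- logical(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- min(arr$end[i], arr$end[j]) - max(arr$start[i], arr$start[j]) + 1
      if (ov > max(arr$period[i], arr$period[j])) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  arr <- arr[kept, , drop = FALSE]
  arr <- arr[order(arr$start, arr$period), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

#' Scan a read set for tandem arrays
#'
#' @param reads A named character vector or `Biostrings::DNAStringSet`.
#' @param params A [detector_params()] object.
#' @return data.frame of arrays across all reads (see
#'   [call_tandem_arrays()]).
#' @export
scan_tandem_arrays <- function(reads, params = detector_params()) {
  reads <- as_read_vector(reads)
  res <- lapply(names(reads), function(id) {
    call_tandem_arrays(reads[[id]], params, read_id = id)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_arrays()
  rownames(out) <- NULL
  out
}

#' Remove low-purity arrays
#'
#' Retains arrays whose purity (fraction of matching aligned columns) is
#' strictly greater than `min_purity`; arrays at or below the floor are
#' removed, preserving input order.
#'
#' @param arrays data.frame of tandem arrays carrying a `purity` column.
#' @param params A [detector_params()] object.
#' @return Filtered data.frame (a subsequence of the input rows).
#' @export
filter_by_purity <- function(arrays, params = detector_params()) {
  if (!"purity" %in% names(arrays)) stop("arrays must carry a purity column")
  arrays[arrays$purity > params$min_purity, , drop = FALSE]
}

#' Mask tandem arrays out of a read set
#'
#' Replaces every reported array span with N so that downstream
#' interspersed-repeat discovery is not seeded by microsatellites.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param arrays data.frame from [scan_tandem_arrays()].
#' @return Named character vector of masked reads.
#' @export
mask_tandem_arrays <- function(reads, arrays) {
  reads <- as_read_vector(reads)
  for (i in seq_len(nrow(arrays))) {
    id <- arrays$read_id[i]
    if (!id %in% names(reads)) next
    s <- reads[[id]]
    substr(s, arrays$start[i], arrays$end[i]) <-
      strrep("N", arrays$end[i] - arrays$start[i] + 1)
    reads[[id]] <- s
  }
  reads
}

# Internal: accept DNAStringSet or named character vector of reads.
as_read_vector <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) {
    v <- as.character(reads)
  } else if (is.character(reads)) {
    v <- reads
  } else {
    stop("reads must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop("reads must have unique names")
  toupper(v)
}

#' Write tandem arrays as GFF3
#'
#' Exports arrays as `tandem_repeat` features (1-based inclusive
#' coordinates) with period, motif, canonical class, copy number, score and
#' purity attributes.
#'
#' @param arrays data.frame from [scan_tandem_arrays()].
#' @param file Output GFF3 path.
#' @return The file path, invisibly.
#' @export
write_tandem_gff3 <- function(arrays, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = arrays$read_id,
    ranges = IRanges::IRanges(start = arrays$start, end = arrays$end),
    type = "tandem_repeat",
    period = arrays$period,
    motif = arrays$motif,
    canonical = arrays$canonical_motif,
    copies = round(arrays$copy_number, 2),
    score = arrays$score,
    purity = round(arrays$purity, 4))
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Write tandem arrays as a flat TSV
#'
#' @param arrays data.frame from [scan_tandem_arrays()].
#' @param file Output TSV path.
#' @param header Optional comment lines (without leading `#`) written
#'   before the column header.
#' @return The file path, invisibly.
#' @export
write_tandem_tsv <- function(arrays, file, header = character(0)) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(arrays, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
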