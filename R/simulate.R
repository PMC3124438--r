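#' Synthetic fosmid-end read simulation
#'
#' Configuration for the synthetic read simulator. Reads emulate a
#' fosmid-end survey: lengths drawn from a truncated normal distribution
#' (SD = (max - min)/6, redrawn until within bounds), i.i.d. background
#' bases at a configured GC content, and optional planted microsatellite
#' arrays and interspersed repeat-family copies with full ground truth.
#' Defaults mirror a typical survey read set: 100-861 bp, mean 531 bp,
#' GC 45.88%.
#'
#' @param n_reads Number of reads to generate.
#' @param length_min,length_max,length_mean Read-length bounds and mean, bp.
#' @param gc_background Background GC fraction in \[0, 1\].
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param planted_ssrs List of [ssr_plant()] descriptions.
#' @param planted_families List of [family_plant()] descriptions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads, length_min = 100, length_max = 861,
                       length_mean = 531, gc_background = 0.4588, seed = 1,
                       planted_ssrs = list(), planted_families = list()) {
  if (!is.numeric(n_reads) || length(n_reads) != 1 || n_reads < 1)
    config_stop("n_reads", "must be a positive count")
  if (length_min <= 0) config_stop("length_min", "must be positive")
  if (length_min > length_mean)
    config_stop("length_mean", "must be >= length_min")
  if (length_mean > length_max)
    config_stop("length_max", "must be >= length_mean")
  if (gc_background < 0 || gc_background > 1)
    config_stop("gc_background", "must be in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1)
    config_stop("seed", "must be a single integer")
  cfg <- list(n_reads = as.integer(n_reads),
              length_min = as.integer(length_min),
              length_max = as.integer(length_max),
              length_mean = length_mean,
              gc_background = gc_background, seed = as.integer(seed),
              planted_ssrs = planted_ssrs,
              planted_families = planted_families)
  class(cfg) <- "sim_config"
  cfg
}

#' Describe a planted microsatellite
#'
#' @param motif Repeat unit, 1-6 bp over A/C/G/T.
#' @param copies Number of unit copies (positive real; the planted array
#'   spans `round(copies * nchar(motif))` bp, at least 12 bp).
#' @param per_base_mutation Substitution probability per array base.
#' @param per_base_indel Single-base insertion/deletion probability per
#'   array base.
#' @param n_loci Number of independent loci to plant.
#' @return A list of class `ssr_plant`.
#' @export
ssr_plant <- function(motif, copies, per_base_mutation = 0,
                      per_base_indel = 0, n_loci = 1) {
  if (!grepl("^[ACGT]{1,6}$", motif))
    config_stop("motif", "must be 1-6 bp over {A,C,G,T}")
  if (copies <= 0) config_stop("copies", "must be positive")
  if (copies * nchar(motif) < 12)
    config_stop("copies", "planted array must span >= 12 bp")
  if (per_base_mutation < 0 || per_base_mutation >= 1)
    config_stop("per_base_mutation", "must be in [0, 1)")
  if (per_base_indel < 0 || per_base_indel >= 1)
    config_stop("per_base_indel", "must be in [0, 1)")
  if (n_loci < 1) config_stop("n_loci", "must be >= 1")
  structure(list(motif = motif, copies = copies,
                 per_base_mutation = per_base_mutation,
                 per_base_indel = per_base_indel,
                 n_loci = as.integer(n_loci)),
            class = "ssr_plant")
}

#' Describe a planted interspersed repeat family
#'
#' @param family_id Label recorded in the truth set.
#' @param consensus_length Length of the family consensus, bp (>= 100).
#' @param n_copies Number of copies planted across the read set.
#' @param divergence Expected substitutions per site applied independently
#'   to each copy (0-0.4).
#' @param truncation_fraction Fraction of copies truncated at the 5' or 3'
#'   end (each truncated copy keeps a uniform 50-90% of the consensus).
#' @return A list of class `family_plant`.
#' @export
family_plant <- function(family_id, consensus_length, n_copies,
                         divergence = 0, truncation_fraction = 0) {
  if (consensus_length < 100)
    config_stop("consensus_length", "must be >= 100 bp")
  if (n_copies < 1) config_stop("n_copies", "must be >= 1")
  if (divergence < 0 || divergence > 0.4)
    config_stop("divergence", "must be in [0, 0.4]")
  if (truncation_fraction < 0 || truncation_fraction > 1)
    config_stop("truncation_fraction", "must be in [0, 1]")
  structure(list(family_id = as.character(family_id),
                 consensus_length = as.integer(consensus_length),
                 n_copies = as.integer(n_copies), divergence = divergence,
                 truncation_fraction = truncation_fraction),
            class = "family_plant")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate background reads
#'
#' Draws `n_reads` read lengths from the configured truncated normal
#' distribution and fills them with i.i.d. bases at the configured GC
#' content. Deterministic for a fixed config and seed.
#'
#' @param config A [sim_config()] object.
#' @return Named character vector of reads (`read_000001`, ...).
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  if (config$length_min == config$length_max) {
    lens <- rep(config$length_min, n)
  } else {
    sdv <- (config$length_max - config$length_min) / 6
    lens <- integer(n)
    need <- seq_len(n)
    while (length(need) > 0) {
      draw <- round(rnorm(length(need), config$length_mean, sdv))
      ok <- draw >= config$length_min & draw <= config$length_max
      lens[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
  }
  reads <- vapply(lens, random_dna, character(1), gc = config$gc_background)
  names(reads) <- sprintf("read_%06d", seq_len(n))
  reads
}

# Internal: substitute bases at given 1-based positions; each substitution
# picks uniformly among the three other bases. Returns list(seq, ops).
apply_substitutions <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(list(seq = s, subs = data.frame(pos = integer(0),
                                                     from = character(0),
                                                     to = character(0))))
  pos <- sort(sample.int(n, k))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  from <- chars[pos]
  to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
               character(1), USE.NAMES = FALSE)
  chars[pos] <- to
  list(seq = paste(chars, collapse = ""),
       subs = data.frame(pos = pos, from = from, to = to))
}

# Internal: apply single-base indels at the given rate; ops are recorded in
# application order with positions in the coordinates current at the time
# each op is applied, so they can be reverted in reverse order.
apply_indels <- function(s, rate) {
  n0 <- nchar(s)
  k <- rbinom(1, n0, rate)
  ops <- data.frame(op = character(0), pos = integer(0), base = character(0))
  if (k == 0) return(list(seq = s, indels = ops))
  for (i in seq_len(k)) {
    n <- nchar(s)
    if (n <= 1) break
    pos <- sample.int(n, 1)
    if (runif(1) < 0.5) {  # deletion of the base at pos
      base <- substr(s, pos, pos)
      s <- paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n))
      ops <- rbind(ops, data.frame(op = "del", pos = pos, base = base))
    } else {               # insertion after pos
      base <- sample(c("A", "C", "G", "T"), 1)
      s <- paste0(substr(s, 1, pos), base, substr(s, pos + 1, n))
      ops <- rbind(ops, data.frame(op = "ins", pos = pos, base = base))
    }
  }
  list(seq = s, indels = ops)
}

#' Revert recorded mutations of a planted feature
#'
#' Undoes the substitutions and indels recorded in a truth entry's
#' parameter JSON, recovering the pristine planted sequence (useful to
#' verify truth-interval round-trips).
#'
#' @param seq Realized sequence extracted at the truth interval (already
#'   reoriented to the plant's forward strand).
#' @param params Parsed parameter list from the truth record.
#' @return The pristine planted sequence.
#' @export
revert_mutations <- function(seq, params) {
  ind <- params$indels
  if (!is.null(ind) && length(ind$op) > 0) {
    for (i in rev(seq_along(ind$op))) {
      pos <- ind$pos[i]
      if (ind$op[i] == "del") {
        seq <- paste0(substr(seq, 1, pos - 1), ind$base[i],
                      substr(seq, pos, nchar(seq)))
      } else {
        # insertion was made after `pos`: drop the base at pos + 1
        seq <- paste0(substr(seq, 1, pos),
                      substr(seq, pos + 2, nchar(seq)))
      }
    }
  }
  sub <- params$subs
  if (!is.null(sub) && length(sub$pos) > 0) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[sub$pos] <- sub$from
    seq <- paste(chars, collapse = "")
  }
  seq
}

empty_truth <- function() {
  data.frame(read_id = character(0), start = integer(0), end = integer(0),
             kind = character(0), label = character(0), params = character(0),
             stringsAsFactors = FALSE)
}

#' Plant microsatellites and repeat-family copies into reads
#'
#' Each planted microsatellite is its unit repeated to the configured span
#' with per-base substitutions and indels applied at the stated rates; each
#' family copy is the family consensus mutated at the divergence rate,
#' optionally truncated, and reverse-complemented with probability 0.5.
#' Plants overwrite background bases (read lengths are preserved up to
#' indels) and never overlap one another. Every insertion is recorded in
#' the returned truth table with its realized interval and a parameter JSON
#' sufficient to reconstruct the pristine planted sequence.
#'
#' @param reads Named character vector from [generate_background()].
#' @param config A [sim_config()] object.
#' @return List with `reads` (modified vector), `truth` (data.frame:
#'   `read_id`, `start`, `end` 1-based inclusive, `kind` "ssr"/"family",
#'   `label`, `params` JSON), and `family_consensi` (named character
#'   vector of the pristine family consensus sequences).
#' @export
plant_features <- function(reads, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  occupied <- lapply(reads, function(r) matrix(numeric(0), ncol = 2))
  truth <- list()

  place <- function(len, label) {
    # find a read with a free slot of `len` bp (3 bp clear of other plants)
    order_try <- sample(seq_along(reads))
    for (ri in order_try) {
      n <- nchar(reads[[ri]])
      if (n < len) next
      occ <- occupied[[ri]]
      free_ok <- function(st) {
        en <- st + len - 1
        nrow(occ) == 0 ||
          all(occ[, 2] + 3 < st | occ[, 1] - 3 > en)
      }
      starts <- sample.int(n - len + 1, min(20L, n - len + 1))
      for (st in starts) if (free_ok(st)) return(c(ri, st))
    }
    stop(sprintf("no read can accommodate plant '%s' of %d bp", label, len),
         call. = FALSE)
  }

  insert <- function(ri, st, insert_seq) {
    r <- reads[[ri]]
    en <- st + nchar(insert_seq) - 1
    reads[[ri]] <<- paste0(substr(r, 1, st - 1), insert_seq,
                           substr(r, en + 1, nchar(r)))
    occupied[[ri]] <<- rbind(occupied[[ri]], c(st, en))
    c(st, en)
  }

  for (p in config$planted_ssrs) {
    stopifnot(inherits(p, "ssr_plant"))
    span <- round(p$copies * nchar(p$motif))
    pristine <- substr(strrep(p$motif, ceiling(p$copies) + 1), 1, span)
    for (locus in seq_len(p$n_loci)) {
      s1 <- apply_substitutions(pristine, p$per_base_mutation)
      s2 <- apply_indels(s1$seq, p$per_base_indel)
      loc <- place(nchar(s2$seq), p$motif)
      iv <- insert(loc[1], loc[2], s2$seq)
      truth[[length(truth) + 1]] <- data.frame(
        read_id = names(reads)[loc[1]], start = iv[1], end = iv[2],
        kind = "ssr", label = p$motif,
        params = as.character(jsonlite::toJSON(list(
          motif = p$motif, copies = p$copies,
          per_base_mutation = p$per_base_mutation,
          per_base_indel = p$per_base_indel,
          subs = s1$subs, indels = s2$indels), auto_unbox = TRUE)),
        stringsAsFactors = FALSE)
    }
  }

  consensi <- character(0)
  for (p in config$planted_families) {
    stopifnot(inherits(p, "family_plant"))
    consensus <- random_dna(p$consensus_length, config$gc_background)
    consensi[[p$family_id]] <- consensus
    for (ci in seq_len(p$n_copies)) {
      keep <- c(1L, p$consensus_length)
      if (runif(1) < p$truncation_fraction) {
        frac <- runif(1, 0.5, 0.9)
        klen <- max(100L, round(frac * p$consensus_length))
        if (runif(1) < 0.5) keep <- c(1L, klen)
        else keep <- c(p$consensus_length - klen + 1L, p$consensus_length)
      }
      copy <- substr(consensus, keep[1], keep[2])
      s1 <- apply_substitutions(copy, p$divergence)
      orient <- if (runif(1) < 0.5) "+" else "-"
      realized <- if (orient == "+") s1$seq else revcomp_chr(s1$seq)
      loc <- place(nchar(realized), p$family_id)
      iv <- insert(loc[1], loc[2], realized)
      truth[[length(truth) + 1]] <- data.frame(
        read_id = names(reads)[loc[1]], start = iv[1], end = iv[2],
        kind = "family", label = p$family_id,
        params = as.character(jsonlite::toJSON(list(
          family_id = p$family_id, divergence = p$divergence,
          orientation = orient, keep_start = keep[1], keep_end = keep[2],
          subs = s1$subs), auto_unbox = TRUE)),
        stringsAsFactors = FALSE)
    }
  }

  truth_df <- if (length(truth) > 0) do.call(rbind, truth) else empty_truth()
  list(reads = reads, truth = truth_df, family_consensi = consensi)
}

#' Simulate a full synthetic read set
#'
#' Convenience wrapper: [generate_background()] then [plant_features()],
#' optionally writing the reads as multi-FASTA and the truth table as TSV.
#'
#' @param config A [sim_config()] object.
#' @param fasta,truth_file Optional output paths.
#' @return See [plant_features()].
#' @export
simulate_reads <- function(config, fasta = NULL, truth_file = NULL) {
  reads <- generate_background(config)
  res <- plant_features(reads, config)
  if (!is.null(fasta)) write_reads_fasta(res$reads, fasta)
  if (!is.null(truth_file)) write_truth(res$truth, truth_file)
  res
}

#' Write reads as multi-FASTA
#' @param reads Named character vector or `DNAStringSet`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_reads_fasta <- function(reads, file) {
  reads <- as_read_vector(reads)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), file)
  invisible(file)
}

#' Read a multi-FASTA into a named character vector
#' @param file FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reads_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  v <- toupper(as.character(x))
  names(v) <- sub("\\s.*$", "", names(v))
  v
}

#' Write / read the ground-truth table
#'
#' The on-disk truth format is tab-separated with 0-based half-open
#' coordinates (`read_id`, `start`, `end`, `kind`, `label`, `params` JSON);
#' in-memory truth data.frames use 1-based inclusive coordinates like the
#' rest of the package.
#'
#' @param truth data.frame from [plant_features()].
#' @param file Path of the TSV.
#' @return `write_truth`: the path, invisibly; `read_truth`: the truth
#'   data.frame (1-based inclusive).
#' @export
write_truth <- function(truth, file) {
  out <- truth
  out$start <- out$start - 1L   # to 0-based half-open
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  tr <- read.delim(file, stringsAsFactors = FALSE)
  tr$start <- tr$start + 1L
  tr
}
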