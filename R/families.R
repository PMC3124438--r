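#' Repeat-family discovery parameters
#'
#' Floors and tolerances for de novo interspersed-repeat-family discovery
#' on tandem-masked reads: all-vs-all seeded local alignment, element
#' definition, single-linkage clustering, consensus building and
#' threshold-driven merge/split curation. Defaults: 11-bp words, hits of
#' at least 100 bp at 80% identity, 30-bp endpoint tolerance, families
#' retained at 20 or more copies, merge at 80% identity over half the
#' shorter consensus, split families whose mean element identity to
#' consensus falls below 60%.
#'
#' @param word_size Seed word length, bp (11).
#' @param min_hit_length Minimum pairwise hit length, bp (100).
#' @param min_hit_identity Minimum pairwise hit identity, fraction (0.80).
#' @param endpoint_tolerance Endpoint agreement for element aggregation,
#'   bp (30).
#' @param min_family_count Minimum copies for a family to be retained (20).
#' @param merge_identity Consensus-vs-consensus identity to merge (0.80).
#' @param merge_coverage Fraction of the shorter consensus that must align
#'   to merge (0.50).
#' @param split_identity_floor Mean element-to-consensus identity below
#'   which a family is re-clustered (0.60).
#' @return A list of class `family_params`.
#' @export
family_params <- function(word_size = 11, min_hit_length = 100,
                          min_hit_identity = 0.80, endpoint_tolerance = 30,
                          min_family_count = 20, merge_identity = 0.80,
                          merge_coverage = 0.50, split_identity_floor = 0.60) {
  p <- list(word_size = as.integer(word_size),
            min_hit_length = as.integer(min_hit_length),
            min_hit_identity = min_hit_identity,
            endpoint_tolerance = as.integer(endpoint_tolerance),
            min_family_count = as.integer(min_family_count),
            merge_identity = merge_identity,
            merge_coverage = merge_coverage,
            split_identity_floor = split_identity_floor)
  if (p$min_family_count < 1)
    config_stop("min_family_count", "must be >= 1")
  for (f in c("min_hit_identity", "merge_identity", "merge_coverage",
              "split_identity_floor")) {
    if (p[[f]] <= 0 || p[[f]] > 1) config_stop(f, "must be in (0, 1]")
  }
  if (p$word_size < 4) config_stop("word_size", "must be >= 4")
  class(p) <- "family_params"
  p
}

empty_hits <- function() {
  data.frame(read_a = character(0), read_b = character(0),
             start_a = integer(0), end_a = integer(0),
             start_b = integer(0), end_b = integer(0),
             orientation = character(0), identity = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' All-vs-all pairwise search on masked reads
#'
#' Runs a seeded, extended local-alignment search of every read against
#' every other read in both orientations (the standard BLASTN engine behind
#' the module surface), keeping hits that pass the length and identity
#' floors. Self-hits are excluded and the hit list is symmetric: every hit
#' (a, b) appears mirrored as (b, a). Input reads should have tandem
#' arrays masked to N first (see [mask_tandem_arrays()]); a warning is
#' emitted when more than 20% of hits fall inside intervals of a supplied
#' tandem table.
#'
#' @param reads Named character vector or `DNAStringSet` of masked reads.
#' @param params A [family_params()] object.
#' @param tandem_arrays Optional array table used for the masking check.
#' @return data.frame with `read_a`, `read_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b` (1-based inclusive on the forward strand of each
#'   read), `orientation` ("same"/"opposite"), `identity` (fraction) and
#'   `score` (bit score).
#' @export
allpairs_search <- function(reads, params = family_params(),
                            tandem_arrays = NULL) {
  reads <- as_read_vector(reads)
  if (length(reads) < 2) return(empty_hits())
  td <- tempfile("allpairs")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "reads.fasta")
  write_reads_fasta(reads, fa)
  db <- file.path(td, "db")
  run_tool("makeblastdb", c("-in", fa, "-dbtype", "nucl", "-out", db))
  out <- file.path(td, "hits.tsv")
  run_tool("blastn", c("-task", "blastn", "-query", fa, "-db", db,
                       "-word_size", params$word_size,
                       "-evalue", "1e-6", "-dust", "no",
                       "-outfmt",
                       shQuote("6 qseqid sseqid pident length qstart qend sstart send bitscore"),
                       "-out", out))
  raw <- utils::read.delim(out, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("q", "s", "pident", "length",
                                         "qstart", "qend", "sstart", "send",
                                         "bits"))
  raw <- raw[raw$q != raw$s &
               raw$length >= params$min_hit_length &
               raw$pident >= 100 * params$min_hit_identity, , drop = FALSE]
  if (nrow(raw) == 0) return(empty_hits())
  opp <- raw$sstart > raw$send
  hits <- data.frame(read_a = raw$q, read_b = raw$s,
                     start_a = raw$qstart, end_a = raw$qend,
                     start_b = ifelse(opp, raw$send, raw$sstart),
                     end_b = ifelse(opp, raw$sstart, raw$send),
                     orientation = ifelse(opp, "opposite", "same"),
                     identity = raw$pident / 100, score = raw$bits,
                     stringsAsFactors = FALSE)
  # symmetrize: dedupe on unordered pair + intervals, then mirror
  key_fwd <- paste(hits$read_a, hits$read_b, hits$start_a, hits$end_a,
                   hits$start_b, hits$end_b)
  key_rev <- paste(hits$read_b, hits$read_a, hits$start_b, hits$end_b,
                   hits$start_a, hits$end_a)
  canon <- ifelse(key_fwd <= key_rev, key_fwd, key_rev)
  hits <- hits[!duplicated(canon), , drop = FALSE]
  mirror <- data.frame(read_a = hits$read_b, read_b = hits$read_a,
                       start_a = hits$start_b, end_a = hits$end_b,
                       start_b = hits$start_a, end_b = hits$end_a,
                       orientation = hits$orientation,
                       identity = hits$identity, score = hits$score,
                       stringsAsFactors = FALSE)
  hits <- rbind(hits, mirror)
  hits <- hits[order(hits$read_a, hits$start_a, hits$read_b, hits$start_b),
               , drop = FALSE]
  rownames(hits) <- NULL
  if (!is.null(tandem_arrays) && nrow(tandem_arrays) > 0 && nrow(hits) > 0) {
    inside <- vapply(seq_len(nrow(hits)), function(i) {
      ta <- tandem_arrays[tandem_arrays$read_id == hits$read_a[i], ,
                          drop = FALSE]
      any(ta$start <= hits$start_a[i] & ta$end >= hits$end_a[i])
    }, logical(1))
    if (mean(inside) > 0.2)
      warning("more than 20% of hits fall inside known tandem intervals; ",
              "did you mask the reads?")
  }
  hits
}

run_tool <- function(tool, args) {
  res <- suppressWarnings(
    system2(tool, args, stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("%s failed (exit %d): %s", tool, status,
                 paste(utils::tail(res, 3), collapse = " ")), call. = FALSE)
  invisible(res)
}

#' Define repeat elements from pairwise hits
#'
#' Per read, hit intervals whose endpoints agree within
#' `endpoint_tolerance` are aggregated (single linkage on endpoint
#' agreement) into one element whose boundaries are the median endpoints;
#' overlapping intervals that do not agree stay separate elements, split at
#' the majority endpoints.
#'
#' @param hits Symmetric hit table from [allpairs_search()].
#' @param params A [family_params()] object.
#' @return data.frame with `element_id`, `read_id`, `start`, `end`.
#' @export
define_elements <- function(hits, params = family_params()) {
  if (nrow(hits) == 0)
    return(data.frame(element_id = integer(0), read_id = character(0),
                      start = integer(0), end = integer(0)))
  per_read <- split(hits[, c("start_a", "end_a")], hits$read_a)
  out <- list()
  for (rid in sort(names(per_read))) {
    iv <- per_read[[rid]]
    iv <- iv[order(iv$start_a, iv$end_a), , drop = FALSE]
    n <- nrow(iv)
    # single linkage: consecutive (sorted) intervals agreeing at both ends
    grp <- integer(n); grp[1] <- 1L
    if (n > 1) {
      for (i in 2:n) {
        linked <- FALSE
        for (j in which(grp == grp[i - 1])) {
          if (abs(iv$start_a[i] - iv$start_a[j]) <= params$endpoint_tolerance &&
              abs(iv$end_a[i] - iv$end_a[j]) <= params$endpoint_tolerance) {
            linked <- TRUE; break
          }
        }
        grp[i] <- if (linked) grp[i - 1] else grp[i - 1] + 1L
      }
    }
    el <- do.call(rbind, lapply(unique(grp), function(g) {
      sel <- grp == g
      data.frame(start = as.integer(round(stats::median(iv$start_a[sel]))),
                 end = as.integer(round(stats::median(iv$end_a[sel]))))
    }))
    # collapse partial images: elements overlapping by at least half the
    # shorter one are the same physical copy seen through truncated
    # partners; merge to the spanning interval. Lesser overlaps stay
    # separate (split at the majority endpoints found above).
    repeat {
      el <- el[order(el$start, el$end), , drop = FALSE]
      merged <- FALSE
      i <- 1L
      while (i < nrow(el)) {
        ov <- min(el$end[i], el$end[i + 1]) - max(el$start[i],
                                                  el$start[i + 1]) + 1
        shorter <- min(el$end[i] - el$start[i], el$end[i + 1] -
                         el$start[i + 1]) + 1
        if (ov >= 0.5 * shorter) {
          el$start[i] <- min(el$start[i], el$start[i + 1])
          el$end[i] <- max(el$end[i], el$end[i + 1])
          el <- el[-(i + 1), , drop = FALSE]
          merged <- TRUE
        } else i <- i + 1L
      }
      if (!merged) break
    }
    out[[length(out) + 1]] <- data.frame(read_id = rid, start = el$start,
                                         end = el$end,
                                         stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, out)
  el <- el[order(el$read_id, el$start, el$end), , drop = FALSE]
  el <- cbind(element_id = seq_len(nrow(el)), el)
  rownames(el) <- NULL
  el
}

# Internal: map each hit side to the element with maximal overlap.
match_element <- function(elements, read_id, start, end) {
  vapply(seq_along(read_id), function(i) {
    cand <- which(elements$read_id == read_id[i] &
                    elements$start <= end[i] & elements$end >= start[i])
    if (length(cand) == 0) return(NA_integer_)
    ov <- pmin(elements$end[cand], end[i]) - pmax(elements$start[cand],
                                                  start[i]) + 1
    elements$element_id[cand[which.max(ov)]]
  }, integer(1))
}

#' Cluster elements into repeat families
#'
#' Builds the element graph (one edge per supporting pairwise hit) and
#' takes single-linkage connected components as families. Element
#' orientations are propagated from an arbitrary reference element along a
#' spanning tree using hit orientation parity; parity conflicts (odd
#' cycles) are resolved by majority vote over incident edges and reported
#' via a message.
#'
#' @param elements Element table from [define_elements()].
#' @param hits Symmetric hit table from [allpairs_search()].
#' @param params A [family_params()] object.
#' @return List of class `repeat_families`: `families` (data.frame:
#'   `family_id`, `count`), `elements` (element table with `family_id` and
#'   `orientation` columns), plus empty `consensus` fields filled by
#'   [build_consensus()].
#' @export
cluster_families <- function(elements, hits, params = family_params()) {
  if (nrow(elements) == 0 || nrow(hits) == 0) {
    return(structure(list(
      families = data.frame(family_id = character(0), count = integer(0)),
      elements = cbind(elements, family_id = character(0),
                       orientation = character(0)),
      consensus = character(0)), class = "repeat_families"))
  }
  ea <- match_element(elements, hits$read_a, hits$start_a, hits$end_a)
  eb <- match_element(elements, hits$read_b, hits$start_b, hits$end_b)
  ok <- !is.na(ea) & !is.na(eb) & ea != eb
  edges <- data.frame(a = ea[ok], b = eb[ok],
                      flip = hits$orientation[ok] == "opposite")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$a), to = as.character(edges$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(elements$element_id)))
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(elements$element_id)]

  # orientation parity by BFS over a spanning forest
  orient <- rep(NA, nrow(elements))
  names(orient) <- as.character(elements$element_id)
  adj <- split(seq_len(nrow(edges)), as.character(edges$a))
  edge_other <- function(ei, v) {
    if (as.character(edges$a[ei]) == v) as.character(edges$b[ei])
    else as.character(edges$a[ei])
  }
  for (root in as.character(elements$element_id)) {
    if (!is.na(orient[root])) next
    orient[root] <- TRUE  # reference element: forward
    queue <- root
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (ei in adj[[v]]) {
        w <- edge_other(ei, v)
        o <- xor(orient[v], edges$flip[ei])
        if (is.na(orient[w])) {
          orient[w] <- o
          queue <- c(queue, w)
        }
      }
    }
  }
  # resolve parity conflicts by majority over incident edges
  conflicts <- 0L
  for (v in as.character(elements$element_id)) {
    eis <- c(adj[[v]], which(as.character(edges$b) == v))
    if (length(eis) == 0) next
    votes <- vapply(eis, function(ei) {
      w <- edge_other(ei, v)
      xor(orient[w], edges$flip[ei])
    }, logical(1))
    maj <- mean(votes) >= 0.5
    if (maj != orient[v]) {
      if (any(votes != maj)) conflicts <- conflicts + 1L
      orient[v] <- maj
    }
  }
  if (conflicts > 0)
    message(conflicts, " orientation parity conflicts resolved by majority")

  el <- elements
  el$family_id <- sprintf("FAM%03d", membership)
  el$orientation <- ifelse(orient[as.character(el$element_id)], "+", "-")
  fam <- as.data.frame(table(el$family_id), stringsAsFactors = FALSE)
  names(fam) <- c("family_id", "count")
  fam <- fam[order(-fam$count, fam$family_id), ]
  rownames(fam) <- NULL
  structure(list(families = fam, elements = el,
                 consensus = character(0)),
            class = "repeat_families")
}

#' Drop families below the copy-number floor
#'
#' Retains families whose element count is at least `min_family_count`
#' (default 20); lower-count families are not analyzed further.
#'
#' @param fams A `repeat_families` object.
#' @param params A [family_params()] object.
#' @return The filtered `repeat_families` object.
#' @export
filter_families <- function(fams, params = family_params()) {
  keep <- fams$families$family_id[fams$families$count >=
                                    params$min_family_count]
  fams$families <- fams$families[fams$families$family_id %in% keep, ,
                                 drop = FALSE]
  fams$elements <- fams$elements[fams$elements$family_id %in% keep, ,
                                 drop = FALSE]
  fams$consensus <- fams$consensus[names(fams$consensus) %in% keep]
  rownames(fams$families) <- rownames(fams$elements) <- NULL
  fams
}

# Internal: extract reoriented element sequences of one family.
element_seqs <- function(fams, reads, family_id) {
  el <- fams$elements[fams$elements$family_id == family_id, , drop = FALSE]
  s <- substring(reads[el$read_id], el$start, el$end)
  flip <- el$orientation == "-"
  s[flip] <- revcomp_chr(s[flip])
  names(s) <- paste0("el", el$element_id)
  s
}

# Internal: star alignment of element sequences against the longest one;
# per-column majority base (ties alphabetical); columns covered by fewer
# than 2 elements are trimmed from both ends.
star_consensus <- function(seqs, params = family_params()) {
  if (length(seqs) == 1) return(toupper(seqs[[1]]))
  seqs <- toupper(seqs)
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  prof <- matrix(0L, nrow = 4, ncol = L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  add_seq <- function(chars, pos) {
    keep <- chars %in% rownames(prof)
    idx <- cbind(match(chars[keep], rownames(prof)), pos[keep])
    for (r in seq_len(nrow(idx)))
      prof[idx[r, 1], idx[r, 2]] <<- prof[idx[r, 1], idx[r, 2]] + 1L
  }
  cov <- integer(L)
  ref_chars <- strsplit(ref, "")[[1]]
  add_seq(ref_chars, seq_len(L))
  cov <- cov + 1L
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  for (i in seq_along(seqs)[-ref_i]) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs[[i]], subject = ref, type = "global-local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    pstr <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sstr <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    pos <- integer(0); chars <- character(0)
    for (k in seq_along(sstr)) {
      if (sstr[k] != "-") {
        spos <- spos + 1L
        if (pstr[k] != "-") {
          pos <- c(pos, spos); chars <- c(chars, pstr[k])
        }
      }
    }
    add_seq(chars, pos)
    cov[unique(pos)] <- cov[unique(pos)] + 1L
  }
  maj <- rownames(prof)[apply(prof, 2, which.max)]
  inside <- which(cov >= 2)
  if (length(inside) == 0) return(ref)
  paste(maj[min(inside):max(inside)], collapse = "")
}

#' Build family consensus sequences
#'
#' Star-aligns every (reoriented) element of each family against the
#' family's longest element, takes the per-column majority base
#' (ties broken alphabetically A < C < G < T) and trims terminal columns
#' covered by fewer than 2 elements. Single-element families use the
#' element itself as consensus.
#'
#' @param fams A `repeat_families` object.
#' @param reads The (unmasked) named read vector the elements live on.
#' @param params A [family_params()] object.
#' @return `fams` with the `consensus` field filled (named character
#'   vector) and consensus length/GC columns added to `families`.
#' @export
build_consensus <- function(fams, reads, params = family_params()) {
  reads <- as_read_vector(reads)
  cons <- vapply(fams$families$family_id, function(fid) {
    star_consensus(element_seqs(fams, reads, fid), params)
  }, character(1))
  fams$consensus <- cons
  fams$families$consensus_length <- nchar(cons[fams$families$family_id])
  fams$families$gc_pct <- vapply(cons[fams$families$family_id], function(s) {
    if (nchar(s) == 0) return(NA_real_)
    gc_content(c(x = s))
  }, numeric(1), USE.NAMES = FALSE)
  fams
}

# Internal: percent identity of a local alignment between two sequences,
# and its length; used by curation and exclusion screening.
local_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(pattern = a, subject = b,
                                       type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  n <- Biostrings::nchar(aln)
  if (n == 0) return(c(identity = 0, length = 0))
  c(identity = Biostrings::pid(aln) / 100, length = n)
}

#' Merge/split curation of repeat families
#'
#' Automated stand-in for manual curation. Merge: families whose consensi
#' align at `merge_identity` or better over at least `merge_coverage` of
#' the shorter consensus are merged transitively and their consensus
#' rebuilt. Split: families whose mean element-to-consensus identity falls
#' below `split_identity_floor` are re-clustered using only hits at
#' identity `min_hit_identity + 0.1` or better. The merge/split pass
#' repeats until a fixed point, bounded at 5 iterations.
#'
#' @param fams A `repeat_families` object with consensi built.
#' @param reads Named read vector.
#' @param hits Symmetric hit table (needed for re-clustering on split).
#' @param params A [family_params()] object.
#' @return The curated `repeat_families` object.
#' @export
curate_families <- function(fams, reads, hits, params = family_params()) {
  reads <- as_read_vector(reads)
  for (iter in seq_len(5)) {
    changed <- FALSE
    ids <- fams$families$family_id
    # ---- merge pass
    if (length(ids) > 1) {
      parent <- seq_along(ids)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
        ca <- fams$consensus[[ids[i]]]; cb <- fams$consensus[[ids[j]]]
        shorter <- min(nchar(ca), nchar(cb))
        li <- local_identity(ca, cb)
        lir <- local_identity(ca, revcomp_chr(cb))
        if (lir["length"] > li["length"] ||
            (lir["length"] == li["length"] &&
             lir["identity"] > li["identity"])) li <- lir
        if (li["identity"] >= params$merge_identity &&
            li["length"] >= params$merge_coverage * shorter) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) { parent[ri] <- rj; changed <- TRUE }
        }
      }
      roots <- vapply(seq_along(ids), find, integer(1))
      if (length(unique(roots)) < length(ids)) {
        relabel <- ids[roots]
        names(relabel) <- ids
        fams$elements$family_id <- unname(relabel[fams$elements$family_id])
        fam <- as.data.frame(table(fams$elements$family_id),
                             stringsAsFactors = FALSE)
        names(fam) <- c("family_id", "count")
        fams$families <- fam[order(-fam$count, fam$family_id), ]
        rownames(fams$families) <- NULL
        fams$consensus <- character(0)
        fams <- build_consensus(fams, reads, params)
      }
    }
    # ---- split pass
    ids <- fams$families$family_id
    for (fid in ids) {
      seqs <- element_seqs(fams, reads, fid)
      if (length(seqs) < 2) next
      cons <- fams$consensus[[fid]]
      idents <- vapply(seqs, function(s) local_identity(s, cons)["identity"],
                       numeric(1))
      if (mean(idents) >= params$split_identity_floor) next
      changed <- TRUE
      message("re-clustering low-coherence family ", fid)
      sub_params <- params
      sub_params$min_hit_identity <- min(1, params$min_hit_identity + 0.1)
      el <- fams$elements[fams$elements$family_id == fid, , drop = FALSE]
      sub_hits <- hits[hits$identity >= sub_params$min_hit_identity &
                         hits$read_a %in% el$read_id &
                         hits$read_b %in% el$read_id, , drop = FALSE]
      sub <- cluster_families(el[, c("element_id", "read_id", "start", "end")],
                              sub_hits, sub_params)
      sub$elements$family_id <- paste0(fid, "s",
                                       as.integer(factor(sub$elements$family_id)))
      fams$elements <- rbind(
        fams$elements[fams$elements$family_id != fid, , drop = FALSE],
        sub$elements)
      fam <- as.data.frame(table(fams$elements$family_id),
                           stringsAsFactors = FALSE)
      names(fam) <- c("family_id", "count")
      fams$families <- fam[order(-fam$count, fam$family_id), ]
      rownames(fams$families) <- NULL
      fams$consensus <- character(0)
      fams <- build_consensus(fams, reads, params)
    }
    if (!changed) break
    if (iter == 5) message("curation did not converge in 5 iterations")
  }
  fams
}

#' Screen families against an exclusion set
#'
#' Sets aside families whose consensus aligns to any exclusion sequence
#' (e.g. an rRNA screen) at 80% identity or better over at least 100 bp.
#'
#' @param fams A `repeat_families` object with consensi built.
#' @param exclusion_fasta Path to the exclusion FASTA, or NULL to skip.
#' @return List with `kept` and `excluded` `repeat_families` objects.
#' @export
screen_exclusion <- function(fams, exclusion_fasta = NULL) {
  if (is.null(exclusion_fasta))
    return(list(kept = fams, excluded = subset_families(fams, character(0))))
  if (!file.exists(exclusion_fasta))
    stop("exclusion file not found: ", exclusion_fasta)
  excl <- read_reads_fasta(exclusion_fasta)
  bad <- vapply(fams$families$family_id, function(fid) {
    cons <- fams$consensus[[fid]]
    for (e in excl) {
      for (target in c(e, revcomp_chr(e))) {
        li <- local_identity(cons, target)
        if (li["identity"] >= 0.80 && li["length"] >= 100) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  list(kept = subset_families(fams, fams$families$family_id[!bad]),
       excluded = subset_families(fams, fams$families$family_id[bad]))
}

# Internal: restrict a repeat_families object to the given family ids.
subset_families <- function(fams, ids) {
  fams$families <- fams$families[fams$families$family_id %in% ids, ,
                                 drop = FALSE]
  fams$elements <- fams$elements[fams$elements$family_id %in% ids, ,
                                 drop = FALSE]
  fams$consensus <- fams$consensus[names(fams$consensus) %in% ids]
  rownames(fams$families) <- rownames(fams$elements) <- NULL
  fams
}

#' Scan a family consensus for internal tandem structure
#'
#' Reuses the tandem-array caller with the unit ceiling raised to
#' consensus length / 1.9, reporting each internal array as a
#' (unit bp, copies) pair with copies to one decimal.
#'
#' @param consensus Consensus DNA string (>= 24 bp).
#' @param params A [detector_params()] object (unit ceiling is overridden).
#' @return data.frame with `unit` and `copies`; zero rows if tandem-free.
#' @export
internal_tandem_scan <- function(consensus, params = detector_params()) {
  if (nchar(consensus) < 24)
    stop("consensus too short for an internal tandem scan (< 24 bp)")
  params$max_unit <- max(1L, as.integer(floor(nchar(consensus) / 1.9)))
  arr <- call_tandem_arrays(consensus, params, read_id = "consensus")
  data.frame(unit = arr$period, copies = round(arr$copy_number, 1))
}

#' Family abundance accounting
#'
#' Per family: summed element length, genome fraction (total length over
#' surveyed bp) and extrapolated genome-wide copy number (count divided by
#' the sampling fraction of the survey), plus grand totals.
#'
#' @param fams A `repeat_families` object.
#' @param surveyed_bp Total surveyed length, bp.
#' @param sampling_fraction Fraction of the genome surveyed, in (0, 1].
#' @return List with `per_family` (data.frame: `family_id`, `count`,
#'   `consensus_length`, `gc_pct`, `total_length`, `genome_fraction_pct`,
#'   `extrapolated_copies`) and `total` (summed length, combined fraction).
#' @export
family_accounting <- function(fams, surveyed_bp, sampling_fraction) {
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  el <- fams$elements
  lens <- tapply(el$end - el$start + 1, el$family_id, sum)
  pf <- fams$families
  pf$total_length <- as.integer(lens[pf$family_id])
  pf$genome_fraction_pct <- pf$total_length / surveyed_bp * 100
  pf$extrapolated_copies <- pf$count / sampling_fraction
  rownames(pf) <- NULL
  list(per_family = pf,
       total = list(total_length = sum(pf$total_length),
                    genome_fraction_pct = sum(pf$total_length) /
                      surveyed_bp * 100))
}

#' Combined repeat-category totals
#'
#' Sums category lengths (e.g. retrotransposons, DNA transposons,
#' virus-like families, unannotated families, microsatellites) and reports
#' each category's and the combined percentage of the surveyed length.
#'
#' @param category_bp Named numeric vector of per-category lengths, bp.
#' @param surveyed_bp Surveyed length, bp.
#' @return List with `per_category` (data.frame: `category`, `bp`, `pct`)
#'   and `total_bp`, `total_pct`.
#' @export
repeat_category_totals <- function(category_bp, surveyed_bp) {
  if (surveyed_bp <= 0) stop("surveyed_bp must be positive")
  df <- data.frame(category = names(category_bp),
                   bp = as.numeric(category_bp),
                   pct = as.numeric(category_bp) / surveyed_bp * 100,
                   stringsAsFactors = FALSE)
  list(per_category = df, total_bp = sum(df$bp),
       total_pct = sum(df$bp) / surveyed_bp * 100)
}

#' Write family outputs
#'
#' Writes the consensus multi-FASTA (one record per family), the element
#' membership TSV (`family_id`, `read_id`, `start`, `end`, `orientation`)
#' and the accounting TSV.
#'
#' @param fams A `repeat_families` object with consensi built.
#' @param accounting Result of [family_accounting()].
#' @param dir Output directory.
#' @param header Optional provenance comment lines for the TSVs.
#' @return The directory, invisibly.
#' @export
write_family_outputs <- function(fams, accounting, dir,
                                 header = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(fams$consensus) > 0)
    write_reads_fasta(fams$consensus, file.path(dir, "family_consensus.fasta"))
  wr <- function(df, name) {
    con <- file(file.path(dir, name), "w")
    on.exit(close(con), add = TRUE)
    for (h in header) writeLines(paste0("# ", h), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(fams$elements[, c("family_id", "read_id", "start", "end",
                       "orientation")], "family_members.tsv")
  pf <- accounting$per_family
  pf$genome_fraction_pct <- round(pf$genome_fraction_pct, 3)
  pf$extrapolated_copies <- round(pf$extrapolated_copies)
  wr(pf, "family_accounting.tsv")
  invisible(dir)
}
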