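#' Canonical microsatellite motif classes
#'
#' A tandem-repeat unit can be written many ways: any rotation of the unit,
#' and any rotation of its reverse complement, describes the same locus
#' (e.g. TC, CT, GA and AG are one class, conventionally written AG;
#' TTAGG and AACCT are one class, the arthropod telomere motif). The
#' canonical label is the lexicographically smallest string (A < C < G < T)
#' over that equivalence set. Units that are themselves repetitions of a
#' shorter unit (e.g. ATAT) are first reduced to their primitive period, so
#' every class label is primitive.
#'
#' @param motif Character vector of repeat units over A/C/G/T, each 1-6 bp.
#' @return Character vector of canonical class labels, same length as
#'   `motif`.
#' @examples
#' canonical_motif(c("TC", "TTAGG", "GGC"))  # "AG" "AACCT" "CCG"
#' @export
canonical_motif <- function(motif) {
  if (length(motif) == 0) return(character(0))
  ok <- grepl("^[ACGT]+$", motif) & nchar(motif) >= 1 & nchar(motif) <= 6
  if (!all(ok)) {
    stop("motifs must be non-empty strings over {A,C,G,T} of length 1-6; ",
         "offending: ", paste(unique(motif[!ok]), collapse = ", "))
  }
  vapply(motif, function(m) {
    p <- primitive_period(m)
    m <- substr(m, 1, p)
    rc <- revcomp_chr(m)
    cands <- c(vapply(seq_len(p) - 1L, rotate_chr, character(1), s = m),
               vapply(seq_len(p) - 1L, rotate_chr, character(1), s = rc))
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all canonical motif classes of a given unit length
#'
#' Brute-force enumeration of all 4^unit strings, dropping units reducible
#' to a shorter period and collapsing the rest under rotation and reverse
#' complementation. Class counts for units 1-6 are 2, 4, 10, 33, 102, 350.
#'
#' @param unit Unit length in bp (1-6).
#' @return Sorted character vector of canonical class labels.
#' @examples
#' enumerate_motif_classes(2)  # "AC" "AG" "AT" "CG"
#' @export
enumerate_motif_classes <- function(unit) {
  if (!is.numeric(unit) || length(unit) != 1 || unit < 1 || unit > 6 ||
      unit != round(unit)) {
    stop("unit must be a single integer in 1..6")
  }
  unit <- as.integer(unit)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), unit), stringsAsFactors = FALSE))
  all_units <- do.call(paste0, grid)
  primitive <- vapply(all_units, primitive_period, integer(1)) == unit
  sort(unique(canonical_motif(all_units[primitive])))
}
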