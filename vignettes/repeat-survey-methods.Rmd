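---
title: "Methods: repeat landscapes from genome survey sequences"
author: "repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscapes from genome survey sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Setting

A genome survey samples a genome by sequencing a few megabases of random
clone ends — here, fosmid-end-like reads of 100–861 bp with a mean around
531 bp — and infers genome-wide properties from that sample: how much of
the genome is microsatellite, which motifs dominate and at what lengths,
which interspersed repeat families exist and at what copy numbers, and how
large the genome is in the first place. Every estimate is an extrapolation
under the assumption of unbiased sampling: a family seen `k` times in a
fraction `f` of the genome is extrapolated to `k / f` genomic copies, and a
class occupying `p`% of the surveyed bases is taken to occupy `p`% of the
genome. Clone-ability and sequencing-failure biases violate this assumption
in real libraries in ways a simulation cannot capture; see *Limitations*.

# Tandem-repeat detection

## Model

A microsatellite locus is modeled as a maximal segment that aligns well
against an unbounded cyclic repetition of a short unit (1–6 bp by default).
The alignment is scored +2 per matching column, −3 per mismatching column
and −5 per gap column, and computed by wraparound dynamic programming: the
DP state is (segment position, unit phase), the unit wraps from its last
phase to its first at no cost, and the start and end phase are free. Within
a DP row, deletion moves cycle through the phases; two relaxation passes
around the phase ring suffice because a full cycle of deletions has
strictly negative weight. The implementation is in C++ (`src/wraparound.cpp`)
with global (whole segment) and local (best sub-segment) modes.

The independent test oracle is a fitting alignment of the segment against
an explicitly unrolled repetition of the unit with free leading and
trailing text. The unroll length is grown adaptively until the score
stabilizes: a fixed unroll of one extra unit is provably sufficient only
when the optimal alignment uses fewer motif deletions than one unit's
worth, and on adversarial random segments (deeply negative scores) that
bound occasionally fails.

## Candidate discovery

Scanning every position at every period with the DP is wasteful, so
candidates are found first: for each period `d`, the indicator
`v[i] = [s[i] == s[i+d]]` is tallied in sliding windows of
`w = max(12, 2d)` positions; windows reaching half matches trigger, and
overlapping triggered windows are merged and trimmed to the first/last
actual match. Any perfect array of at least 12 bp is guaranteed a covering
candidate: a perfect array of length `L ≥ 12` yields `L − d ≥ w − d ≥ w/2`
consecutive matches. Random background triggers occasional candidates;
these die at the score filter and only cost time.

The consensus unit of a candidate is the per-phase majority base, with two
safeguards: only positions that confirm the periodicity (`v[i] = 1`, or
`d` ahead of one) vote, so flanking sequence inside a generous candidate
window cannot pollute the unit; and ties break alphabetically (A < C < G <
T), which keeps detection symmetric under reverse complement.

## Reporting filters and boundary semantics

An array is reported when score ≥ 50 **and** span ≥ 12 bp **and** purity
(matches over aligned columns) is strictly greater than 0.55. The score and
length floors deliberately do not interlock: with weights {2, 3, 5} a
perfect 12-bp array scores 24, so at the default score floor the effective
perfect-array floor is 25 bp. Both knobs are exposed; setting
`min_score = 24` realizes a literal 12-bp floor. Purity is defined over the
array-vs-cyclic-unit alignment, which is simpler than the adjacent-copy
definition some tools use and is documented as such.

Boundaries are those of the score-maximal local alignment. Score-maximal
boundaries genuinely wander a few bases into flanking sequence whenever the
flank happens to continue the repeat phase (possibly via a single-indel
"unit slip"); this is a property of the objective, not a defect, and the
recovery tests therefore compare calls against boundaries recomputed by an
independent exhaustive local DP on the planted window rather than against
raw planted coordinates, which no score-maximal detector could reproduce
when terminal bases are mutated.

Two post-rules shape multi-array loci: a sustained interruption inside a
called span (a 12-bp window with at most 25% distance-d matches) splits the
call, so two same-period arrays bridged by a short spacer are reported
separately; and overlap resolution keeps the highest score (ties: smaller
period, then leftmost), dropping any call that overlaps an accepted one by
more than one repeat unit. Units that are repetitions of a shorter unit are
reassigned to the primitive period. Alignments never cross runs of two or
more N; a single N scores as a mismatch.

# Motif canonicalization

Rotation (a phase choice) and reverse complementation (a strand choice) do
not change a tandem-repeat locus, so units are classified by the
lexicographically smallest string among all rotations of the unit and of
its reverse complement, after reduction to the primitive period. The
enumeration of classes (2, 4, 10, 33, 102, 350 for units 1–6) is tested
against brute-force partitioning of all `4^k` strings with an independently
written canonicalizer.

# Landscape statistics

Per-class statistics follow the standard survey-report layout: locus count,
number and percentage of reads carrying the class (a read counts once per
class), summed bases and their share of the surveyed length, max/mean/SD
locus length, mean repeat number (mean length / unit), relative abundance
(RA%, class bases over all microsatellite bases) and relative frequency
(RF%, class loci over all loci). RA and RF each sum to 100% by
construction. Density is surveyed kb per locus, to two decimals; length
classes use the conventional bins 12–20, 21–40, …, 181–200, > 200 bp.
Internally everything is kept at full precision; only written reports round
to two decimals. In-memory coordinates are 1-based inclusive throughout
(the R/Bioconductor convention); the on-disk truth format is 0-based
half-open, converted at the I/O boundary.

# Repeat-family discovery

The pipeline mirrors the classic survey workflow: mask tandem arrays to N,
run an all-vs-all nucleotide search, and cluster the resulting pairwise
hits into families.

- **Search.** The all-vs-all stage runs the standard BLASTN engine
  (word size 11, E ≤ 1e−6, dust off) and keeps hits of at least 100 bp at
  80% identity or better, symmetrized and deduplicated. The search
  parameters of the original survey protocols are not fully published;
  these floors are the commonly stated ones and are configurable.
- **Element definition.** Per read, hit intervals whose two endpoints agree
  within 30 bp (single linkage) become one element at the median endpoints.
  Elements on the same read overlapping by at least half the shorter are
  then merged to their span: such pairs are partial "images" of one
  physical copy seen through truncated partners, and without this merge
  truncated families inflate their counts. Lesser overlaps stay separate.
- **Clustering.** Elements are nodes; each hit contributes an edge;
  connected components are families. Orientations propagate from an
  arbitrary reference element by hit-orientation parity along a BFS tree;
  parity conflicts (odd cycles) resolve by majority over incident edges.
- **Consensus.** A star alignment of all reoriented elements against the
  longest element (Biostrings pairwise alignment, global-local), per-column
  majority with alphabetical tie-break, ends trimmed where fewer than two
  elements cover. For substitution-dominated divergence this is close to a
  full MSA at a fraction of the cost; a progressive MSA plus tree, as a
  manual-curation workflow would use, is deliberately out of scope.
- **Curation.** Manual merge/split decisions are replaced by thresholds:
  merge families whose consensi align at ≥ 80% identity over ≥ 50% of the
  shorter consensus (transitively); re-cluster families whose mean
  element-to-consensus identity falls below 60% using only hits at the
  base identity floor + 0.1. The pass iterates to a fixed point, bounded at
  five iterations.
- **Screening and accounting.** Families matching an exclusion FASTA
  (e.g. rRNA) at ≥ 80% identity over ≥ 100 bp are set aside. Families with
  fewer than 20 copies are not analyzed further. Accounting reports summed
  element length, genome fraction, and extrapolated genome copies
  (count / sampling fraction); consensi are scanned for internal tandem
  structure by the same wraparound detector with the unit ceiling raised to
  consensus length / 1.9.

A note on divergence: copies drawn at per-copy divergence `d` from a common
consensus differ pairwise at roughly `2d(1 − d/ …)` ≈ `2d` sites. The 80%
hit-identity floor therefore admits families up to ~15% *pairwise*
divergence (per-copy rates up to ~7.5%); at 15% per-copy divergence no
pairwise hits can form at the default floors, which is a property of the
parameterization, not a bug. The recovery tests plant per-copy rates of
0.05–0.10 accordingly.

# Genome sizing and survey calculators

The 1C DNA content is the ratio of the sample G1 fluorescence peak to the
standard's G1 peak, times the standard's content (default human lymphocyte,
3.50 pg/nucleus). Peaks are located as the mode of a moving-average-
smoothed histogram (window 5 channels), refined to the count-weighted
centroid of the contiguous region at or above half the peak height; if a
second local maximum within 5% of the peak height lies outside that region
the histogram is declared multimodal and an explicit gate is required.

Two picogram-to-base-pair conversions are offered. The default scales a
reference genome length by the measured ratio (`ratio × 3.0e9` for a human
standard): a ratio of 0.722 then gives 2.53 pg and ≈ 2.17 Gb, the
convention under which a survey's coverage and sampling-fraction arithmetic
is self-consistent. The alternative multiplies picograms by 0.978e9 bp/pg,
giving ≈ 2.47 Gb for the same ratio. The two differ by ~14% and published
surveys are not always explicit about which they used; both are exposed
(`bp_from = "reference"` / `"pg"`). Note that with the reference
convention, a sampling fraction quoted as 0.45% for ≈ 11.1 Mb of survey
implies the pg-converted genome size — the two conventions genuinely
disagree at the second decimal, and the package simply computes whichever
the caller configures.

Coverage is clones × insert / genome (the nominal 40-kb fosmid insert by
default, the measured mean being configurable); gene count is
coding-fraction × genome / gene-size evaluated at both ends of a gene-size
range, with density as its reciprocal.

# The simulator

The simulator emulates the study conditions, not sequencing chemistry:
read lengths from a truncated normal with SD = (max − min)/6 redrawn into
[min, max] (the published distribution summary gives only min/mean/max);
i.i.d. background bases at the configured GC (45.88% by default — no
higher-order composition); planted microsatellites as unit repetitions with
per-base substitution and single-base indel rates; planted family copies as
a per-family random consensus mutated per copy, optionally 5'/3'-truncated
(keeping a uniform 50–90%), reverse-complemented with probability 0.5, and
overwritten into reads without overlap. Every plant is recorded with its
realized interval and the exact mutation operations, so tests can revert
mutations and verify byte-level round-trips. All randomness flows from one
integer seed; identical configuration and seed give byte-identical FASTA.

What passing on this simulator does **not** show: robustness to sequencing
error and quality variation (no error model, no FASTQ), chimeric clones,
compositional heterogeneity (isochores, GC-rich islands), nested or
fragmented ancient repeat copies, and the clone-ability biases that make
real fosmid libraries non-uniform samples. Results on real surveys depend
on those factors; the simulator establishes correctness of the machinery,
not field performance.

# Numerical and design choices

- Problem sizes in the test suite (150–300 reads, ~80–160 kb; families of
  20–30 copies; 100 flow-histogram pairs; 500 oracle alignments) were
  chosen as the smallest scales at which the statistical properties under
  test are stable across seeds.
- Alignment tie-breaks: traceback prefers diagonal over insertion over
  deletion; overlap resolution prefers higher score, then smaller period,
  then leftmost start; consensus ties go to the alphabetically first base.
  All are deterministic, making whole-pipeline outputs byte-reproducible.
- Degenerate inputs: empty or non-ACGTN sequences, zero-locus density,
  empty partitions, non-positive peaks and out-of-range fractions raise
  errors naming the offending field; single-element families use the
  element as consensus; single-bin histograms return that bin.
- The wraparound DP stores the full (n+1) × m matrix; with survey reads of
  ≤ 1 kb and units ≤ 6 bp (or consensus-scan units up to a few hundred bp
  on consensi of a few kb) this is at most a few megabytes.
- `scan-ssr` on the reverse complement of a read yields the
  coordinate-mirrored calls; this held on every tested case once consensus
  tie-breaking was made orientation-symmetric, and is enforced by test.

# Limitations

- The family-discovery stage requires the external `blastn` binary; the
  search is not reimplemented in R.
- Star-alignment consensus degrades for indel-rich families (the simulator
  plants substitution-only family copies; real decayed transposons have
  indels), and single-linkage clustering can chain families through shared
  domains — the merge/split curation bounds but does not eliminate this.
- Element counts for heavily truncated families depend on the 50%-overlap
  image merge; pathological truncation mixtures can still split one family
  into count-inflated fragments.
- The multimodality guard in peak detection assumes G1 peaks dominate;
  G2/S-phase modeling and staining corrections are out of scope.
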