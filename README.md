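# repeatscape

Repeat landscapes from genome survey sequences.

`repeatscape` is an R package for characterizing the repetitive fraction of
a genome from a random sample of reads — the classic genome-survey setting
in which a few megabases of fosmid- or BAC-end sequences stand in for an
unsequenced, repeat-rich genome (large marine invertebrates are the
motivating case). It provides, as one pipeline or as independent pieces:

- **Tandem-repeat (microsatellite) detection.** Candidate periods are found
  by a distance-d base-match scan; each candidate is aligned against an
  unbounded cyclic repetition of its majority unit by wraparound dynamic
  programming with weights {match, mismatch, indel} = {2, 3, 5}. Arrays are
  reported when score ≥ 50, span ≥ 12 bp, and percent matches (purity)
  strictly exceeds 55%; compound adjacent arrays are reported separately.
- **Canonical motif classification.** A repeat unit and all rotations of
  itself and of its reverse complement form one class named by the
  lexicographically smallest member (TC/GA/CT → AG; TTAGG → AACCT, the
  arthropod telomere motif). There are 2, 4, 10, 33, 102 and 350 classes of
  unit 1–6.
- **Landscape statistics.** Per-class locus counts, bases, relative
  abundance (RA%, bases over all microsatellite bases) and relative
  frequency (RF%, loci over all loci), read incidence, density (kb per
  locus), length-class histograms (L1: 12–20 bp … L11: > 200 bp) and
  genomic-vs-transcript partition comparisons.
- **De novo repeat-family discovery.** All-vs-all search of tandem-masked
  reads (BLASTN engine), RECON-style element definition with endpoint
  tolerance, single-linkage clustering with orientation propagation,
  star-alignment majority consensus, threshold-driven merge/split curation,
  rRNA-style exclusion screening, internal-tandem scans of consensi, and
  abundance accounting with genome-wide copy extrapolation
  (count / sampling fraction).
- **Genome sizing and survey calculators.** Flow-cytometry G1-peak
  detection (moving-average smoothing, FWHM centroid) and 1C estimation by
  fluorescence ratio to a standard (default human lymphocyte, 3.50
  pg/nucleus); library coverage, GC content, gene count and density
  extrapolations.
- **A seeded synthetic-read simulator** producing fosmid-end-like reads
  (100–861 bp, mean 531 bp, configurable GC) with planted microsatellites
  and repeat families and a full ground-truth table, so the whole pipeline
  is testable without any external data.

## A worked example

```r
library(repeatscape)

cfg <- sim_config(
  n_reads = 300, seed = 42,
  planted_ssrs = list(ssr_plant("AG", 40, per_base_mutation = 0.02, n_loci = 25),
                      ssr_plant("AAT", 20, per_base_mutation = 0.05, n_loci = 15),
                      ssr_plant("AACCT", 30, n_loci = 5)),
  planted_families = list(family_plant("famA", 500, 30, divergence = 0.05,
                                       truncation_fraction = 0.2),
                          family_plant("famB", 300, 24, divergence = 0.10)))
sim    <- simulate_reads(cfg)
arrays <- scan_tandem_arrays(sim$reads)
report <- landscape_report(arrays, length(sim$reads),
                           sum(nchar(sim$reads)), sim$reads)
print(report)
```

```
Microsatellite landscape: 45 loci, 3763 bp (2.38% of survey)
  density: 1 per 3.51 kb; mean locus length 83.6 bp; A/T 63.5%
  reads with >=1 locus: 14.0%
Top motifs by RF%:
 motif counts bases mean_length ra_pct rf_pct
    AG     25  2073       82.92  55.09  55.56
   AAT     15   934       62.27  24.82  33.33
 AACCT      5   756      151.20  20.09  11.11
```

All 45 planted loci are recovered into their three canonical classes; RA
and RF columns sum to 100%. Continuing with family discovery:

```r
masked <- mask_tandem_arrays(sim$reads, arrays)
fp     <- family_params()
hits   <- allpairs_search(masked, fp, arrays)
fams   <- cluster_families(define_elements(hits, fp), hits, fp)
fams   <- filter_families(fams, fp)                      # keep >= 20 copies
fams   <- build_consensus(fams, sim$reads, fp)
fams   <- curate_families(fams, sim$reads, hits, fp)
fams$families
#>   family_id count consensus_length   gc_pct
#> 1    FAM001    30              508 48.03150
#> 2    FAM002    24              302 46.68874
```

Both planted families come back at their planted copy numbers with
consensi essentially identical to the planted truth. Genome-survey
arithmetic works the same way on real constants, e.g. a library of 288,000
clones with 40-kb inserts over a 2.17-Gb genome:

```r
library_coverage(288000, 40000, 2.17e9)   # 5.31 — ~5.3x genome equivalents
estimate_genome_size(722, 1000)           # ratio 0.722 -> 2.53 pg, 2.17e9 bp
microsat_density(8441, 11114786)          # 1.32 kb per locus
```

The same stages are available from a shell via the thin CLI,
`inst/cli/repeatscape`, with subcommands `simulate`, `scan-ssr`,
`summarize`, `families`, `genome-size`, `survey` and `run` (the bundled
demo: `repeatscape run --config inst/extdata/demo_config.yaml --out out/`).

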