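# chipprox

Downstream analysis of ChIP-seq peak calls, built for the question *"does
this transcription factor bind near the genes of one cell-type's expression
program?"* — the setting where a factor driving oligodendrocyte
differentiation is contrasted against neuron- and astrocyte-specific gene
lists. The package takes called peaks (BED), gene tables (TSV) and
peak-flanking sequences (FASTA), and provides:

* **Control filtering** — remove treatment peaks with a corresponding
  (≥ 1 bp overlapping) peak in a control condition, partitioning the set
  exactly.
* **TSS-proximity annotation** — strand-aware assignment of peak midpoints
  to ±window TSS neighborhoods (default 100 kb), per-gene peak tallies, and
  the gene-body / upstream 1 kb / 1–20 kb / 20–100 kb / downstream category
  taxonomy.
* **Enrichment against a uniform background** — under uniform placement,
  density = `n_peaks / G` and the expected in-window count is
  `n_peaks/G × n_genes × 2 × window`; observed counts per list are reported
  as fold enrichment with per-list and joint chi-squared tests (the joint
  test conditions on the observed total, df = k − 1).
* **TSS-relative incidence histograms** — signed, strand-aware distances
  binned over ±100 kb.
* **Multi-factor overlap** — fractions of one factor's peaks overlapped by
  a second and third factor's peaks, plus the triple-overlap count.
* **Consensus motif statistics** — IUPAC scanning on both strands
  (`CTGGYAC`-style degenerate consensi), central enrichment of the best
  site per sequence against a uniform-placement binomial null, spaced-pair
  co-occurrence with a Bonferroni-adjusted binomial test, and
  discriminative k-mer discovery (Fisher exact scoring, single-position
  IUPAC generalization, mask-and-repeat).
* **Synthetic data with ground truth** — genomes, disjoint gene lists,
  peak sets with a planted within-window density fold, control sets with an
  exact constructed overlap count, and sequence sets with planted,
  centrally biased motifs, so every stage is testable offline.

## Worked example

```r
library(chipprox)

cfg <- sim_preset("tss-enriched", seed = 42)   # 3-fold planted enrichment
ds  <- simulate_dataset(cfg, "simdir")          # writes BED/TSV/FASTA + truth

flt <- filter_against_control(ds$peaks, ds$control)
nrow(flt$retained)   # 1983   (2000 treatment peaks - 17 control overlaps)
nrow(flt$removed)    # 17

lists    <- lapply(ds$lists, dedup_unique_tss)
observed <- sapply(lists, function(gl)
  peaks_per_gene(flt$retained, gl)$distinct_peaks)
expected <- sapply(lists, function(gl)
  expected_count(nrow(flt$retained), ds$genome, gl, merge_windows = TRUE))
enrichment_test(observed, expected)
#>              list observed expected   fold     chi2   p_value
#> 1          neuron      127    147.7 0.8597   2.9096 8.806e-02
#> 2       astrocyte      145    154.9 0.9363   0.6275 4.283e-01
#> 3 oligodendrocyte      391    150.2 2.6026 385.8477 6.635e-86
#> joint chi2 = 199.3, df = 2, p = 5.224e-44 (conditional on total)
```

The target list shows ~2.6-fold enrichment over the uniform expectation
(the planted fold is 3 relative to the background component; measured
against the all-peaks expectation the estimate converges to
`f·G/(G + (f−1)W_T)` ≈ 2.6 — see the vignette), while the two non-target
lists sit near fold 1.

```r
peaks_per_gene(flt$retained, lists$oligodendrocyte)$tally
#>   1   2 >=3
#>  10  14  74          # genes with 1, 2, >= 3 peaks within 100 kb

central_enrichment(ds$sequences, cfg$motif)
#> <central_enrichment> 83/85 best hits central (width 100, null 0.202): p = 6.02e-55

discover_motifs(ds$sequences, shuffle_sequences(ds$sequences, seed = 42))[1, ]
#>     iupac pos_count neg_count     fisher_p      e_value n_candidates round
#> 1 CTGGYAC        85        13 2.124703e-26 7.570531e-22        35631     1
```

The planted degenerate 7-mer is recovered as the top discovered motif, and
its planted central bias (sd 10 bp in 500 bp sequences) is detected by the
central-enrichment binomial test.

A YAML-driven end-to-end run (`run_pipeline("run.yaml")`) executes
filter → annotate → enrich → histogram → overlap → motif stages, skipping
stages whose inputs are absent, and writes per-stage TSV/JSON plus a
self-describing `summary.json`. A thin CLI wrapper lives at
`inst/scripts/chipprox` (`chipprox simulate ...`, `chipprox run ...`).

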