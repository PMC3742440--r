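---
title: "Peak-to-TSS proximity, enrichment and consensus motif statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-to-TSS proximity, enrichment and consensus motif statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipprox)
```

## The problem

A ChIP-seq experiment for a transcription factor yields a set of genomic
intervals ("peaks") where the factor binds. The biological question this
package addresses is downstream of peak calling: *are those binding sites
concentrated around the genes of one cell-type-specific expression program?*
The motivating setting is a factor driving oligodendrocyte differentiation,
with three curated gene lists (neuron-, astrocyte- and
oligodendrocyte-specific genes) serving as the contrast. The same peak set
also supports sequence-level questions: does a short consensus motif
underlie binding, is it centrally located within peak-flanking sequences,
and does it co-occur with itself or a partner motif at a fixed spacing?

`chipprox` implements this entire downstream path as small, composable
functions, plus a synthetic-data module that generates inputs with known
ground truth so that every stage can be validated end to end without any
external genome or database.

## Coordinate conventions

All intervals are BED-style: 0-based, half-open `[start, end)`. Two
intervals overlap when they share at least one base; intervals that merely
abut do not overlap. A transcript is represented by its strand, its body
`[tx_start, tx_end)` and its TSS; for a plus-strand gene the TSS is
`tx_start`, for a minus-strand gene `tx_end - 1`. Signed distances to a TSS
are strand-aware: negative means upstream (5' of the TSS), positive
downstream, so histograms over minus-strand genes mirror correctly onto
the same axis as plus-strand genes.

Every peak is reduced to a single reference point, the floored midpoint
`floor((start + end)/2)`, before any distance or window computation. The
alternative — counting a peak when any part of it overlaps a window — is
available via `peak_point = "any"`, but the midpoint is the default because
a wide peak straddling a bin or window edge would otherwise be counted in
two places at once. Window membership is closed: a midpoint exactly
`window` bp from a TSS counts.

## The control filter

`filter_against_control()` removes every treatment peak that shares at
least 1 bp with any control-condition peak; such peaks are considered
artifacts of the assay rather than factor-specific binding. The ≥1 bp
reading of "corresponding peak" is the simplest reproducible choice; a
stricter reciprocal-overlap criterion could be layered on top, but the
retained/removed partition is exact either way
(`|retained| + |removed| = |treatment|`, enforced by tests).

## Proximity counting and the uniform background

`peaks_per_gene()` assigns a peak to a gene when its midpoint lies within
`window` bp (default 100 kb, the conventional reach of distal enhancer
assignment) of the gene's TSS. Isoforms sharing an identical
(chromosome, TSS, strand) are collapsed first with `dedup_unique_tss()` so
multi-isoform genes are not over-represented. Two numbers come out of the
counting and both are reported, because they answer different questions:

* **per-gene counts** — how many genes have 1, 2, ≥3 nearby peaks (a peak
  lying between two nearby genes legitimately counts for both);
* **the distinct-peak total per list** — each peak counted once, which is
  the right numerator for a density comparison between lists.

The null model is deliberately naive: peaks placed uniformly over the
genome, density `n_peaks / genome_size`, expected in-window count
`density × n_genes × 2 × window`. `expected_count()` uses that
back-of-envelope span by default because it is the transparent,
reproducible form of the published comparison; with
`merge_windows = TRUE` it instead measures the merged union of windows
clipped to chromosome ends, which is the exact span the midpoint counting
can see and therefore the better-calibrated denominator when nearby genes'
windows overlap. With 200 genes and a 100 kb window the two differ by a
few percent at realistic TSS spacings.

`categorize_peak()` refines window membership into the taxonomy used for
binding-site pie charts: gene body (which takes precedence — an intronic
peak near the TSS is "within the gene", not "upstream"), within 1 kb /
1–20 kb / 20–100 kb upstream, or downstream of the 3' end but still within
`window` of the TSS. The upstream bin edges are fixed by the taxonomy;
`window` caps only the downstream class.

`tss_histogram()` bins the signed midpoint–TSS distances (default ±100 kb
in 5 kb bins, the resolution at which promoter-proximal structure is
visible without emptying the bins). A distance exactly on a bin edge goes
to the bin closer to the TSS; distance 0 goes to the first downstream bin.

## The enrichment test

`enrichment_test()` reports, per gene list, the fold
`observed / expected` and a one-degree-of-freedom chi-squared statistic
`(obs − exp)² / exp`, plus a joint test across lists. For the joint test
the package conditions on the observed total: expectations are rescaled to
sum to the observed in-window total and the statistic is referred to
chi-squared with `k − 1` degrees of freedom — the classic multinomial
goodness-of-fit. The unconditional alternative (raw expectations, `k`
degrees of freedom) is available via `conditional = FALSE`.

The conditional default is a deliberate calibration choice. In-window
counts behave like independent Poisson draws; the sum of `k` standardized
squared deviations from *externally fixed* expectations is approximately
chi-squared with `k` (not `k − 1`) degrees of freedom, so referring it to
`k − 1` rejects a true null at roughly twice the nominal rate for three
lists. Conditioning on the total turns the counts into a multinomial and
restores nominal behavior; the package's acceptance tests verify the
rejection rate at α = 0.05 over 200 null simulations against the exact
binomial 99% band. The conditional test asks "are peaks *distributed*
across the lists' windows in proportion to their spans?", which is the
scientific contrast of interest when one list is suspected of enrichment.

## What the peak simulator plants, exactly

`simulate_peaks()` places `n_bg` background midpoints uniformly over the
genome and `n_t` targeted midpoints uniformly over the merged union of
±`window` intervals around the target list's TSSs (span `W_T`, clipped to
chromosome ends). Requiring the within-window density to be `f` times the
surrounding background density,

```
n_bg/G + n_t/W_T = f × n_bg/G,   n_bg + n_t = n
```

gives the allocation `n_t = (f − 1) n W_T / (G + (f − 1) W_T)`. Planting
uniformly over the *merged* union keeps the planted density flat even
where neighboring genes' windows overlap.

One consequence worth stating: the pipeline's fold estimate divides by the
expectation computed from *all* `n` peaks, while the planted `f` is
relative to the background component only, so the estimate converges to
`f·G / (G + (f − 1) W_T)` rather than `f` — about 2.6 when `f = 3` at the
default sizes (2,000 peaks, 100 genes per list, 250 Mb genome, ±100 kb).
Recovery tests therefore check the mean estimate over 20 seeds against a
±20% band around the planted values, which this bias sits comfortably
inside; the per-run truth object records both `planted_fold` and
`expected_fold_vs_uniform`. Non-target lists additionally pick up planted
peaks wherever their windows overlap target windows, nudging their
expected fold from `G/(G + (f − 1) W_T)` back toward 1.

`simulate_control()` works backwards from the desired filter arithmetic:
it copies `control_overlap_count` treatment peaks that overlap no other
treatment peak (so each control peak removes exactly one), plus optional
decoys that overlap nothing. The treatment/control filter on the
`filter-demo` preset (2,102 peaks, 17 constructed overlaps) therefore
retains exactly 2,085 by construction — that preset validates the filter's
arithmetic, not its statistics.

`make_genome_and_genes()` draws TSSs uniformly per chromosome with a
minimum spacing of `2 × window / 10` (20 kb at defaults), random strands,
and 5–100 kb gene bodies; the three lists are a random partition, hence
disjoint, matching how per-cell-type top-N expression lists behave in
practice.

## Motif statistics

Motifs are IUPAC consensus strings (`CTGGYAC` with Y = C/T is the default
planted motif; `ACAAWG` is the kind of partner-factor motif the spacing
stage is meant for). `scan_motif()` reports every offset, on both strands,
where the window matches the consensus; `N` in a sequence never matches
any motif letter, including `N` in the motif, so masked bases cannot
create hits. Scanning is backed by `Biostrings` pattern matching with an
explicit N-window post-filter, and the test suite checks it against an
independent expand-every-degeneracy, try-every-offset oracle on hundreds
of random instances.

`central_enrichment()` takes the *best* site per sequence — the hit whose
center is closest to the sequence center, ties broken toward the plus
strand then leftmost — and compares the number of central best sites
(window of `central_width` bp, default 100, around the center of the
default 500 bp sequences) with a binomial null in which a hit center is
uniform over the `L − m + 1` possible placements. Best-site-only is the
default because it is robust to sequences with many incidental hits;
`best_site_only = FALSE` scores every hit as a trial. With no hit-bearing
sequences the p-value is 1 by convention.

`spaced_pair()` counts, for two motifs, co-occurrences at each gap
`g ∈ [0, max_gap]`, where the gap is the number of bases strictly between
the two matched words (two 7-mers separated by 3 bp occupy 17 bp).
Overlapping occurrences are excluded rather than errors. When primary and
secondary are the same motif, each unordered hit pair is counted once
(leftmost hit as primary); counting both orders would double every count
uniformly without changing the best gap. The null is uniform over the
`max_gap + 1` gap bins; the p-value is the binomial upper tail at the best
gap, Bonferroni-multiplied by the number of gaps and capped at 1. This is
an intentionally simple screen for fixed-spacing dimer-like binding, not a
full spacing-analysis model.

`discover_motifs()` is a desk-scale discriminative search: every exact
k-mer (k = 6–8, strand-collapsed so a word and its reverse complement are
one candidate, palindromes counted once) is scored by a one-sided Fisher
exact test on the number of positive vs negative sequences containing it;
the top words are then generalized by merging, at a single position, words
differing only there whenever the merge improves the p-value
(`CTGGCAC + CTGGTAC → CTGGYAC`). Several seeds (default 10) are
generalized because at small sample sizes the best *merged* motif often
grows from an exact word that is not itself rank 1. The reported E-value
is the Fisher p times the number of candidates evaluated — a
Bonferroni-style surrogate, not the exact E-value of a full motif-discovery
algorithm, and it is documented as such. After a motif is reported its
occurrences are masked with Ns and one further round runs.

## What the sequence simulator emulates — and what it does not

`simulate_sequences()` produces i.i.d. uniform A/C/G/T backgrounds of
fixed length (default 100 × 500 bp) and plants one motif instance in a
fraction `plant_rate` (default 0.8) of sequences, degenerate positions
realized uniformly, strand random, position normal around the center
(default sd 10 bp), clipped to valid offsets. The negatives for discovery
are per-sequence letter shuffles (`shuffle_sequences()`), preserving
composition but destroying order.

Real peak-flanking sequences are not uniform: they have GC structure,
repeats, and co-occurring partner motifs, and real motifs vary in strength
rather than being exact consensus instances. Passing the planted-recovery
tests therefore demonstrates that the statistics and search are correct
and well calibrated on their stated null, not that they would match a
production motif-discovery tool's sensitivity on genomic sequence.
Likewise the peak simulator plants enrichment as a flat density step
within windows, not the TSS-peaked decay real binding shows; that is the
matching null for the flat expectation model being tested, and a
TSS-peaked planting would be the natural extension for histogram-shape
work.

## Determinism and problem sizes

Every generator is a pure function of its configuration and seed
(`withr::with_seed` around an explicit sub-seed per generator; no global
RNG state is disturbed), so emitted FASTA/BED/TSV files are byte-identical
across runs and the pipeline summary reproduces all non-timing fields.
The validation suite runs at the sizes the defaults encode: 200 null
simulations for the type-I check, 20 seeds each for fold recovery and
motif recovery, and ~1,000 random instances for the brute-force oracle
equivalences — a few minutes in total on one core.

## Known limitations

* Peak calling itself, and its FDR model, are out of scope; the pipeline
  consumes called intervals.
* The uniform background ignores mappability, chromatin accessibility and
  sono-seq-style biases; observed "enrichment" folds are relative to a
  deliberately simple null.
* Regulatory-domain enrichment frameworks (GO-term tools over peak sets)
  and position-weight-matrix models are not reimplemented; the consensus
  representation cannot express partial-strength sites.
* The E-values of `discover_motifs()` are comparable within a run, not
  with external motif-discovery tools.
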