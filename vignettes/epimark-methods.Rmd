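---
title: "epimark: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epimark: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

epimark analyses histone-modification ChIP-seq time courses in which an
activating mark (H3K4me2) and a repressive mark (H3K27me3) are profiled over
four developmental stages (E17.5, PN1, PN7, PN15) in two genotypes — wild type
and a mutant that loses rod photoreceptors (*rd1*) — together with mock
(anti-GFP) control immunoprecipitations. This vignette documents the models,
the tunable parameters, the synthetic world used for validation, and the
design decisions that were genuinely open.

## From reads to coverage

Uniquely mapped reads arrive as BED6 intervals, 0-based half-open. Every
sequenced fragment is assumed to be 190 bp, so the fragment midpoint is taken
95 bp downstream of the read 5' end (`start + 95` on the plus strand,
`end - 95` on the minus strand), clamped to the chromosome. All downstream
counting — coverage bins, enrichment windows, interval occupancies — operates
on these midpoints, which keeps the two routes mutually consistent.

Coverage tracks count midpoints in 100-bp bins (`bin i` covers
`[100 i, 100 (i + 1))`) and are depth-normalized to reads per 5 million mapped
reads. bedGraph output omits zero bins and round-trips exactly.

### TSS metaprofiles

The metaprofile aggregates midpoints over `TSS ± 5 kb` windows of every
transcript (splice variants and alternative TSS each contribute
independently; overlapping windows may double-count, matching an aggregate
over a full transcript catalogue). Minus-strand windows are reflected so that
positive offsets point downstream of transcription. Each offset bin is
divided by the total count across all windows, so the profile integrates
to 1; the alternative reading of the normalization (per-sample total) is a
constant factor and does not change the shape. The default offset resolution
is 100 bp — the resolution at which such profiles are conventionally plotted —
with per-bp profiles available via `bin_size = 1`.

Profiles are smoothed with classic LOWESS (locally weighted linear
regression). The smoother's span is not dictated by the procedure being
reproduced, which names the smoother but not its span; the default of 0.05
(five points of a 100-bin profile per local fit) follows the visual smoothing
level of typical published profiles. Peak counting on a sampled noisy curve is
degenerate if every local maximum counts, so `find_profile_peaks()` requires a
prominence of at least 20% of the curve's range — with a bimodal signal ~10×
above background this retains exactly the two TSS-flanking peaks and discards
background wiggles.

## Enrichment calling

Windows of width `window` are tested every `step` bp along each chromosome
(defaults 100/100, matching the 100-bp track resolution; `window > step` is
supported and recommended when the expected feature is wider than 100 bp —
matching the window to the feature width maximizes power). The null is
Poisson: the background rate per window is the genome-wide mean midpoint
count per window (`lambda_mode = "global"`, the simplest null consistent
with a genome-wide Poisson model), or per chromosome. A window with upper
tail probability `P(X >= k)` *strictly below* `1e-5` is enriched; no
multiple-testing correction is applied, reproducing the fixed-threshold
convention of the original analysis. Overlapping or abutting significant
windows merge into regions.

Control filtering re-tests each candidate region on the mock sample: the
control count over the region span is compared against the control's own
background rate scaled to the span (the span pooled as `span / window`
windows). Whether the original analysis used the control's own rate or the
IP rate is not stated; the control's own rate is the default
(`lambda_source = "control"`) because it asks the sharper question — "is the
control itself enriched here?" — and the IP-rate variant is a flag.

At the packaged background of 0.2 reads per bin, a 100-bp window needs 5
reads to clear the threshold while an 8-fold-enriched bin has mean 1.8 —
single-bin windows are essentially powerless at this depth, whatever the
caller. The planted-peak validation therefore calls with 1-kb windows at
100-bp pace (whole-peak count ~ Poisson(18) against a threshold of 11),
the standard window-matched configuration.

## Interval occupancy

Occupancy of a genomic interval is

    occupancy = reads × 5,000,000 / (total_reads × length_in_kb)

i.e. reads per kb per 5 million mapped reads. The source material prints the
formula twice with constants that differ by a factor of 1000; the form above
is the one whose magnitudes are commensurate with the published mock-control
background of 9.12, and the other constant is exposed as `kb_constant`.
"Reads in the interval" are fragment midpoints, consistent with the track
pipeline. Three interval kinds are built per gene: `TSS ± 2.5 kb`, the
promoter (2.5 kb upstream of the TSS, strand-aware) and the gene body (TSS to
TES). Occupancy is invariant under uniform sequencing-depth scaling by
construction.

## The no-mark cutoff

The mock-control background `b` is the mean anti-GFP occupancy over all gene
TSS windows and all stages (the published value for the real data is 9.12). A
gene sitting exactly at background in all 8 dimensions (2 marks × 4 stages)
has Euclidean row norm `sqrt(8) × b` — 25.80 for `b = 9.12` — and that norm
is the cutoff: genes with row norm strictly below it are `NO_MARK`.
"Euclidean row distance" could in principle mean row-to-row distances inside
a clustering, but only the norm-from-origin reading reproduces the printed
25.80 = sqrt(8) × 9.12, so that is what is implemented. Boundary genes (norm
equal to the cutoff) are retained as marked; the choice is arbitrary but
fixed.

## Signature classification

The original study found its gene classes by unsupervised average-linkage
clustering; epimark provides that route (`hierarchical_cluster()`, Euclidean
or uncentered-correlation distance, the latter being the historical default
of the Gene Cluster software) and, as the primary interface, a deterministic
rule set with explicit thresholds, because a reproducible pipeline needs a
decision procedure that does not depend on manual tree cutting.

All thresholds are multiples of `b`: `c_rep` (absence ceiling), `c_act`
(presence floor) and `f_min` (de novo fold), applied in fixed precedence
`NO_MARK` > `ROD_SPECIFIC` > `NONROD_RETINAL` > `UBIQUITOUS` > `OTHER`.
The rod signature demands H3K27me3 below `c_rep·b` at every stage, H3K4me2
below `c_rep·b` at the two early stages, and late H3K4me2 at least `c_act·b`
and `f_min` times `max(early, b)`; optionally the same de novo gain over the
gene body (`use_body`).

Two threshold choices deserve justification:

* `c_rep = 2.5`. These thresholds are free parameters (they are not part of
  the published analysis). With TSS-window counts of order 10 — exactly what a
  background of 0.2 reads/bin gives over a 5-kb window — a ceiling of 1.5×`b`
  is only ~1.6 standard deviations above the background mean, so each of the
  six absence conditions of the rod rule would falsely fail ~5% of truly
  unmarked stage values and rod sensitivity would collapse to ~74%. At
  2.5×`b` the per-condition false-failure rate is below 1e-4 while every
  planted "present" level (≥ 4×`b`) remains far above the ceiling.
* Stage means for level bands. The non-rod-retinal band ("activating mark
  present but modest") and the ubiquitous level test use the mean over the
  four stages rather than per-stage tests: a per-stage band on a count of
  ~20 fails ~3% per stage and ~11% per gene for genes that truly sit inside
  the band. Stage-resolved conditions are kept where the biology is
  stage-resolved (the rod de novo timing, repressive-mark absence).

Classification is per transcript; a gene-level call takes the transcript with
the maximal row norm.

## Comparisons

`pooled_t_test()` is the classic equal-variance two-sample t, with stars
`(*) 0.05 > P > 0.01`, `(**) 0.01 > P > 0.001`, `(***) P < 0.001`. Raw
p-values are reported without multiple-testing correction, matching the
reporting convention of the analysis being reproduced.

`compare_promoter_body()` tests, per mark and stage, promoter against
gene-body occupancy (both per kb) across a gene set.

`compare_genotypes()` contrasts wild type against the rod-less mutant on a
gene set and reports the mean wt/mutant fold with a pooled t-test. By default
it should be fed *background-relative* occupancies
(`relative_occupancy()` with `sample_background_occupancy()`): each library's
occupancies are divided by that library's genome-background occupancy,
estimated outside gene territories. Raw occupancies carry a
library-composition factor — a library with more enriched signal spends a
larger share of its reads inside peaks, deflating every occupancy after depth
normalization — which systematically biases between-genotype comparisons at
unchanged genes. Background-relative values cancel the factor exactly; with
them, unchanged genes test as unchanged and the rod set shows the full
planted reduction.

## The synthetic world

The generator plants five classes of 50 genes each (lengths 2–20 kb,
alternating strands, 15–25 kb gaps) on two 8-Mb chromosomes, with per-bin
counts Poisson-distributed around `lambda_bg × (1 + fold × shape)`:

| class            | H3K4me2 fold (E17.5→PN15) | shape          | H3K27me3 fold | shape            |
|------------------|---------------------------|----------------|---------------|------------------|
| ROD              | 0, 0, 4, 8                | flat, gene-wide| 0             | —                |
| NONROD_RETINAL   | 1 constant                | bimodal TSS    | 6 constant    | flat, TSS + body |
| UBIQUITOUS       | 8 constant                | bimodal TSS    | 0             | —                |
| SILENT           | 0                         | —              | 0             | —                |
| DOWN             | 8, 6, 2, 0                | bimodal TSS    | 0, 1, 2, 4    | flat, TSS        |

Design choices, fixed once:

* `lambda_bg = 0.2` reads per 100-bp bin and 50 genes per class keep tests in
  the seconds range while leaving stable statistics.
* The bimodal TSS shape is two Gaussian bumps (σ = 300 bp) at ±1 kb,
  normalized so the mean fold over the TSS window equals the stated fold —
  the qualitative twin-peak geometry of activating-mark profiles.
* The rod-class activating mark is planted as a *flat* domain covering
  promoter and gene body: the rod signature covers the whole gene, and a flat
  domain makes promoter and body per-kb rates exactly equal, which is the
  stated generative property for the promoter-vs-body null comparison.
* Per-gene lognormal mark-strength multipliers (sdlog 0.3, shared across
  stages, marks and genotypes) model the gene-to-gene occupancy spread real
  data always shows; without it, two-sample t-tests on planted classes are
  unrealistically hypersensitive.
* The rd1 genotype multiplies the whole local H3K4me2 rate over rod-gene
  territories by `rd1_rod_scale = 0.4`, modeling the loss of rod nuclei
  (scaling only the enrichment term would leave the background contribution
  of the vanished cells in place and caps the observable fold below 2).
* The genome size (2 × 8 Mb) was set by a power analysis so the planted
  signal occupies a realistic fraction of each library: large enough that
  silent genes sit clearly below the GFP-derived Euclidean cutoff (as in the
  real data, where 18% of genes fell below it), small enough for desk-scale
  runtimes.
* Reads are placed so the 190-bp midpoint rule recovers the drawn bin
  exactly; strands are uniform; a fixed master seed makes the whole fixture
  byte-identical across runs (per-sample seeds derive from it).

What the generator does **not** emulate: mappability and GC structure,
duplicate reads, fragment-length variation, nucleosome positioning,
replicates, and degeneration kinetics (the rd1 scaling is stage-constant). A
green test on this world therefore establishes the correctness and
calibration of the *computations*, not the field performance of the caller on
real libraries.

## Numerical and format notes

* Coordinates are 0-based half-open everywhere; BED round-trips are
  identities. Minus-strand TSS is `txEnd` (UCSC convention).
* Readers reject invariant-violating rows with the line number; reads on
  unknown chromosomes are dropped with a warning count rather than erroring.
* The Poisson upper tail uses the regularized incomplete gamma via `ppois`,
  stable for rates up to 1e4; it agrees with direct term-by-term summation to
  1e-12 over the tested grid.
* Significance thresholds are strict (`p < threshold`); ties at the threshold
  are not called.
* Manifests and pipeline configs are JSON (`jsonlite`); no YAML parser is a
  declared dependency of this package.
* Partial windows at chromosome ends (shorter than `window`) are not tested.
* Zero-variance rows under the uncentered-correlation metric get distance 1
  to everything.

## Limitations

The caller is a fixed-threshold genome-wide-null scanner: no local lambda, no
broad-domain mode, no FDR. Classification thresholds are calibrated for
TSS-window counts of order 10+; at much lower coverage the rules lose power
before they lose validity. The genotype contrast assumes the background
estimate is signal-free; on a genome saturated with marks the
outside-gene-territory estimator would be biased upward.
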