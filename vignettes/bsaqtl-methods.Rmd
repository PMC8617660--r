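---
title: "Methods: bulked-segregant QTL mapping with bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL mapping with bsaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A dominant, temperature-sensitive fertility-restorer (*Rf*) locus segregates
in a BC~1~ backcross population of a CMS (cytoplasmic male sterility) crop:
every plant is either heterozygous for the donor restorer allele or
homozygous for the recurrent parent's allele. Fertility is scored on an
ordinal 0 (sterile) to 4 (fully fertile) scale, and restoration is
quantitative — carrier and non-carrier grade distributions overlap.
Bulked-segregant analysis sequences pooled DNA from the two phenotypic
extremes (30 fertile plants, grades 3–4, the F-bulk; 30 sterile plants,
grades 0–1, the S-bulk) together with the two parents, and locates the
locus by allele-frequency divergence between the pools.

`bsaqtl` implements the full desk side of that experiment: variant
screening, three genome-scan statistics with their significance
thresholds, QTL-interval calling with a cross-method consensus, and an
interval-to-gene candidate funnel — plus a simulator that generates the
whole dataset so every stage is testable without sequencing data.

## Variant screening

Input is a 4-sample VCF (donor parent, recurrent parent, F-bulk, S-bulk,
FORMAT `GT:AD:DP`). Two layers:

1. **Hard filters** (GATK-style, ORed for rejection; a missing annotation
   passes its clause): `QUAL < 30`, `QD < 13`, `FS > 20`, `MQ < 20`,
   `MQRankSum < -3`, `ReadPosRankSum < -3`. The quality-by-depth reading of
   the second clause is a judgment call — the commonly printed compound
   label is not a standard annotation — and the threshold is configurable
   (`qd_min`).
2. **Genotype rules**: (1) both parents homozygous; (2) parents differ;
   (3) the S-bulk's called genotype equals the recurrent parent's; (4) both
   bulks' depths within [10, 100]. Multi-allelic records are dropped, not
   decomposed, because all three statistics below are defined biallelically.

Survivors are polarized onto the **donor allele** (the allele the donor
parent carries homozygously): the table stores donor/other read depths per
bulk (`aF, rF, aS, rS`). Drop reasons are tallied; `kept + dropped = total`
is asserted on every run.

## The three genome scans

Let `idxF = aF/(aF+rF)` and `idxS = aS/(aS+rS)` be the bulks' SNP-indices.

**ΔSNP-index.** `Δ = idxF − idxS`. Unlinked loci give Δ ≈ 0; a fully
linked locus in this BC~1~ design gives Δ → 0.5 (F-bulk all heterozygous,
index 0.5; S-bulk all homozygous recurrent, index 0). Significance comes
from Monte-Carlo null bands: at each observed depth `d` (the smaller of the
two bulk depths at the SNP), 10,000 replicates draw 30 genotypes per bulk
under null segregation (BC~1~ 1:1; optionally F~2~ 1:2:1), form the pooled
donor frequency, draw binomial read counts at depth `d`, and take Δ. The
95% and 99% empirical quantiles form the bands; they are memoized per
depth. Both Δ and the bands are then smoothed (below) so curve and band
are comparable; the 99% band is the default for interval calling (the
stricter of the two plotted bands).

**G′.** Per SNP, the 2×2 likelihood-ratio statistic on
`(aF, rF; aS, rS)`: `G = 2 Σ n_i ln(n_i/e_i)` with independence
expectations `e_i` and `0·ln 0 = 0` (zero row/column ⇒ G = 0). G is
smoothed into G′, and the null is fitted as a log-normal: on `ln G′`,
values above `median + 5.2·MAD` (raw MAD — Hampel's rule) are trimmed as
probable signal; the null mean is the trimmed median and the null SD is
`1.4826·MAD`. Upper-tail normal p-values are Benjamini–Hochberg adjusted;
SNPs with `q ≤ 0.01` are significant. All constants are exposed in
`scan_config()`.

**ED⁵.** The Euclidean distance between the bulks' allele-frequency
vectors, `ED = √2·|idxF − idxS|` for a biallelic SNP, raised to the fifth
power to sharpen peaks (exponent configurable). ED⁵ is fitted per
chromosome by local quadratic regression (Loess, span 0.3, degree 2,
`surface = "direct"` so fits are deterministic and exact for polynomial
inputs), and the threshold is `median + 3·SD` (population SD) of the
genome-wide fitted values. Whether the published construction used raw or
fitted values, genome-wide or per chromosome, is not stated; both are
selectable (`ed_threshold_on`, `ed_threshold_scope`), with
fitted/genome-wide as the default — thresholds on fitted values are far
more stable at ED's fifth-power scale.

**Smoothing kernel.** The 1 Mb "window" is implemented as tricube
Nadaraya–Watson weighting: for focal position `p` and neighbour at
distance `D ≤ W/2`, weight `(1 − (2D/W)³)³`; chromosomes are independent.
The kernel itself is a design choice — the statistic family names the
window, not the kernel — and tricube is the standard choice in
G′-with-FDR genome scans. A brute-force O(n²) reference implementation in
the test suite pins the windowed implementation to 1e-12.

## Interval calling and the candidate funnel

Per method, maximal runs of ≥ `min_run` (default 10) consecutive
significant SNPs become intervals; runs never bridge gaps wider than one
smoothing window, since published scans report sub-intervals separately
rather than merging across dead zones. The **consensus** is the set of
regions covered by ≥ `min_methods` (default 2) distinct methods — a
coverage-function intersection, and explicitly a construction of this
pipeline: the source experiments do not state how the three scans were
combined, so reports flag the rule. Genes from a GFF3/BED annotation
overlapping any interval by ≥ 1 bp are reported, optionally filtered by
boolean attribute flags (e.g. `mito_targeted`, `expressed` — stand-ins for
external predictions this package deliberately does not compute), with
screened-variant counts per gene. Coordinates are 1-based inclusive
internally; BED export is 0-based half-open.

## The simulator: what it emulates, what it does not

`simulate_dataset()` generates the stated world end to end:

* **Marker map** — jittered regular spacing; degenerate chromosomes
  (spacing > length) get one midpoint marker.
* **BC~1~ genotypes** — a two-state Markov walk along each chromosome with
  Haldane recombination fractions at 4 cM/Mb (uniform, single parameter);
  the causal locus is walked as a pseudo-marker so its linkage is exact.
* **Penetrance** — categorical grade distributions per genotype class
  (defaults: carriers `(0.02, 0.08, 0.20, 0.35, 0.35)`, non-carriers
  `(0.60, 0.30, 0.08, 0.02, 0)` over grades 0–4). This is the simplest
  mechanism that yields a continuous-looking phenotype distribution with
  configurable misclassification; a liability-threshold model would add a
  parameter without adding testable structure.
* **Bulks** — 30 plants drawn without replacement per grade class; pooled
  donor frequency is exactly `0.5 × (fraction heterozygous)`, so it lives
  on the lattice `{0, 1/60, …, 0.5}`.
* **Reads** — depth uniform on [10, 100]; donor reads binomial with a
  per-read miscall rate (default 0.001) folded in symmetrically.
* **VCF** — 4 samples; parents homozygous-opposite; bulk genotypes called
  from the donor-read fraction (< 0.15 homozygous recurrent, > 0.85
  homozygous donor, else heterozygous — a simulator convention recorded in
  the header that makes screening rule (3) exercisable); site annotations
  drawn from passing ranges unless a contaminant fraction is requested.
  Fixed seed ⇒ byte-identical output apart from the file-date line. The
  BC~1~ population size behind the bulks is not a published quantity;
  default 200, configurable.

**What a green test does not establish.** The simulator emits SNPs only
(no indels), one QTL (no epistasis), no linkage-disequilibrium structure
beyond the backcross itself, independent uniform depths (no GC or
mappability bias), and genotype-independent errors. Passing tests
demonstrate the statistics and plumbing are correct in this world, not
that any particular real dataset will behave as cleanly.

**A bias worth knowing about.** Screening rule (3) keeps a SNP only where
the S-bulk is *called* homozygous recurrent. For an unlinked marker the
sterile pool's donor frequency is ≈ 0.25, so the bulk is usually called
heterozygous and dropped; near the restorer the S-bulk is fixed recurrent
and kept. On a real-scale genome (thousands of cM) this enrichment is
diluted; on a desk-scale simulated genome of a few chromosomes the QTL
chromosome can dominate the kept set, and then the *outlier-calibrated*
thresholds (G′'s trimmed null, ED's median + 3 SD) self-normalize and lose
contrast, while the ΔSNP-index bands — which are absolute, simulated
null quantiles — keep firing. The calibration and parameter-recovery test
properties are therefore assessed on complete marker tables, and the
screening round trip is verified separately.

## Numerical choices and degenerate inputs

* Zero-depth SNPs are rejected at screening; `snp_index` refuses zero
  totals rather than returning NaN.
* A constant G′ track has null SD 0: all p-values are set to 1 with a
  warning, never a division by zero.
* SNPs with undefined statistics are excluded from Loess fitting and
  threshold computation, never silently zeroed.
* Loess falls back to tricube smoothing (with a warning) below 10 SNPs
  per chromosome or on numerical failure.
* `delta_ci` refuses fewer than 100 replicates; bands are cached per depth.
* One master seed drives every stage through fixed offsets; no function
  mutates the caller's RNG state.

## Limitations

* The consensus rule and the min-run interval rule are this package's
  constructions; published interval boundaries arising from different
  conventions will differ in detail.
* Indels are screened like SNPs when present in the input but are never
  simulated.
* The candidate funnel's biological flags (mitochondrial targeting,
  expression) must be supplied in the annotation; the package does not
  predict them.
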