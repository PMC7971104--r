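---
title: "Calling copy-number alterations from UMI depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number alterations from UMI depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umicna)
```

## Overview and assumptions

`umicna` calls somatic copy-number alterations on targeted gene panels whose
reads carry unique molecular identifiers (UMIs). The signal unit is the
number of *distinct* UMI sequences overlapping a targeted region — a count of
input molecules rather than of PCR products. The method rests on four
assumptions:

1. **UMI counting is faithful.** Each input fragment receives a practically
   unique barcode (a 12-mer gives `4^12 = 16,777,216` possibilities, far more
   than the number of molecules per region), and exact string identity is
   enough to deduplicate; error-tolerant UMI clustering is out of scope.
2. **Controls are diploid on the panel** and capture efficiency per region is
   stable across libraries, so a geometric-mean baseline over controls
   captures the region effect.
3. **The tumor sample is majority-characterizable by a diploid state**: the
   Gaussian-mixture component of the log-ratio distribution closest to zero
   is diploid. Genome-doubled / polyploid profiles violate this and are a
   known limitation.
4. **Observed log-ratios mix tumor and normal signal linearly in copy
   ratio:** `L = log2(c * CN/2 + (1 - c))` for tumor fraction `c` and tumor
   copy number `CN`. The purity inversion further assumes significant
   segments carry single-copy events.

## Pipeline stages

### Counting (`read_panel`, `count_umis`, `normalize_counts`)

Regions come from a 4-column BED (0-based half-open; the package keeps this
convention internally). Reads pass if they are primary, mapped, not QC-fail,
with MAPQ ≥ 20 (`min_mapq`, dimensionless, the conventional uniqueness
cutoff). A read overlapping a region by ≥ 1 aligned base contributes its UMI;
a UMI seen several times in a region counts once. Two deliberate choices:

- **Positional duplicate flags are ignored.** UMI deduplication supersedes
  positional deduplication; coordinate-duplicate reads with distinct UMIs
  are distinct molecules, and removing them would delete signal.
- **`U` is the genome-wide distinct-UMI total**, not the sum over regions,
  so a UMI spanning two adjacent regions is not double-counted in the
  normalizer. Normalized values `C_p/U` are therefore comparable across
  samples of different depth; log-ratios are invariant to depth scaling.

### Pseudo-reference (`build_reference`)

The baseline is the per-region geometric mean of normalized control values.
Regions with a zero count in any control are excluded rather than
pseudocounted: the geometric mean is undefined at zero, and a zero in a deep
targeted control indicates assay failure, not biology. Outlier filtering uses
the absolute deviation from the baseline and the Tukey fence
`T = Q3 + 1.5 * IQR` with linear-interpolation quartiles
(`stats::quantile` type 7, the mainstream default — fixed and documented
because the fence is sensitive to the quartile convention).

Design choices where the construction narrative leaves room:

- **`T` is pooled** over all (region, sample) deviations of the control set,
  yielding one global scalar as the fence formula implies.
- **Two passes, no fixed point:** samples with ≥ 20 % (`sample_frac`) of
  regions above `T` are excluded; if any were, the baseline, deviations and
  `T` are recomputed once; then regions above `T` in ≥ 50 % (`region_frac`)
  of retained controls are excluded. Iterating to a fixed point could
  cascade exclusions on small cohorts with little benefit.
- A numerical guard treats deviations below `1e-12` relative to the baseline
  as zero, so perfectly concordant controls (deviation = 1 ulp from the
  `exp(mean(log(.)))` round trip) are never flagged.

Segmentation weights are inverse control variances (denominator `S - 1`),
min–max scaled to [0, 1]. The variance is floored at `1e-12` and the scaled
weight at `0.01`: the plain min–max map gives the noisiest region weight 0,
which would silently delete its data point; the floor keeps the ordering but
preserves the observation. Equal variances degenerate the scaling and all
weights become 1.

### Centering (`fit_mixture`, `center_profile`)

Log-ratios use the normalized tumor value over the baseline; a tumor count of
zero is informative (homozygous deletion) and receives a half-count
pseudocount `0.5/U` plus a flag instead of being dropped. A univariate
Gaussian mixture with 1–3 components is fitted by `mclust::Mclust` with free
variances (`modelNames = "V"`) and the component count chosen by BIC; the
free-variance family is the more general single choice and BIC is mclust's
standard criterion. mclust initializes from deterministic model-based
hierarchical clustering, so repeated fits are identical and no seed is
consumed. The component whose mean is closest to zero is subtracted (ties
broken toward the larger mixing proportion). Degenerate inputs — fewer than
10 finite values is an error; constant values, or a component standard
deviation collapsing below `1e-6`, are floored and flagged (constant input
short-circuits the fit entirely, which mclust does not handle). Centering can
be disabled, in which case the shift is recorded as 0.

### Weighted CBS (`segment_gene`, `seg_params`)

Each gene's consecutive retained regions are segmented independently by
circular binary segmentation, reimplemented with observation weights:

- The statistic for an arc against its complement is the weighted two-sample
  t under the model `x_k ~ N(mu_group, sigma^2 / w_k)`; maximizing it over
  arcs reduces to maximizing the between-group weighted sum of squares,
  computed with prefix sums in compiled code (`src/cbs.cpp`).
- Significance is by permutation of the *values* with weights fixed to their
  *positions* — the weights encode per-region assay variance, a property of
  the position, not of the observation. The permutation loop early-stops as
  soon as the exceedance count already forces `p > alpha`; this only ever
  abandons tests whose outcome is decided.
- Defaults (all exposed in `seg_params()`): `alpha = 0.01`,
  `n_perm = 10000`, `min_width = 2` regions, `undo_sd = 1.0` pooled weighted
  SDs — the conventional defaults of the CBS lineage; the undo step merges
  adjacent segments whose weighted means differ by less than
  `undo_sd * sigma_hat` to prune over-segmentation.
- Flat signals return one segment without running permutations; genes with
  fewer than `2 * min_width` regions return one segment; genes reduced to
  very few retained regions are flagged `short-gene` (six non-overlapping
  regions per gene is the recommended minimum for a confident call).
- Each (sample, gene) pair derives its own RNG stream from the global seed
  (default 17), so results are reproducible and independent of gene
  processing order.

### Calling and purity (`test_segments`, `estimate_purity`)

Segments with ≥ 2 members get a two-sided one-sample t-test against 0 on the
*unweighted* member log-ratios — the weights served segmentation; the test
treats every retained region as one observation. p-values are adjusted by
Benjamini–Hochberg across the sample's tested segments ("an FDR correction"
is read as BH at `alpha = 0.05`, the standard choice). Zero-variance
segments use the convention p = 0 (mean ≠ 0, flagged) or p = 1 (mean = 0);
single-region segments are reported as `untested`.

Tumor content is inverted from the pooled member log-ratios of gain segments
(`c = 2(2^L - 1)`) and, independently, of loss segments (`c = -2(2^L - 1)`);
the mean of the available estimates is reported. Pooling member regions
(rather than averaging segment means) weights long segments more, matching
the definition of the per-gene log-ratio vectors whose means the model
interprets. Raw estimates outside [0, 1] are clamped and flagged: above 1
arises legitimately from multi-copy events violating the single-copy
assumption; below 0 from a significant segment whose unweighted mean crosses
zero.

## The synthetic-data generator

`sim_panel` / `simulate_controls` / `simulate_tumor` emulate a desk-scale
version of a multi-gene amplicon panel: 20 genes × 15 regions (P = 300,
preserving the ≥ 6-regions-per-gene recommendation at a size where the full
pipeline runs in milliseconds; real panels are ~5× larger), log-normal
per-region capture efficiencies (sdlog 0.5, reproducing systematic
region-to-region depth differences), and negative-binomial UMI counts with
mean per-region depth 2000 (the high-coverage regime targeted panels run at)
and NB size 50, i.e. ~14 % count CV, representing residual cross-library
variability in UMI counts. Events scale expected counts by
`c * CN/2 + (1 - c)`; per-sample totals are the summed panel counts. All
randomness flows from explicit seeds and identical seeds give bit-identical
output. `simulate_bam_fixture` additionally realizes a count vector as a
sorted, indexed micro-BAM (UMIs as read-name suffixes and `RX` tags, 1–3
duplicate reads per UMI) to exercise the BAM-counting path end to end.

What the generator does *not* model: GC or amplicon-length bias, UMI
sequencing errors and barcode collisions, read-level error profiles,
sex-chromosome baselines, and subclonal heterogeneity. Passing tests
therefore demonstrate the correctness of the statistical machinery under a
clean overdispersed-count model, not performance on any particular assay.

## Detection limit under the default noise model

`dilution_experiment()` spikes four whole-gene events (CN 4, 3, 1, 0) and
runs the full pipeline across tumor fractions 100/50/20/10/5 % with
replicates. Under the default noise model the per-region log-ratio SD is
about 0.23 (tumor CV ~0.14 plus baseline noise from 5 controls), so a
15-region segment resolves mean shifts of roughly 3 × 0.23/√15 ≈ 0.18. A
heterozygous deletion at 10 % tumor fraction shifts the log-ratio by only
log2(0.95) ≈ −0.074; consequently single-copy events stop being reliably
significant below ~50 % tumor fraction, and the measured detection limit for
*all four* events is 50 %. Equivalently, purity estimates below ~30 %
fraction are driven by whichever events happen to reach significance, which
widens their spread. Both are properties of the chosen noise level, not of
the algorithm: detecting that same het deletion at 10 % fraction with power
would require a per-region log-ratio SD ≤ ~0.07, i.e. per-region count CVs
in the low single digits — the regime that deep, strongly deduplicated UMI
counting aims for. The package reports what it measures under its stated
defaults.

## Numerical conventions, in one place

- Coordinates: 0-based half-open everywhere (BED convention).
- Quartiles: `stats::quantile` type 7.
- Variance floors: `1e-12` (weights), `1e-6` (mixture SD); weight floor 0.01.
- Deviation zero-guard: `1e-12` relative to the baseline.
- Mixture selection ties: larger mixing proportion.
- CBS: statistic maximization is exact (exhaustive over arcs); ties between
  an arc and its complement are the same split and resolve identically.
- Zero-variance segment tests: p = 0 / p = 1 by the sign of the mean.
- Undefined purity (no significant segments): `NA`, never 0.

## Limitations

- No B-allele-frequency integration; a balanced genome-doubled tumor is
  invisible and a diploid-majority assumption is required.
- No cross-gene segmentation: events are bounded by gene blocks.
- Purity estimates assume single-copy events; multi-copy events bias the
  estimate upward (clamped at 1) though the dilution *trend* remains.
- Integer copy-number assignment and subclone deconvolution are out of
  scope.
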