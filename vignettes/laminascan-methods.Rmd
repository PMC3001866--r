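---
title: "Methods: misexpression clustering and 3D territory quantification"
author: "laminascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: misexpression clustering and 3D territory quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminascan)
```

## Scope and model

Laminopathy studies link mutations in the nuclear-lamina protein lamin A/C
to two observable phenotypes: misexpression of specific genes, and
mispositioning of the chromosomal domains that carry them. `laminascan`
implements the computational chain connecting the two:

1. **Misexpression calling.** Expression tables normalized two different
   ways are each ranked by fold change with the rank-products statistic;
   the misexpression call in each direction is the intersection of the two
   variants' top-K lists. With a single mutant/control pair per variant the
   rank product degenerates to a plain fold-change ordering — the package
   makes this explicit rather than hiding it, because a one-comparison RP
   is exactly its one rank.
2. **Genomic clustering.** A 500 kb window slides in 100 kb steps along
   each chromosome. A window qualifies when misexpressed genes make up at
   least 75% of the chip genes it contains and it holds at least two
   misexpressed genes; overlapping or abutting qualifying windows merge
   into clusters. Significance comes from an empirical null: many random
   probeset lists of the observed size, each scanned identically.
3. **Per-chromosome enrichment.** Observed misexpressed genes per
   chromosome are compared to the expectation that each chromosome carries
   the genome-wide misexpressed fraction of *its chip genes* (chip
   composition, not genome gene counts, defines the expectation), with a
   plain chi-square goodness-of-fit test, no continuity correction.
4. **3D FISH quantification.** From multi-channel confocal stacks:
   territory-to-nuclear-edge minimum distances via per-slice Euclidean
   distance maps (EDM) with an orthogonal reslice, inter-locus distances
   between signal centroids, binary lamina-contact scores, and voxel-count
   volumes normalized to nuclear volume.

Everything is driven either by real tables/stacks or by the package's own
synthetic generators, which plant a known truth so that each stage can be
validated end to end.

## Conventions that matter

* **Coordinates.** Internally 0-based half-open; annotation TSVs are
  declared 1-based inclusive (browser style) and converted on read. A
  gene's *anchor* for window membership is its start coordinate regardless
  of strand; a single-point anchor prevents length-weighted double
  counting. Density ratios compare *genes* (deduplicated symbols), not
  probesets.
* **Window grid.** Starts at coordinate 0 of each chromosome; the final
  partial window is scanned. A fixed grid keeps results deterministic.
* **Ties.** All rankings break ties by probeset id, lexicographically.
* **Empirical P.** One-sided upper tail with the plus-one convention,
  `p = (b + 1)/(N + 1)`; zero exceedances are additionally rendered as the
  bound `"<1/N"`. The plus-one form cannot produce `p = 0` and keeps the
  estimator super-uniform under the null, which the acceptance suite
  verifies by simulation.
* **Null draws.** At probeset level, then collapsed to genes before
  scanning — mirroring the real pipeline, where the randomized lists were
  probeset lists.
* **Image axes.** Arrays are `[y, x, z]`; `voxel_size = c(dx, dy, dz)` in
  µm with a 0.12 µm z-step default (the study's optical sectioning). A
  voxel's physical position is its center; generator and measurement share
  this convention, so planted and measured coordinates are directly
  comparable.

## The two-plane edge distance

The study's procedure computes, per x-y slice, the EDM of the nucleus mask
and records the minimum EDM value under the territory mask; the stack is
then resliced into x-z planes (spacing `dx`, `dz` — the anisotropy is
honored, which is why the package carries its own anisotropic exact
distance transform rather than an isotropic library one) and the pass is
repeated; the result is the minimum over both passes. Territory voxels
outside the nucleus mask contribute 0.

The two-plane minimum restricts candidate directions to two axial planes,
so it can only *overestimate* the true 3D distance; a full anisotropic 3D
transform is provided as `mode = "3d"` for auditing, and the test suite
asserts `two-plane >= 3d == brute force` on random masks.

**Tangency.** A territory mask strictly inside the nucleus mask can never
score exactly 0 under the EDM-to-background convention (its boundary voxel
is ≥ 1 voxel step from background). Tangency is therefore representable on
a voxel grid only by letting the territory reach the nuclear surface: the
generator accepts territories protruding up to `edge_slack` (default one
voxel diagonal, ≈ 0.165 µm at default voxel sizes) past the surface,
records their true edge distance as 0, and the measurement then scores
exactly 0 through the outside-voxels-contribute-0 rule. This mirrors how
direct territory–edge contact is observed in real data.

## Segmentation choices

* Global threshold over the whole volume (not per slice), Otsu by default;
  `fixed` and `percentile` alternatives are exposed because "thresholding"
  alone underdetermines the operation.
* Holes are filled per 2D slice; nucleus and territory masks keep only the
  largest 3D 6-connected component.
* **Point-like FISH signals use half-maximum thresholding** (`halfmax`),
  not Otsu. A diffraction-limited spot occupies on the order of 0.01% of
  the stack's voxels; a histogram-based threshold sees essentially one
  class plus noise and can land inside the background, flooding the mask.
  The FWHM convention is the standard spot answer and is robust at the
  SNRs simulated here.
* Signal positions are intensity-weighted centroids of the segmented
  component — the deterministic analogue of a 3D ROI-manager readout.
* Lamina contact uses 26-adjacency between signal and lamin masks: the
  most permissive standard connectivity, matching a "physical continuity"
  reading of contact.
* The despeckle step is the 3×3 hybrid median filter (median of the
  plus-neighborhood median, cross-neighborhood median, and center), with
  mirror (reflect-101) borders.

## Synthetic generators: what they emulate, and what they do not

**Expression.** Latent log2 intensities are Gaussian; planted probesets
receive ±`effect_log2fc`; the two normalization variants share a latent
fold-change noise component and carry independent variant-specific noise,
so their fold changes correlate at `normalization_corr`. This is the
minimal structure the dual-normalization intersection assumes — it does
not model probe-level effects, intensity-dependent variance, or the actual
RMA/MAS5 computations, so passing tests say nothing about normalization
internals. In the noiseless limit (`noise_sd = 0`, `corr = 1`) the planted
probesets occupy exactly the top fold-change ranks, which pins the ranking
and intersection algebra.

**Nuclei.** An ellipsoidal DAPI volume, a lamin shell straddling the
surface, spherical territories and small spherical signal spots, blurred
with an isotropic Gaussian PSF (default σ = 0.08 µm) and degraded with
Poisson shot noise at a stated peak SNR (default 20) plus a small Gaussian
read-noise floor. Inputs to the measurement engine are assumed
deconvolved, as in the source workflow, which is why the default PSF is
narrow; chromatin texture, photobleaching and depth-dependent aberrations
are deliberately not modeled. Truth values are analytic: sphere-in-sphere
edge distances in closed form, ellipsoid cases by dense surface sampling
(≈0.001 µm accuracy), pair distances exactly.

## Statistical conventions

Two-sided tests throughout; Welch (unequal variance) by default with a
pooled-variance option. Published `mean ± x` values reproduce the
published p-values only when `x` is read as the standard error of the
mean, so the summary-statistic interface documents and defaults to the SEM
reading without claiming the source intended it. Binary contact data are
compared with a two-sample t-test applied directly to the 0/1 scores,
which is numerically identical to the summary-statistic Welch test on the
same data (asserted in the suite). No multiple-testing correction is
applied anywhere. Percents are rounded only in the report layer
(`render_percent`); all stored values keep full precision.

## Problem sizes and numerical tolerances

The validation experiments use sizes chosen to exercise every code path at
desk scale: synthetic chips of 2–3 chromosomes × 8–20 genes/Mb (≈200–300
probesets), nulls of 199–1000 simulations, calibration over 500
repetitions, and 50 simulated nuclei of semi-axis 2.2 µm at 0.08/0.12 µm
voxels (≈70³ voxel stacks). Image-derived quantities are asserted to one
voxel diagonal (≈0.165 µm) for distances and 5% for volume ratios —
voxelization bounds, not statistical ones; observed errors are typically
5–10× smaller. The distance transform is exact (Felzenszwalb lower
envelope), so EDM agreement with the brute-force oracle is required to
machine precision, not a tolerance.

## Known limitations

* With one mutant/control pair per normalization variant the RP statistic
  is a fold-change sort; RP permutation E-values are intentionally not
  implemented because the pipeline only consumes fixed-size top lists.
* Whether the published cluster count came from merged or single windows
  is not stated in the source; merging is the implemented interpretation
  and the cluster table records how many windows each cluster spans.
* The chi-square expectation uses chip composition; chromosomes absent
  from the chip are excluded from the categories (df adjusts accordingly).
* The two-plane edge distance inherits the source's approximation; use
  `mode = "3d"` where fidelity to the original macro is not required.
* The simulator's nuclei are convex and noise is stationary; segmentation
  behavior on lobulated or dim real nuclei is out of validated scope.
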