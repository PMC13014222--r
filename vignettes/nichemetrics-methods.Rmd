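---
title: "Methods: niche morphometry, the Divergence Index, and scaffold physics"
author: "nichemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche morphometry, the Divergence Index, and scaffold physics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemetrics)
```

# Scope

`nichemetrics` re-implements, as a tested and reusable pipeline, the
quantitative analyses used to characterize engineered bone-marrow niche
models built on porous silk-fibroin scaffolds: 3D megakaryocyte
morphometry, a Divergence Index (DI) over cell-size frequency
distributions with a moderate/substantial threshold and a
treatment-response reduction metric, and the scaffold physical
characterization computations (swelling, Darcy permeability, amide-II
crystallinity deconvolution, modulus-distribution fitting, strain-sweep
ultimate strain, Rg/Rh shape factor). A seeded synthetic-data module
provides niche volumes and instrument-like signals with known ground
truth, so every stage is testable end to end without any external data.

# The Divergence Index

## Model

Two conditions are compared through the frequency distributions of a
per-cell scalar size (projected area in µm², or volume in µm³). Both
samples are binned on one shared set of class edges; with class
frequencies $p_i$ and $q_i$ (each summing to 1), the index is

$$\mathrm{DI} = \frac{1}{2}\sum_i |p_i - q_i|,$$

the sum of absolute class-wise frequency differences normalized by its
theoretical maximum. For two probability vectors the raw sum can reach at
most 2 (fully disjoint supports), so the normalization constant is 2 and
DI lies in $[0, 1]$: 0 for identical binned distributions, 1 for
disjoint ones. This makes DI the total-variation distance on the binned
distributions — symmetric, bounded, and a true metric (triangle
inequality), properties the test suite verifies on random histogram
triples.

A threshold of 0.4 separates *moderate* (DI ≤ 0.4) from *substantial*
(DI > 0.4) divergence. The boundary itself is assigned to moderate:
"substantial" requires a strict exceedance. The threshold direction at
the exact tie is not dictated by the index itself; we chose the
conservative assignment and state it in the documentation.

Treatment response is summarized by the relative reduction
$100\,(\mathrm{DI}_{pre} - \mathrm{DI}_{post})/\mathrm{DI}_{pre}$.
For the divergence pair 0.61 → 0.29 this evaluates to 52.46%, which
rounds to the headline figure of a 50% reduction; the package reports
the exact ratio. A worsening (negative reduction) is allowed and
flagged; a pre-treatment DI of zero leaves the ratio undefined and is an
error.

## Binning

DI values depend on the class scheme, and no canonical scheme exists for
cell-size histograms. The default is $K = 10$ equal-width classes over
the pooled min–max of all groups being compared; Freedman–Diaconis
widths (`bins = "fd"`) and explicit edges are available. Three rules are
fixed:

* all groups share identical edges, computed on the *pooled* data —
  comparing histograms binned separately is meaningless and
  `divergenceIndex()` refuses mismatched edges rather than silently
  rebinning;
* frequencies are per-group proportions, so unequal sample sizes compare
  fairly;
* explicit edges must cover every pooled value — values falling outside
  are an error, not silently dropped.

Because published DI values always depend on the (usually unreported)
class scheme of the original histograms, point values from one scheme
should not be compared numerically with values from another; the metric
properties (ordering, threshold classification, reduction under
treatment) are the robust readouts.

## Finite-sample behavior and the bootstrap

Two finite samples from the *same* law have a strictly positive expected
DI (each class frequency fluctuates as $\sqrt{p_i(1-p_i)/n}$), a bias
floor that shrinks with $n$. The test suite calibrates this: at
$n = 500$ per group and 10 classes the mean null DI over 200 replicates
stays below 0.1 and decreases when $n$ grows. DI values of real
comparisons should always be read against this floor at the relevant
sample size.

`bootstrapDI()` attaches a percentile confidence interval from
resampling both groups with replacement (edges frozen from the original
pooled data). At least 100 resamples are required; fewer make the
percentile quantiles unstable, and the function refuses rather than
returning a noisy interval. The bootstrap is an uncertainty extension of
this package — the original statistic is a point value.

# Morphometry

## Per-cell descriptors

`measureCells()` computes, per label of a `VoxelVolume` (a 3D integer
array in (z, y, x) order with per-axis spacing in µm):

* **volume** — voxel count × voxel volume;
* **surface area** — area of the 0.5 level set of the label mask,
  triangulated by marching tetrahedra after a 3×3×3 box smoothing of the
  binary field (below);
* **sphericity** — Wadell's $\psi = \pi^{1/3} (6V)^{2/3} / A$, the
  standard definition normalized to 1 for a sphere. Cell sphericity in
  imaging studies is often reported in arbitrary units without a stated
  formula; fixing Wadell's form makes values comparable and bounded.
* **projected area** — footprint of the label projected along z by
  default (matching 2D histological sections); the axis is
  configurable. Which scalar feeds the DI (projected area or volume) is
  a pipeline flag, defaulting to projected area.
* **equivalent diameter** — $(6V/\pi)^{1/3}$.

## Surface area: why a smoothed isosurface

Counting exposed voxel faces overestimates the area of smooth bodies by
up to 50% (the staircase effect) and would bias sphericity badly.
Instead the binary mask is zero-padded, averaged with a 3×3×3 box
kernel, and the 0.5 isosurface of the smoothed field is triangulated by
marching tetrahedra (six tetrahedra per grid cube, linear edge
interpolation). The box average places the isosurface through the true
position of flat interfaces and closely tracks curved ones: on a
digitized r = 20 voxel sphere the measured area is within 0.1% of
$4\pi r^2$ and sphericity is 0.999. Two consequences are documented
rather than hidden:

* discretization can push sphericity slightly above 1; a mesh tolerance
  of $\varepsilon_{mesh} = 0.02$ applies to all sphericity comparisons
  on rasterized solids;
* smoothing rounds sharp edges, so faceted bodies (boxes) read a few
  percent low, and structures thinner than about 2 voxels across lose
  area. Cells and protrusions at the recommended sampling (protrusion
  diameter ≥ 4 voxels) are unaffected in practice; the anisotropic-box
  test bounds the residual deficit.

Labels are treated as 26-connected (a protrusion touching its cell body
diagonally stays attached).

## Porosity and local thickness

`porosityThickness()` reports the void fraction plus the distributions
of local wall thickness (material phase) and local separation (void
phase). Local thickness follows the largest-inscribed-sphere definition
used by micro-CT trabecular analysis: the thickness at a point is the
diameter of the largest sphere, fully contained in the phase, that
contains the point. It is computed by an exact Euclidean distance
transform followed by sphere painting in decreasing-radius order, which
is algebraically identical to the exhaustive search (the suite verifies
exact equality on small volumes against an $O(n^2)$ brute-force oracle).

Two conventions are fixed and documented: the inscribed-sphere radius at
a candidate center is the distance to the nearest opposite-phase voxel
center minus half a voxel (so a slab of $t$ voxels reads exactly $t$,
and a one-voxel sheet reads 1); and voxels beyond the array faces are
treated as belonging to the phase, so a structure touching the border is
measured as if it continued (an infinite slab can be represented by a
finite block). Degenerate all-void or all-material volumes return
porosity 1 or 0 with the corresponding distribution empty — documented,
not an error.

# Scaffold physics

* **Swelling** — exact formula $100\,(W_h - W_d)/W_d$; $W_h < W_d$ is
  non-physical and an error.
* **Darcy permeability** — per-trial flow $Q = V/t$ for a fixed perfused
  volume (default 2 mL), superficial velocity $v = Q/A$, and a
  least-squares fit of $\Delta p = (\mu L / k)\, v$ **through the
  origin**: zero pressure difference drives zero flow, so an intercept
  would only absorb noise. (Permeability reports often say only "linear
  fits"; the through-origin choice is ours and is physically forced.)
  Goodness of fit is the uncentered $R^2$. The default viscosity,
  0.015 Pa·s, is that of a 66 wt% aqueous glycerol solution near 25 °C;
  the measurement temperature is rarely reported, so viscosity is a
  configurable constant, never hard-coded. The standard design uses
  pressures of 3, 5, 6, 7 and 8 kPa; generate-and-recover tests show
  exact recovery without noise and <5% error at 1% timing noise.
* **Amide II deconvolution** — the 1480–1580 cm⁻¹ band, after a linear
  baseline anchored at the window endpoints (baseline handling is not
  standardized in the field; anchoring at the band edges is the simplest
  defensible rule and is stated), is fitted with two Gaussians whose
  centers are bounded to 1510–1520 cm⁻¹ (β-sheet) and 1540–1550 cm⁻¹
  (α-helix). Fractions are analytic component areas over the total
  fitted area. The crystallinity index is additionally reported as the
  interpolated 1515/1545 cm⁻¹ absorbance ratio of the raw input
  spectrum, since both conventions circulate.
* **Modulus distribution** — nanoindentation moduli are histogrammed
  (Freedman–Diaconis) and fitted with
  $y = y_0 + \frac{2A}{\pi}\frac{w}{4(x - x_c)^2 + w^2}$. This printed
  form is a Cauchy/Lorentzian peak even though such fits are sometimes
  labelled "Gaussian" in the literature; because the naming is genuinely
  ambiguous in places, a Gaussian peak with the same area/FWHM
  parametrization is available behind `model = "gaussian"`, and the
  Lorentzian form is the default since it matches the printed equation.
  The peak (most probable) modulus $x_c$ and the arithmetic mean of the
  raw values are reported separately — for heavy-tailed surface
  distributions they differ materially.
* **Strain sweep** — the plateau storage modulus is the mean G′ over the
  first $m = 5$ points (how the plateau is averaged is not standardized;
  $m$ is configurable). The ultimate strain — the end of the linear
  viscoelastic region — is the first strain where G′ falls 10% (the
  `deviation` parameter) below the plateau, linearly interpolated in
  log-strain between the bracketing points. A sweep whose G′ never drops
  below the threshold has no ultimate strain: the result is flagged,
  not an error. tan δ = G″/G′ is computed pointwise. Note the ultimate
  strain necessarily grows when the allowed deviation grows (a 5% drop
  is crossed before a 10% drop); the suite tests this direction.
* **Shape factor** — $R_g/R_h$, with the usual reading: ≈0.66–0.8
  compact globular chains, >1 extended/unfolded.

# The synthetic-data module

The generators define the study conditions for every test; their
defaults are configuration, not measured claims.

* **Cells** are rasterized spheres with lognormal diameters (healthy
  median 30 µm, σ_log 0.35) and, with probability `protrusionRate`
  (default 0.3), one cylindrical protrusion (length lognormal, median
  15 µm; radius 0.25 of the cell radius) — the simplest solids with
  closed-form volume and area, giving exact oracles, while protrusions
  lower sphericity the way proplatelet formation does. Non-overlap is
  enforced by center rejection sampling with a cap of 1000 retries per
  cell ("overcrowded" error beyond it); every solid keeps one voxel of
  clearance from other cells and the volume faces, so labels are
  unambiguous and each cell is one 26-connected component.
* **Regimes**: `fibrotic` multiplies the diameter median by 0.6
  (smaller megakaryocytes under fibrotic remodeling) and `treated`
  moves that shift half-way back toward healthy (factor 0.8), mirroring
  partial pharmacological restoration *qualitatively* — effect sizes
  are ours, chosen once, and no published magnitude is asserted. With
  these conditions fixed, the scenario suite checks direction only:
  healthy-vs-fibrotic divergence exceeds healthy-vs-treated in ≥95% of
  seeds, and mean DI grows with the shift distance from 1.
* **Size samples** are drawn from the diameter law directly (area of
  the equatorial section, $\pi (d/2)^2$), so large populations cost
  nothing to rasterize.
* **Signals**: noiseless instruments satisfy their generating laws to
  numerical precision (collinear pressure–velocity through the origin;
  exact two-Gaussian bands; a sweep crossing −10% exactly at the
  configured strain; slabs and spheres of known thickness). `noiseSd`
  is relative (multiplicative) noise; for the spectra this makes a
  noise level of 0.02 a uniform signal-to-noise of 50 across the band.
* All generators are seeded and bit-reproducible; the RNG state of the
  caller is left untouched.

What the generators do **not** emulate: microscope point-spread
functions, shot noise, segmentation errors, touching cells, non-spherical
cell bodies, or anisotropic illumination. Passing tests therefore
validate the *computational* pipeline — rasterization-level accuracy of
the descriptors, correctness and calibration of the statistic, and
recovery of known physical parameters — not robustness to imaging
artifacts, which must be established on real data.

# Pipeline determinism

`runPipeline()` executes config-driven stage chains
(simulate → morpho → di, and a physics batch). One run seed is fanned
out per stage by folding the stage name into a 31-bit hash, so stages
draw from unrelated substreams and inserting a stage never perturbs
another stage's randomness. All analysis stages are pure functions of
their inputs; randomness lives only in the generators and the
bootstrap. The JSON manifest records inputs, outputs, per-stage seeds,
package version and MD5 checksums — and no timestamps — so identical
config + seed reproduce identical manifests, which the suite asserts.

# Problem sizes

The test and acceptance computations use sizes chosen to exercise each
property at comfortable statistical margins: spheres of radius 20 voxels
for the analytic-solid oracles; volumes ≤ 64³ for the exhaustive
local-thickness equivalence (the brute-force oracle is $O(n^2)$); 500
cells per group, 10 classes and 200 replicates for the null calibration;
50 seeds for scenario directionality; 100 seeds for noisy Darcy
recovery; 4096 draws for the modulus peak. These are the package's
standard verification sizes and scale linearly if enlarged.

# Known limitations

* DI point values are bin-scheme-dependent; only comparisons under a
  shared scheme are meaningful, and published values cannot be
  reproduced exactly without the original per-cell data and class
  edges.
* The surface mesher reads faceted bodies a few percent low and loses
  sub-2-voxel-thick structures (see above); sample thin protrusions at
  ≥ 4 voxels across.
* Local thickness at strongly anisotropic spacing inherits the
  half-voxel radius convention from the finest axis; near-isotropic
  sampling is recommended for thickness histograms.
* The bootstrap CI reflects resampling variability only; it does not
  correct the finite-sample bias floor of the DI itself.
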