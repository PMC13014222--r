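# nichemetrics

Quantitative analysis of engineered bone-marrow niche models built on
porous protein (silk-fibroin) scaffolds. The package is aimed at groups
running *ex vivo* megakaryopoiesis models — healthy or patient-derived
hematopoietic progenitors maturing into megakaryocytes inside a 3D
scaffold — who need reproducible numbers for three questions:

1. **How mature are the megakaryocytes?** 3D morphometry of labeled
   microscopy volumes: per-cell volume, isosurface area, Wadell
   sphericity ψ = π^(1/3)(6V)^(2/3)/A, projected area; plus porosity
   and local wall-thickness/separation distributions of binary scaffold
   volumes (the micro-CT largest-inscribed-sphere "local thickness"
   metric).
2. **How far has a condition shifted the cell-size distribution?** The
   **Divergence Index**: with both samples binned on shared class edges,

   DI = ½ Σᵢ |pᵢ − qᵢ|

   — the sum of absolute class-wise frequency differences normalized by
   its theoretical maximum of 2, i.e. the total-variation distance, in
   [0, 1]. DI > 0.4 is classified *substantial*, otherwise *moderate*.
   Treatment response is the relative reduction
   100·(DI_pre − DI_post)/DI_pre, with bootstrap confidence intervals
   available.
3. **What are the scaffold's physical constants?** Swelling
   100·(W_h − W_d)/W_d; Darcy permeability k = µL/slope from a
   through-origin fit of Δp against superficial velocity; two-Gaussian
   amide-II deconvolution (β-sheet 1510–1520 cm⁻¹, α-helix
   1540–1550 cm⁻¹) with crystallinity index; Thioflavin-T relative
   β-sheet content; Lorentzian fit
   y = y₀ + (2A/π)·w/(4(x−x_c)² + w²) of nanoindentation modulus
   distributions; strain-sweep ultimate strain (10% G′ drop from the
   plateau) and tan δ = G″/G′; and the R_g/R_h shape factor.

A seeded synthetic-data module generates labeled niche volumes and
instrument-like signals with known ground truth, so the full pipeline is
testable end to end with no external data. See the methods vignette
(`vignettes/nichemetrics-methods.Rmd`) for models, conventions and
limitations.

## Worked example

Simulate healthy/fibrotic/treated megakaryocyte populations, compare
their size distributions, and quantify the treatment response:

```r
library(nichemetrics)

sizes <- simulateSizeSamples(list(
  healthy  = nicheConfig(nCells = 500, regime = "healthy",  seed = 101),
  fibrotic = nicheConfig(nCells = 500, regime = "fibrotic", seed = 102),
  treated  = nicheConfig(nCells = 500, regime = "treated",  seed = 103)))
h <- binSizes(sizes, bins = 10)

divergenceIndex(h$healthy, h$fibrotic)
#> Divergence Index: 0.5160 (substantial; threshold 0.40)
divergenceIndex(h$healthy, h$treated)
#> Divergence Index: 0.2260 (moderate; threshold 0.40)
percentReduction(divergenceIndex(h$healthy, h$fibrotic),
                 divergenceIndex(h$healthy, h$treated))
#> DI reduction: 0.516 -> 0.226 (absolute 0.290, 56.2%)
```

The fibrotic niche shifts cells small enough to cross the substantial
threshold; the treated regime (half the shift recovered) falls back to
moderate, and the reduction metric summarizes the recovery.

Morphometry against the generator's analytic ground truth:

```r
sim <- simulateNicheVolume(nicheConfig(nCells = 2,
  volumeShape = c(80, 160, 160), protrusionRate = 0, seed = 4))
measureCells(sim$volume)
#>   label volume_um3 surface_um2 sphericity projected_area_um2 eq_diameter_um
#> 1     1      17762    3287.941   1.001278                826       32.37162
#> 2     2       7989    1920.994   1.006051                480       24.80264
sim$truth[, c("label", "trueDiameter", "trueVolume")]
#>   label trueDiameter trueVolume
#> 1     1     32.36448  17750.255
#> 2     2     24.81194   7997.989
```

Measured volumes agree with the analytic sphere volumes to ~0.1%, and
sphericity is 1 within the documented mesh tolerance (0.02).

Permeability from perfusion trials at 3/5/6/7/8 kPa:

```r
df <- simulateSignal(signalConfig("pressure_flow",
  trueParams = list(k = 2e-12, area = 1e-4, length = 5e-3)))
fitDarcy(df$pressure_Pa, df$time_s, area = 1e-4, length = 5e-3)
#> Darcy permeability k = 2e-12 m^2 (slope 3.75e+07 Pa s/m, R^2 1.0000, n = 5)
```

A command-line front end over the same functions is shipped in
`inst/scripts/nichemetrics.R` (subcommands `run`, `simulate`, `morpho`,
`di`, `darcy`, `amide2`, `modfit`, `sweep`, `swelling`, `shape`), and
`runPipeline()` drives YAML-configured multi-stage runs with a
checksummed, timestamp-free JSON manifest.

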