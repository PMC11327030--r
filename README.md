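# collmigr

Quantitative analysis of cell migration, invasion and collagen matrix
architecture for cells embedded in 3D collagen gels.

As collagen concentration rises (roughly 1 mg/mL in normal breast tissue to
~6 mg/mL in advanced tumors), the matrix stiffens, pores shrink and fibers
shorten, and tumor cells can switch from elongated mesenchymal migration to
rounded, bleb-driven amoeboid migration (the mesenchymal–amoeboid
transition, MAT). `collmigr` is for researchers running such 3D gel assays:
it takes tracker exports, SHG-like fiber images, two-channel cell stacks and
depth/count tables, and turns them into the standard read-outs of that
transition.

## What it computes

**Trajectory metrics** (per cell, then per condition): mean instantaneous
speed; the fraction of *static* cells, whose total path length is below 1.5
cell diameters (75 µm); the anomalous-diffusion exponent **α**, the slope of
the log–log mean-squared-displacement curve

&nbsp;&nbsp;&nbsp;&nbsp;MSD(ℓ) = ⟨|r(t+ℓ) − r(t)|²⟩ₜ ∝ ℓ^α

(α = 1 Brownian, α < 1 confined/subdiffusive, α = 2 ballistic); and the
persistence ratio, net displacement / total path length.

**Collagen structure** from 2D SHG-like images: sampled fiber lengths from a
skeletonised mask; the free-space length **Lf** (side of the largest
fiber-free square, a pore-scale proxy); spectral anisotropy (power-spectrum
second-moment ellipse; aligned fibers give an elongated ellipse); pore and
fiber size from the radially averaged spectrum; SHG-positive pixel fraction.

**Morphometry** from two-channel 3D stacks: hierarchical k-means
segmentation (3 intensity classes, minimum region size), per-channel hole
filling + union, volume in µm³, and longitudinal / transverse Feret axes.

**Invasion**: depths from the gel top, counts per 250-µm quartile band
(analysis maximum 750 µm), median depth with a distribution-free 95 % CI.

**Assay arithmetic**: viability/apoptosis percentages from field counts and
collagen-degradation percentage from fluorescence readouts.

**Synthetic data** with known ground truth for every stage: Brownian,
fractional-Brownian (exact Cholesky, α = 2H) and persistent-walk
trajectories; fiber-field images whose density presets emulate 1/3/6 mg/mL
gels; ellipsoidal two-channel cell phantoms; truncated-exponential invasion
depths.

## Worked example

Simulate three cohorts whose motile cells are fractional Brownian walkers
with Hurst exponents 0.45 / 0.30 / 0.15 (ground-truth α 0.9 / 0.6 / 0.3) and
increasing static fractions, then run the full trajectory pipeline:

```r
library(collmigr)
set.seed(20)
conds <- list("1 mg/mL" = list(hurst = 0.45, scale = 3.0, p_static = 0.06),
              "3 mg/mL" = list(hurst = 0.30, scale = 2.2, p_static = 0.45),
              "6 mg/mL" = list(hurst = 0.15, scale = 0.7, p_static = 0.80))
summ <- do.call(rbind, lapply(names(conds), function(cl) {
  cc <- conds[[cl]]
  tracks <- lapply(1:60, function(i) {
    scale <- if (runif(1) < cc$p_static) 0.05 else cc$scale
    simulate_fbm_track(sim_config(), cc$hurst, scale, track_id = paste0(cl, i))
  })
  summarize_cohort(do.call(rbind, lapply(tracks, compute_track_metrics)), cl)
}))
print(summ, digits = 2)
#>   condition n_tracks percent_static mean_instant_speed mean_alpha
#> 1   1 mg/mL       60            1.7              0.370       0.91
#> 2   3 mg/mL       60           61.7              0.111       0.55
#> 3   6 mg/mL       60           73.3              0.028       0.29
#>   percent_persistence
#> 1                 6.5
#> 2                 3.0
#> 3                 1.5
```

The fitted mean α recovers each cohort's designed exponent (0.9 / 0.6 / 0.3
within sampling noise): slow, confined cohorts read out as subdiffusive, and
the static fraction and speed fall as designed. Structure metrics work the
same way:

```r
img <- generate_fiber_image(collagen_condition_spec(6), sim_config(seed = 7))
structure_metrics(img, threshold_method = "fixed", fixed_threshold = 60, seed = 1)
#> <structure_metrics>
#>   fiber length : 3.4 um (n = 20 sampled)
#>   Lf           : 10.1 um
#>   anisotropy   : 1.10 @ -2 deg
#>   pore / fiber : 25.1 / 10.7 um
#>   SHG-positive : 30.0 %
```

Dense-gel presets give short fibers, small free-space length and a nearly
isotropic spectrum; `collagen_condition_spec(1)` gives the opposite.

Tracks can be read from CSV (`track_id, frame, x_um, y_um[, z_um]`) or
TrackMate-dialect XML via `read_tracks()`; tracker settings embedded in the
XML are carried through as metadata, never re-executed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's calibration figure from scratch: it simulates 200
two-dimensional Brownian tracks (144 frames at 10-min intervals, 2 µm step
SD), fits each track's MSD log–log slope over lags 1–20, and writes the mean
fitted exponent — the Brownian α = 1 reference of the migration analysis —
as JSON.

## Documentation

The methods vignette (`vignettes/collmigr-methods.Rmd`) describes the
models, parameter defaults and units, the numerical choices (tolerances,
tie-breaks, degenerate inputs), what the synthetic generators do and do not
emulate, and known limitations.
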