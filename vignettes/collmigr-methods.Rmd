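---
title: "Quantifying cell migration and collagen architecture in 3D gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell migration and collagen architecture in 3D gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collmigr)
```

## Scope and scientific background

Cells embedded in three-dimensional collagen gels change how they move as the
matrix gets denser: elongated, adhesion- and protease-dependent (mesenchymal)
migration gives way to rounded, bleb-driven (amoeboid) migration. Detecting
that transition quantitatively requires several independent read-outs:

* **migration statistics** from time-lapse trajectories,
* **matrix architecture** from second-harmonic-generation (SHG) images of the
  collagen network,
* **cell shape** from two-channel 3D stacks,
* **invasion depth** of cells that penetrated a gel,
* and small **assay percentages** (viability, collagen degradation).

`collmigr` implements this analysis chain as composable R functions, together
with a synthetic-data generator that produces inputs with *known* ground truth
for every stage. All tests and the acceptance script run purely on synthetic
data; no microscopy files are required.

## Trajectory metrics

A `trajectory()` is a time-ordered list of positions (µm) at a fixed frame
interval (default 10 min over 24 h, i.e. 144 frames). Four measures are
computed per cell:

1. **Mean instantaneous speed** — mean over consecutive observed frames of
   step length over elapsed time. Steps spanning tracker gaps use the true
   elapsed time.
2. **Static classification** — a cell is *static* if its total path length is
   strictly below 1.5 cell diameters (default cell diameter 50 µm, threshold
   75 µm). Ties at the threshold count as motile.
3. **Anomalous-diffusion exponent α** — the least-squares slope of
   log MSD versus log lag, where the MSD is *time-averaged within each track*:
   for lag $\ell$, $\mathrm{MSD}(\ell) = \langle |r(t+\ell) - r(t)|^2
   \rangle_t$. α = 1 is Brownian motion, α < 1 confined (subdiffusive)
   motion, α = 2 ballistic motion.
4. **Persistence** — net displacement divided by total path length, in
   [0, 1]. A zero-length path is assigned persistence 0.

`summarize_cohort()` aggregates per-track rows into the per-condition summary
(percent static, mean speed, mean α, percent persistence).

### Numerical choices

* Lags are restricted to 25 % of the track length by default
  (`max_lag_fraction = 0.25`), standard practice for short single-particle
  tracks where long-lag time averages are dominated by noise. An explicit
  `max_lag` override exists; the calibration runs use lags 1–20 of a 144-frame
  track.
* Lags averaging fewer than `min_pairs = 3` displacement pairs are dropped
  from the fit by default. For hand-sized examples (3-point tracks) pass
  `min_pairs = 1`.
* Zero MSD values (perfectly static tracks) are removed before the log-log
  fit; fewer than 3 surviving points flags α as `NA` rather than erroring, so
  batch processing never aborts.
* Tracks shorter than `min_track_frames = 10` get `alpha = NA` but still
  contribute speed, persistence and the static count — static cells are part
  of the cohort.
* Whether a cohort α should be fitted per cell and averaged, or fitted on a
  pooled MSD, is genuinely open; per-cell-then-average is implemented because
  the per-cell exponent is the quantity being classified. Cohort speed and
  persistence averages include static cells by default
  (`include_static = TRUE`), with the flag to exclude them.
* The static-total-distance is the summed path length, not the net
  displacement: "moved a total distance" parallels the persistence
  denominator, which is explicitly the total displacement.

### What the generators emulate

* `simulate_brownian_track()` draws i.i.d. Gaussian steps; its ensemble MSD
  is $d\,\sigma^2\,\tau$ for per-axis step SD σ in d dimensions
  (equivalently $2dD\tau$ with $D = \sigma^2/2$), so fitted α must
  recover 1.
* `simulate_fbm_track()` generates exact fractional Brownian motion by
  Cholesky factorisation of the fBm covariance (cheap at 144 frames, and free
  of spectral-approximation error), giving ground-truth α = 2H across the
  subdiffusive range observed for confined cells (α ≈ 0.9 / 0.6 / 0.3 at
  increasing gel density).
* `simulate_persistent_track()` is a constant-speed correlated walk with von
  Mises turning angles — a tunable persistence dial from uncorrelated
  (κ = 0) to ballistic (κ → ∞).

These are statistical emulations only: no bleb mechanics, no matrix coupling,
no proteolysis. A green test establishes that the estimators recover known
exponents and persistence levels, not that any biological mechanism is
modelled.

## Collagen structure

`binarize_fibers()` thresholds an SHG-like image (Otsu, or a fixed threshold
that must be shared across a batch — the consistency rule used for real
stacks). On the mask:

* `measure_fiber_lengths()` skeletonises (Zhang–Suen thinning), cuts the
  skeleton at junction pixels, and samples 20 branch segments, mirroring the
  manual "pick twenty fibers and measure with a ruler" protocol. Junction
  removal on crossing fibers leaves sub-pixel debris no human would call a
  fiber; segments shorter than `min_length = 2` µm are excluded before
  sampling. Segment length is the sum of inter-pixel steps (1 orthogonal,
  √2 diagonal, corner-cutting diagonals skipped) plus one pixel of extent,
  so a straight N-pixel run measures N pixels. Where fibers cross heavily
  the estimator measures junction-to-junction pieces and therefore
  *underestimates* true fiber length — consistently across conditions, which
  preserves the density trend.
* `free_space_length()` computes the Lf value. The deterministic mode is the
  exact side of the largest fiber-free axis-aligned square (binary search
  over the side with summed-area-table window counts); rotated squares are
  out of scope. The Monte-Carlo mode implements the stochastic phrasing of
  the estimand — the largest side whose *modal* crossing count over random
  placements is zero. The modal criterion demands that empty placements be
  the plurality outcome, not merely exist, so on sparse random masks it
  stops near $1/\sqrt{\text{pixel density}}$, below the deterministic
  maximum; the two coincide only when the mask's free space dominates.
  Deterministic is the default and the cross-validated reference.
* `fft_power_spectrum()` returns the DC-centred power spectrum of the
  mean-subtracted image. A Hann window is applied by default to suppress
  edge ringing; Parseval checks use `window = "none"`.
* `anisotropy_ellipse()` thresholds the spectrum at the 0.95 power quantile
  and takes second moments of the retained power; the ratio of ellipse axes
  measures alignment and the real-space fiber orientation is perpendicular
  to the spectral major axis. The 0.95 default is a bias choice: retaining
  only the top 1 % of a 256² speckled spectrum leaves so few pixels that
  isotropic fields show a chance axis ratio of ~1.4, while the top 5 % brings
  the isotropic null to ~1.25 without losing contrast on aligned fields.
* `radial_size_profile()` radially averages the spectrum, finds the dominant
  non-zero frequency $f^*$ (rings 0–1 are excluded as DC/window leakage; a
  profile whose maximum is under twice its median — white noise — is flagged
  undefined), and converts the spacing $1/f^*$ into fiber and pore size via
  the fiber area fraction: `fiber = spacing * fraction`,
  `pore = spacing - fiber`. This is the simplest decomposition that is
  exactly verifiable on analytic stripe patterns (period 10 px, duty 30 % →
  spacing 10, fiber 3, pore 7).

`generate_fiber_image()` renders anti-aliased fiber segments with additive
intensity on overlap (clipped at saturation), Gaussian lengths, von
Mises-distributed axis angles and uniform centres.
`collagen_condition_spec()` maps gel concentrations 1 / 3 / 6 mg/mL onto
presets in which fiber *area scales with collagen mass* while individual
fibers shorten (mean lengths 33 / 16 / 8 µm — the measured progression) and
alignment degrades (κ = 4 / 1 / 0.2). The counts (28 / 150 / 500 fibers on a
108-µm field) are this package's stated world, chosen once from the mass
argument; the real study's absolute Lf and pore values are not reproducible
from synthetic fields and serve as direction-of-effect templates only.

## Morphometry

`hkmeans_segment()` reproduces the hierarchical k-means contract used by
interactive tools: intensities are clustered into 3 classes by recursively
splitting the class with the largest within-class sum of squares on a 256-bin
histogram (deterministic — no random initialisation); the brightest class is
foreground and components below 10,000 voxels (at acquisition resolution;
scale down for phantoms) are removed. `fill_and_union()` fills interior
cavities per channel (background flood from the border, 6-connected), takes
the union and keeps the largest component — the membrane channel outlines the
cell, the nucleus channel covers its interior, so the union is the solid cell
body.

* **Volume** is voxel count × voxel volume.
* **Longitudinal axis** is the 3D Feret diameter between surface voxels.
  With no convex-hull library available, support extremes over 500
  deterministic Fibonacci-sphere directions are collected and measured
  exactly pairwise — exact for convex bodies up to the angular resolution.
  Voxel centres bias the Feret diameter half a voxel low, cube corners bias
  it equally high in the opposite rotation-dependent way; the midpoint of
  the two support estimates is reported, which is unbiased to within
  discretisation noise (< 2 % at 1-µm voxels for a 20-µm cell).
* **Transverse axis** is the diameter of the mask's projection onto the
  plane perpendicular to the longitudinal direction (max support width over
  180 in-plane directions) — the only rotation-invariant reading of
  "transversal distance between the furthest points".
* Anisotropic voxels are scaled to µm before any distance computation.
* A single-voxel mask is degenerate: both axes report the voxel diagonal and
  a flag is set.

`generate_cell_phantom()` provides the ground truth: a bright ellipsoidal
shell (membrane) plus inner ellipsoid (nucleus) over noisy background, with
closed-form volume $\tfrac{4}{3}\pi abc$ and axes 2a / 2b, optional rotation
about z, and a fit-with-margin precondition (≥ 2 voxels).

## Invasion profiling

`depths_from_positions()` measures depth from the gel top downwards, clamping
cells above the surface to depth 0 with a warning. `quartile_counts()` bins
depths into half-open 250-µm quartile bands, the final band closed at the
750-µm analysis maximum; deeper cells are clamped into the final band (and
counted) rather than discarded, so cells are conserved. `median_depth()`
reports the sample median with the distribution-free order-statistic 95 %
interval; the mean is also reported since "average depth" can mean either.

The synthetic depth distribution is a truncated exponential (rejection
truncation, keeping the density analytic for closed-form tests). The true
distribution of invasion depths is unknown; the exponential is a stand-in
with a tunable mean, adequate for testing binning, medians and
skew-direction comparisons, and nothing more.

## Assay arithmetic

`viability_percent()` computes per-field viability
$100(1 - \text{positive}/\text{reference})$ and averages across fields after
taking percentages (the order is not specified by the protocol; per-field
first keeps the field SD meaningful). The same function serves apoptosis
scoring with caspase-positive counts. `degradation_percent()` normalises a
fluorescence readout between its no-cell background and collagenase total,
clips to [0, 100] with a warning (noise can push a sample below background),
and is invariant to detector gain and offset.

## Reproducibility and verification

Every generator draws from a single seeded stream (`sim_config(seed = )`),
and identical seeds give bit-identical output. The test suite checks each
operation against an independent oracle: closed forms (ballistic α = 2,
square-wave spectra, truncated-exponential moments, ellipsoid volumes), an
independent dynamic-programming search for Lf, and Monte-Carlo recovery of
designed exponents (α = 2H for fBm cohorts). `scripts/acceptance.R` re-runs
the Brownian α calibration from scratch and writes the fitted mean exponent
to JSON.

Known limitations: fiber-length sampling measures inter-junction segments,
not full fibers, in crossing-dense fields; the Monte-Carlo Lf mode is
systematically below the deterministic maximum on sparse masks (see above);
pore/fiber size from the radial spectrum is a characteristic-spacing
decomposition, not a morphological pore measurement; no 3D fiber tracing,
bleb detection or stiffness estimation is attempted.
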