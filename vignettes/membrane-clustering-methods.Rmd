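---
title: "Quantifying membrane protein clustering and dynamics with memclust"
author: "memclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane protein clustering and dynamics with memclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memclust)
```

## Scope and model of the data

memclust quantifies how a plasma-membrane protein such as the PIN2 auxin
transporter is organised and moves on the cell surface, from calibrated
fluorescence images and time lapses. Five measurement families are covered:

1. **Lateral condensation** — segmentation of the membrane signal into
   discrete clusters ("islands"), their area distribution in four size
   classes, nearest-neighbour spacing, a per-cell clustering index, and the
   percentage of signal values outside the 95% confidence interval of a mock
   group.
2. **Single-particle mobility** — spot detection, trajectory linking,
   time-averaged mean-squared displacement (MSD) and diffusion-coefficient
   estimation.
3. **Bulk mobility (FRAP)** — single-exponential recovery fitting into
   mobile and stable fractions.
4. **Endocytic residence** — kymograph extraction and supra-threshold
   residence-lifetime measurement with censoring.
5. **Tissue-level asymmetry** — upper/lower root signal ratios, fold
   changes, and gravitropic deviation-angle summaries.

All physical quantities are in micrometres, seconds and arbitrary intensity
units (um, s, AU). Every analysis stage has a seeded synthetic generator
that produces inputs with known ground truth, so the whole pipeline is
testable without raw microscopy.

## Cluster detection and size classes

`segment_membrane()` thresholds an image with Otsu's bimodal split by
default (quantile and fixed policies are available); the computed threshold
is attached to the mask so an analysis is auditable after the fact.
`detect_clusters()` labels the mask with 8-connectivity and reports one
record per island. Areas fall into four classes, left-closed and
right-open: tiny (< 0.2 um^2), small (0.2–0.6), medium (0.6–1) and long
(>= 1 um^2). On continuous membranes most signal sits in one long island;
condensation shifts the mass into tiny and small islands.

Cluster area is measured at the island's **full width at half maximum**: the
region at or above `background + (peak - background)/2`. Measuring at
half-maximum rather than at the global segmentation threshold makes the
area insensitive to where that threshold happens to fall on each island's
intensity profile. The super-level region is integrated on an 8x bilinearly
upsampled midpoint grid because whole-pixel counting quantises the area by
up to roughly half the boundary length in pixels, a 15–20% error for the
smallest islands. A `"threshold"` policy (plain pixel count, areas summing
exactly to the masked area) remains available.

```{r clusters}
sim <- generate_cluster_image(cluster_field_spec(n_clusters = 60, seed = 1))
mask <- segment_membrane(sim$image)
rec <- detect_clusters(sim$image, mask)
size_distribution(rec)
```

## Clustering index and the outside-confidence statistic

The clustering index summarises condensation per cell as a dispersion
statistic of the membrane-pixel intensities: condensing a fixed amount of
protein into fewer, brighter pixels widens the intensity distribution and
raises the index, while a perfectly uniform membrane scores 0. The default
estimator is the coefficient of variation, which is invariant to uniform
intensity rescaling (exposure, gain); Gini and variance-over-mean
estimators can be selected through the `estimator` argument. Published
absolute index values depend on the exact estimator used there, so only
orderings (treated vs mock) are meaningful comparisons for this
implementation.

`outside_confidence()` compares a treated intensity sample against the
pooled mock sample: the mock 95% interval is the empirical 2.5–97.5
percentile range, and the statistic is the percentage of treated values
outside it. The percentile (rather than mean ± 1.96 sd) interval is the
default because membrane intensity distributions are right-skewed; a
parametric variant is selectable. Under the null the statistic sits at the
5% baseline; at least 40 mock values are required so the empirical
percentiles are defined.

```{r outside}
set.seed(1)
mock <- rlnorm(10000, 5, 0.6)
outside_confidence(rlnorm(10000, 5, 0.6), mock)
```

## Single-particle tracking and diffusion

`detect_spots()` finds local maxima above `median + snr_min * MAD` and
refines them to sub-pixel centroids by intensity weighting. The flux window
is ±3 expected radii; the centroid window is ±2 radii so a neighbouring
spot pulls the centroid less; non-maximum suppression covers ±1 radius so
spots four radii apart are all retained. `link_trajectories()` uses greedy
nearest-neighbour linking (closest pairs first, each detection used once,
up to `max_gap` bridged frames) — adequate at the low densities this
package targets and simple enough to verify against ground truth exactly.

`compute_msd()` averages time-averaged per-track squared displacements; in
2-D, `MSD(t) = 4 D t + 4 sigma^2` for Brownian motion observed with static
localisation noise `sigma`. `fit_diffusion()` fits a weighted line through
the first 4 lags by default — the standard short-lag compromise: more lags
lower the variance but bias D downwards for confined or noisy tracks. The
intercept is retained as the localisation-noise term, and a negative fitted
slope is clipped to `D = 0` with a flag. Spot brightness classes use fixed
boundaries: low < 5e3, medium 5e3–15e3 (inclusive), high > 15e3 AU.

```{r spt}
tracks <- generate_trajectories(trajectory_field_spec(
  n_tracks = 200, D_free = 0.05, localization_sd = 0.02, seed = 2))
fit_diffusion(compute_msd(tracks, n_lags = 10))[c("D", "intercept")]
```

## FRAP

Curves are normalised as `(I - background) / (prebleach - background)` and
fitted post-bleach with the single-exponential model
`I(t) = I0 + (Iinf - I0)(1 - exp(-k t))` by bounded Levenberg–Marquardt.
The mobile fraction is the recovered amplitude relative to the bleached
amplitude, `(Iinf - I0)/(1 - I0)`, and `stable = 1 - mobile` holds exactly
by construction. A single-exponential model is used because the analysis
targets a mobile/stable dichotomy; multi-component recovery and
bleach-geometry corrections are out of scope. A completely flat post-bleach
curve is returned as `mobile = 0` with `k = 0` rather than as a failed fit,
since the rate is unidentifiable there.

Parameter accuracy: noise-free curves are recovered to well under 1% over
a (mobile, k) grid spanning 0.2–0.9 and 0.05–0.5 /s. With realistic
per-trace noise (5% of the plateau), single traces at low mobile fractions
carry 5–10% statistical error in k, so noisy parameters are estimated from
the mean of ~20 replicate curves (`average_frap_curves()`), as FRAP is
analysed in practice; accuracy is then summarised as RMS error across the
grid (< 5% in the shipped tests).

## Kymographs and residence lifetimes

`extract_kymograph()` samples a time lapse along a polyline at 1-pixel
steps (maximum across the perpendicular width) and stacks positions over
frames. `measure_lifetimes()` turns each contiguous supra-threshold run in
a spatial row into one record with `duration = run length x frame_interval`
(inclusive frame count). Runs touching the first or last frame are flagged
censored — their full residence time is unobserved — and the default
summary excludes them; Kaplan–Meier-style corrections are a possible
extension, not implemented because the target readout is a simple mean
lifetime chart. One particle per row is assumed at the densities generated
here; two runs in a row are split at any sub-threshold frame.

Note a deliberate property of the synthetic conditions: with nucleation
times uniform over a 90 s movie and mean 8 s exponential lifetimes,
excluding censored records length-biases the uncensored mean to about
7.2–7.4 s (longer residencies are more likely to touch the movie end).
This is a property of censoring-by-exclusion itself, reproduced faithfully
rather than corrected.

## Root asymmetry and angles

Profiles are sampled along polylines at 1-pixel steps with bilinear
interpolation; `sided_ratio()` is the lower/upper mean ratio (reciprocal
under swapping, by construction), and `fold_change()` is plain
treated/control division, invariant to common rescaling. Deviation angles
are stored signed in degrees but summarised as absolute deviations by
default, matching how deviated root-tip angles are charted. Group
comparisons use the two-tailed equal-variance Student's t-test; dose
series are tabulated with a monotonicity flag.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their spec (including the seed) and
return the planted ground truth:

* **Cluster fields** — Gaussian-profiled blobs whose area is defined at
  half-maximum (`sigma = sqrt(area / (2 pi ln 2))`), placed largest-first
  by rejection sampling so no two islands merge above half-maximum, over a
  uniform membrane background; optional Poisson shot noise then Gaussian
  read noise (the standard camera model; defaults are light read noise so
  tests may also run noise-free). Overcrowded specs fail with an explicit
  density error rather than degrading.
* **Trajectories** — 2-D Brownian steps with per-axis variance
  `2 D dt` for the mobile class, anchored points for the immobile class,
  reflecting boundaries (which preserve the Brownian MSD), additive
  localisation noise, and class-dependent brightness (immobile spots
  brighter, mirroring the inverse intensity–mobility relation of
  oligomerised membrane proteins).
* **FRAP curves** — the exact single-exponential model above plus Gaussian
  noise.
* **Kymographs** — one particle per row, uniform nucleation from frame 2
  (a run starting at frame 1 would be indistinguishable from one predating
  acquisition), exponential lifetimes quantised to frames, truncated and
  flagged censored at the movie end with the same rule the measurement
  uses.
* **Asymmetric roots** — two parallel bands whose noise-free means differ
  by exactly `lower_fold`.

None of the generators simulate a real point-spread function, detector
pixelation artefacts, photobleaching, out-of-focus light or motion blur.
Passing tests therefore demonstrate that the estimators recover the
quantities they claim from data obeying their assumptions — not that those
assumptions hold for any particular microscope.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped tests: 1000-cluster fields (~1400^2 px),
  500-track ensembles of 60 frames, 200-particle kymographs, 10,000-sample
  outside-confidence calibrations — chosen so each stage's recovery
  statistics are tight while the whole suite runs in well under a minute.
* Size-class and brightness-class boundaries are total, deterministic step
  functions; boundary values are covered by tests (0.2 um^2 is small,
  5e3 AU is medium).
* Connected components are 8-connected; the implementation is verified
  against a brute-force flood fill on random 64x64 masks.
* Constant images cannot be auto-thresholded and raise an error, as do
  zero-mean intensity vectors (clustering index), mock samples under 40
  values (outside-confidence), sub-minimum post-bleach samples (FRAP), and
  empty polygon regions.
* Seeds: every random draw flows from the spec or config seed through
  `withr::with_seed`, so generators never disturb the caller's RNG stream
  and identical specs give bit-identical output.
* TIFF output stores intensities as 16-bit counts (1 AU = 1 count, clamped
  at 65535); integer-AU images round-trip exactly.

## Known limitations

Greedy linking degrades at high particle density (global assignment would
be needed); diffusion estimation assumes free 2-D Brownian motion over the
fitted lags (no anomalous-diffusion model selection); lifetime summaries
ignore censoring bias by design; the clustering index is one of several
dispersion estimators in use and its absolute values are not comparable
across implementations; and root-tip angles are consumed as tables — angle
extraction from raw images is out of scope.
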