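---
title: "Digital microarray counting: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital microarray counting: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiris)
```

## The measurement

A single-particle interferometric reflectance sensor images a DNA
microarray printed on a layered Si/SiO~2~ chip. Each captured target
molecule is tagged with a plasmonic gold nanorod, and each nanorod appears
in the microscope as a faint diffraction-limited spot whose contrast is a
few percent of the background reflection. Quantification is *digital*:
instead of integrating an analog signal over a spot, individual particles
are counted.

Two read-outs are supported:

* **Endpoint.** A z-stack is taken through focus. The interferometric
  particle signature is an odd function of defocus, so after per-pixel
  median normalization the max--min *differential image* across the stack
  concentrates each particle into a bright bump on a near-zero background.
  One count per particle.
* **Kinetic.** A time-lapse movie is recorded during incubation, every
  binding (and debinding) event is tracked, and the *cumulative* number of
  binding events per spot is accumulated. A complex that binds and later
  debinds still counts — this "total binding" convention is what buys
  sensitivity over endpoint counting, because at very low concentration the
  equilibrium surface coverage is tiny while the event rate is steadily
  positive.

Binding rates (events/hour, the slope of the cumulative curve) feed a
calibration model. At low concentration the rate is transport-limited and
scales with the *sheet density* of targets, proportional to the 2/3 power
of the volumetric concentration $c$:

$$\lambda(c) = k\,\left(\frac{c}{c_\mathrm{ref}}\right)^{2/3},$$

so on double-logarithmic axes calibration curves approach a slope of 0.67.
The package fixes $c_\mathrm{ref}$ at 1 fM so rate constants are
human-scale numbers.

Two limit-of-detection conventions are implemented:

* endpoint: $\mathrm{LOD} = 3.3\,\sigma/\mathrm{slope}$, with $\sigma$ the
  blank standard deviation and the slope on the *linear* response scale;
* kinetic: the concentration where the theoretical-slope (2/3) line through
  the measured $(\log c, \log \lambda)$ points crosses the decision
  threshold $\bar{r}_\mathrm{blank} + 3\,\sigma_\mathrm{blank}$, with an
  interval from the free best-fit line (lower bound) and the steepest
  plausible line (upper bound).

## The synthetic scene generator

Real instrument data is not required anywhere: `simulation_config()` /
`sample_events()` / `render_timelapse()` / `render_zstack()` generate
ground-truth event streams and image stacks with the statistical structure
the detection stages assume.

* Arrivals per spot are homogeneous Poisson with rate $\lambda(c)$; a
  blank, concentration-independent nonspecific rate can be added.
* Dwell times are exponential with mean $\tau$, except a fraction
  $p_\mathrm{perm}$ of events that never debind. The underlying assay
  literature invokes only a dwell-time *prior*, not a distribution; the
  exponential-plus-permanent mixture is the simplest model that produces
  both transient and stable binders, and both parameters are exposed.
* Each visible particle is rendered as an isotropic Gaussian bump
  (sd `psf_sigma`, default 1.5 px) of amplitude
  `particle_contrast * background_level` on a uniform background, plus
  i.i.d. Gaussian shot noise. The orientation-dependent polarization
  contrast of real gold nanorods is deliberately abstracted into this
  single scalar amplitude: the detection operators only require
  diffraction-limited bright spots.
* In z, the bump amplitude follows the defocus curve
  $a(z) = A \sin(2\pi z/\Lambda)\, e^{-z^2/2w^2}$ (odd through focus,
  default $\Lambda = 4\,\mu m$, $w = 1.5\,\mu m$), which reproduces the
  sign-flipping interferometric signature that makes the max–min
  differential image work.
* Flow rate is recorded as metadata only; no transport PDE is solved.

Default study conditions, chosen once: contrast 0.1 against noise sd 0.01
(contrast/noise = 10, the reference operating point used throughout the
validation suite), frame interval 10 s over a 35-minute incubation, rate
constant 50 events·h⁻¹·spot⁻¹ at 1 fM, mean dwell 600 s, permanent
fraction 0.1, calibration grid 100 aM–1 pM in decade steps, spot pitch
200 µm with sixteen replicate spots per probe in the array layout.

What the generator does **not** emulate: structured backgrounds
(reflectivity texture, spot rims), drift and vibration, polarization
effects, correlated camera noise, and crowding beyond simple bump
addition. Green tests therefore demonstrate algorithmic correctness under
the stated statistical model, not instrument-grade robustness.

## Detection operators

The kinetic and endpoint detectors share one operator chain
(`detect_stack()`):

1. **Temporal averaging** (`temporal_average()`): non-overlapping blocks of
   $n$ frames are averaged; an incomplete tail block is *dropped*, never
   padded, so every output frame has identical noise statistics.
2. **Normalization.** Endpoint stacks are divided per pixel by the
   z-median (`normalize_stack()`). Kinetic movies are divided per pixel by
   a temporal baseline. The default baseline is the per-pixel *minimum*
   across the movie rather than the median: a binder that dwells for more
   than half the movie contaminates its pixel's median and silently erases
   its own event, whereas the minimum is valid as long as the pixel is
   particle-free in a single frame. The minimum is biased low by a constant
   ~2σ of the noise, but the correlation score below is invariant to
   affine intensity changes, so the bias is harmless. The median (global or
   rolling) remains available via `detection_params(baseline = "median")`.
3. **Differential image** (endpoint): per-pixel max − min across z.
4. **Matched filtering** (`correlate()`): zero-normalized cross-correlation
   (ZNCC) against a detection kernel — a measured particle image in
   production, a Gaussian template (`gaussian_kernel()`) for synthetic
   work. Scores are Pearson correlations in [−1, 1], computed with
   zero-padded FFTs that reproduce the direct windowed sums exactly
   (border pixels are scored on the valid overlap); the direct
   implementation is retained internally and the two routes are compared
   in the test suite.
5. **Binarization** at a global threshold, default 0.55.
6. **Keypoint filtering** (`extract_and_filter_keypoints()`): 8-connected
   components, area = pixel count, perimeter = border-pixel count,
   score-weighted sub-pixel centroid; keep components with area in
   [5, 200] px² and area-to-perimeter ratio in [1.05, 5]. The ratio filter
   passes compact (round) blobs and rejects elongated artifacts — a 1-px
   line of any length has ratio exactly 1.

The numeric defaults are not published for the original instrument; they
were calibrated once on the synthetic generator and frozen. At the default
operating point they give zero false positives on blank movies, exact
recall on noiseless scenes, and ≥95% recall at contrast/noise = 10. The
threshold of 0.55 (rather than a higher value) matters jointly with the
compactness filter: at higher thresholds the surviving blob of a
marginal particle shrinks to a 2×2 square, whose ratio of 1.0 is
indistinguishable from a line's.

A sparse **pseudomedian** smoother (`pseudomedian_smooth()`) is provided
for background estimation: per window, the mean of the maximum and minimum
of row medians, evaluated on a strided grid and bilinearly interpolated,
with a dense reference mode tested to agree within 2% of dynamic range.
It is *not* subtracted by default: ZNCC is locally zero-normalized, and
measured on synthetic scenes a kernel only slightly larger than the PSF
absorbs a large fraction of the particle amplitude when subtracted. Enable
`smooth_background = TRUE` (with a kernel at least twice the particle
footprint) only when large-scale background undulation survives
normalization.

## Tracking

Particles are immobile once bound, so `associate()` uses greedy per-frame
nearest-neighbour matching within an association radius (default 2 px,
ties by distance then lowest track id) rather than global assignment; the
known cost is that two binders closer than roughly one PSF merge — a
physical resolution limit shared by any single-emitter detector.
`repair_gaps()` merges co-located track fragments separated by at most
`max_gap` frames (default 2; detector dropouts are short compared with the
dwell-time prior) and is idempotent; `remove_single_frame()` discards
tracks supported by fewer than `min_duration` frames (default 2,
suppressing single-frame positives). A reappearance after a gap longer
than `max_gap` is deliberately a *new* binding event, consistent with
cumulative total-binding counting (`cumulative_binding()`), whose curves
are non-decreasing by construction.

On every instance whose emitters are resolvable (separation above the
association radius), the associate → repair → filter chain is provably
equivalent to interval reconstruction per site; the test suite checks this
against an independent brute-force oracle on hundreds of randomized small
instances.

## Microarray geometry and aggregation

`build_grid()` lays out replicate probe spots on a regular lattice
(default: sixteen replicates per probe at 200 µm pitch, the spotter layout
of the assay this package models); grids are authored in micrometres and
converted through the stack's pixel pitch, keeping them
instrument-independent. `assign_spots()` sends each track to the unique
disc containing it or to background; counts partition exactly.
`per_probe_curves()` aggregates replicate spots pointwise either as mean ±
SD (default, preserving error bars and blank statistics) or as a pooled
sum — published figures do not always say which convention a lab used, so
both are first-class.

## Quantification: numerical choices

* Rates are OLS slopes of cumulative count vs time in hours
  (`estimate_rate()`), with an optional burn-in/window.
* All calibration fits are in log10 (`fit_calibration()`); zero responses
  cannot be log-transformed and are **excluded with a warning** — never
  patched with pseudo-counts.
* The theoretical-slope line fixes the slope at 2/3 and fits only the
  intercept (least squares); on model-exact data its residual is zero.
* `lod_endpoint()` computes 3.3σ/slope. Because the calibration is a power
  law, "slope" is ambiguous; the default takes the local derivative
  $a\,b\,c^{b-1}$ of the fitted response at the lowest measured
  concentration (the linear-response approximation is best at the low
  end), with a global straight-line fit available by flag.
* `lod_kinetic()` inverts the 2/3 line at the threshold
  $\bar r_b + 3\sigma_b$. "Steepest possible slope" has no published
  formula; it is operationalized as the upper bound of the free slope's
  95% confidence interval, pivoted through the centroid of the points
  (the OLS-invariant point). The lower bound is the free best-fit
  crossing. A degenerate all-zero blank makes the threshold zero and is an
  error unless a positive `floor` is supplied; an LOD outside the fitted
  concentration range is flagged `extrapolated` rather than silenced.
* Blanks default to rates measured on non-complementary control spots;
  buffer-only (zero-concentration) runs are equally valid input to
  `blank_stats()`.
* Copy-number conversion uses $N_A = 6.02214076\times 10^{23}$:
  10 aM in 0.2 mL is `r round(molarity_copies(1e-17, 2e-4), 1)` copies.

## Validation problem sizes

The shipped test suite validates the pipeline at deliberately desk-scale
sizes: 64–160 px frames, 30–180 frame movies, ≤ 50 planted particles,
50 replicates per concentration for calibration statistics, and an
end-to-end limit-of-detection recovery study of 100 independent seeds
(three calibration movies and three hour-long blank movies each) in which
the blank nonspecific rate is solved in closed form — from the covariance
of the Poisson counting process pushed through the least-squares weights —
so that the true decision threshold sits exactly on the rate law at
10 aM; the study requires the median recovered LOD to fall within a
factor of two of that planted value.

## Known limitations

* Greedy association degrades in dense scenes (mean spacing approaching
  the association radius); no global assignment or motion model is
  attempted.
* The minimum-baseline normalization cannot see a particle that is present
  in *every* frame of a movie — by design, such a particle is not a
  binding event.
* Sub-pixel localization is a score-weighted centroid; no PSF fitting.
* The simulator's noise is white and Gaussian; real cameras and real
  chips are less kind.
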