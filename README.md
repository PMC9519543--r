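# spiris — digital microarray particle counting

`spiris` quantifies DNA microarray assays read out on a single-particle
interferometric reflectance sensor (SP-IRIS), where every captured target
molecule is tagged with a gold-nanorod label that appears as a faint
diffraction-limited spot. Instead of integrating an analog spot signal,
the package counts particles one by one — in endpoint mode from a
through-focus z-stack, and in kinetic mode by tracking every individual
binding and debinding event in a time-lapse movie and accumulating the
cumulative number of binding events per probe spot. It is aimed at
developers of single-molecule biosensing assays (e.g. attomolar miRNA
detection) who need the full computation chain — detection, tracking,
per-spot aggregation, calibration and limit of detection — plus a
synthetic scene simulator so everything can be exercised and validated
without instrument data.

## The model in brief

* **Detection.** Stacks are normalized per pixel (z-median for endpoint
  stacks, a robust temporal baseline for movies); endpoint stacks are
  collapsed to the per-pixel max−min differential image; candidate
  particles are scored by zero-normalized cross-correlation (ZNCC) with a
  detection kernel, binarized at a global threshold, and filtered by blob
  area and area-to-perimeter ratio so that only compact,
  diffraction-limited keypoints survive.
* **Tracking.** Greedy nearest-neighbour linking of immobile emitters,
  gap repair across short dropouts, and removal of single-frame positives.
  Each surviving track is one binding event; debinding never decrements
  the count (total-binding convention).
* **Calibration.** At low concentration the binding rate is
  transport-limited and scales with the sheet density of targets,
  λ(c) = k·(c/c_ref)^(2/3) — slope 0.67 on log-log axes. Rates are OLS
  slopes of cumulative curves (events/hour).
* **Limits of detection.** Endpoint: LOD = 3.3·σ/slope on the linear
  response scale. Kinetic: the concentration where the slope-2/3 line
  through the calibration points crosses blank mean + 3 SD, with an
  interval from the free best-fit line (lower) and the steepest plausible
  slope (upper). 10 aM in 0.2 mL corresponds to ≈1204 molecules.

## Worked example

```r
library(spiris)

## 1. simulate a kinetic calibration at 100 aM - 1 pM and fit the rate law
cfg <- simulation_config()          # 50 events/h/spot at 1 fM, c^(2/3) law
cal <- make_calibration_dataset(cfg, replicates = 20, seed = 7)
agg <- aggregate(rate ~ concentration, cal$points, mean)
cbind(concentration = format_molarity(agg$concentration),
      rate_per_hour = round(agg$rate, 2))
#>      concentration rate_per_hour
#> [1,] "100 aM"      "13.6"
#> [2,] "1 fM"        "51.23"
#> [3,] "10 fM"       "221.28"
#> [4,] "100 fM"      "1078.24"
#> [5,] "1 pM"        "4992.13"
fit_calibration(agg$concentration, agg$rate)
#> calibration_fit: slope 0.6453 (CI 0.6061..0.6845), intercept 11.4179;
#>   slope-0.667 line intercept 11.7171

## 2. limit of detection from the fitted trend and the blank replicates
lod <- lod_kinetic(agg$concentration, agg$rate, cal$blank_stats)
lod
#> lod_estimate (kinetic_intersection): LOD = 11.4 aM [9.12 aM, 13.6 aM] (extrapolated)
round(molarity_copies(lod$lod, 2e-4))
#> [1] 1375    # copies in 0.2 mL at the LOD

## 3. image-level round trip: render a movie, detect, track, count
set.seed(7)
movie_cfg <- simulation_config(image_shape = c(96, 96), frame_interval = 15,
                               duration = 900, rate_constant = 60)
spot   <- spot_region(47.5, 47.5, radius = 40)
events <- sample_events(movie_cfg, spot, concentration = 1e-15)
movie  <- render_timelapse(movie_cfg, events)
movie
#> frame_stack: 60 frames of 96 x 96 px (time axis, 0..885 s, 0.5 um/px)
tracks <- link_tracks(detect_stack(movie))
length(tracks)
#> [1] 19      # vs 18 planted events visible for >= 2 frames (23 planted in all)
```

Reading the numbers: the mean rates climb by roughly ×4 per decade of
concentration — the (10)^(2/3) ≈ 4.6 signature of diffusion-limited
binding, softened slightly at the top of the range — and the free-fit
log-log slope of 0.645 sits next to the theoretical 0.67. The kinetic LOD
is the crossing of the slope-2/3 trend with the blank threshold; it lies
below the lowest measured concentration, hence the `extrapolated` flag.
In the image-level run, every planted event that was visible for at least
two frames is recovered (one extra count comes from a track split); events
that bind in the last frame or dwell for under two frames are not
countable by construction.

A full simulate → detect → track → quantify run, with TIFF movies, CSV
tables and a JSON report written to disk, is one call
(`run_pipeline(run_config(...))`) or one shell command
(`exec/spiris run --config run.json --seed 1`).

## Layout

* `R/` — simulator, detection, tracking, spot grid, quantification,
  pipeline + CLI entry (`exec/spiris`)
* `vignettes/digital-microarray-counting.Rmd` — models, parameter
  defaults, numerical choices, limitations
* `tests/testthat/` — unit, property and acceptance tests
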