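# rsomvasc

Vascular biomarker analysis for raster-scan optoacoustic mesoscopy (RSOM)
of human skin.

RSOM images the skin's microvasculature through its entire depth at
tens-of-micrometre resolution by raster-scanning a focused ultra-broadband
ultrasound detector over laser-excited tissue. Malignant melanoma remodels
the dermal vasculature around a lesion — denser, shorter, more tortuous,
more heterogeneous vessels than around benign nevi — and those changes can
be quantified from RSOM volumes. This package implements the complete
analysis chain for dermatology imaging groups working with such data:

* **Motion**: per-A-line skin-surface tracking, displacement estimation by
  envelope cross-correlation, quality grading (Q1 ≤ 70 µm / Q2 ≤ 300 µm /
  Q3), and motion correction.
* **Reconstruction**: dual-band (10–40 and 40–120 MHz) zero-phase
  band-splitting, sensitivity-weighted delay-and-sum beamforming onto a
  fixed voxel grid (12 × 12 × 3 µm default), red/green dual-band
  composites, layer-restricted maximum-intensity projections, and linear
  spectral unmixing (melanin / HbO2 / Hb) by non-negative least squares.
* **Segmentation**: surface flattening, epidermis/dermis boundary and
  pigmented-lesion boundary by a globally optimal dynamic-programming
  tracer, the 500 µm surrounding-tissue-vessel (STV) band by distance
  transform, and AngioQuant-style vessel segmentation into mask, skeleton,
  branch points and segments.
* **Biomarkers**: total blood volume TBV = N/V, vessel density, average
  vessel length (total skeleton length / branch count), tortuosity from
  the distance metric DM = AL/SL (reported as the index mean(DM − 1)),
  box-counting fractal number FN = slope of log N(r) vs log(1/r), and
  lacunarity L = mean(I²)/mean(I)² − 1.
* **Cohort statistics**: two-tailed Mann–Whitney U tests (exact by
  enumeration for small samples), fixed-orientation ROC/AUC with the
  midrank identity AUC = U/(nA·nB), and an in-sample multivariate
  logistic combination of markers.
* **Synthetic data**: ground-truth skin/vessel phantom generation and a
  band-limited optoacoustic forward model with breathing motion, so the
  whole chain is testable without patient data.

## Worked example

Simulate a breathing scan of a known phantom, correct it, and quantify:

```r
library(rsomvasc)

phantom <- generate_vessel_phantom(
  target_tbv = 0.03,
  grid = phantom_grid(dim = c(80, 40, 60), voxel_size = c(20, 20, 10)),
  depth_range = c(300, 550), mean_segment_length = 250,
  curvature = 0.3, radius = 40, seed = 42)
phantom <- generate_skin_phantom(phantom,
                                 melanin_depth_range = c(100, 250),
                                 contrast = 3)

config <- scan_config(n_fast = 40, n_slow = 20, step_fast = 40,
                      step_slow = 40, n_samples = 1100)
sens <- sensitivity_field(focal_depth = 800)
scan <- simulate_scan(phantom, config, standoff = 400, sensitivity = sens,
                      motion = motion_params(amplitude = 30, period = 4))

trace <- estimate_displacement(scan, window = 150)
classify_quality(trace)
#> <qc_grade> Q1 (usable as-is): max |displacement| 22.5 um (q1 = 70, q2 = 300)

scan <- correct_motion(scan, trace)
grid <- recon_grid(dim = c(78, 38, 45), voxel_size = c(20, 20, 10),
                   origin = c(0, 0, 500))
result <- run_pipeline(scan, grid, dermis_range = c(700, 950),
                       sensitivity = sens)
result$biomarkers
#> <biomarker_set>
#>   TBV                 0.0400 (4.00%)
#>   vessel density      0.0388
#>   avg vessel length   460.56 um
#>   tortuosity (DM - 1) 0.0292   [mean DM 1.0292]
#>   fractal number      1.8850
#>   lacunarity          0.0147
```

The injected motion (30 µm breathing sinusoid) grades Q1 and is removed;
the measured TBV of 4.0% sits near the phantom's rasterized truth of
3.1%, and the near-straight injected vessels (true tortuosity index
0.013) read 0.029 after skeletonization.

Group comparison on a cohort table (here the moment-matched synthetic
stand-in cohort; any CSV read with `read_cohort_table()` works the same):

```r
cohort_report(synthetic_cohort(seed = 1))
#> <cohort_report> nevus n = 16, melanoma n = 16
#>                marker melanoma_mean melanoma_sd nevus_mean nevus_sd   U        p    auc
#>                   tbv        0.3594      0.0622     0.2362   0.0561 239 3.12e-05 0.9336
#>        vessel_density        0.0170      0.0040     0.0100   0.0035 229 0.000152 0.8945
#>  avg_vessel_length_um      139.6000     46.6300   260.3900  62.4900  11 1.13e-05 0.9570
#>            tortuosity        0.4700      0.0830     0.2700   0.0820 246 9.49e-06 0.9609
#>        fractal_number        1.2600      0.1800     1.1200   0.0620 194 0.013563 0.7578
#>            lacunarity        0.1700      0.0830     0.0880   0.0500 205 0.003937 0.8008
#> combined (tbv + tortuosity): AUC = 0.969
```

A thin command-line front end over the same functions lives at
`inst/cli/rsomvasc.R` (`simulate`, `qc`, `motion-correct`, `reconstruct`,
`biomarkers`, `cohort-stats`).

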