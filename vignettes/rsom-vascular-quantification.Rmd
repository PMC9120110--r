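---
title: "Quantifying skin microvasculature from raster-scan optoacoustic mesoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin microvasculature from raster-scan optoacoustic mesoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the model

Raster-scan optoacoustic mesoscopy (RSOM) excites skin with nanosecond
laser pulses and records the resulting ultrasound with a focused,
ultra-broadband detector raster-scanned over the skin. Each scan position
yields an A-line: a time-resolved pressure signal in which time maps to
depth through the speed of sound. Melanin and hemoglobin are the dominant
endogenous absorbers, so a reconstructed volume shows the pigmented
epidermis and the dermal microvasculature through the whole skin depth at
resolutions of tens of micrometres. Around malignant melanoma the dermal
vasculature becomes denser, more tortuous and more heterogeneous than
around benign nevi, and this package exists to turn raw RSOM scans into
the six scalar biomarkers that quantify those changes, plus the cohort
statistics that compare lesion groups.

`rsomvasc` implements the full chain:

1. breathing-motion estimation, grading and correction on the raw A-lines,
2. dual-band (10–40 / 40–120 MHz) delay-and-sum reconstruction with a
   detector-sensitivity weighting,
3. skin-surface flattening, epidermis/dermis layer segmentation and
   pigmented-lesion boundary extraction by dynamic programming,
4. vessel segmentation into mask, skeleton and branch points,
5. the biomarkers — total blood volume (TBV), vessel density, average
   vessel length, tortuosity, fractal number, lacunarity,
6. group comparison (two-tailed Mann–Whitney U), logistic marker
   combination and ROC/AUC.

Because patient scans cannot ship with a package, a first-class synthetic
module generates layered skin phantoms with known vessel geometry and
simulates the raster acquisition, so that every stage is tested against
ground truth.

# The forward model and what it deliberately leaves out

`simulate_scan()` is a single-scattering, fluence-flat model: every
absorbing voxel emits one band-limited bipolar (N-shaped,
derivative-of-Gaussian) pulse, delayed by the one-way travel time
`distance / c`, weighted by `1/distance` spreading and by a lateral
Gaussian sensitivity whose width grows away from the focal depth
(`sensitivity_field()`: waist 30 µm, Rayleigh-type depth scale 300 µm,
support truncated at 3 sigma). Breathing is a rigid vertical translation
`amplitude * sin(2*pi*t/period + phase) + drift*t` evaluated at each
A-line's acquisition time, which is derived from the acquisition order and
the pulse repetition rate. White Gaussian noise is added last.

Deliberately excluded: acoustic heterogeneity, frequency-dependent
attenuation, wavelength-dependent fluence, and full-wave propagation.
The model is sufficient to exercise band-splitting, beamforming,
segmentation and the biomarkers; it is not a wave solver, so tests that
pass here certify the analysis chain, not the physics of any particular
instrument.

Defaults mirror a fast-RSOM acquisition: a 4 × 2 mm field scanned at
201 × 101 positions (20 µm steps), 1 GS/s digitization, a 1.4 kHz pulse
rate (the full raster completes within a ~15 s breath-hold), 532 nm
illumination, and a speed of sound of 1500 m/s.

# Phantoms

`generate_vessel_phantom()` grows vessel trees inside a depth slab.
Each vessel keeps a base heading and meanders around it sinusoidally;
the `curvature` parameter is the amplitude (radians) of that heading
oscillation and the meander wavelength is drawn from
`meander_wavelength` (default 300–600 µm). This parameterization was
chosen over white-noise direction jitter for a structural reason: jitter
puts the injected tortuosity at the step scale (tens of µm), below the
acoustic resolution, so no imaging pipeline could ever observe it. A
meander at hundreds of µm is what real dermal vessels do and what the
system can resolve. `curvature = 0` produces exactly straight vessels
(arc/chord ratio 1 to machine precision), and tortuosity grows
monotonically with the amplitude.

Trees are added until the rasterized vessel fraction in the slab reaches
`target_tbv`; the last gap is closed with single short segments so the
realized fraction lands within a few percent of the target. The continuous
centerlines, branch points and per-segment arc/chord lengths are retained
as ground truth (`true_biomarkers()`), computed with the same formulas as
the image-based module.

`generate_skin_phantom()` adds the epidermal melanin band: a slab with
mean absorption `contrast` times the vessel value, multiplicative speckle
(`texture`, default ±50%), and optionally an elevated-absorption lesion
disk. The speckle matters: a perfectly uniform slab is an acoustic
pathology — its interior band-passes away and only the two boundary
sheets reconstruct — whereas real epidermal melanin is granular and
reconstructs as a filled band.

# Motion

The skin surface in each A-line is the first sample whose signal envelope
(analytic-signal magnitude) exceeds half that line's envelope maximum;
lines whose peak-to-median envelope ratio is below 6 carry no echo and are
flagged missing rather than failing. Displacement is the lag of the
cross-correlation maximum between each line's envelope and the first
acquired line's envelope, restricted to a window (default ±100 samples,
wider when large motion is expected) around the reference surface,
refined to sub-sample precision with a 3-point parabolic fit, and
converted through the one-way relation `lag * c / sample_rate`.
Correlating envelopes rather than raw signals makes the estimate
insensitive to the oscillatory fine structure of the pulses; ties between
equal correlation peaks resolve to the smallest |lag|.

Correction shifts each A-line by minus its displacement with linear
interpolation. On simulated breathing of 20–350 µm the corrected residual
is below 2.5% of the injected motion, far inside the 80%-reduction
requirement the automated checks assert. Quality grading is a pure threshold function of the
maximum absolute displacement: Q1 (≤ 70 µm, usable as-is — the level of a
held breath), Q2 (≤ 300 µm, correctable), Q3 (reject; free breathing at
350 µm is beyond correction). The 70 µm anchor is empirical; the 300 µm
Q2/Q3 split is a repository choice sitting just under the documented
350 µm failure level.

# Reconstruction

A-lines are split into 10–40 MHz (large structures) and 40–120 MHz (fine
structures) with a zero-phase 4th-order Butterworth filter; the per-line
mean is removed first so filter edge transients cannot leak a DC offset.
Beamforming is sensitivity-weighted delay-and-sum: each voxel averages,
over all scan positions within the sensitivity support, the band-passed
sample at the one-way delay (linear time interpolation), weighted by the
lateral Gaussian sensitivity; the output intensity is the envelope of the
summed image along depth. Beamforming is linear up to envelope detection
(`envelope = FALSE` exposes the signed image, and the test suite asserts
superposition on it). A simulated point source localizes to within one
voxel across the field. Dual-band composites normalize each band to its
99.9th percentile and assign low → red, high → green; MIPs are plain
per-pixel maxima along depth (coronal) or the slow axis (cross-sectional),
optionally restricted to a depth slab (the epidermal or dermal layer).

Multiwavelength volumes unmix per voxel by non-negative least squares
against a chromophore matrix (melanin, HbO2, Hb); the unconstrained
solution is accepted where it is already non-negative and refined with
NNLS elsewhere.

# Segmentation

Layer and lesion boundaries both reduce to one primitive:
`trace_boundary_dp()`, a dynamic program that finds the minimal-cost path
visiting one row per column with a vertical step bound (default 2 px).
The optimum is global for that neighbourhood — the suite checks exact
agreement with an independent Dijkstra oracle on random instances — and
ties resolve to the topmost row.

The epidermal bottom is traced per B-scan on a falling-edge cost (only
negative depth gradients attract, so the melanin band's top edge cannot),
below a superficial exclusion margin, then median-filtered across the
grid. Whether a band exists at all is decided by edge *coherence*: the
mean falling-edge strength along the traced paths divided by the 99.9th
percentile of all falling-edge values. A melanin band presents a strong
edge in every column (coherence ≈ 0.9); scattered vessels force the path
through near-zero edges (≈ 0.3). The default acceptance threshold is 0.5;
below it the function refuses and suggests the `fixed_thickness_um`
override. The detected boundary carries a systematic offset of roughly
half the axial envelope width (~25 µm in the high band), which is why
layer tests use a half-envelope tolerance rather than one voxel.

The pigmented lesion is the largest connected component above an Otsu
threshold of the epidermal MIP (rejected as "no lesion contrast" when the
between-class/total variance ratio is below 0.2), refined by running the
same DP on the falling radial edge in polar coordinates around the
component centroid (three tiled revolutions, middle one kept, so the
contour can close). The surrounding-tissue-vessel (STV) band is the set
of outside pixels within `ceiling(band_width / pixel_size)` pixels of the
lesion by Euclidean distance transform — 500 µm by default, the
extension toward healthy skin in which the biomarkers are computed.

Vessel segmentation is AngioQuant-style: background subtraction,
hysteresis thresholding, small-component removal, closing, Zhang–Suen
thinning, spur pruning, branch points as skeleton pixels with ≥ 3
skeleton neighbours (adjacent junction pixels merged), and skeleton paths
between nodes as segments with arc length AL and chord length SL.
Hysteresis levels are percentile-based by default (0.97/0.90, matching
sparse clinical images); `threshold = "halfmax"` switches to fractions of
the robust maximum, the width-faithful choice for well-resolved
structures and the default inside `run_pipeline()`.

The 3D vessel mask for TBV uses a full-width-half-maximum criterion:
blur spreads a structure approximately symmetrically about its half-peak
contour, so thresholding there recovers its volume. `run_pipeline()`
brackets the truth with two such masks — the 10–40 MHz volume renders
vessels filled but blur-broadened (an overestimate), the full 10–120 MHz
volume renders them sharp but boundary-weighted (an underestimate) — and
reports the geometric mean. On ground-truth phantoms this estimator
recovers the vessel volume fraction to within ±15% typically and ±25%
across realizations, which is also the documented validity bound: vessels
far below the band's resolvable calibre inflate under any half-maximum
rule.

# Biomarkers

* **TBV** = nonzero voxels / ROI voxels of the binary vessel volume.
* **Vessel density** = nonzero pixels of the 2D representation / ROI
  pixels; the default representation is the skeleton — the published
  density scale (~0.01–0.017) is consistent with centerline-pixel
  fractions, not mask fractions.
* **Average vessel length** = total skeleton arc length / branch-point
  count (the branch count standing in for the vessel number; an
  unbranched network divides by 1).
* **Tortuosity**: per segment the distance metric DM = AL/SL. The primary
  output is the tortuosity index mean(DM − 1), because the published
  group values (0.27, 0.47) lie below the DM lower bound of 1 — they can
  only be an excess-length index; the raw mean DM is also reported.
  `smooth_px` optionally measures on moving-average-smoothed pixel paths,
  suppressing the staircase bias of raw centerlines (a floor of ~0.05
  otherwise); chord-length filters drop fragments too short to carry
  shape. The plain (unweighted) mean is the default.
* **Fractal number**: box counting over dyadic box sides 2, 4, 8, …
  (≥ 4 scales), slope of log N(r) versus log(1/r). The 1-px scale is
  excluded: it counts pixelization, not structure, and drags the slope
  low for patterns whose natural subdivision is not dyadic (a depth-5
  Sierpinski carpet reads 1.87 versus the analytic 1.893 with this rule;
  including r = 1 gives 1.84).
* **Lacunarity** = mean(I²)/mean(I)² − 1 on the same binary image used
  for box counting; a gliding-box variant is available. For a binary
  image of fill fraction p this is exactly 1/p − 1, which the suite
  property-tests.

# Cohort statistics

`mann_whitney_u()` is exact by enumeration for pooled n ≤ 16 without
ties, otherwise a normal approximation with tie and continuity
correction (the behaviour of the commercial packages typically used for
such analyses). `roc_auc()` sweeps empirical thresholds with tied scores
grouped, so the trapezoidal area equals the midrank identity
U/(nA·nB) exactly. The combined model is an in-sample multivariate
logistic regression (IRLS; quasi-separation triggers a small ridge and a
flag) whose predicted probabilities feed the ROC — in-sample because
that is how such combined AUCs are conventionally reported for pilot
cohorts; no cross-validation is applied by default. Marker orientation
is fixed a priori: higher TBV, density, tortuosity, fractal number and
lacunarity indicate melanoma; *lower* average vessel length does.
Reported spreads are sample SDs (n − 1).

`synthetic_cohort()` deserves a precise statement of what it is: a
moment-matched stand-in for the study's per-lesion source data, which is
not redistributable. Draws are correlated normals standardized per group
and marker and rescaled so the sample means and SDs equal the published
group summaries exactly. Group-level statistics computed from it (means,
SDs) therefore reproduce the published values by construction — that
validates the reporting arithmetic, not the biology — while joint
statistics (AUCs, p-values) depend on the assumed within-group
correlation (`rho = 0.4`) and are indicative only.

# Study conditions used by the automated checks

The acceptance-level checks run on scaled-down acquisitions chosen so the
full battery completes on a single CPU in minutes while every claim is
still measured end-to-end:

* point-source localization: 20 × 20 positions at 40 µm steps, 3 × 3
  source grid;
* motion: 64 × 32 positions at 20 µm steps, breathing envelopes 20–350 µm;
* TBV recovery and density ladder: 1.2 × 0.6 mm field, vessels of 40 µm
  radius at 3% slab fraction (the calibre the low band resolves),
  reconstruction voxels 20 × 20 × 10 µm;
* curvature ladder: 2.6 × 1.6 mm field, branch-free vessels of 20 µm
  radius at 0.8% fraction with meander wavelengths 400–700 µm, measured
  on the 40–120 MHz band at 10 µm lateral voxels, several phantom
  realizations averaged per rung. Branch-free, low-density phantoms are
  the clean instrument for an ordering experiment: junctions chop
  skeleton segments to below one meander period and destroy the very
  signal being ordered.

The measured tortuosity index compresses the injected scale (skeleton
staircase floor plus blur straightening), so ladder checks assert
ordering, and absolute recovery is asserted only at the nominal
conditions (to within ±0.1).

# Known limitations

* The forward model's amplitude scale is arbitrary; all thresholds are
  relative, and no attempt is made to model fluence or attenuation.
* Motion is vertical and rigid; lateral motion is out of scope.
* Tortuosity below the acoustic resolution is invisible by construction;
  the measured index saturates and then collapses for strongly coiled
  vessels whose loops blur shut.
* The epidermal boundary carries a half-envelope systematic offset; at
  3 µm depth voxels and 120 MHz this is ~10–25 µm.
* Cohort-level AUCs computed from the synthetic stand-in are functions of
  an assumed correlation structure, not measurements of the study data.
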