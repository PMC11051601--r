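---
title: "Methods: 3D microbe tracking from inline holographic video"
author: "holotrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D microbe tracking from inline holographic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(holotrackr)
```

## The problem

Inline digital holographic microscopy (DHM) images a dilute suspension of
swimming micro-organisms with a single coherent source and a single camera.
Light scattered by each cell interferes with the unscattered reference
beam, so one 2D intensity frame encodes every cell's 3D position: the
centre of a cell's concentric ring pattern gives its lateral position, and
the extent of the rings grows with its distance from the focal plane.
holotrackr implements the full analysis chain at desk scale:

1. a synthetic hologram generator with known ground truth (`simulate_scene()`,
   `render_hologram()`);
2. median-image background normalization (`compute_median_background()`,
   `normalize_frame()`);
3. a classical localization engine — angular-spectrum back-propagation plus
   Gouy-phase axial localization (`build_stack()`, `gouy_criterion()`,
   `localize_objects()`);
4. the box-size-versus-depth heuristic and darknet-style label generation
   (`fit_heuristic()`, `make_annotations()`, `write_labels()`);
5. a fast per-frame detector with a depth proxy (`detect_reference()`,
   `z_from_box()`), corrected by a fourth-order polynomial
   (`fit_depth_correction()`, `apply_correction()`);
6. optimal-assignment track linking (`link_tracks()`) and detection metrics
   (`evaluate_detections()`).

The classical engine is precise but slow (a full back-propagation stack per
frame); the detector path is orders of magnitude cheaper per frame and is
the template for replacing the detector with a trained object-detection
network: anything that emits darknet-format boxes plugs in through
`load_detections()` unchanged.

## Optical model and conventions

All lengths are micrometres. The default `optical_config()` describes a
512 × 512 px sensor spanning 360 × 360 µm (0.703 µm/px), 642 nm vacuum
wavelength in water (n = 1.33), 30 Hz acquisition, and a 280 µm deep
chamber. Pixel (1, 1) is the top-left corner at physical (0, 0); x runs
along columns, y along rows.

Propagation between parallel planes uses the angular-spectrum
(Rayleigh–Sommerfeld) kernel

$$ H(f_x, f_y; \Delta z) \;=\; \exp\!\Big\{\, i\, 2\pi\, \Delta z\,
\big( \sqrt{(n/\lambda)^2 - f_x^2 - f_y^2} \; - \; n/\lambda \big) \Big\} $$

with evanescent components ($f_x^2+f_y^2 > (n/\lambda)^2$) set to zero.
The $-n/\lambda$ term references the phase to the plane reference wave.
This is the natural convention for *normalized* inline holograms, whose
contrast encodes the ratio of scattered to reference field: the
through-focus phase of a refocused particle is then the slowly varying
Gouy anomaly rather than a sub-micrometre optical carrier, which is what
makes axial localization from a 2 µm plane spacing possible at all.
Intensities, round trips, unitarity and beam widths are unchanged by this
global phase.

A frame is rendered as $I = |1 + \sum_j \psi_j|^2$, where $\psi_j$ is a
unit-pixel point source of amplitude $\epsilon_j \le 0.2$ (the
weak-scattering contract) placed at the cell's continuous position by the
Fourier shift theorem and propagated to the focal plane with the same
kernel the reconstruction uses. Using one kernel for both directions makes
localization a true round trip: whatever the simulator writes, the
reconstructor must read back.

## The synthetic scene generator

Motion is run-and-tumble with Brownian jitter: straight runs at `speed`
(default 20 µm/s, a typical *E. coli* run speed), tumbles at `tumble_rate`
(default 1 s⁻¹) that redraw the heading uniformly on the sphere, and
per-axis Gaussian displacements of variance $2 D \Delta t$ (default
D = 0.4 µm²/s). All boundaries reflect, keeping the per-frame cell count
constant. Defaults put 40 cells in the field of view, matching a dilute
suspension at ~2000 cells/µl.

Sensor noise is additive Gaussian with `noise_sd = 0.002` of the unit
background. The unit-pixel point source spreads its amplitude over the
whole ring pattern, so fringe contrast is a few 10⁻³ for
$\epsilon = 0.15$; at 0.002 noise the rings are clearly visible, as cells
are in well-exposed holographic video. A static multiplicative artifact
field (`make_artifact()`: smooth illumination nonuniformity plus Gaussian
blemishes) emulates dust and diffraction from optics; the median image
removes it.

What the generator does *not* emulate: Mie scattering and cell morphology
(rods, orientation), partial coherence, shot noise, camera vignetting
drift, and hydrodynamic wall interactions. Passing tests therefore
demonstrate the *algorithms* are correct and self-consistent at realistic
geometry and SNR; they do not certify performance on any particular
instrument's recordings.

An option worth noting: `motion_params(stratified_z = TRUE)` draws initial
depths stratified over equal bins of the chamber. Depth calibrations are
only trustworthy where calibration data exist, so the pipeline's
validation videos use stratified depths to guarantee coverage of the full
axial range — mirroring the practical requirement that training and
validation data span the sample chamber.

## Background normalization

The per-pixel median over a video captures everything static; dividing
each frame by it centres the background at 1 and removes fixed-pattern
artifacts. Pixels whose background falls below $10^{-6}$ of the median
level are floored before division and counted (`n_floored` attribute).
One practical caveat the tests exposed: the median only works if cells
move far compared with their ring patterns within the video. Very short
clips of slow swimmers partially absorb the cells into the background;
the pipeline's defaults (tens of frames at 30 Hz) avoid this regime.

## Classical 3D localization

`build_stack()` apodizes the contrast $I - 1$ with a 16 px cosine edge
taper (suppressing FFT wrap-around), then back-propagates it to a uniform
ladder of planes (default spacing 2 µm over the chamber). The Gouy
criterion is

$$ G(x, y, z) = -\,\partial_z\, \mathrm{Im}\,[\psi(x, y, z)] $$

computed by central finite differences (one-sided at the stack ends). The
imaginary part of the refocused field is odd through focus — the π phase
flip — so $|G|$ concentrates at the particle plane.

Numerical details that matter:

* **Lateral smoothing.** A 3 × 3 box blur stabilises the criterion against
  sensor noise, but it also suppresses the sharp central peak more than
  the broader side lobes, leaving the smoothed $|G|$ *bimodal* at about
  ±4 µm around the particle. The localizer therefore never trusts the raw
  argmax: each 26-connected voxel cluster above threshold is reduced to a
  $|G|$-weighted centroid over its half-maximum core, which sits on the
  particle plane to well under a plane spacing.
* **Threshold.** `threshold` × MAD of $|G|$ over the volume (default 8),
  minimum cluster size 4 voxels.
* **End planes.** The first and last planes are excluded from peak
  detection: the derivative there is one-sided, and at the hologram plane
  itself the imaginary part of a back-propagated real contrast is
  identically zero.
* **Ghost rejection.** The twin image and particle–particle interference
  leave faint structure roughly an order of magnitude below a genuine
  particle, whose refocused peak is nearly depth-independent. Clusters
  below `min_response_frac` (default 0.25) of the strongest cluster are
  dropped, and satellite clusters within 8 µm are merged into their
  stronger neighbour. Residual spurious localizations are transient and
  are removed downstream by minimum track length.

At the study conditions (256² frames, 2 µm spacing, default noise) the
engine recovers isolated scatterers over z ∈ [20, 250] µm with ≲1 px
lateral and ≲1 µm axial error and no measurable axial bias — this is the
"ground truth" side of every downstream comparison.

## The box-size depth heuristic

`measure_apparent_size()` renders a noiseless pattern and reports the
outermost radius at which the radial envelope of $|I-1|$ exceeds 20% of
its peak — an automated, deliberately *conservative* reading of where the
rings fade, counting only the clearly visible ones. Over the intermediate
regime (50 µm < z ≤ 200 µm) the resulting size is linear in depth to
better than 1%; nearer the focal plane and beyond 200 µm it bends away.
`fit_heuristic()` fits the line only inside the regime. With the
conservative measurement the fitted intercept at the study optics is
slightly negative, so the calibration raises it by a vertical offset until
the box at the focal plane has side `min_box` (12 px): boxes used as
detector labels are therefore modestly oversized relative to the visible
pattern everywhere.

`make_annotations()` turns localizations into square boxes of the
calibrated side, clipped at frame edges to rectangles, and writes
darknet-format label files (`class x y w h`, normalized, one file per
frame; empty files are negative controls). `z_from_box()` inverts the
line through the *longest* box edge, so edge-clipped rectangles still read
the un-truncated pattern size; results are floored at z = 0.

## The reference detector

`detect_reference()` stands in for a trained object-detection network.
For each depth in a template bank it renders the expected ring pattern
(unit amplitude, simulator kernel), windows it to a small support, and
computes normalized cross-correlation against the frame contrast by FFT.
Local maxima above `score_threshold` (0.3) become candidates; candidates
are merged across depths by greedy non-maximum suppression.

Three design points were forced by measurement rather than chosen freely:

* **Geometric template ladder.** Ring radii scale as $\sqrt{\lambda z}$,
  so the depth mismatch a correlation tolerates grows proportionally to
  z. `template_depths()` uses a constant ratio (1.15; 20 templates over
  20–260 µm). A linear 20 µm ladder loses shallow cells entirely: at
  z = 32 µm against a 40 µm template the score is already below any
  usable threshold.
* **Inner-ring support.** Correlating over the full pattern makes the
  score collapse within ±5 µm of template mismatch (the outer rings shift
  fastest). A 32 px support window keeps half-spacing mismatches above
  threshold while the score still falls off monotonically with mismatch,
  so the nearest template wins and the template index is a usable depth
  estimate.
* **Suppression on support regions.** The depth-proxy boxes of deep cells
  are hundreds of pixels wide; two genuinely distinct cells 40 µm apart
  can have box IoU > 0.45. Cross-scale merging therefore applies the IoU
  rule to the support regions (plus an 8 px centre-distance duplicate
  rule for the same cell firing at adjacent depths); `nms()` itself
  remains the standard greedy IoU operator on whatever boxes it is given.

The detector's per-frame cost is set by the template bank (a fixed number
of FFTs), independent of how many cells are present — the same property
that makes a single-pass network attractive.

**Box policy.** By default (`box_side = "pattern"`) a detection's box is a
tight fit to the matched pattern's measured apparent extent. Because the
calibration line carries the vertical offset, tight boxes read back
through `z_from_box()` systematically shallow — a smooth, depth-dependent
bias of order (offset)/(slope) ≈ 9 µm. This reproduces, mechanistically,
the situation where a detector trained on oversized labels predicts boxes
that fit the visible pattern more tightly, and it is exactly the bias the
fourth-order correction exists to remove. `box_side = "heuristic"` makes
the detector echo the label-convention box instead (no systematic bias;
useful for isolating other error sources).

## The fourth-order depth correction

`fit_depth_correction()` fits $z_{\mathrm{corr}} = \sum_{k=0}^{4} a_k
z_{\mathrm{raw}}^k$ by least squares on validation pairs only (the fit is
solved in a scaled basis $u = z/\max|z|$; the raw Vandermonde at
z ≈ 250 µm is too ill-conditioned for exact coefficient recovery). The
fit domain is stored; the pipeline evaluates the polynomial with raw
depths clamped to the domain, because a quartic extrapolates explosively,
and flags those rows. A non-monotone fit over the domain warns — depth
inversion would be ambiguous.

Validation pairs come from two independent stratified-depth videos at the
same cell density as the test video. Density matters: crowding lowers the
detectability of deep, faint patterns, so validation data at a different
density anchors the polynomial in the wrong places.

On the full simulated pipeline (10 cells, 100 frames, 512², default
noise) the corrected pooled track RMSE is roughly half the uncorrected
one, with every matched track improving; the absolute noise floor is set
by template quantization (~5 µm) rather than by the optics.

## Track linking and evaluation

`link_tracks()` matches localizations frame to frame by minimum total 3D
distance (Hungarian assignment via `clue::solve_LSAP`), gated at
`max_disp` (30 µm, about one fast swimmer step at 30 Hz), carries
unmatched tracks across gaps up to `max_gap` = 2 frames, and discards
tracks shorter than `min_length` = 5 — the step that rejects spurious,
transient detections. Assignment optimality makes the linker
order-independent and testable against brute-force enumeration.

`evaluate_detections()` implements single-class detection metrics:
greedy confidence-ordered matching at an IoU threshold, precision and
recall at a confidence operating point (and at the maximum-F1 point,
since reported tables rarely state which operating point they use), and
average precision by 101-point interpolation — the convention of the
standard detection benchmark — swept over IoU thresholds 0.50–0.95 for
mAP(0.5) and mAP(0.5:0.95). With one class, mAP equals AP; both names are
reported for comparability with standard result tables.

## Problem sizes and determinism

The package's own validation (test suite and `scripts/acceptance.R`) runs
at: 256² frames for propagation and localization checks (50 seeded
scatterers, 141-plane stacks), 512² for the end-to-end pipeline (10 cells,
60–100 test frames plus matched validation), 100-seed sweeps for the metric and
correction oracles. These sizes keep a full run in the tens of minutes on
one CPU while exercising the same geometry as the instrument. Every
random draw is seeded; `run_pipeline()` logs the configuration hash and
reruns bit-identically.

## Known limitations

* The simulator's point sources underweight near-focus contrast relative
  to real rod-shaped cells; detection below z ≈ 15 µm is poor in both
  the detector path (no template) and physically (few rings).
* The relative response filter in `localize_objects()` assumes roughly
  equal scattering amplitudes, true for a clonal population but not for
  mixed samples; set `min_response_frac = 0` and rely on track filtering
  instead.
* Crowded samples (hundreds of cells per frame) degrade the reference
  detector just as they degrade a trained network — overlapping patterns
  raise the local variance the correlation normalizes by; recall falls
  before precision does.
* mAP values compare detector boxes with label-convention boxes, which by
  design differ in size under `box_side = "pattern"`; mAP(0.5:0.95) is
  pessimistic there (the high-IoU rungs fail on size, not position).

## A worked example

```{r example, eval = FALSE}
library(holotrackr)

cfg <- pipeline_config(
  seed = 11,
  simulation = list(n_cells = 10L, n_frames = 100L,
                    n_validation_frames = 100L))
res <- run_pipeline(cfg, "holorun")

glance(res$cal)          # slope, intercept, offset of the heuristic
tidy(res$correction)     # a0..a4 of the quartic
res$rmse                 # per-track corrected vs uncorrected RMSE
glance(res$report)       # precision, recall, mAP(0.5), mAP(0.5:0.95)

autoplot(res$cal)
autoplot(res$correction)
plot_tracks(res$tracks)
```
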