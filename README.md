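# holotrackr

Three-dimensional localization and tracking of swimming micro-organisms
from inline digital holographic microscopy (DHM) video, in R.

In inline DHM a coherent source illuminates a dilute suspension of cells;
light scattered by each cell interferes with the unscattered beam, and a
single 2D intensity frame encodes every cell's 3D position. The centre of
a cell's concentric diffraction rings gives its lateral position (x, y);
the extent of the rings grows with its axial distance z from the focal
plane. Two routes recover z from a frame:

* the **classical route**: back-propagate the normalized contrast with the
  angular-spectrum (Rayleigh–Sommerfeld) kernel to a stack of planes and
  localize each cell at the sign flip of the Gouy phase anomaly, via the
  criterion G(x, y, z) = −∂z Im ψ(x, y, z) — precise, but a full
  reconstruction stack per frame;
* the **box-proxy route**: detect each ring pattern with a fast per-frame
  detector and read z from the size of its bounding box through a
  calibrated line s = m·z + c (fitted in the intermediate regime
  50 µm < z ≤ 200 µm, with a vertical offset keeping s(0) > 0), using the
  longest edge for boxes clipped at the frame border, followed by a
  fourth-order polynomial correction z_corr = Σ aₖ z_rawᵏ fitted on
  validation data only.

holotrackr implements both routes end to end, plus everything around
them: a synthetic hologram generator with run-and-tumble ground truth,
per-pixel median background normalization, darknet-format label and
detection I/O (the training-data interface for an object-detection
network), optimal-assignment track linking with transient rejection, and
single-class detection metrics (IoU, precision, recall, mAP(0.5),
mAP(0.5:0.95) with 101-point interpolation).

## A worked example

```r
library(holotrackr)

cfg <- pipeline_config(
  seed = 501,
  simulation = list(n_cells = 10L, n_frames = 100L,
                    n_validation_frames = 100L))
res <- run_pipeline(cfg, "holorun")
```

The pipeline logs each stage as it runs:

```
[simulate] 100 test + 100 validation frames, 10 cells
[preprocess] median background from 100 frames
[calibrate] size(z) = 1.559 z + 12.00 px (n = 15)
[annotate] 1000 boxes over 100 frames
[detect] 882 detections (test), 790 (validation)
[depthmap] correction fitted on 790 validation pairs, sigma 5.35 um
[track] 13 tracks; mean RMSE 7.11 um corrected / 11.53 um raw
[evaluate] precision 0.878 recall 0.774 mAP(0.5) 0.749 mAP(0.5:0.95) 0.335
```

Reading the numbers: the box-size heuristic calibrated itself at
1.56 px/µm with a 12 px box at the focal plane; detector boxes are a
tight fit to the visible rings, so raw box-derived depths carry a smooth
systematic bias that the fourth-order correction (fitted on two
stratified validation videos, residual σ ≈ 5 µm) removes — track RMSE
against the known ground truth drops from ~11.5 µm to ~7 µm
(per-track mean; pooled over track points, 10.4 µm to 6.0 µm).
Precision, recall and mAP compare detector boxes against the
label-convention ground-truth boxes at IoU 0.5.

Individual stages are ordinary functions on tibbles and matrices —
`simulate_scene()`, `render_hologram()`, `compute_median_background()`,
`normalize_frame()`, `locate_cells()`, `fit_heuristic()`,
`detect_reference()`, `add_depths()`, `fit_depth_correction()`,
`link_tracks()`, `evaluate_detections()` — with `tidy()`/`glance()`
accessors and `autoplot()`/`plot_*()` graphics for the fitted objects.
A thin command-line front end over the same functions lives at
`inst/cli/holotrackr.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "holotrackr.R", package = "holotrackr"))') \
    pipeline --config my_run.yaml --out runs/demo
```

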