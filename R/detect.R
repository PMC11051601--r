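# Pluggable per-frame detector. The reference implementation matches a bank
# of rendered ring templates (one per axial depth) against the normalized
# frame by normalized cross-correlation; anything that emits darknet-style
# boxes (e.g. a trained object-detection network) can replace it through
# load_detections().

# Wrapped 0/1 box mask of side s centred at the origin of an n-point axis.
wrapped_box_axis <- function(n, s) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance to origin
  as.numeric(d <= s / 2)
}

.template_cache <- new.env(parent = emptyenv())

#' Geometric template depth bank
#'
#' Ring patterns scale with the square root of depth, so the depth mismatch
#' a normalized cross-correlation tolerates grows proportionally to depth;
#' a geometric ladder keeps the relative mismatch to the nearest template
#' constant across the working range.
#'
#' @param z_min,z_max Working depth range, um. Defaults 20 and 260.
#' @param ratio Successive-depth ratio. Default 1.15 (about +-7% mismatch
#'   at the midpoints).
#' @return Increasing vector of template depths, um.
#' @export
template_depths <- function(z_min = 20, z_max = 260, ratio = 1.15) {
  stopifnot(z_min > 0, z_max > z_min, ratio > 1)
  k <- ceiling(log(z_max / z_min) / log(ratio))
  unique(pmin(z_min * ratio^(0:k), z_max))
}

# Apparent side length (px) of the rendered pattern at one depth, cached:
# what a detector that fits a tight box around the visible rings reports.
.apparent_side_cache <- new.env(parent = emptyenv())

apparent_box_side <- function(optics, z, frac = 0.2) {
  key <- sprintf("%d_%d_%.8g_%.8g_%.6g_%.4g", optics$frame_width,
                 optics$frame_height, optics$pixel_pitch,
                 effective_wavelength(optics), z, frac)
  hit <- .apparent_side_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- 2 * measure_apparent_size(optics, z, frac = frac)$size
  .apparent_side_cache[[key]] <- out
  out
}

# Template spectra for one depth: conj FFT of the zero-mean masked ring
# contrast, conj FFT of the mask, support size and template norm. The
# support (`side`) covers only the innermost rings: the outer rings shift
# fastest with defocus, so a small support keeps the correlation tolerant
# to the half-spacing depth mismatch between template planes while the
# score still falls off monotonically with |dz| (nearest template wins).
ring_template <- function(optics, z, side) {
  key <- sprintf("%d_%d_%.8g_%.8g_%.6g_%.6g", optics$frame_width,
                 optics$frame_height, optics$pixel_pitch,
                 effective_wavelength(optics), z, side)
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- optics$frame_width; ny <- optics$frame_height
  kern <- asm_kernel(optics, nx, ny)
  spec <- propagate_spectrum(point_source_spectrum(optics, nx, ny, 0, 0, 1),
                             z, kern)
  psi <- stats::fft(spec, inverse = TRUE) / length(spec)
  tmpl <- 2 * Re(psi)  # linearized contrast of a unit weak scatterer
  mask <- outer(wrapped_box_axis(ny, side), wrapped_box_axis(nx, side))
  npix <- sum(mask)
  tm <- tmpl * mask
  tm <- tm - mask * (sum(tm) / npix)
  out <- list(conj_ft = Conj(stats::fft(tm)),
              conj_ft_mask = Conj(stats::fft(mask)),
              npix = npix, norm = sqrt(sum(tm^2)))
  .template_cache[[key]] <- out
  out
}

# TRUE where x is a strict 8-neighbour local maximum (circular edges).
local_maxima <- function(x) {
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  ok <- matrix(TRUE, nrow(x), ncol(x))
  for (s in shifts) {
    y <- x
    if (s[1] == 1) y <- rbind(y[nrow(y), , drop = FALSE], y[-nrow(y), , drop = FALSE])
    if (s[1] == -1) y <- rbind(y[-1, , drop = FALSE], y[1, , drop = FALSE])
    if (s[2] == 1) y <- cbind(y[, ncol(y), drop = FALSE], y[, -ncol(y), drop = FALSE])
    if (s[2] == -1) y <- cbind(y[, -1, drop = FALSE], y[, 1, drop = FALSE])
    ok <- ok & (x > y)
  }
  ok
}

#' Reference ring-template detector
#'
#' For each depth in `z_templates`, the expected scattering pattern of a
#' unit-amplitude point scatterer is rendered with the simulator's own
#' kernel and cross-correlated (normalized, over the box support implied by
#' the calibration) with the frame's contrast. Local correlation maxima
#' above `score_threshold` become candidate detections whose confidence is
#' the correlation score clamped to \[0, 1\]; candidates are merged across
#' depths by non-maximum suppression. With `box_side = "pattern"` (the
#' default) the reported box is a tight fit to the matched pattern's
#' apparent extent, as an object detector trained on real patterns
#' produces; because the depth calibration line carries a vertical offset,
#' tight boxes read back through [z_from_box()] are systematically shallow
#' — the smooth bias the fourth-order depth correction is fitted to remove.
#' `box_side = "heuristic"` instead echoes [box_size_from_z()] at the
#' template depth (label-convention boxes, no systematic bias).
#'
#' Its cost is set by the template bank (FFTs per frame), not by the number
#' of cells, mirroring the constant per-frame cost of a CNN detector.
#'
#' @param frame Normalized frame (background about 1).
#' @param cal A [fit_heuristic()] calibration (box side per depth).
#' @param optics An [optical_config()].
#' @param z_templates Template depths, um; at least 2.
#'   Default [template_depths()], a geometric ladder over 20-260 um.
#' @param score_threshold Minimum correlation score. Default 0.3.
#' @param nms_iou IoU threshold for cross-scale suppression, applied to the
#'   correlation-support regions (the full depth-proxy boxes of deep cells
#'   overlap heavily even for well-separated cells). Default 0.45.
#' @param support_px Side of the square correlation support window (px),
#'   covering the innermost rings of the template. Default 32.
#' @param box_side `"pattern"` (tight box, default) or `"heuristic"`
#'   (calibration-line box at the template depth).
#' @param merge_px The same physical cell detected at neighbouring template
#'   depths produces near-coincident centres with different box sizes (low
#'   IoU); candidates whose centre lies within `merge_px` of a kept
#'   detection are suppressed as duplicates. Default 8.
#' @param frame_index Frame id attached to the detections.
#' @return Tibble of detections: `frame`, `x_center`, `y_center` (px,
#'   0-based), `width`, `height` (px), `confidence`, `z_template` (um).
#' @export
detect_reference <- function(frame, cal, optics,
                             z_templates = template_depths(),
                             score_threshold = 0.3, nms_iou = 0.45,
                             support_px = 32, merge_px = 8,
                             box_side = c("pattern", "heuristic"),
                             frame_index = 0L) {
  stopifnot(is.matrix(frame), inherits(cal, "heuristic_cal"),
            inherits(optics, "optical_config"))
  box_side <- match.arg(box_side)
  if (length(z_templates) < 2) rlang::abort("need at least 2 template depths")
  nx <- optics$frame_width; ny <- optics$frame_height
  stopifnot(nrow(frame) == ny, ncol(frame) == nx)
  ctr <- apodize(frame - mean(frame), margin = 8L)
  Fc <- stats::fft(ctr)
  Fc2 <- stats::fft(ctr^2)
  npx <- length(Fc)
  # the local-variance maps depend only on the support size, which is
  # shared by most templates: compute them once per distinct support
  raw_sides <- if (box_side == "pattern") {
    vapply(z_templates, function(z) apparent_box_side(optics, z), numeric(1))
  } else {
    box_size_from_z(cal, z_templates)
  }
  sides <- pmin(raw_sides, min(nx, ny) - 1)
  supports <- pmin(support_px, sides)
  var_cache <- new.env(parent = emptyenv())
  local_sd <- function(z, support) {
    key <- sprintf("%.6g", support)
    hit <- var_cache[[key]]
    if (!is.null(hit)) return(hit)
    tp <- ring_template(optics, z, support)
    s1 <- Re(stats::fft(Fc * tp$conj_ft_mask, inverse = TRUE)) / npx
    s2 <- Re(stats::fft(Fc2 * tp$conj_ft_mask, inverse = TRUE)) / npx
    out <- sqrt(pmax(s2 - s1^2 / tp$npix, 0))
    var_cache[[key]] <- out
    out
  }
  cands <- purrr::map(seq_along(z_templates), function(k) {
    z <- z_templates[k]
    side <- sides[k]
    tp <- ring_template(optics, z, supports[k])
    num <- Re(stats::fft(Fc * tp$conj_ft, inverse = TRUE)) / npx
    den <- local_sd(z, supports[k]) * tp$norm
    score <- num / pmax(den, 1e-12)
    peaks <- which(local_maxima(score) & score > score_threshold, arr.ind = TRUE)
    if (nrow(peaks) == 0) return(NULL)
    tibble::tibble(
      frame = as.integer(frame_index),
      x_center = peaks[, 2] - 1,
      y_center = peaks[, 1] - 1,
      width = side, height = side,
      confidence = pmin(pmax(score[peaks], 0), 1),
      z_template = z,
      support = min(support_px, side)
    )
  })
  out <- dplyr::bind_rows(cands)
  if (nrow(out) == 0) {
    return(tibble::tibble(frame = integer(), x_center = double(),
                          y_center = double(), width = double(),
                          height = double(), confidence = double(),
                          z_template = double()))
  }
  out <- merge_candidates(out, nms_iou, merge_px)
  dplyr::select(out, -"support")
}

# Cross-scale merge: greedy by confidence. Suppression is decided on the
# correlation-support regions (where the scattering pattern actually
# matched), not on the full depth-proxy boxes, whose area grows with depth
# and would swallow genuinely distinct neighbours; an additional centre
# proximity rule catches the same cell fired at two template depths.
merge_candidates <- function(detections, iou_threshold, merge_px) {
  d <- dplyr::arrange(detections, dplyr::desc(.data$confidence))
  n <- nrow(d)
  if (n <= 1) return(d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(n) > i)
    if (length(rest) == 0) break
    iou <- iou_one_many(d$x_center[i], d$y_center[i],
                        d$support[i], d$support[i],
                        d$x_center[rest], d$y_center[rest],
                        d$support[rest], d$support[rest])
    cdist <- sqrt((d$x_center[rest] - d$x_center[i])^2 +
                    (d$y_center[rest] - d$y_center[i])^2)
    alive[rest[iou > iou_threshold | cdist < merge_px]] <- FALSE
  }
  d[keep, ]
}

# IoU of one box against many (center/size parameterization, px).
iou_one_many <- function(x, y, w, h, xs, ys, ws, hs) {
  ix <- pmax(0, pmin(x + w / 2, xs + ws / 2) - pmax(x - w / 2, xs - ws / 2))
  iy <- pmax(0, pmin(y + h / 2, ys + hs / 2) - pmax(y - h / 2, ys - hs / 2))
  inter <- ix * iy
  inter / (w * h + ws * hs - inter)
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in descending confidence; any detection whose IoU
#' with an already-kept detection exceeds `iou_threshold` is removed.
#'
#' @param detections Tibble with `x_center`, `y_center`, `width`, `height`,
#'   `confidence`.
#' @param iou_threshold In (0, 1). Default 0.45.
#' @return The surviving detections, in descending confidence.
#' @export
nms <- function(detections, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  d <- dplyr::arrange(tibble::as_tibble(detections),
                      dplyr::desc(.data$confidence))
  n <- nrow(d)
  if (n <= 1) return(d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(n) > i)
    if (length(rest) == 0) break
    iou <- iou_one_many(d$x_center[i], d$y_center[i], d$width[i], d$height[i],
                        d$x_center[rest], d$y_center[rest],
                        d$width[rest], d$height[rest])
    alive[rest[iou > iou_threshold]] <- FALSE
  }
  d[keep, ]
}

#' Run the reference detector on every frame of a video
#'
#' @param frames Named list of normalized frames (names = frame indices), as
#'   produced by [render_video()] + [normalize_frame()].
#' @inheritParams detect_reference
#' @return Tibble of detections across frames.
#' @export
detect_video <- function(frames, cal, optics,
                         z_templates = template_depths(),
                         score_threshold = 0.3, nms_iou = 0.45,
                         support_px = 32, merge_px = 8,
                         box_side = c("pattern", "heuristic")) {
  box_side <- match.arg(box_side)
  ids <- as.integer(names(frames))
  dplyr::bind_rows(purrr::map2(frames, ids, function(f, i) {
    detect_reference(f, cal, optics, z_templates = z_templates,
                     score_threshold = score_threshold, nms_iou = nms_iou,
                     support_px = support_px, merge_px = merge_px,
                     box_side = box_side, frame_index = i)
  }))
}

#' Read darknet-style detection files
#'
#' Same format as [read_labels()] with an optional 6th confidence field
#' (missing confidence defaults to 1.0). Boxes are denormalized to pixel
#' units of `optics`.
#'
#' @param dir Directory of detection files.
#' @param optics An [optical_config()].
#' @param prefix File-stem prefix. Default `"frame"`.
#' @return Tibble of detections in px (`x_center`, `y_center`, `width`,
#'   `height`, `confidence`, `frame`).
#' @export
load_detections <- function(dir, optics, prefix = "frame") {
  lab <- read_labels(dir, prefix = prefix)
  if (!"confidence" %in% names(lab)) lab$confidence <- 1.0
  tibble::tibble(
    frame = lab$frame,
    x_center = lab$x_center * optics$frame_width,
    y_center = lab$y_center * optics$frame_height,
    width = lab$width * optics$frame_width,
    height = lab$height * optics$frame_height,
    confidence = lab$confidence
  )
}

#' Write detections as darknet-style files
#'
#' Boxes are clipped to the frame, normalized, and written with a 6th
#' confidence field via [write_labels()].
#'
#' @param detections Tibble of detections in px.
#' @inheritParams load_detections
#' @param frames Frame indices to emit files for (empty frames give empty
#'   files).
#' @return Invisibly, the written paths.
#' @export
write_detections <- function(detections, dir, optics, frames = NULL,
                             prefix = "frame") {
  d <- tibble::as_tibble(detections)
  W <- optics$frame_width; H <- optics$frame_height
  x1 <- pmax(d$x_center - d$width / 2, 0); x2 <- pmin(d$x_center + d$width / 2, W)
  y1 <- pmax(d$y_center - d$height / 2, 0); y2 <- pmin(d$y_center + d$height / 2, H)
  ann <- tibble::tibble(
    frame = d$frame, class_id = 0L,
    x_center = (x1 + x2) / 2 / W, y_center = (y1 + y2) / 2 / H,
    width = (x2 - x1) / W, height = (y2 - y1) / H,
    confidence = pmin(pmax(d$confidence, 0), 1)
  )
  write_labels(ann, dir, frames = frames, prefix = prefix)
}
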