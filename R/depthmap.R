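# Bounding box -> axial depth. The calibrated line is inverted through the
# longest edge of the detected box (edge-clipped boxes are rectangles; the
# longer side reflects the un-truncated pattern size), then a fourth-order
# polynomial correction, fitted on validation data, removes the systematic
# depth-dependent bias of the detector.

#' Raw depth from a bounding box (longest-edge rule)
#'
#' Inverts the heuristic: `z_raw = (max(width, height) - c) / m`, floored at
#' zero. Clipped rectangular boxes use the longest edge.
#'
#' @param cal A [fit_heuristic()] calibration.
#' @param width,height Box sides, px (vectors recycle).
#' @return Raw depth(s), um.
#' @export
z_from_box <- function(cal, width, height = width) {
  stopifnot(inherits(cal, "heuristic_cal"))
  pmax((pmax(width, height) - cal$intercept) / cal$slope, 0)
}

#' Fit a fourth-order depth correction
#'
#' Least-squares polynomial `z_corr = a0 + a1 z + a2 z^2 + a3 z^3 + a4 z^4`
#' mapping raw detector depths to reference depths, fitted on validation
#' pairs only and applied unchanged elsewhere. The fit domain is recorded;
#' applying the correction outside it is flagged as extrapolation. A
#' non-monotone fit over the domain triggers a warning (depth inversion
#' would be ambiguous).
#'
#' @param pairs Data frame with columns `z_raw` and `z_true` (um).
#' @param order Polynomial order. Default 4.
#' @return A `depth_correction` with `coefficients` (a0..a4), `domain`,
#'   `sigma`, `n`.
#' @export
fit_depth_correction <- function(pairs, order = 4L) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("z_raw", "z_true") %in% names(pairs)), order >= 1)
  n <- nrow(pairs)
  if (n < order + 1) {
    rlang::abort(sprintf("need at least %d pairs for an order-%d fit", order + 1, order))
  }
  if (n < order + 2) {
    rlang::warn("fit is an exact interpolation; residual scale is undefined")
  }
  # solve in a scaled basis u = z/s for conditioning, then rescale
  s <- max(abs(pairs$z_raw), 1)
  U <- outer(pairs$z_raw / s, 0:order, `^`)
  qr_ <- qr(U)
  if (qr_$rank < order + 1) {
    rlang::abort("rank-deficient design: z_raw values do not span the polynomial basis")
  }
  beta <- qr.coef(qr_, pairs$z_true) / s^(0:order)
  resid <- pairs$z_true - poly_eval(unname(beta), pairs$z_raw)
  dof <- n - (order + 1)
  corr <- structure(
    list(coefficients = unname(beta),
         order = as.integer(order),
         domain = range(pairs$z_raw),
         sigma = if (dof > 0) sqrt(sum(resid^2) / dof) else 0,
         n = n),
    class = "depth_correction"
  )
  if (!poly_monotone(corr)) {
    rlang::warn("fitted correction is not monotone over its domain; depth inversion is ambiguous there")
  }
  corr
}

poly_eval <- function(coef, x) {
  acc <- rep(0, length(x))
  for (k in rev(seq_along(coef))) acc <- acc * x + coef[k]
  acc
}

poly_monotone <- function(corr, n_grid = 201L) {
  g <- seq(corr$domain[1], corr$domain[2], length.out = n_grid)
  all(diff(poly_eval(corr$coefficients, g)) >= -1e-9 * max(1, diff(corr$domain)))
}

#' @export
print.depth_correction <- function(x, ...) {
  cat("<depth_correction> order", x$order, "\n")
  cat("  coefficients:", paste(format(x$coefficients, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  domain [%.4g, %.4g] um; n = %d; sigma = %.3g um\n",
              x$domain[1], x$domain[2], x$n, x$sigma))
  invisible(x)
}

#' Apply a depth correction
#'
#' Evaluates the fitted polynomial at `z_raw`, floors the result at 0, and
#' flags values whose input lay outside the fit domain (attribute
#' `extrapolated`, a logical vector).
#'
#' @param corr A [fit_depth_correction()] result.
#' @param z_raw Raw depth(s), um.
#' @return Corrected depth(s), um, with attribute `extrapolated`.
#' @export
apply_correction <- function(corr, z_raw) {
  stopifnot(inherits(corr, "depth_correction"), all(is.finite(z_raw)))
  out <- pmax(poly_eval(corr$coefficients, z_raw), 0)
  attr(out, "extrapolated") <- z_raw < corr$domain[1] | z_raw > corr$domain[2]
  out
}

#' Attach depths to detections
#'
#' Adds `z_raw` ([z_from_box()], longest edge) and, when a correction is
#' given, `z_um` plus an `extrapolated` flag; without a correction,
#' `z_um = z_raw`. A fitted polynomial is meaningless outside its domain,
#' so the correction is evaluated with the raw depth clamped to the fit
#' domain (constant extension); rows whose raw depth lay outside are
#' flagged. Lateral positions are converted to micrometres as `x_um`,
#' `y_um`. Rows are tagged `source = "box_proxy"`.
#'
#' @param detections Detector output (px).
#' @param cal A [fit_heuristic()] calibration.
#' @param correction Optional [fit_depth_correction()] result.
#' @param optics An [optical_config()].
#' @return The detections with `x_um`, `y_um`, `z_raw`, `z_um`,
#'   `extrapolated`, `source` columns added.
#' @export
add_depths <- function(detections, cal, optics, correction = NULL) {
  d <- tibble::as_tibble(detections)
  d$x_um <- d$x_center * optics$pixel_pitch
  d$y_um <- d$y_center * optics$pixel_pitch
  d$z_raw <- z_from_box(cal, d$width, d$height)
  if (is.null(correction)) {
    d$z_um <- d$z_raw
    d$extrapolated <- FALSE
  } else {
    clamped <- pmin(pmax(d$z_raw, correction$domain[1]), correction$domain[2])
    d$z_um <- as.numeric(apply_correction(correction, clamped))
    d$extrapolated <- d$z_raw < correction$domain[1] |
      d$z_raw > correction$domain[2]
  }
  d$source <- "box_proxy"
  d
}

#' Persist / load a depth correction as JSON
#'
#' @param corr A `depth_correction`.
#' @param path File path.
#' @return `write_correction` returns `path` invisibly; `read_correction`
#'   returns the `depth_correction`.
#' @export
write_correction <- function(corr, path) {
  stopifnot(inherits(corr, "depth_correction"))
  jsonlite::write_json(
    list(type = "depth_correction", order = corr$order,
         coefficients = corr$coefficients, domain = corr$domain,
         sigma = corr$sigma, n = corr$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction
#' @export
read_correction <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "depth_correction")) {
    rlang::abort(sprintf("%s is not a depth_correction document", path))
  }
  structure(list(coefficients = as.numeric(j$coefficients),
                 order = as.integer(j$order),
                 domain = as.numeric(j$domain),
                 sigma = as.numeric(j$sigma), n = as.integer(j$n)),
            class = "depth_correction")
}
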