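# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the heuristic calibration
#'
#' @param x A [fit_heuristic()] object.
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`, plus the slope's
#'   standard error).
#' @export
tidy.heuristic_cal <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se)
  )
}

#' @rdname tidy.heuristic_cal
#' @export
glance.heuristic_cal <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 offset = x$offset, sigma = x$sigma, n = x$n,
                 z_lo = x$z_range[1], z_hi = x$z_range[2])
}

#' Tidy the polynomial depth correction
#'
#' @param x A [fit_depth_correction()] object.
#' @param ... Unused.
#' @return One row per polynomial coefficient a0..a_order.
#' @export
tidy.depth_correction <- function(x, ...) {
  tibble::tibble(term = paste0("a", 0:x$order),
                 estimate = x$coefficients)
}

#' @rdname tidy.depth_correction
#' @export
glance.depth_correction <- function(x, ...) {
  tibble::tibble(order = x$order, sigma = x$sigma, n = x$n,
                 domain_lo = x$domain[1], domain_hi = x$domain[2])
}

#' One-row summary of an evaluation report
#'
#' Mirrors the columns of a standard detection results table:
#' precision, recall, mAP(0.5), mAP(0.5:0.95).
#'
#' @param x An [evaluate_detections()] report.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 map50 = x$map50, map50_95 = x$map50_95,
                 tp = x$tp, fp = x$fp, fn = x$fn, n_gt = x$n_gt)
}

#' @rdname glance.eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(iou_threshold = x$iou_thresholds, ap = x$ap)
}
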