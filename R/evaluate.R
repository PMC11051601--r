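# Detection-quality metrics for a single object class: IoU, greedy
# confidence-ordered matching, precision/recall, and average precision with
# 101-point interpolation; mAP(0.5) and mAP(0.5:0.95) in the usual
# detection-benchmark sense. With one class, mAP equals AP; both names are
# reported for comparability with standard result tables.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `(x_center, y_center, width, height)` vectors in any common
#' unit. Zero-area boxes are an error.
#'
#' @param box_a,box_b Numeric length-4 vectors.
#' @return IoU in \[0, 1\].
#' @examples
#' box_iou(c(1, 1, 2, 2), c(2, 2, 2, 2))  # corner overlap: 1/7
#' @export
box_iou <- function(box_a, box_b) {
  stopifnot(length(box_a) == 4, length(box_b) == 4)
  if (box_a[3] <= 0 || box_a[4] <= 0 || box_b[3] <= 0 || box_b[4] <= 0) {
    rlang::abort("zero-area box")
  }
  iou_one_many(box_a[1], box_a[2], box_a[3], box_a[4],
               box_b[1], box_b[2], box_b[3], box_b[4])
}

# IoU matrix between detection rows and ground-truth rows of one frame.
iou_matrix <- function(det, gt) {
  n <- nrow(det); m <- nrow(gt)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    out[i, ] <- iou_one_many(det$x_center[i], det$y_center[i],
                             det$width[i], det$height[i],
                             gt$x_center, gt$y_center, gt$width, gt$height)
  }
  out
}

#' Match detections to ground truth in one frame
#'
#' Detections are processed in descending confidence; each is matched to the
#' still-unmatched ground-truth box of highest IoU provided that IoU meets
#' `iou_threshold` (a true positive), otherwise it is a false positive. Each
#' ground truth matches at most once; unmatched ground truths are false
#' negatives.
#'
#' @param detections,ground_truth Single-frame tibbles with `x_center`,
#'   `y_center`, `width`, `height` (+ `confidence` for detections; missing
#'   confidence is taken as 1).
#' @param iou_threshold Matching threshold. Default 0.5.
#' @return List: `detections` (input rows plus `tp` logical and `iou` of the
#'   match), `n_gt`, `tp`, `fp`, `fn`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  det <- tibble::as_tibble(detections)
  gt <- tibble::as_tibble(ground_truth)
  if (!"confidence" %in% names(det)) det$confidence <- 1
  det <- dplyr::arrange(det, dplyr::desc(.data$confidence))
  n <- nrow(det); m <- nrow(gt)
  tp <- logical(n); iou_of <- rep(NA_real_, n)
  if (n > 0 && m > 0) {
    M <- iou_matrix(det, gt)
    taken <- logical(m)
    for (i in seq_len(n)) {
      free <- which(!taken)
      if (length(free) == 0) break
      j <- free[which.max(M[i, free])]
      if (M[i, j] >= iou_threshold) {
        tp[i] <- TRUE
        iou_of[i] <- M[i, j]
        taken[j] <- TRUE
      }
    }
  }
  det$tp <- tp
  det$iou <- iou_of
  list(detections = det, n_gt = m, tp = sum(tp), fp = n - sum(tp),
       fn = m - sum(tp))
}

#' Average precision with 101-point interpolation
#'
#' Sweeps the precision-recall curve over detection confidence and averages
#' the interpolated precision `max{p(r') : r' >= r}` over the 101 recall
#' points `r = 0, 0.01, ..., 1`.
#'
#' @param labeled Tibble of detections with `confidence` and `tp` columns
#'   (pooled across frames, e.g. from [match_detections()]).
#' @param n_gt Total number of ground-truth objects (> 0).
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(labeled, n_gt) {
  if (n_gt <= 0) rlang::abort("average precision undefined with zero ground truths")
  d <- dplyr::arrange(tibble::as_tibble(labeled),
                      dplyr::desc(.data$confidence))
  if (nrow(d) == 0) return(0)
  tp_cum <- cumsum(d$tp)
  fp_cum <- cumsum(!d$tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  r_grid <- (0:100) / 100
  # interpolated precision: max precision at recall >= r
  p_interp <- vapply(r_grid, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1))
  mean(p_interp)
}

#' Evaluate detections against ground truth
#'
#' Pools all frames of a dataset (matching per frame), then reports: TP/FP/FN
#' counts and precision/recall at the given confidence operating point, the
#' PR-curve-optimal operating point (maximum F1), AP at each IoU threshold,
#' and mAP(0.5) / mAP(0.5:0.95).
#'
#' @param detections Tibble of detections across frames (`frame`,
#'   `x_center`, `y_center`, `width`, `height`, `confidence`).
#' @param ground_truth Tibble of ground-truth boxes across frames (same
#'   columns, no confidence needed).
#' @param iou_thresholds IoU thresholds for the AP sweep. Default
#'   `(50 + 5 * 0:9) / 100`, i.e. 0.50 to 0.95 in steps of 0.05.
#' @param score_threshold Confidence operating point for the reported
#'   precision/recall. Default 0 (all detections).
#' @return An `eval_report` list; see [glance.eval_report()].
#' @export
evaluate_detections <- function(detections, ground_truth,
                                iou_thresholds = (50 + 5 * (0:9)) / 100,
                                score_threshold = 0) {
  det <- tibble::as_tibble(detections)
  gt <- tibble::as_tibble(ground_truth)
  if (!"confidence" %in% names(det)) det$confidence <- 1
  if (nrow(gt) == 0) rlang::abort("no ground-truth objects; metrics undefined")
  frames <- union(unique(det$frame), unique(gt$frame))
  label_at <- function(thr) {
    res <- purrr::map(frames, function(f) {
      match_detections(det[det$frame == f, , drop = FALSE],
                       gt[gt$frame == f, , drop = FALSE], thr)
    })
    dplyr::bind_rows(purrr::map(res, "detections"))
  }
  aps <- vapply(iou_thresholds, function(thr) {
    average_precision(label_at(thr), nrow(gt))
  }, numeric(1))
  lab50 <- label_at(0.5)
  at_point <- dplyr::filter(lab50, .data$confidence >= score_threshold)
  tp <- sum(at_point$tp); fp <- sum(!at_point$tp); fn <- nrow(gt) - tp
  # PR-optimal (max F1) operating point over the confidence sweep
  d <- dplyr::arrange(lab50, dplyr::desc(.data$confidence))
  tpc <- cumsum(d$tp); fpc <- cumsum(!d$tp)
  prec_sweep <- tpc / (tpc + fpc)
  rec_sweep <- tpc / nrow(gt)
  f1 <- ifelse(prec_sweep + rec_sweep > 0,
               2 * prec_sweep * rec_sweep / (prec_sweep + rec_sweep), 0)
  best <- if (length(f1) > 0) which.max(f1) else NA_integer_
  structure(
    list(
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      tp = tp, fp = fp, fn = fn, n_gt = nrow(gt),
      score_threshold = score_threshold,
      precision_best_f1 = if (!is.na(best)) prec_sweep[best] else NA_real_,
      recall_best_f1 = if (!is.na(best)) rec_sweep[best] else NA_real_,
      confidence_best_f1 = if (!is.na(best)) d$confidence[best] else NA_real_,
      iou_thresholds = iou_thresholds,
      ap = aps,
      map50 = aps[which.min(abs(iou_thresholds - 0.5))],
      map50_95 = mean(aps)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  precision %.3f  recall %.3f  (at confidence >= %.2f; TP %d FP %d FN %d)\n",
              x$precision, x$recall, x$score_threshold, x$tp, x$fp, x$fn))
  cat(sprintf("  mAP(0.5) %.3f   mAP(0.5:0.95) %.3f\n", x$map50, x$map50_95))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
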