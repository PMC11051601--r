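# IoU, matching, AP and mAP against closed forms and brute-force oracles.

bx <- function(x, y, w, h = w) c(x, y, w, h)

rand_boxes <- function(n, conf = TRUE) {
  out <- tibble::tibble(
    frame = 0L,
    x_center = runif(n, 10, 90), y_center = runif(n, 10, 90),
    width = runif(n, 5, 30), height = runif(n, 5, 30))
  if (conf) out$confidence <- round(runif(n), 4)
  out
}

test_that("IoU closed forms", {
  expect_equal(box_iou(bx(5, 5, 4), bx(5, 5, 4)), 1)
  expect_equal(box_iou(bx(0, 0, 2), bx(10, 10, 2)), 0)
  # corner boxes (0,0)-(2,2) and (1,1)-(3,3): intersection 1, union 7
  expect_equal(box_iou(bx(1, 1, 2), bx(2, 2, 2)), 1 / 7)
  expect_error(box_iou(bx(0, 0, 0), bx(1, 1, 2)), "zero-area")
})

test_that("matching trivial cases", {
  gt <- tibble::tibble(x_center = 10, y_center = 10, width = 6, height = 6)
  d1 <- dplyr::mutate(gt, confidence = 0.9)
  m <- match_detections(d1, gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  d2 <- dplyr::bind_rows(dplyr::mutate(gt, confidence = 0.9),
                         dplyr::mutate(gt, confidence = 0.8))
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_true(m2$detections$tp[1])      # the higher confidence matched
  expect_false(m2$detections$tp[2])
})

test_that("matching equals brute-force enumeration on random sets", {
  for (seed in 1:30) {
    set.seed(seed)
    det <- rand_boxes(sample(1:20, 1))
    gt <- rand_boxes(sample(1:20, 1), conf = FALSE)
    m <- match_detections(det, gt, 0.5)
    want_tp <- oracle_match(det, gt, 0.5)
    expect_equal(m$detections$tp, want_tp)
    expect_equal(m$fn, nrow(gt) - sum(want_tp))
  }
})

test_that("AP is 1 for perfect detections and 0 for none", {
  lab <- tibble::tibble(confidence = c(0.9, 0.8, 0.7), tp = TRUE)
  expect_equal(average_precision(lab, 3), 1)
  lab0 <- tibble::tibble(confidence = c(0.9, 0.8), tp = FALSE)
  expect_equal(average_precision(lab0, 5), 0)
  expect_error(average_precision(lab, 0), "zero ground truths")
})

test_that("AP equals the brute-force all-threshold computation", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    lab <- tibble::tibble(confidence = round(runif(n), 3),
                          tp = runif(n) > 0.4)
    lab <- lab[!duplicated(lab$confidence), ]
    n_gt <- sum(lab$tp) + sample(0:4, 1)
    if (n_gt == 0) next
    expect_equal(average_precision(lab, n_gt),
                 oracle_ap(lab$confidence, lab$tp, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("perfect detections give unit mAP at every threshold", {
  gt <- dplyr::mutate(rand_boxes(6, conf = FALSE), frame = rep(0:1, 3))
  det <- dplyr::mutate(gt, confidence = 0.9)
  rep_ <- evaluate_detections(det, gt)
  expect_equal(rep_$map50, 1)
  expect_equal(rep_$map50_95, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
})

test_that("IoU exactly 0.6 passes thresholds 0.50-0.60 only", {
  # 10x10 ground truth; detection shifted 2.5 in x: inter 75, union 125
  gt <- tibble::tibble(frame = 0L, x_center = 20, y_center = 20,
                       width = 10, height = 10)
  det <- tibble::tibble(frame = 0L, x_center = 22.5, y_center = 20,
                        width = 10, height = 10, confidence = 0.9)
  expect_equal(box_iou(bx(20, 20, 10), bx(22.5, 20, 10)), 0.6)
  rep_ <- evaluate_detections(det, gt)
  expect_equal(rep_$ap, c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(rep_$map50, 1)
  expect_equal(rep_$map50_95, 0.3)
})

test_that("mAP(0.5:0.95) never exceeds mAP(0.5)", {
  for (seed in 1:10) {
    set.seed(seed)
    gt <- rand_boxes(8, conf = FALSE)
    det <- dplyr::mutate(gt,
                         x_center = x_center + rnorm(8, 0, 2),
                         width = width * runif(8, 0.8, 1.2),
                         confidence = round(runif(8), 3))
    det <- dplyr::bind_rows(det, rand_boxes(3))  # extra false positives
    rep_ <- evaluate_detections(det, gt)
    expect_lte(rep_$map50_95, rep_$map50 + 1e-12)
    expect_true(all(rep_$ap >= 0 & rep_$ap <= 1))
    expect_true(all(diff(rep_$ap) <= 1e-12))  # AP non-increasing in IoU thr
  }
})

test_that("a low-confidence false positive cannot raise AP; an extra true positive cannot lower recall", {
  set.seed(8)
  gt <- rand_boxes(7, conf = FALSE)
  det <- dplyr::mutate(gt[1:5, ], confidence = round(runif(5, 0.5, 1), 3))
  base <- evaluate_detections(det, gt)
  fp <- tibble::tibble(frame = 0L, x_center = 500, y_center = 500,
                       width = 5, height = 5, confidence = 0.01)
  with_fp <- evaluate_detections(dplyr::bind_rows(det, fp), gt)
  expect_lte(with_fp$map50, base$map50 + 1e-12)
  extra_tp <- dplyr::mutate(gt[6, ], confidence = 0.6)
  with_tp <- evaluate_detections(dplyr::bind_rows(det, extra_tp), gt)
  expect_gte(with_tp$recall, base$recall)
})

test_that("single-class mAP equals AP and the report glances to one row", {
  set.seed(9)
  gt <- rand_boxes(5, conf = FALSE)
  det <- dplyr::mutate(gt, x_center = x_center + 1,
                       confidence = round(runif(5, 0.3, 1), 3))
  rep_ <- evaluate_detections(det, gt)
  expect_equal(rep_$map50, rep_$ap[1])
  g <- glance(rep_)
  expect_equal(nrow(g), 1)
  expect_named(g, c("precision", "recall", "map50", "map50_95",
                    "tp", "fp", "fn", "n_gt"))
  td <- tidy(rep_)
  expect_equal(td$iou_threshold, (50 + 5 * (0:9)) / 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$map50, rep_$map50)
})

test_that("zero ground truth errors; empty detections give zero recall", {
  gt <- rand_boxes(4, conf = FALSE)
  expect_error(evaluate_detections(rand_boxes(2), gt[0, ]), "ground-truth")
  rep_ <- evaluate_detections(rand_boxes(0), gt)
  expect_equal(rep_$recall, 0)
  expect_equal(rep_$map50, 0)
})
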