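# Reference template detector, NMS, darknet detection I/O.

make_cal <- function() {
  z <- seq(60, 190, 10)
  fit_heuristic(tibble::tibble(z = z, size = 1.3 * z + 20), offset = 0)
}

test_that("a single scatterer at a template depth is detected precisely", {
  opt <- optical_config(frame_width = 256, frame_height = 256)
  cal <- make_cal()
  z0 <- 80
  x0 <- 80; y0 <- 100
  I <- one_scatterer_frame(opt, x0, y0, z0, noise_sd = 0)
  det <- detect_reference(I, cal, opt, z_templates = seq(40, 140, 20),
                          box_side = "heuristic")
  expect_gte(nrow(det), 1)
  top <- det[1, ]
  expect_lt(abs(top$x_center * opt$pixel_pitch - x0), opt$pixel_pitch)
  expect_lt(abs(top$y_center * opt$pixel_pitch - y0), opt$pixel_pitch)
  expect_equal(top$width, box_size_from_z(cal, z0))
  expect_equal(top$z_template, z0)
  # default mode reports a tight box: the pattern's measured apparent side
  det_tight <- detect_reference(I, cal, opt, z_templates = seq(40, 140, 20))
  expect_equal(det_tight$width[1],
               2 * measure_apparent_size(opt, z0)$size)
})

test_that("a blank frame yields no detections", {
  opt <- optical_config(frame_width = 128, frame_height = 128)
  set.seed(2)
  blank <- matrix(1 + rnorm(128 * 128, 0, 0.002), 128)
  det <- detect_reference(blank, make_cal(), opt,
                          z_templates = seq(40, 120, 20))
  expect_equal(nrow(det), 0)
})

test_that("template list must have at least two depths", {
  opt <- optical_config(frame_width = 128, frame_height = 128)
  expect_error(detect_reference(matrix(1, 128, 128), make_cal(), opt,
                                z_templates = 50), "at least 2")
})

test_that("well-separated cells are each detected exactly once", {
  opt <- optical_config(frame_width = 512, frame_height = 512)
  set.seed(9)
  # jittered grid: 10 cells far apart laterally
  gx <- rep(c(70, 180, 290), times = 4)[1:10] + runif(10, -10, 10)
  gy <- rep(c(70, 180, 290, 290), each = 3)[1:10] + runif(10, -10, 10)
  zt <- runif(10, 30, 140)
  sc <- tibble::tibble(x_um = gx, y_um = gy, z_um = zt, amplitude = 0.15)
  I <- render_hologram(sc, opt, noise_sd = 0.002)
  det <- detect_reference(I, make_cal(), opt,
                          z_templates = template_depths(20, 160))
  expect_equal(nrow(det), 10)
  # one detection within 2 px of each true cell
  for (i in 1:10) {
    d <- sqrt((det$x_center * opt$pixel_pitch - gx[i])^2 +
                (det$y_center * opt$pixel_pitch - gy[i])^2)
    expect_lte(min(d), 2 * opt$pixel_pitch)
  }
})

test_that("greedy NMS keeps the confident box and drops duplicates", {
  two <- tibble::tibble(x_center = c(50, 50), y_center = c(50, 50),
                        width = 20, height = 20, confidence = c(0.9, 0.8))
  kept <- nms(two, 0.45)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
  disjoint <- tibble::tibble(x_center = c(20, 80, 140), y_center = 50,
                             width = 20, height = 20,
                             confidence = c(0.5, 0.9, 0.7))
  expect_equal(nrow(nms(disjoint, 0.45)), 3)
  expect_error(nms(two, 0), "iou_threshold")
})

test_that("NMS equals brute-force enumeration on random overlapping chains", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1)
    det <- tibble::tibble(
      x_center = runif(n, 40, 70), y_center = runif(n, 40, 70),
      width = runif(n, 15, 40), height = runif(n, 15, 40),
      confidence = round(runif(n), 3))
    det <- det[!duplicated(det$confidence), ]
    got <- nms(det, 0.45)
    want <- oracle_nms(det, 0.45)
    expect_equal(dplyr::arrange(got, confidence),
                 dplyr::arrange(tibble::as_tibble(want), confidence))
  }
})

test_that("detections round-trip through darknet files", {
  opt <- optical_config(frame_width = 256, frame_height = 256)
  dir <- withr::local_tempdir()
  det <- tibble::tibble(frame = c(0L, 0L, 1L),
                        x_center = c(50.25, 120, 200),
                        y_center = c(60.5, 130, 40),
                        width = c(40, 64, 30), height = c(40, 64, 30),
                        confidence = c(0.87, 0.5, 0.99))
  write_detections(det, dir, opt, frames = 0:1)
  back <- load_detections(dir, opt)
  expect_equal(nrow(back), 3)
  expect_equal(sort(back$confidence), sort(det$confidence), tolerance = 1e-5)
  expect_equal(sort(back$x_center), sort(det$x_center), tolerance = 2e-3)
})

test_that("labels written without confidence load as confidence 1", {
  opt <- optical_config(frame_width = 128, frame_height = 128)
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(frame = 0L, class_id = 0L, x_center = 0.5,
                        y_center = 0.5, width = 0.1, height = 0.1)
  write_labels(ann, dir)
  det <- load_detections(dir, opt)
  expect_equal(det$confidence, 1)
  expect_equal(det$x_center, 64)
})

test_that("a confidence field parses and out-of-range values are rejected", {
  opt <- optical_config(frame_width = 128, frame_height = 128)
  dir <- withr::local_tempdir()
  writeLines("0 0.5 0.5 0.1 0.1 0.87", file.path(dir, "frame_000000.txt"))
  expect_equal(load_detections(dir, opt)$confidence, 0.87)
  writeLines("0 0.5 0.5 0.1 0.1 1.2", file.path(dir, "frame_000000.txt"))
  expect_error(load_detections(dir, opt), "confidence")
})

test_that("detector cost is set by the template bank, not the cell count", {
  opt <- optical_config(frame_width = 256, frame_height = 256)
  cal <- make_cal()
  zt <- seq(30, 130, 20)
  set.seed(4)
  sparse <- render_hologram(tibble::tibble(x_um = 90, y_um = 90, z_um = 60,
                                           amplitude = 0.15), opt)
  many <- simulate_scene(motion_params(n_cells = 30, n_frames = 1, seed = 5),
                         optical_config(frame_width = 256, frame_height = 256,
                                        chamber_depth = 140))
  busy <- render_hologram(many, opt)
  # warm template cache, then take the median of repeated timings
  detect_reference(sparse, cal, opt, z_templates = zt)
  t1 <- median(vapply(1:3, function(i) {
    system.time(detect_reference(sparse, cal, opt, z_templates = zt))[["elapsed"]]
  }, numeric(1)))
  t2 <- median(vapply(1:3, function(i) {
    system.time(detect_reference(busy, cal, opt, z_templates = zt))[["elapsed"]]
  }, numeric(1)))
  expect_lt(t2 / t1, 2)
})

test_that("reference detector recall and precision on clean frames", {
  opt <- optical_config(frame_width = 256, frame_height = 256)
  cal <- make_cal()
  sim_opt <- optical_config(frame_width = 256, frame_height = 256,
                            chamber_depth = 130)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (seed in 1:3) {
    truth <- simulate_scene(motion_params(n_cells = 10, n_frames = 1,
                                          seed = seed), sim_opt)
    truth$z_um <- pmax(truth$z_um, 20)
    set.seed(seed + 100)
    I <- render_hologram(truth, opt)
    det <- detect_reference(I, cal, opt,
                            z_templates = template_depths(20, 150))
    matched <- rep(FALSE, nrow(truth))
    for (k in seq_len(nrow(det))) {
      d <- sqrt((det$x_center[k] * opt$pixel_pitch - truth$x_um)^2 +
                  (det$y_center[k] * opt$pixel_pitch - truth$y_um)^2)
      j <- which.min(ifelse(matched, Inf, d))
      if (d[j] < 5) matched[j] <- TRUE else fp <- fp + 1L
    }
    tp <- tp + sum(matched)
    fn <- fn + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.9)  # recall
  expect_gte(tp / (tp + fp), 0.9)  # precision
})
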