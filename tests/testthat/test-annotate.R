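# Heuristic calibration, annotation geometry, darknet label round trips.

test_that("noiseless in-regime pairs are recovered to machine precision", {
  z <- seq(60, 190, 10)
  pairs <- tibble::tibble(z = z, size = 1.2 * z + 15)
  cal <- fit_heuristic(pairs, offset = 0)
  expect_equal(cal$slope, 1.2, tolerance = 1e-12)
  expect_equal(cal$intercept, 15, tolerance = 1e-10)
})

test_that("pairs outside the intermediate regime never affect the fit", {
  z_in <- seq(60, 190, 10)
  inregime <- tibble::tibble(z = z_in, size = 1.2 * z_in + 15 + rnorm(length(z_in)))
  outregime <- tibble::tibble(z = c(10, 30, 50, 201, 250),
                              size = c(900, -50, 3, 0.5, 1))
  cal_a <- fit_heuristic(inregime, offset = 0)
  cal_b <- fit_heuristic(dplyr::bind_rows(outregime, inregime), offset = 0)
  expect_identical(cal_a$slope, cal_b$slope)
  expect_identical(cal_a$intercept, cal_b$intercept)
  expect_identical(cal_a$n, cal_b$n)
})

test_that("slope and errors behave like the least-squares oracle", {
  set.seed(6)
  m <- 1.6; c0 <- 15; sd_noise <- 3
  z <- runif(40, 55, 200)
  s <- m * z + c0 + rnorm(40, 0, sd_noise)
  cal <- fit_heuristic(tibble::tibble(z = z, size = s), offset = 0)
  # independent normal-equations oracle
  X <- cbind(1, z)
  beta <- solve(t(X) %*% X, t(X) %*% s)
  expect_equal(cal$slope, beta[2], tolerance = 1e-10)
  expect_lt(abs(cal$slope - m), 3 * cal$slope_se)
  # predicted sizes within 2 noise SD across the regime
  zg <- seq(60, 195, 5)
  expect_lt(max(abs(box_size_from_z(cal, zg) - (m * zg + c0))), 2 * sd_noise)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_heuristic(tibble::tibble(z = c(10, 220), size = c(5, 9))),
               ">= 2 pairs")
  z <- seq(60, 190, 10)
  expect_error(fit_heuristic(tibble::tibble(z = z, size = 300 - z)),
               "slope")
})

test_that("vertical offset guarantees a positive size at the focal plane", {
  z <- seq(60, 190, 10)
  pairs <- tibble::tibble(z = z, size = 1.5 * z - 40)  # negative raw intercept
  cal <- fit_heuristic(pairs)  # automatic offset
  expect_equal(box_size_from_z(cal, 0), 12, tolerance = 1e-9)
  cal2 <- fit_heuristic(pairs, offset = 100)
  expect_equal(cal2$intercept, 60, tolerance = 1e-9)
  # radius measurements double into side lengths
  cal3 <- fit_heuristic(dplyr::mutate(pairs, size = size / 2),
                        radius_to_side = TRUE)
  expect_equal(cal3$slope, cal$slope, tolerance = 1e-9)
})

test_that("box size is strictly increasing in depth and inverts exactly", {
  z <- seq(60, 190, 10)
  cal <- fit_heuristic(tibble::tibble(z = z, size = 1.2 * z + 15), offset = 0)
  zg <- seq(0, 280, 7)
  s <- box_size_from_z(cal, zg)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0))
  expect_equal(z_from_box(cal, s), zg, tolerance = 1e-10)
})

test_that("annotation geometry matches hand arithmetic", {
  opt <- optical_config()   # 512 x 512
  cal <- fit_heuristic(tibble::tibble(z = seq(60, 190, 10),
                                      size = seq(60, 190, 10) + 8), offset = 0)
  # size(z) = z + some intercept; pick z so the side is exactly 64
  z64 <- 64 - cal$intercept
  p <- opt$pixel_pitch
  ctr <- make_annotations(
    tibble::tibble(frame = 0L, x_um = 256 * p, y_um = 256 * p, z_um = z64),
    cal, opt)
  expect_equal(unlist(ctr[1, c("x_center", "y_center", "width", "height")]),
               c(x_center = 0.5, y_center = 0.5, width = 0.125, height = 0.125),
               tolerance = 1e-12)
  edge <- make_annotations(
    tibble::tibble(frame = 0L, x_um = 10 * p, y_um = 256 * p, z_um = z64),
    cal, opt)
  expect_equal(edge$width[1], (10 + 32) / 512, tolerance = 1e-12)
  expect_equal(edge$height[1], 0.125, tolerance = 1e-12)
  expect_warning(
    make_annotations(tibble::tibble(frame = 0L, x_um = -50, y_um = 10, z_um = 50),
                     cal, opt),
    "outside")
})

test_that("every in-view simulated cell yields exactly one annotation", {
  opt <- tiny_optics()
  truth <- simulate_scene(motion_params(n_cells = 9, n_frames = 5, seed = 12),
                          opt)
  cal <- fit_heuristic(tibble::tibble(z = seq(60, 190, 10),
                                      size = 0.5 * seq(60, 190, 10) + 8),
                       offset = 0)
  ann <- make_annotations(truth, cal, opt)
  expect_equal(nrow(ann), nrow(truth))
  counts <- dplyr::count(ann, frame)
  expect_true(all(counts$n == 9))
  expect_true(all(ann$width > 0 & ann$width <= 1))
  expect_true(all(ann$x_center >= 0 & ann$x_center <= 1))
})

test_that("labels survive a write/read round trip, including empty frames", {
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(frame = c(0L, 0L, 2L),
                        class_id = 0L,
                        x_center = c(0.5, 0.25, 0.75),
                        y_center = c(0.5, 0.5, 0.3),
                        width = c(0.125, 0.1, 0.2),
                        height = c(0.125, 0.1, 0.2))
  write_labels(ann, dir, frames = 0:2)
  expect_true(file.exists(file.path(dir, "frame_000001.txt")))
  expect_identical(readLines(file.path(dir, "frame_000001.txt")), character(0))
  back <- read_labels(dir)
  expect_equal(nrow(back), 3)
  expect_equal(back$x_center, ann$x_center, tolerance = 1e-6)
  expect_equal(back$width, ann$width, tolerance = 1e-6)
  expect_equal(attr(back, "frames"), 0:2)
})

test_that("a literal darknet line parses to a centred box", {
  dir <- withr::local_tempdir()
  writeLines("0 0.5 0.5 0.125 0.125", file.path(dir, "frame_000000.txt"))
  lab <- read_labels(dir)
  expect_equal(lab$class_id, 0L)
  expect_equal(unlist(lab[1, c("x_center", "y_center", "width", "height")]),
               c(x_center = 0.5, y_center = 0.5, width = 0.125, height = 0.125))
})

test_that("malformed label lines raise errors naming file and line", {
  dir <- withr::local_tempdir()
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5 0.1"),
             file.path(dir, "frame_000003.txt"))
  expect_error(read_labels(dir), "frame_000003.*line 2")
  writeLines("0 1.2 0.5 0.1 0.1", file.path(dir, "frame_000003.txt"))
  expect_error(read_labels(dir), "outside")
  writeLines("0 0.5 x 0.1 0.1", file.path(dir, "frame_000003.txt"))
  expect_error(read_labels(dir), "non-numeric")
})

test_that("calibration survives a JSON round trip", {
  z <- seq(60, 190, 10)
  cal <- fit_heuristic(tibble::tibble(z = z, size = 1.7 * z - 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(box_size_from_z(back, 123), box_size_from_z(cal, 123))
})

test_that("measured apparent size is near-linear in the intermediate regime", {
  opt <- optical_config(frame_width = 256, frame_height = 256,
                        chamber_depth = 170)
  pairs <- measure_apparent_size(opt, seq(60, 150, 15))
  expect_true(all(diff(pairs$size) > 0))
  fit <- stats::lm(size ~ z, data = pairs)
  expect_gt(summary(fit)$r.squared, 0.99)
})
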