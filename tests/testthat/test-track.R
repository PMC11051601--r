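# Track linking against brute-force assignment, transient rejection, RMSE.

loc_row <- function(frame, x, y = 0, z = 0) {
  tibble::tibble(frame = frame, x_um = x, y_um = y, z_um = z)
}

test_that("a stationary localization links into one full-length track", {
  loc <- loc_row(0:9, x = 50, y = 50, z = 100)
  tr <- link_tracks(loc, min_length = 5)
  expect_equal(unique(tr$track), 1L)
  expect_equal(nrow(tr), 10)
})

test_that("single-frame transients are rejected", {
  loc <- dplyr::bind_rows(loc_row(0:9, x = 50, y = 50, z = 100),
                          loc_row(4, x = 200, y = 200, z = 30))
  tr <- link_tracks(loc, min_length = 3)
  expect_equal(length(unique(tr$track)), 1)
  expect_false(any(tr$x_um == 200))
})

test_that("parallel movers never swap identities", {
  n <- 100
  a <- loc_row(0:(n - 1), x = 10 + 2 * (0:(n - 1)), y = 0, z = 50)
  b <- loc_row(0:(n - 1), x = 10 + 2 * (0:(n - 1)), y = 20, z = 50)
  tr <- link_tracks(dplyr::bind_rows(a, b), max_disp = 10, min_length = 5)
  expect_equal(length(unique(tr$track)), 2)
  by_track <- split(tr$y_um, tr$track)
  for (ys in by_track) expect_equal(length(unique(ys)), 1)
})

test_that("frame-pair linking equals the brute-force optimal assignment", {
  for (seed in 1:25) {
    set.seed(seed)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    p1 <- matrix(runif(3 * n1, 0, 100), n1)
    p2 <- matrix(runif(3 * n2, 0, 100), n2)
    loc <- dplyr::bind_rows(
      tibble::tibble(frame = 0L, x_um = p1[, 1], y_um = p1[, 2], z_um = p1[, 3]),
      tibble::tibble(frame = 1L, x_um = p2[, 1], y_um = p2[, 2], z_um = p2[, 3]))
    max_disp <- 60
    tr <- link_tracks(loc, max_disp = max_disp, max_gap = 0, min_length = 2)
    # oracle on the same cost matrix
    cost <- sqrt(outer(p1[, 1], p2[, 1], `-`)^2 +
                   outer(p1[, 2], p2[, 2], `-`)^2 +
                   outer(p1[, 3], p2[, 3], `-`)^2)
    if (n1 <= n2) {
      assign <- oracle_assign(cost, max_cost = max_disp)
      pairs_oracle <- sum(!is.na(assign))
      cost_oracle <- sum(cost[cbind(which(!is.na(assign)),
                                    assign[!is.na(assign)])])
    } else {
      assign <- oracle_assign(t(cost), max_cost = max_disp)
      pairs_oracle <- sum(!is.na(assign))
      cost_oracle <- sum(t(cost)[cbind(which(!is.na(assign)),
                                       assign[!is.na(assign)])])
    }
    # linked 2-frame tracks = matched pairs; compare count and total cost
    linked <- tr |>
      dplyr::group_by(track) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::summarise(d = sqrt(diff(x_um)^2 + diff(y_um)^2 + diff(z_um)^2))
    expect_equal(nrow(linked), pairs_oracle)
    if (pairs_oracle > 0) {
      expect_equal(sum(linked$d), cost_oracle, tolerance = 1e-9)
    }
  }
})

test_that("every localization belongs to at most one track", {
  set.seed(41)
  loc <- tibble::tibble(frame = rep(0:19, each = 4),
                        x_um = runif(80, 0, 300),
                        y_um = runif(80, 0, 300),
                        z_um = runif(80, 0, 200))
  tr <- link_tracks(loc, max_disp = 100, min_length = 1)
  expect_lte(nrow(tr), nrow(loc))
  expect_false(any(duplicated(tr[, c("frame", "x_um", "y_um", "z_um")])))
  # within a track, frames strictly increase
  ok <- tr |>
    dplyr::group_by(track) |>
    dplyr::summarise(mono = all(diff(frame) > 0))
  expect_true(all(ok$mono))
})

test_that("within-frame ordering does not change the linked tracks", {
  set.seed(13)
  base <- tibble::tibble(frame = rep(0:9, each = 3),
                         x_um = rep(c(10, 150, 290), 10) + rnorm(30, 0, 2),
                         y_um = rep(c(10, 150, 290), 10),
                         z_um = 50)
  shuffled <- base[order(base$frame, runif(30)), ]
  t1 <- link_tracks(base, min_length = 5) |>
    dplyr::arrange(track, frame)
  t2 <- link_tracks(shuffled, min_length = 5) |>
    dplyr::arrange(track, frame)
  key <- function(t) {
    t |>
      dplyr::group_by(track) |>
      dplyr::summarise(sig = paste(round(x_um, 6), round(y_um, 6),
                                   collapse = "|")) |>
      dplyr::pull(sig) |>
      sort()
  }
  expect_equal(key(t1), key(t2))
})

test_that("gap tolerance bridges missing frames; zero tolerance splits", {
  loc <- loc_row(setdiff(0:9, 4), x = 10, y = 10, z = 10)
  bridged <- link_tracks(loc, max_gap = 2, min_length = 5)
  expect_equal(length(unique(bridged$track)), 1)
  split_ <- link_tracks(loc, max_gap = 0, min_length = 4)
  expect_equal(length(unique(split_$track)), 2)
})

test_that("track RMSE matches closed forms and the direct formula", {
  a <- loc_row(0:9, x = 1:10, y = 0, z = 5)
  expect_equal(track_rmse(a, a), 0)
  b <- dplyr::mutate(a, z_um = z_um + 3)
  expect_equal(track_rmse(a, b), 3)
  set.seed(5)
  c_ <- dplyr::mutate(a, x_um = x_um + rnorm(10), y_um = y_um + rnorm(10),
                      z_um = z_um + rnorm(10))
  direct <- sqrt(mean((a$x_um - c_$x_um)^2 + (a$y_um - c_$y_um)^2 +
                        (a$z_um - c_$z_um)^2))
  expect_equal(track_rmse(a, c_), direct)
  expect_error(track_rmse(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("match_tracks pairs by maximal frame overlap", {
  ref <- dplyr::bind_rows(
    dplyr::mutate(loc_row(0:9, x = 10, y = 0, z = 0), track = 1L),
    dplyr::mutate(loc_row(0:9, x = 500, y = 0, z = 0), track = 2L))
  pred <- dplyr::mutate(loc_row(2:8, x = 10.5, y = 0, z = 0), track = 7L)
  m <- match_tracks(pred, ref)
  expect_equal(m$track_ref, 1L)
  expect_equal(m$n_common, 7L)
  expect_equal(m$rmse_um, 0.5, tolerance = 1e-9)
})

test_that("tracks survive a CSV round trip", {
  tr <- dplyr::mutate(loc_row(0:5, x = 1:6, y = 2, z = 3),
                      track = 1L, source = "box_proxy")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(back$x_um, tr$x_um)
  expect_equal(back$track, tr$track)
  expect_equal(back$source, tr$source)
})
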