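# Synthetic hologram video generator: point-like weak scatterers performing
# run-and-tumble swimming inside a bounded chamber, imaged by inline DHM.
# Every downstream stage (normalization, reconstruction, calibration,
# detection, depth mapping, tracking, evaluation) is exercised against the
# known 3D ground truth this module produces.

#' Motion and population parameters for a simulated scene
#'
#' Describes a population of point-like swimmers. Motion is run-and-tumble:
#' each cell swims at constant `speed` along its heading; tumble events
#' arrive at rate `tumble_rate` (per-frame Bernoulli with probability
#' `1 - exp(-tumble_rate * dt)`) and redraw the heading uniformly on the
#' sphere; isotropic Brownian jitter with variance `2 * diffusion * dt` per
#' axis is added each step. Boundaries (lateral field of view and the
#' chamber faces z = 0 and z = chamber_depth) are reflecting, so the
#' per-frame cell count is constant.
#'
#' Defaults emulate a dilute suspension of swimming *E. coli*:
#' 40 cells per frame, 20 um/s runs, ~1 tumble/s, D = 0.4 um^2/s.
#'
#' @param n_cells Number of cells (>= 0). Default 40.
#' @param n_frames Number of frames (>= 0). Default 100.
#' @param speed Swimming speed, um/s. Default 20.
#' @param tumble_rate Mean tumble rate, 1/s. Default 1.
#' @param diffusion Translational diffusion coefficient, um^2/s. Default 0.4.
#' @param amplitude Weak-scattering amplitude epsilon of each cell
#'   (dimensionless, must be <= 0.2 so single scattering holds). Default 0.15.
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @param stratified_z Draw the initial depths stratified over equal bins of
#'   the chamber instead of fully at random, guaranteeing that the
#'   population spans the full axial range (validation and training data
#'   must contain cells at all depths for depth calibration to be
#'   trustworthy). Default FALSE.
#' @return A `motion_params` object.
#' @export
motion_params <- function(n_cells = 40L, n_frames = 100L, speed = 20,
                          tumble_rate = 1, diffusion = 0.4,
                          amplitude = 0.15, seed = 1L,
                          stratified_z = FALSE) {
  stopifnot(n_cells >= 0, n_frames >= 0, speed >= 0, tumble_rate >= 0,
            diffusion >= 0, amplitude > 0)
  if (amplitude > 0.2) {
    rlang::abort("amplitude must be <= 0.2 (single-scattering contract)")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
         speed = speed, tumble_rate = tumble_rate, diffusion = diffusion,
         amplitude = amplitude, seed = as.integer(seed),
         stratified_z = isTRUE(stratified_z)),
    class = "motion_params"
  )
}

# Uniform random unit vectors on the sphere.
random_headings <- function(n) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(phi), s * sin(phi), u)
}

# Reflect positions into [0, hi] and report the sign flip applied to the
# matching velocity component. Handles multiple bounces.
reflect_axis <- function(p, hi) {
  flip <- rep(1, length(p))
  for (i in 1:50) {
    below <- p < 0
    above <- p > hi
    if (!any(below | above)) break
    p[below] <- -p[below]
    p[above] <- 2 * hi - p[above]
    flip[below | above] <- -flip[below | above]
  }
  list(p = p, flip = flip)
}

#' Simulate a run-and-tumble scene with known ground truth
#'
#' Generates per-frame 3D positions for `params$n_cells` cells over
#' `params$n_frames` frames. Cells start uniformly distributed in the field
#' of view and chamber depth. Returned positions are the ground-truth tracks;
#' the same tibble doubles as the per-frame scene description consumed by
#' [render_hologram()].
#'
#' @param params A [motion_params()].
#' @param optics An [optical_config()]; provides the lateral extent, chamber
#'   depth and frame rate.
#' @return A tibble with columns `frame` (0-based), `cell`, `x_um`, `y_um`,
#'   `z_um`, `amplitude`. Zero cells or zero frames give an empty tibble.
#' @examples
#' truth <- simulate_scene(motion_params(n_cells = 3, n_frames = 5), optical_config())
#' dplyr::count(truth, cell)
#' @export
simulate_scene <- function(params, optics) {
  stopifnot(inherits(params, "motion_params"), inherits(optics, "optical_config"))
  empty <- tibble::tibble(frame = integer(), cell = integer(),
                          x_um = double(), y_um = double(), z_um = double(),
                          amplitude = double())
  if (params$n_cells == 0L || params$n_frames == 0L) return(empty)

  nc <- params$n_cells
  nf <- params$n_frames
  dt <- 1 / optics$frame_rate
  lx <- (optics$frame_width - 1) * optics$pixel_pitch
  ly <- (optics$frame_height - 1) * optics$pixel_pitch
  lz <- optics$chamber_depth

  old <- .Random.seed_exists()
  set.seed(params$seed)
  on.exit(.restore_seed(old), add = TRUE)

  z0 <- if (params$stratified_z) {
    ((sample(nc) - stats::runif(nc)) / nc) * lz
  } else {
    stats::runif(nc, 0, lz)
  }
  pos <- cbind(stats::runif(nc, 0, lx), stats::runif(nc, 0, ly), z0)
  head_ <- random_headings(nc)
  p_tumble <- 1 - exp(-params$tumble_rate * dt)
  sd_bm <- sqrt(2 * params$diffusion * dt)

  out <- vector("list", nf)
  out[[1]] <- pos
  for (t in seq_len(nf - 1)) {
    tum <- stats::runif(nc) < p_tumble
    if (any(tum)) head_[tum, ] <- random_headings(sum(tum))
    step <- params$speed * dt * head_
    if (sd_bm > 0) step <- step + matrix(stats::rnorm(3 * nc, 0, sd_bm), nc)
    pos <- pos + step
    for (ax in 1:3) {
      hi <- c(lx, ly, lz)[ax]
      r <- reflect_axis(pos[, ax], hi)
      pos[, ax] <- r$p
      head_[, ax] <- head_[, ax] * r$flip
    }
    out[[t + 1]] <- pos
  }
  tibble::tibble(
    frame = rep(0:(nf - 1), each = nc),
    cell = rep(seq_len(nc), nf),
    x_um = unlist(lapply(out, function(m) m[, 1])),
    y_um = unlist(lapply(out, function(m) m[, 2])),
    z_um = unlist(lapply(out, function(m) m[, 3])),
    amplitude = params$amplitude
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Render an inline hologram of one frame
#'
#' Camera-plane intensity \eqn{I = |1 + \sum_j \psi_j|^2}, where each
#' \eqn{\psi_j} is the field of a point source of amplitude \eqn{\epsilon_j}
#' at depth \eqn{z_j}, propagated to the focal plane with the same
#' angular-spectrum kernel used for reconstruction (see [propagate()]). An
#' optional static multiplicative artifact pattern (dust, diffraction from
#' optics) is applied, then zero-mean Gaussian sensor noise is added and the
#' image is clipped at zero.
#'
#' @param scatterers Data frame with columns `x_um`, `y_um`, `z_um` and
#'   optionally `amplitude` (default 0.15): the cells present in this frame.
#'   Typically one frame's rows of [simulate_scene()] output.
#' @param optics An [optical_config()].
#' @param noise_sd Standard deviation of additive Gaussian sensor noise, in
#'   units of the unit background intensity. Default 0.002, which leaves the
#'   interference fringes of a unit-pixel point source clearly visible, as
#'   cells are in well-exposed holographic video.
#' @param artifact Optional static multiplicative pattern (matrix of frame
#'   geometry, values near 1), e.g. from [make_artifact()].
#' @return Numeric intensity matrix (`frame_height` x `frame_width`),
#'   background level 1.
#' @export
render_hologram <- function(scatterers, optics, noise_sd = 0.002,
                            artifact = NULL) {
  stopifnot(inherits(optics, "optical_config"), noise_sd >= 0)
  nx <- optics$frame_width
  ny <- optics$frame_height
  if (!is.null(artifact)) {
    stopifnot(is.matrix(artifact), nrow(artifact) == ny, ncol(artifact) == nx)
  }
  sc <- tibble::as_tibble(scatterers)
  if (nrow(sc) > 0) {
    if (!all(c("x_um", "y_um", "z_um") %in% names(sc))) {
      rlang::abort("scatterers need columns x_um, y_um, z_um")
    }
    if (!"amplitude" %in% names(sc)) sc$amplitude <- 0.15
    zmax <- max_reliable_depth(optics, min(nx, ny))
    if (any(sc$z_um > zmax)) {
      rlang::warn(sprintf(
        "%d scatterer(s) deeper than the reliably band-limited depth (%.0f um); rings may alias",
        sum(sc$z_um > zmax), zmax))
    }
  }
  kern <- asm_kernel(optics, nx, ny)
  spec <- matrix(0 + 0i, ny, nx)
  for (j in seq_len(nrow(sc))) {
    s <- point_source_spectrum(optics, nx, ny, sc$x_um[j], sc$y_um[j],
                               sc$amplitude[j])
    spec <- spec + propagate_spectrum(s, sc$z_um[j], kern)
  }
  psi <- stats::fft(spec, inverse = TRUE) / length(spec)
  I <- Mod(1 + psi)^2
  if (!is.null(artifact)) I <- I * artifact
  if (noise_sd > 0) I <- I + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
  pmax(I, 0)
}

#' Render every frame of a simulated scene
#'
#' @param truth Output of [simulate_scene()].
#' @inheritParams render_hologram
#' @param frames Optional subset of frame indices (0-based) to render.
#' @return Named list of intensity matrices, one per frame, names
#'   `"0", "1", ...`.
#' @export
render_video <- function(truth, optics, noise_sd = 0.002, artifact = NULL,
                         frames = NULL) {
  ids <- sort(unique(truth$frame))
  if (!is.null(frames)) ids <- intersect(ids, frames)
  out <- lapply(ids, function(f) {
    render_hologram(dplyr::filter(truth, .data$frame == f), optics,
                    noise_sd = noise_sd, artifact = artifact)
  })
  names(out) <- as.character(ids)
  out
}

#' Static multiplicative artifact pattern
#'
#' Emulates the fixed-pattern background of a real instrument: smooth
#' illumination nonuniformity plus a handful of Gaussian blemishes
#' ("dust on optical elements"). Identical in every frame, so per-pixel
#' median normalization removes it.
#'
#' @param optics An [optical_config()].
#' @param n_spots Number of blemishes. Default 6.
#' @param strength Peak fractional deviation from 1. Default 0.1.
#' @param seed Seed for blemish placement. Default 1.
#' @return Matrix of frame geometry with values near 1.
#' @export
make_artifact <- function(optics, n_spots = 6L, strength = 0.1, seed = 1L) {
  nx <- optics$frame_width
  ny <- optics$frame_height
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  a <- 1 + (strength / 2) * sin(2 * pi * xs / nx) * cos(2 * pi * ys / ny)
  for (i in seq_len(n_spots)) {
    cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
    sg <- stats::runif(1, 2, 8)
    amp <- stats::runif(1, -strength, strength)
    a <- a + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2))
  }
  pmax(a, 0.1)
}
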