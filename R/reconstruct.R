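# Classical DHM ground-truth engine: numerically refocus a normalized
# hologram over a stack of axial planes, then localize scatterers in 3D from
# the Gouy phase anomaly — the pi phase flip a converging wave acquires
# through focus. The axial derivative of the imaginary part of the refocused
# field changes character sharply at the particle plane, so the magnitude of
# G = -dIm[psi]/dz peaks there.

#' Back-propagate a normalized frame to a stack of axial planes
#'
#' The contrast field `frame - 1` is apodized with a cosine edge taper (to
#' suppress FFT wrap-around), Fourier transformed once, and propagated to
#' every requested plane with the angular-spectrum kernel (see
#' [propagate()]). Plane `z` refocuses scatterers that sat at axial distance
#' `z` from the focal plane.
#'
#' @param frame Normalized intensity frame (background about 1).
#' @param z_planes Strictly increasing, uniformly spaced axial positions
#'   (um), at least 3.
#' @param optics An [optical_config()].
#' @param apodize_px Cosine taper width in pixels (default 16; 0 disables).
#' @return A `recon_stack`: list with `fields` (complex array
#'   `ny x nx x n_planes`), `z_planes`, `dz`, `optics`.
#' @export
build_stack <- function(frame, z_planes, optics, apodize_px = 16L) {
  stopifnot(is.matrix(frame), inherits(optics, "optical_config"))
  z_planes <- as.numeric(z_planes)
  if (length(z_planes) < 3) rlang::abort("need at least 3 z planes")
  dzs <- diff(z_planes)
  if (any(dzs <= 0)) rlang::abort("z_planes must be strictly increasing")
  if (max(dzs) - min(dzs) > 1e-9 * max(abs(z_planes), 1)) {
    rlang::abort("z_planes must be uniformly spaced")
  }
  ny <- nrow(frame); nx <- ncol(frame)
  contrast <- apodize(frame - 1, margin = apodize_px)
  kern <- asm_kernel(optics, nx, ny)
  spec0 <- stats::fft(contrast)
  fields <- array(0 + 0i, c(ny, nx, length(z_planes)))
  npx <- length(spec0)
  for (j in seq_along(z_planes)) {
    s <- propagate_spectrum(spec0, -z_planes[j], kern)
    fields[, , j] <- stats::fft(s, inverse = TRUE) / npx
  }
  structure(list(fields = fields, z_planes = z_planes, dz = dzs[1],
                 optics = optics),
            class = "recon_stack")
}

# 3x3 box blur (edge-replicating) used to smooth the criterion laterally.
box_blur3 <- function(g) {
  n <- nrow(g); m <- ncol(g)
  s <- g + rbind(g[1, , drop = FALSE], g[-n, , drop = FALSE]) +
    rbind(g[-1, , drop = FALSE], g[n, , drop = FALSE])
  (s + cbind(s[, 1, drop = FALSE], s[, -m, drop = FALSE]) +
     cbind(s[, -1, drop = FALSE], s[, m, drop = FALSE])) / 9
}

#' Gouy-phase axial localization criterion
#'
#' Computes \eqn{G(x,y,z) = -\partial_z \,\mathrm{Im}[\psi(x,y,z)]} by
#' central finite differences along the stack (one-sided at the ends). The
#' Gouy pi-phase flip through focus concentrates `|G|` at the particle
#' plane; a 3x3 lateral box smoothing (optional) stabilises the peak against
#' sensor noise.
#'
#' @param stack A [build_stack()] result with at least 3 planes.
#' @param smooth Apply 3x3 lateral smoothing (default TRUE).
#' @return A `gouy_volume`: list with `g` (numeric array), `z_planes`, `dz`,
#'   `optics`.
#' @export
gouy_criterion <- function(stack, smooth = TRUE) {
  stopifnot(inherits(stack, "recon_stack"))
  nz <- length(stack$z_planes)
  if (nz < 3) rlang::abort("need at least 3 planes for the axial derivative")
  im <- Im(stack$fields)
  g <- array(0, dim(im))
  g[, , 2:(nz - 1)] <- -(im[, , 3:nz, drop = FALSE] -
                           im[, , 1:(nz - 2), drop = FALSE]) / (2 * stack$dz)
  g[, , 1] <- -(im[, , 2] - im[, , 1]) / stack$dz
  g[, , nz] <- -(im[, , nz] - im[, , nz - 1]) / stack$dz
  if (smooth) for (j in seq_len(nz)) g[, , j] <- box_blur3(g[, , j])
  structure(list(g = g, z_planes = stack$z_planes, dz = stack$dz,
                 optics = stack$optics),
            class = "gouy_volume")
}

# Label sparse voxels (rows of an index matrix) into 26-connected clusters.
label_voxels_26 <- function(vox) {
  k <- nrow(vox)
  if (k == 0) return(integer(0))
  dims <- apply(vox, 2, max) + 1L
  key <- (vox[, 1] + 1L) + vox[, 2] * (dims[1] + 2L) +
    vox[, 3] * (dims[1] + 2L) * (dims[2] + 2L)
  lookup <- new.env(parent = emptyenv(), size = k)
  kc <- as.character(key)
  for (i in seq_len(k)) lookup[[kc[i]]] <- i
  parent <- seq_len(k)
  find <- function(i) {          # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  off_key <- offsets[, 1] + offsets[, 2] * (dims[1] + 2L) +
    offsets[, 3] * (dims[1] + 2L) * (dims[2] + 2L)
  for (i in seq_len(k)) {
    for (ok in off_key) {
      j <- lookup[[as.character(key[i] + ok)]]
      if (!is.null(j) && j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

#' Localize scatterers in a Gouy criterion volume
#'
#' Voxels with `|G|` above `threshold` times the volume's median absolute
#' deviation are grouped by 26-connectivity; clusters smaller than
#' `min_voxels` are discarded; each surviving cluster yields a
#' `|G|`-weighted centroid, converted to micrometres.
#'
#' @param vol A [gouy_criterion()] result.
#' @param threshold Detection threshold as a multiple of `mad(|G|)`.
#'   Default 8.
#' @param min_voxels Minimum cluster size. Default 4.
#' @param merge_radius_um Weaker clusters whose centroid lies within this 3D
#'   distance of a stronger cluster are absorbed into it (side lobes of the
#'   criterion around a bright particle form small satellite clusters).
#'   Default 8.
#' @param exclude_end_planes Drop the first and last plane before peak
#'   detection: the axial derivative there is one-sided, and at a plane
#'   coinciding with the hologram itself the imaginary part of the
#'   back-propagated real contrast vanishes identically. Default TRUE.
#' @param min_response_frac Clusters whose peak `|G|` falls below this
#'   fraction of the strongest cluster's peak are dropped. Twin-image and
#'   particle-particle interference residues form faint structure roughly
#'   an order of magnitude below a genuine particle, whose refocused peak
#'   is nearly depth-independent, so a relative floor separates them
#'   cleanly. Default 0.25 (set to 0 to disable).
#' @param frame_index Frame id attached to the output rows. Default 0.
#' @return Tibble with `frame`, `x_um`, `y_um`, `z_um`, `response` (peak
#'   `|G|` in the cluster), `n_voxels`, `source = "classical"`.
#' @export
localize_objects <- function(vol, threshold = 8, min_voxels = 4L,
                             merge_radius_um = 8, exclude_end_planes = TRUE,
                             min_response_frac = 0.25, frame_index = 0L) {
  stopifnot(inherits(vol, "gouy_volume"))
  empty <- tibble::tibble(frame = integer(), x_um = double(), y_um = double(),
                          z_um = double(), response = double(),
                          n_voxels = integer(), source = character())
  a <- abs(vol$g)
  if (exclude_end_planes && dim(a)[3] > 4) {
    a[, , 1] <- 0
    a[, , dim(a)[3]] <- 0
  }
  scale <- stats::mad(a, center = stats::median(a))
  if (scale == 0) scale <- stats::median(a[a > 0])
  if (!is.finite(scale)) return(empty)
  thr <- threshold * scale
  idx <- which(a > thr)
  if (length(idx) == 0) return(empty)
  d <- dim(a)
  vox <- cbind((idx - 1L) %% d[1],
               ((idx - 1L) %/% d[1]) %% d[2],
               (idx - 1L) %/% (d[1] * d[2]))  # 0-based (row, col, plane)
  lab <- label_voxels_26(vox)
  w <- a[idx]
  pitch <- vol$optics$pixel_pitch
  groups <- split(seq_along(lab), lab)
  rows <- purrr::map(groups, function(g) {
    if (length(g) < min_voxels) return(NULL)
    wg <- w[g]
    # centroid over the half-maximum core only: the faint defocus tail of
    # |G| is asymmetric about the particle plane and would bias a
    # full-cluster centroid
    core <- wg >= 0.5 * max(wg)
    gc <- g[core]; wc <- wg[core]
    tibble::tibble(
      frame = as.integer(frame_index),
      x_um = sum(vox[gc, 2] * wc) / sum(wc) * pitch,
      y_um = sum(vox[gc, 1] * wc) / sum(wc) * pitch,
      z_um = sum(vol$z_planes[vox[gc, 3] + 1L] * wc) / sum(wc),
      response = max(wg),
      n_voxels = length(g),
      source = "classical"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, dplyr::desc(.data$response))
  if (min_response_frac > 0) {
    out <- out[out$response >= min_response_frac * max(out$response), ]
  }
  # absorb satellite clusters into the stronger cluster they sit next to
  if (merge_radius_um > 0 && nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      rest <- which(keep & seq_len(nrow(out)) > i)
      d <- sqrt((out$x_um[rest] - out$x_um[i])^2 +
                  (out$y_um[rest] - out$y_um[i])^2 +
                  (out$z_um[rest] - out$z_um[i])^2)
      keep[rest[d < merge_radius_um]] <- FALSE
    }
    out <- out[keep, ]
  }
  out
}

#' Classical 3D localization of one frame
#'
#' Convenience wrapper: [build_stack()] then [gouy_criterion()] then
#' [localize_objects()].
#'
#' @inheritParams build_stack
#' @inheritParams localize_objects
#' @param smooth Passed to [gouy_criterion()].
#' @return Tibble of localizations (see [localize_objects()]).
#' @export
locate_cells <- function(frame, optics, z_planes = NULL, threshold = 8,
                         min_voxels = 4L, merge_radius_um = 8,
                         min_response_frac = 0.25, smooth = TRUE,
                         frame_index = 0L, apodize_px = 16L) {
  if (is.null(z_planes)) z_planes <- seq(0, optics$chamber_depth, by = 2)
  stack <- build_stack(frame, z_planes, optics, apodize_px = apodize_px)
  vol <- gouy_criterion(stack, smooth = smooth)
  localize_objects(vol, threshold = threshold, min_voxels = min_voxels,
                   merge_radius_um = merge_radius_um,
                   min_response_frac = min_response_frac,
                   frame_index = frame_index)
}
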