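# Scalar diffraction engine: angular-spectrum (Rayleigh-Sommerfeld)
# propagation of complex fields between parallel planes.
#
# Convention: fields are complex matrices indexed [row = y, col = x], pixel
# (1, 1) is the top-left corner at physical position (0, 0) um; physical
# position = (index - 1) * pixel_pitch. Kernel phase is referenced to the
# plane reference wave, i.e. the optical carrier exp(i k dz) is factored out,
# so the through-focus phase of a scatterer's field is the slowly varying
# Gouy anomaly rather than a sub-micrometre carrier oscillation. This is the
# natural convention for normalized inline holograms, where the recorded
# contrast encodes the scattered-to-reference field ratio.

# FFT sample frequencies in cycles per micrometre, standard FFT ordering.
fft_freq <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# Angular-spectrum kernel pieces for a grid: axial wavenumber phase per unit
# dz (2*pi*(k_z - n/lambda)) and the propagating-frequency mask. Evanescent
# components ((n/lambda)^2 < f^2) are hard-zeroed. Cached per grid geometry.
.kernel_cache <- new.env(parent = emptyenv())

asm_kernel <- function(optics, nx, ny) {
  key <- sprintf("%d_%d_%.10g_%.10g", nx, ny, optics$pixel_pitch,
                 effective_wavelength(optics))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  inv_l <- 1 / effective_wavelength(optics)
  fx <- fft_freq(nx, optics$pixel_pitch)
  fy <- fft_freq(ny, optics$pixel_pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  prop <- f2 < inv_l^2
  kz <- sqrt(pmax(inv_l^2 - f2, 0))
  out <- list(phase = 2 * pi * (kz - inv_l), prop = prop)
  .kernel_cache[[key]] <- out
  out
}

# Multiply a spectrum (FFT of a field) by the transfer function for dz.
propagate_spectrum <- function(spectrum, dz, kern) {
  H <- exp((1i * dz) * kern$phase)
  H[!kern$prop] <- 0
  spectrum * H
}

#' Propagate a complex field between parallel planes
#'
#' Angular-spectrum (Rayleigh-Sommerfeld) propagation: the field's spatial
#' spectrum is multiplied by
#' \eqn{H(f_x,f_y;\Delta z)=\exp\{i 2\pi \Delta z (\sqrt{(n/\lambda)^2 -
#' f_x^2 - f_y^2} - n/\lambda)\}}
#' for propagating frequencies; evanescent components are set to zero. The
#' phase is referenced to the plane reference wave (the carrier
#' \eqn{e^{ik\Delta z}} is factored out), which leaves all intensities and
#' round trips unchanged and keeps the through-focus phase slowly varying.
#'
#' @param field Complex (or numeric) matrix, the field at the source plane.
#' @param dz Signed axial displacement in micrometres; positive moves away
#'   from the focal plane toward the light source.
#' @param optics An [optical_config()].
#' @return Complex matrix of the same geometry.
#' @examples
#' opt <- optical_config(frame_width = 64, frame_height = 64)
#' psi <- matrix(complex(real = rnorm(64 * 64)), 64)
#' all.equal(propagate(psi, 0, opt), psi + 0i)
#' @export
propagate <- function(field, dz, optics) {
  stopifnot(is.matrix(field), inherits(optics, "optical_config"),
            is.numeric(dz), length(dz) == 1, is.finite(dz))
  kern <- asm_kernel(optics, ncol(field), nrow(field))
  spec <- stats::fft(field)
  spec <- propagate_spectrum(spec, dz, kern)
  stats::fft(spec, inverse = TRUE) / length(spec)
}

# Spectrum of a unit-amplitude point source at continuous position
# (x_um, y_um) on its own plane: pure phase ramps (Fourier shift theorem),
# so sub-pixel positions are exact.
point_source_spectrum <- function(optics, nx, ny, x_um, y_um, amplitude = 1) {
  fx <- fft_freq(nx, optics$pixel_pitch)
  fy <- fft_freq(ny, optics$pixel_pitch)
  amplitude * outer(exp(-2i * pi * fy * y_um), exp(-2i * pi * fx * x_um))
}

#' Cosine edge taper for a frame
#'
#' Smoothly rolls the contrast of a frame off to zero over `margin` pixels at
#' each edge (raised-cosine window) to suppress periodic wrap-around
#' artifacts when the frame is propagated with FFT-based kernels. The taper
#' is applied to the deviation from `pedestal` so a uniform frame stays
#' uniform.
#'
#' @param frame Numeric matrix.
#' @param margin Taper width in pixels (default 16).
#' @param pedestal Value the edges relax to (default 0, appropriate for
#'   contrast images).
#' @return Matrix of the same size.
#' @export
apodize <- function(frame, margin = 16L, pedestal = 0) {
  stopifnot(is.matrix(frame), margin >= 0)
  if (margin == 0) return(frame)
  wfun <- function(n) {
    w <- rep(1, n)
    m <- min(margin, floor(n / 2))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
    w
  }
  win <- outer(wfun(nrow(frame)), wfun(ncol(frame)))
  pedestal + (frame - pedestal) * win
}
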