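#' Optical configuration of the holographic microscope
#'
#' Bundles the physical parameters that govern every propagation kernel and
#' every pixel-to-micrometre conversion in the pipeline. Defaults describe a
#' typical inline DHM setup for imaging swimming bacteria: a 642 nm laser
#' diode, water-immersed sample, and a 512 x 512 px sensor spanning a
#' 360 x 360 um field of view (0.703 um/px), with a sample chamber about
#' 280 um deep.
#'
#' All lengths are in micrometres. The effective wavelength inside the medium,
#' `wavelength / medium_index`, is what every diffraction kernel uses.
#'
#' @param wavelength Vacuum illumination wavelength (um). Default 0.642.
#' @param medium_index Refractive index of the suspension medium.
#'   Default 1.33 (water).
#' @param pixel_pitch Object-plane size of one pixel (um/px). Default 360/512.
#' @param frame_width,frame_height Sensor size in pixels (>= 16).
#' @param frame_rate Acquisition rate (Hz); sets the motion time step.
#' @param chamber_depth Axial extent of the sample chamber (um).
#'
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' effective_wavelength(opt)
#' @export
optical_config <- function(wavelength = 0.642,
                           medium_index = 1.33,
                           pixel_pitch = 360 / 512,
                           frame_width = 512L,
                           frame_height = 512L,
                           frame_rate = 30,
                           chamber_depth = 280) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1, wavelength > 0,
    is.numeric(medium_index), length(medium_index) == 1, medium_index >= 1,
    is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0,
    is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0,
    is.numeric(chamber_depth), length(chamber_depth) == 1, chamber_depth > 0
  )
  frame_width <- as.integer(frame_width)
  frame_height <- as.integer(frame_height)
  if (frame_width < 16L || frame_height < 16L) {
    rlang::abort("frame dimensions must be at least 16 px")
  }
  structure(
    list(
      wavelength = wavelength,
      medium_index = medium_index,
      pixel_pitch = pixel_pitch,
      frame_width = frame_width,
      frame_height = frame_height,
      frame_rate = frame_rate,
      chamber_depth = chamber_depth
    ),
    class = "optical_config"
  )
}

#' @rdname optical_config
#' @param optics An `optical_config`.
#' @export
effective_wavelength <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  optics$wavelength / optics$medium_index
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength     %.4g um (eff. %.4g um in medium, n = %.3g)\n",
              x$wavelength, effective_wavelength(x), x$medium_index))
  cat(sprintf("  frame          %d x %d px @ %.4g um/px (%.4g x %.4g um)\n",
              x$frame_width, x$frame_height, x$pixel_pitch,
              x$frame_width * x$pixel_pitch, x$frame_height * x$pixel_pitch))
  cat(sprintf("  frame rate     %.4g Hz\n", x$frame_rate))
  cat(sprintf("  chamber depth  %.4g um\n", x$chamber_depth))
  invisible(x)
}

# Deepest axial distance the discrete angular-spectrum kernel represents
# without phase aliasing on this grid (paraxial estimate N * p^2 / lambda_eff).
max_reliable_depth <- function(optics, nx = optics$frame_width) {
  nx * optics$pixel_pitch^2 / effective_wavelength(optics)
}
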