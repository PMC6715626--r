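#' Microscope and camera configuration
#'
#' Bundles the optical and camera parameters of a prism-TIRF acquisition:
#' the evanescent-field penetration depth, the point-spread-function width,
#' the pixel size, the frame interval, and an EMCCD-like noise model
#' (Poisson shot noise followed by additive Gaussian read noise; EM-gain
#' excess noise is folded into \code{read_noise_sd}).
#'
#' @param penetration_depth Evanescent field 1/e decay length in nm.
#'   Prism-TIRF at the quartz/buffer interface gives ~100 nm.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param pixel_size Camera pixel size in the sample plane, nm.
#' @param frame_interval Time between frames in seconds (0.2 s for the
#'   slower dense-core/insulin acquisitions, 0.04 s for synaptic vesicles).
#' @param em_gain Electron-multiplying gain setting (dimensionless,
#'   recorded for provenance; the excess noise it introduces is absorbed
#'   into \code{read_noise_sd}).
#' @param read_noise_sd Additive Gaussian noise SD in counts.
#' @param background_rate Mean background in counts/pixel/frame.
#'
#' @return An object of class \code{"optics_config"} (a named list).
#' @examples
#' opt <- optics_config(frame_interval = 0.04)
#' opt$penetration_depth
#' @export
optics_config <- function(penetration_depth = 100,
                          psf_sigma = 1,
                          pixel_size = 160,
                          frame_interval = 0.2,
                          em_gain = 200,
                          read_noise_sd = 10,
                          background_rate = 100) {
  if (penetration_depth <= 0) stop("penetration_depth must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(penetration_depth = penetration_depth,
                 psf_sigma = psf_sigma,
                 pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 em_gain = em_gain,
                 read_noise_sd = read_noise_sd,
                 background_rate = background_rate),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("TIRF optics configuration\n")
  cat(sprintf("  penetration depth : %g nm\n", x$penetration_depth))
  cat(sprintf("  PSF sigma         : %g px\n", x$psf_sigma))
  cat(sprintf("  pixel size        : %g nm\n", x$pixel_size))
  cat(sprintf("  frame interval    : %g s\n", x$frame_interval))
  cat(sprintf("  EM gain           : %g\n", x$em_gain))
  cat(sprintf("  read noise SD     : %g counts\n", x$read_noise_sd))
  cat(sprintf("  background        : %g counts/px/frame\n", x$background_rate))
  invisible(x)
}

#' Acquisition defaults for a vesicle preset
#'
#' Returns the \code{\link{optics_config}} conventionally used for a vesicle
#' type: 40 ms frames for synaptic vesicles, 200 ms for dense-core and
#' insulin vesicles.
#'
#' @param preset A \code{vesicle_preset} or preset name ("SV", "DCV",
#'   "INSULIN").
#' @param ... Overrides passed to \code{\link{optics_config}}.
#' @return An \code{optics_config}.
#' @export
default_optics <- function(preset = "DCV", ...) {
  name <- if (inherits(preset, "vesicle_preset")) preset$name else preset
  dots <- list(...)
  if (is.null(dots$frame_interval)) {
    dots$frame_interval <- if (identical(name, "SV")) 0.04 else 0.2
  }
  do.call(optics_config, dots)
}
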