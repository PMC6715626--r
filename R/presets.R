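#' Generative parameters for one vesicle type
#'
#' A vesicle preset collects the per-type parameters used by the simulator:
#' the radius distribution, the label chemistry (fluorescent protein cargo,
#' a self-quenched small dye such as acridine orange, or both), the
#' calcium-triggered fusion rate constant, the fusion probability of docked
#' vesicles, and the two characteristic lags of the fusion line shape
#' (pore-widening lag between small-dye efflux and protein efflux, and the
#' lag from protein efflux onset to full collapse into the planar membrane).
#'
#' @param name Preset label ("SV", "DCV", "INSULIN", or any custom string).
#' @param radius_mean Mean vesicle radius, nm.
#' @param radius_sd SD of the radius, nm (must be < \code{radius_mean}).
#' @param label_kind One of \code{"protein"}, \code{"small_dye"},
#'   \code{"dual"}.
#' @param fusion_rate_k Single-exponential fusion rate constant after
#'   calcium arrival, 1/s. \code{1/fusion_rate_k} is the characteristic
#'   fusion time constant.
#' @param fusion_probability Probability that a docked vesicle fuses, in
#'   [0, 1].
#' @param pore_widen_lag Time (s) by which small-dye efflux through the
#'   narrow initial pore precedes protein efflux.
#' @param collapse_lag Time (s) from protein-efflux onset to vesicle
#'   collapse into the planar membrane; also the time constant of the slow
#'   pore efflux of protein content.
#' @param quench_factor Residual fluorescence fraction of the self-quenched
#'   intralumenal dye, in (0, 1]. Released dye dequenches to 1.
#' @param cleft_diffusion_D Lateral diffusion coefficient of released label
#'   in the cleft between the supported membrane and the substrate,
#'   um^2/s. Not constrained by available measurements; the default (0.1)
#'   gives an ROI residence time a^2/4D of ~0.4 s for the standard 5x5 ROI,
#'   matching the ~1 s post-fusion decay of spot fluorescence.
#' @param brightness Fully dequenched, surface-proximal spot intensity in
#'   counts/frame.
#' @param dock_to_pore Dock-to-fusion-onset interval (s) used for the
#'   packaged worked example trace of this type (a typical single event,
#'   not the stochastic delay used by the samplers).
#'
#' @return An object of class \code{"vesicle_preset"}.
#' @seealso \code{\link{default_presets}}, \code{\link{get_preset}}
#' @export
vesicle_preset <- function(name,
                           radius_mean,
                           radius_sd,
                           label_kind = c("protein", "small_dye", "dual"),
                           fusion_rate_k,
                           fusion_probability = 0.9,
                           pore_widen_lag = 0.2,
                           collapse_lag = 0.6,
                           quench_factor = 0.2,
                           cleft_diffusion_D = 0.1,
                           brightness = 2000,
                           dock_to_pore = 0.25) {
  label_kind <- match.arg(label_kind)
  if (fusion_rate_k < 0) stop("fusion_rate_k must be >= 0")
  if (fusion_probability < 0 || fusion_probability > 1)
    stop("fusion_probability must lie in [0, 1]")
  if (!(radius_mean > radius_sd) || radius_sd < 0)
    stop("need radius_mean > radius_sd >= 0")
  if (pore_widen_lag < 0 || collapse_lag < 0)
    stop("lags must be >= 0")
  if (quench_factor <= 0 || quench_factor > 1)
    stop("quench_factor must lie in (0, 1]")
  if (cleft_diffusion_D <= 0) stop("cleft_diffusion_D must be > 0")
  if (brightness <= 0) stop("brightness must be > 0")
  structure(list(name = name,
                 radius_mean = radius_mean,
                 radius_sd = radius_sd,
                 label_kind = label_kind,
                 fusion_rate_k = fusion_rate_k,
                 fusion_probability = fusion_probability,
                 pore_widen_lag = pore_widen_lag,
                 collapse_lag = collapse_lag,
                 quench_factor = quench_factor,
                 cleft_diffusion_D = cleft_diffusion_D,
                 brightness = brightness,
                 dock_to_pore = dock_to_pore),
            class = "vesicle_preset")
}

#' @export
print.vesicle_preset <- function(x, ...) {
  cat(sprintf("Vesicle preset '%s' (%s label)\n", x$name, x$label_kind))
  cat(sprintf("  radius        : %g +/- %g nm\n", x$radius_mean, x$radius_sd))
  cat(sprintf("  fusion rate k : %g 1/s (tau = %g s)\n",
              x$fusion_rate_k, 1 / x$fusion_rate_k))
  cat(sprintf("  P(fuse)       : %g\n", x$fusion_probability))
  cat(sprintf("  pore-widen lag: %g s, collapse lag: %g s\n",
              x$pore_widen_lag, x$collapse_lag))
  invisible(x)
}

#' Packaged vesicle-type presets
#'
#' The three secretory-vesicle types studied with the supported-membrane
#' assay, with their characteristic calcium-triggered fusion time constants:
#' synaptic vesicles (SV, tau = 0.23 s, acridine-orange-like small-dye
#' label, 40 ms frames), dense-core vesicles (DCV, tau = 3.3 s, dual
#' NPY-protein + small-dye label), and insulin vesicles (INSULIN,
#' tau = 9.1 s, protein label). Radii follow conventional literature scales
#' for the three organelles (SV ~40 nm, DCV ~100 nm, insulin granule
#' ~240 nm diameter); only their ordering is load-bearing downstream.
#'
#' @return Named list of \code{\link{vesicle_preset}} objects.
#' @examples
#' default_presets()$SV
#' @export
default_presets <- function() {
  list(
    SV = vesicle_preset("SV", radius_mean = 20, radius_sd = 2.5,
                        label_kind = "small_dye",
                        fusion_rate_k = 1 / 0.23,
                        dock_to_pore = 0.25),
    DCV = vesicle_preset("DCV", radius_mean = 50, radius_sd = 8,
                         label_kind = "dual",
                         fusion_rate_k = 1 / 3.3,
                         pore_widen_lag = 0.2, collapse_lag = 0.6),
    INSULIN = vesicle_preset("INSULIN", radius_mean = 120, radius_sd = 15,
                             label_kind = "protein",
                             fusion_rate_k = 1 / 9.1,
                             pore_widen_lag = 0.2, collapse_lag = 0.6)
  )
}

#' Fetch a packaged preset by name
#'
#' @param name "SV", "DCV" or "INSULIN" (case-insensitive).
#' @return A \code{\link{vesicle_preset}}.
#' @export
get_preset <- function(name) {
  p <- default_presets()
  key <- toupper(name)
  if (!key %in% names(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  p[[key]]
}
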