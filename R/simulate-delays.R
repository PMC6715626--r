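#' Sample calcium-to-fusion delay times
#'
#' Draws per-vesicle fusion outcomes for a population of docked vesicles
#' after calcium arrival: each vesicle fuses independently with probability
#' \code{p_fuse}, and fused vesicles draw their delay from an exponential
#' distribution with rate \code{k} (time constant \code{1/k}).
#'
#' @param k Fusion rate constant, 1/s (>= 0).
#' @param p_fuse Fusion probability in [0, 1].
#' @param n Number of docked vesicles (>= 1).
#' @param seed Integer seed; identical inputs and seed reproduce the draw.
#' @return A data.frame with columns \code{fused} (logical) and
#'   \code{delay} (s; \code{NA} for non-fused vesicles).
#' @examples
#' d <- sample_delay_times(k = 1 / 0.23, p_fuse = 1, n = 100, seed = 1)
#' mean(d$delay)
#' @export
sample_delay_times <- function(k, p_fuse, n, seed = 1L) {
  if (k < 0) stop("k must be >= 0")
  if (p_fuse < 0 || p_fuse > 1) stop("p_fuse must lie in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  fused <- stats::runif(n) < p_fuse
  delay <- rep(NA_real_, n)
  if (any(fused)) {
    if (k == 0) {
      # zero rate: fusion never happens in finite time
      fused[] <- FALSE
    } else {
      delay[fused] <- stats::rexp(sum(fused), rate = k)
    }
  }
  data.frame(fused = fused, delay = delay)
}

#' Sample vesicle diameters
#'
#' Truncated-normal (> 0) diameter draws emulating cryo-EM size
#' distributions, with mean \code{2 * radius_mean} and SD
#' \code{2 * radius_sd} of the preset.
#'
#' @param preset A \code{\link{vesicle_preset}}.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of diameters in nm (all > 0).
#' @examples
#' d <- sample_diameters(get_preset("SV"), n = 1000, seed = 1)
#' mean(d) # ~ 40 nm
#' @export
sample_diameters <- function(preset, n, seed = 1L) {
  stopifnot(inherits(preset, "vesicle_preset"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  mu <- 2 * preset$radius_mean
  sdv <- 2 * preset$radius_sd
  if (sdv == 0) return(rep(mu, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), mean = mu, sd = sdv)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}
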