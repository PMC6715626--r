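#' Empirical cumulative distribution of fusion delays
#'
#' Right-continuous ECDF of the delay times, exported as paired arrays for
#' plotting against fitted kinetic curves.
#'
#' @param delays Nonempty numeric vector of delays (s), all >= 0.
#' @return List with \code{times} (sorted delays), \code{fraction}
#'   (cumulative fraction at each time), and \code{fn} (the
#'   \code{stats::ecdf} step function).
#' @export
empirical_cdf <- function(delays) {
  if (length(delays) == 0) stop("delays must be nonempty")
  if (any(delays < 0)) stop("delays must be >= 0")
  s <- sort(delays)
  list(times = s, fraction = seq_along(s) / length(s),
       fn = stats::ecdf(delays))
}

.new_kinetic_fit <- function(model, rate_k, n_steps, n_obs, censored_n,
                             loglik, boot_k = NULL, conf = 0.95) {
  ci <- c(NA_real_, NA_real_)
  if (!is.null(boot_k) && length(boot_k) > 0) {
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_k, c(alpha, 1 - alpha),
                                 na.rm = TRUE))
  }
  structure(list(model = model, rate_k = rate_k, tau = 1 / rate_k,
                 n_steps = n_steps, ci_low = ci[1], ci_high = ci[2],
                 n_obs = n_obs, censored_n = censored_n,
                 loglik = loglik, aic = -2 * loglik + 2,
                 boot_k = boot_k),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit: k = %.4g 1/s (tau = %.4g s)", x$model, x$rate_k,
              x$tau))
  if (x$model == "n_step_gamma") cat(sprintf(", n_steps = %d", x$n_steps))
  if (!is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.4g, %.4g] 1/s", x$ci_low, x$ci_high))
  cat(sprintf("\n  n = %d events", x$n_obs))
  if (x$censored_n > 0) cat(sprintf(" + %d right-censored", x$censored_n))
  cat(sprintf(", logLik = %.2f, AIC = %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Fit a single-exponential fusion rate to delay times
#'
#' Maximum-likelihood single-rate fit of calcium-to-fusion delay times,
#' optionally with right-censored observations (docked vesicles that had
#' not fused when the recording ended). The MLE is
#' \code{k = n_events / (sum(delays) + sum(censored))}; the uncertainty is
#' a percentile bootstrap over the (delay, censored) records.
#'
#' @param delays Uncensored delay times, s (>= 1 value; a warning is
#'   issued below 5).
#' @param censored Censoring times of never-fusing docked vesicles, s
#'   (may be empty).
#' @param n_boot Number of bootstrap resamples (0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A \code{kinetic_fit} (model \code{"single_exponential"}).
#' @examples
#' fit_single_exponential(c(2, 2, 2), n_boot = 0)$tau  # exactly 2
#' @export
fit_single_exponential <- function(delays, censored = numeric(0),
                                   n_boot = 1000L, seed = 1L,
                                   conf = 0.95) {
  delays <- as.numeric(delays)
  if (length(delays) < 1) stop("need at least one uncensored delay")
  if (length(delays) < 5)
    warning("fewer than 5 delays: rate estimate will be unstable")
  if (any(delays < 0) || any(censored < 0))
    stop("delays and censoring times must be >= 0")
  total <- sum(delays) + sum(censored)
  if (total <= 0) stop("degenerate fit: all delays are zero")
  n <- length(delays)
  k <- n / total
  loglik <- n * log(k) - k * total
  boot_k <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    tt <- c(delays, censored)
    is_event <- c(rep(TRUE, n), rep(FALSE, length(censored)))
    m <- length(tt)
    boot_k <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      ne <- sum(is_event[idx])
      if (ne == 0) return(NA_real_)
      ne / sum(tt[idx])
    }, numeric(1))
    boot_k <- boot_k[!is.na(boot_k)]
  }
  .new_kinetic_fit("single_exponential", k, 1L, n, length(censored),
                   loglik, boot_k, conf)
}

# gamma log-likelihood at the rate MLE for a fixed integer shape
.gamma_profile <- function(delays, shape) {
  rate <- shape / mean(delays)
  list(rate = rate,
       loglik = sum(stats::dgamma(delays, shape = shape, rate = rate,
                                  log = TRUE)))
}

#' Fit sequential-step (gamma) fusion kinetics
#'
#' Fits the delay distribution as the completion time of \code{n_steps}
#' sequential first-order transitions, i.e. a gamma distribution with
#' integer shape \code{n_steps} and a single free rate. Sigmoidal
#' cumulative distributions (as seen for incompletely primed insulin
#' vesicles) indicate hidden priming steps, \code{n_steps > 1};
#' \code{n_steps = 1} is exactly the single-exponential model. In
#' \code{"auto"} mode the step count is chosen among 1..5 by AIC.
#'
#' @param delays Delay times, s (>= 10 values, all > 0 for multi-step
#'   fits).
#' @param n_steps Integer step count, or \code{"auto"}.
#' @param n_boot Bootstrap resamples for the rate CI (0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return A \code{kinetic_fit} (model \code{"n_step_gamma"}) with the
#'   per-candidate AIC table in \code{$aic_table} when \code{"auto"}.
#' @export
fit_sequential_steps <- function(delays, n_steps = "auto", n_boot = 0L,
                                 seed = 1L) {
  delays <- as.numeric(delays)
  if (length(delays) < 10) stop("need >= 10 delays for a step fit")
  if (any(delays < 0)) stop("delays must be >= 0")
  if (mean(delays) <= 0) stop("degenerate fit: all delays are zero")
  candidates <- if (identical(n_steps, "auto")) 1:5 else as.integer(n_steps)
  if (any(candidates < 1)) stop("n_steps must be >= 1")
  prof <- lapply(candidates, function(m) {
    if (m > 1 && any(delays == 0))
      return(list(rate = NA_real_, loglik = -Inf))
    .gamma_profile(delays, m)
  })
  ll <- vapply(prof, `[[`, numeric(1), "loglik")
  if (all(!is.finite(ll))) stop("fit error: no candidate model converged")
  aic <- -2 * ll + 2
  best <- which.min(aic)
  m <- candidates[best]
  rate <- prof[[best]]$rate
  boot_k <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    nd <- length(delays)
    boot_k <- vapply(seq_len(n_boot), function(b) {
      m / mean(delays[sample.int(nd, nd, replace = TRUE)])
    }, numeric(1))
  }
  fit <- .new_kinetic_fit("n_step_gamma", rate, m, length(delays), 0L,
                          ll[best], boot_k)
  fit$aic <- aic[best]
  fit$aic_table <- data.frame(n_steps = candidates, loglik = ll, aic = aic)
  fit
}

#' Mean curvature from a diameter sample
#'
#' Reduces a vesicle diameter distribution (e.g. cryo-EM measurements) to
#' the mean curvature 1/R used as the abscissa of the curvature-rate
#' relation. The default is the reciprocal of the mean radius,
#' \code{1/mean(diameters/2)}; \code{method = "mean_inverse_radius"} gives
#' \code{mean(2/diameters)} instead.
#'
#' @param diameters Diameters in nm, all > 0.
#' @param method \code{"inverse_mean_radius"} (default) or
#'   \code{"mean_inverse_radius"}.
#' @return Curvature in 1/nm, with the method recorded as an attribute.
#' @examples
#' mean_curvature(c(40, 40)) # 0.05
#' @export
mean_curvature <- function(diameters,
                           method = c("inverse_mean_radius",
                                      "mean_inverse_radius")) {
  method <- match.arg(method)
  if (length(diameters) == 0 || any(diameters <= 0))
    stop("diameters must be positive")
  r <- diameters / 2
  out <- if (method == "inverse_mean_radius") 1 / mean(r) else mean(1 / r)
  attr(out, "method") <- method
  out
}

#' Fit the curvature-activation-energy relation
#'
#' Under an Arrhenius picture in which the fusion activation energy is
#' linear in membrane curvature, the rate constants of different vesicle
#' types obey \code{ln k = a + b * (1/R)}. Fits that line by least squares
#' through the (curvature, ln rate) points.
#'
#' @param points data.frame with columns \code{curvature} (1/nm) and
#'   \code{rate_k} (1/s, > 0); >= 2 distinct curvatures required.
#' @return A \code{curvature_fit}: list with \code{intercept_a},
#'   \code{slope_b}, \code{points}, \code{predict(curvature)} returning
#'   the fitted k, and the underlying \code{lm} object.
#' @examples
#' pts <- data.frame(curvature = c(0.1, 0.2, 0.3),
#'                   rate_k = exp(1 + 10 * c(0.1, 0.2, 0.3)))
#' fit_curvature_model(pts)$slope_b  # 10
#' @export
fit_curvature_model <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("curvature", "rate_k") %in% names(points)))
  if (any(points$rate_k <= 0)) stop("rates must be > 0")
  if (length(unique(points$curvature)) < 2)
    stop("need >= 2 distinct curvatures")
  fit <- stats::lm(log(rate_k) ~ curvature, data = points)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  structure(list(intercept_a = a, slope_b = b, points = points,
                 predict = function(curvature) exp(a + b * curvature),
                 lm = fit),
            class = "curvature_fit")
}

#' @export
print.curvature_fit <- function(x, ...) {
  cat(sprintf(
    "curvature fit: ln k = %.4g + %.4g * (1/R)  [%d vesicle types]\n",
    x$intercept_a, x$slope_b, nrow(x$points)))
  invisible(x)
}

#' Compare fitted fusion rates across conditions
#'
#' Pairwise rate ratios between conditions with bootstrap ratio intervals
#' (propagated from each fit's bootstrap sample by elementwise pairing of
#' independent resamples).
#'
#' @param fits Named list of \code{kinetic_fit}s (>= 2).
#' @param conf Confidence level for the ratio intervals.
#' @return data.frame with one row per ordered pair: \code{numerator},
#'   \code{denominator}, \code{ratio}, \code{ci_low}, \code{ci_high}.
#' @export
compare_conditions <- function(fits, conf = 0.95) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "kinetic_fit")))
  if (is.null(names(fits)))
    names(fits) <- paste0("condition", seq_along(fits))
  alpha <- (1 - conf) / 2
  combs <- utils::combn(names(fits), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    f1 <- fits[[combs[1, j]]]; f2 <- fits[[combs[2, j]]]
    ci <- c(NA_real_, NA_real_)
    if (!is.null(f1$boot_k) && !is.null(f2$boot_k)) {
      nb <- min(length(f1$boot_k), length(f2$boot_k))
      rr <- f1$boot_k[seq_len(nb)] / f2$boot_k[seq_len(nb)]
      ci <- unname(stats::quantile(rr, c(alpha, 1 - alpha)))
    }
    data.frame(numerator = combs[1, j], denominator = combs[2, j],
               ratio = f1$rate_k / f2$rate_k,
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, rows)
}
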