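#' Simulate the calcium-indicator (perfusion) channel
#'
#' Generates the spatially uniform soluble-dye channel used to time the
#' arrival of the calcium-containing buffer at the imaging site: zero
#' before \code{t_start}, a monotone linear rise over \code{ramp_duration},
#' and a saturated plateau after. \code{ramp_duration = 0} gives a step.
#'
#' @param optics An \code{\link{optics_config}}.
#' @param t_start Time perfusion commences, s.
#' @param ramp_duration True commencement-to-saturation spread
#'   (Delta-t-Ca), s (>= 0).
#' @param duration Movie length, s (must cover the ramp).
#' @param noise_sd Per-pixel Gaussian noise SD, counts.
#' @param amplitude Plateau amplitude, counts.
#' @param seed Integer seed for the noise.
#' @param width,height Frame size in pixels.
#' @return List with \code{stack} (an \code{image_stack}, channel
#'   \code{"calcium_indicator"}), and the true arrival parameters
#'   \code{t_start}, \code{ramp_duration} (= true Delta-t-Ca), and
#'   \code{t_arrival} (midpoint of the rise, the reference time for fusion
#'   delays).
#' @export
simulate_calcium_arrival <- function(optics, t_start = 2,
                                     ramp_duration = 0.4,
                                     duration = 6,
                                     noise_sd = 5,
                                     amplitude = 1000,
                                     seed = 1L,
                                     width = 16, height = 16) {
  if (ramp_duration < 0 || duration < 0) stop("durations must be >= 0")
  if (t_start + ramp_duration > duration)
    stop("duration must cover t_start + ramp_duration")
  times <- seq(0, duration, by = optics$frame_interval)
  level <- if (ramp_duration == 0) {
    as.numeric(times >= t_start)
  } else {
    pmin(pmax((times - t_start) / ramp_duration, 0), 1)
  }
  set.seed(seed)
  frames <- array(rep(amplitude * level, each = height * width),
                  dim = c(height, width, length(times)))
  if (noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), sd = noise_sd)
    frames[frames < 0] <- 0
  }
  list(stack = image_stack(frames, "calcium_indicator", optics),
       t_start = t_start,
       ramp_duration = ramp_duration,
       t_arrival = t_start + ramp_duration / 2)
}

# rejection-sample n integer pixel centers, pairwise >= min_sep apart and
# >= margin from every edge
.place_spots <- function(n, height, width, min_sep, margin) {
  if (n == 0) return(cbind(row = integer(0), col = integer(0)))
  rows <- integer(0); cols <- integer(0)
  tries <- 0L; max_tries <- 2000L * n
  while (length(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("field too small to place ", n, " vesicles ",
           min_sep, " px apart")
    r <- sample(seq.int(margin + 1L, height - margin), 1L)
    c <- sample(seq.int(margin + 1L, width - margin), 1L)
    if (length(rows) == 0 ||
        all((rows - r)^2 + (cols - c)^2 >= min_sep^2)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  cbind(row = rows, col = cols)
}

#' Simulate a TIRF movie of docking and fusing vesicles
#'
#' Composes single-vesicle line shapes (\code{\link{trace_model}}) into
#' image frames: each vesicle is placed at a random pixel position (spot
#' centers at least \code{6 * psf_sigma} apart), its trace rendered as a
#' normalized Gaussian PSF spot on a constant background, and EMCCD-like
#' noise applied (Poisson shot noise, then additive Gaussian read noise).
#'
#' Two acquisition modes: spontaneous (\code{calcium = NULL}), where dock
#' times are uniform over the early movie and fusion follows docking with
#' the preset rate; and calcium-triggered (\code{calcium} a list of
#' arguments for \code{\link{simulate_calcium_arrival}}), where all
#' vesicles are docked before the movie starts and the fusion clock starts
#' at the true calcium arrival time, mirroring experiments in which docking
#' proceeds for ~20 min before the triggering buffer is injected. Fusion
#' events that would not complete within the recording are counted as
#' docked-only (right-censored) in the ground truth.
#'
#' For dual-label presets the rendered channel is the protein component
#' (the native cargo label); the dye component is available through
#' \code{\link{trace_model}}.
#'
#' @param presets A \code{\link{vesicle_preset}} or list of presets
#'   (recycled across vesicles).
#' @param optics An \code{\link{optics_config}}.
#' @param n_vesicles Number of vesicles (>= 0).
#' @param duration Movie length, s.
#' @param calcium \code{NULL}, or a list of overrides for
#'   \code{\link{simulate_calcium_arrival}} (e.g.
#'   \code{list(t_start = 2, ramp_duration = 0.3)}).
#' @param seed Integer seed; frames and ground truth are reproducible.
#' @param width,height Frame size, pixels.
#' @param noise Apply the camera noise model? \code{FALSE} returns
#'   expected (noise-free) intensities.
#' @return List with \code{label} (an \code{image_stack}),
#'   \code{calcium} (an arrival list as returned by
#'   \code{\link{simulate_calcium_arrival}}, or \code{NULL}), and
#'   \code{truth} (data.frame of \code{\link{ground_truth_record}} rows
#'   plus \code{label_kind} and \code{preset} columns).
#' @export
simulate_movie <- function(presets, optics, n_vesicles, duration,
                           calcium = NULL, seed = 1L,
                           width = 48, height = 48, noise = TRUE) {
  if (inherits(presets, "vesicle_preset")) presets <- list(presets)
  stopifnot(all(vapply(presets, inherits, TRUE, "vesicle_preset")))
  if (n_vesicles < 0) stop("n_vesicles must be >= 0")
  set.seed(seed)
  times <- seq(0, duration, by = optics$frame_interval)
  nf <- length(times)

  arrival <- NULL
  if (!is.null(calcium)) {
    ca_args <- utils::modifyList(
      list(optics = optics, duration = duration, seed = seed + 1000L,
           width = width, height = height), as.list(calcium))
    arrival <- do.call(simulate_calcium_arrival, ca_args)
  }

  margin <- 6L
  pos <- .place_spots(n_vesicles, height, width,
                      min_sep = 6 * optics$psf_sigma, margin = margin)

  idx <- if (n_vesicles > 0) rep_len(seq_along(presets), n_vesicles) else integer(0)
  truth_rows <- vector("list", n_vesicles)
  censor_margin <- 3 * optics$frame_interval
  for (v in seq_len(n_vesicles)) {
    pre <- presets[[idx[v]]]
    radius <- 0
    while (radius <= 0)
      radius <- stats::rnorm(1, pre$radius_mean, pre$radius_sd)
    if (is.null(arrival)) {
      dock <- stats::runif(1, 5 * optics$frame_interval, 0.5 * duration)
      clock0 <- dock
    } else {
      dock <- 0
      clock0 <- arrival$t_arrival
    }
    fused <- stats::runif(1) < pre$fusion_probability
    pore <- onset <- coll <- NA_real_
    if (fused) {
      pore <- clock0 + stats::rexp(1, pre$fusion_rate_k)
      event_end <- pore +
        if (pre$label_kind == "small_dye") 0 else
          pre$pore_widen_lag + pre$collapse_lag
      if (event_end > duration - censor_margin) {
        fused <- FALSE
        pore <- NA_real_
      } else if (pre$label_kind != "small_dye") {
        onset <- pore + pre$pore_widen_lag
        coll <- onset + pre$collapse_lag
      }
    }
    rec <- ground_truth_record(radius = radius, dock_time = dock,
                               fused = fused, pore_time = pore,
                               protein_onset_time = onset,
                               collapse_time = coll,
                               row = pos[v, "row"], col = pos[v, "col"])
    rec$label_kind <- pre$label_kind
    rec$preset <- pre$name
    truth_rows[[v]] <- rec
  }
  truth <- if (n_vesicles > 0) do.call(rbind, truth_rows) else
    data.frame(row = integer(0), col = integer(0), radius = numeric(0),
               dock_time = numeric(0), fused = logical(0),
               pore_time = numeric(0), protein_onset_time = numeric(0),
               collapse_time = numeric(0), label_kind = character(0),
               preset = character(0))

  # normalized Gaussian PSF kernel
  kr <- as.integer(ceiling(4 * optics$psf_sigma))
  off <- -kr:kr
  g1 <- exp(-off^2 / (2 * optics$psf_sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)

  frames <- array(optics$background_rate, dim = c(height, width, nf))
  for (v in seq_len(n_vesicles)) {
    pre <- presets[[idx[v]]]
    comp <- if (pre$label_kind == "small_dye") "dye" else "protein"
    tr <- trace_model(pre, optics, truth[v, ], times,
                      label_kind = if (pre$label_kind == "dual") "protein"
                                   else pre$label_kind)[, comp]
    rr <- truth$row[v] + off; cc <- truth$col[v] + off
    keep_r <- rr >= 1 & rr <= height; keep_c <- cc >= 1 & cc <= width
    spot <- outer(kern[keep_r, keep_c, drop = FALSE],
                  tr)  # [kr, kc, frame]
    frames[rr[keep_r], cc[keep_c], ] <-
      frames[rr[keep_r], cc[keep_c], ] + spot
  }
  if (noise) {
    frames[] <- stats::rpois(length(frames), lambda = frames)
    if (optics$read_noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames),
                                      sd = optics$read_noise_sd)
    frames[frames < 0] <- 0
  }
  list(label = image_stack(frames, "label", optics),
       calcium = arrival,
       truth = truth)
}
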