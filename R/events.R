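# robust SD with a floor so that noise-free traces still threshold sanely
.robust_sd <- function(x, series) {
  max(stats::mad(x), 1e-6 * max(abs(series), 1), 1e-12)
}

# trace-wide frame-noise SD from successive differences; robust to steps
# and monotone event segments (their diffs are outvoted by the plateau),
# floored so noise-free traces threshold on any real change
.trace_noise_sd <- function(series) {
  max(stats::mad(diff(series)) / sqrt(2),
      1e-6 * max(abs(series), 1), 1e-12)
}

#' Detect vesicle docking in a trace
#'
#' Docking appears as an abrupt, sustained step increase of the
#' central-pixel intensity. The baseline is estimated causally (median and
#' MAD of all frames before the candidate), and the dock time is the first
#' frame exceeding \code{baseline median + sigma_mult * robust SD} for at
#' least two consecutive frames.
#'
#' @param trace A \code{particle_trace}.
#' @param sigma_mult Threshold in robust baseline SDs.
#' @return Dock time in s, or \code{NA} if no docking step is found.
#' @export
detect_docking <- function(trace, sigma_mult = 3) {
  stopifnot(inherits(trace, "particle_trace"))
  x <- trace$central
  n <- length(x)
  if (n < 10) stop("trace needs >= 10 frames to estimate a baseline")
  s <- .trace_noise_sd(x)
  for (t in 4:(n - 1)) {
    thr <- stats::median(x[1:(t - 1)]) + sigma_mult * s
    if (x[t] > thr && x[t + 1] > thr) return(trace$times[t])
  }
  NA_real_
}

# first index >= from where the series departs from the plateau in the
# given direction ("up"/"down") for >= 3 consecutive frames; the causal
# plateau median sets the level, the trace-wide noise SD the threshold
.first_departure <- function(x, plateau_start, from, sigma_mult,
                             direction, noise_sd) {
  n <- length(x)
  if (from > n - 2) return(NA_integer_)
  for (t in from:(n - 2)) {
    med <- stats::median(x[plateau_start:(t - 1)])
    seg <- x[t:(t + 2)]
    hit <- if (direction == "up") {
      all(seg > med + sigma_mult * noise_sd)
    } else {
      all(seg < med - sigma_mult * noise_sd)
    }
    if (hit) return(t)
  }
  NA_integer_
}

#' Classify and time a fusion event
#'
#' Applies the label-appropriate fusion signature to a docked-vesicle
#' trace. Small dye (acridine orange-like): fusion onset is the start of a
#' sustained rise above the docked plateau (dequenching at pore opening).
#' Protein cargo: fusion onset is the start of a sustained decrease below
#' the docked plateau (slow efflux through the narrow pore), and collapse
#' is the subsequent rise as the remaining content is pulled into the
#' evanescent field. A vesicle is flagged \code{fused} only when the full
#' signature is present; ambiguous traces are classified docked-only.
#'
#' When no docking step is observed (a vesicle already docked before the
#' recording started, as in calcium-triggered acquisitions where docking
#' proceeds for many minutes before injection), the recording start is
#' taken as the docked plateau and \code{dock_time} stays \code{NA} in the
#' record; fusion is still classified and timed.
#'
#' @param trace A \code{particle_trace}.
#' @param label_kind \code{"small_dye"} or \code{"protein"} (for
#'   dual-labeled vesicles classify each channel's trace separately).
#' @param dock_time Dock time in s, or \code{NULL} to detect it here.
#' @param sigma_mult Onset threshold in robust plateau SDs.
#' @return An \code{event_record}: list with \code{particle_id},
#'   \code{dock_time}, \code{fused}, \code{pore_onset_time} (dye),
#'   \code{protein_onset_time}, \code{collapse_time}, \code{label_kind}.
#' @export
classify_and_time_fusion <- function(trace,
                                     label_kind = c("small_dye", "protein"),
                                     dock_time = NULL, sigma_mult = 2) {
  stopifnot(inherits(trace, "particle_trace"))
  label_kind <- match.arg(label_kind)
  if (is.null(dock_time)) dock_time <- detect_docking(trace)
  rec <- list(particle_id = trace$particle_id, dock_time = dock_time,
              fused = FALSE, pore_onset_time = NA_real_,
              protein_onset_time = NA_real_, collapse_time = NA_real_,
              label_kind = label_kind)
  class(rec) <- "event_record"
  x <- trace$central
  n <- length(x)
  dock_idx <- if (is.na(dock_time)) 1L else
    which(trace$times >= dock_time)[1]
  if (is.na(dock_idx) || dock_idx > n - 6) return(rec)
  noise_sd <- .trace_noise_sd(x)
  from <- dock_idx + 4L  # >= 4 plateau frames stabilize the level
  if (label_kind == "small_dye") {
    t_on <- .first_departure(x, dock_idx, from, sigma_mult, "up",
                             noise_sd)
    if (!is.na(t_on)) {
      rec$fused <- TRUE
      rec$pore_onset_time <- trace$times[t_on]
    }
  } else {
    t_on <- .first_departure(x, dock_idx, from, sigma_mult, "down",
                             noise_sd)
    if (!is.na(t_on) && t_on < n) {
      # collapse: the largest upward jump against the post-onset decay
      jumps <- diff(x[t_on:n])
      j <- which.max(jumps)
      if (jumps[j] > sigma_mult * sqrt(2) * noise_sd) {
        rec$fused <- TRUE
        rec$protein_onset_time <- trace$times[t_on]
        rec$collapse_time <- trace$times[t_on + j]
      }
    }
  }
  rec
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("event_record #%s [%s]: dock=%s fused=%s\n", x$particle_id,
              x$label_kind, format(x$dock_time), x$fused))
  if (x$fused)
    cat(sprintf("  onset (dye/protein): %s / %s, collapse: %s\n",
                format(x$pore_onset_time), format(x$protein_onset_time),
                format(x$collapse_time)))
  invisible(x)
}

#' Lag between small-dye and protein fusion onsets
#'
#' For a dual-labeled vesicle imaged in two co-registered channels,
#' measures how long small-dye efflux through the initial narrow fusion
#' pore precedes protein efflux: \code{protein onset - dye onset},
#' positive when the dye leads.
#'
#' @param dye_trace,protein_trace \code{particle_trace}s of the same
#'   vesicle, sharing the time base.
#' @param sigma_mult Onset threshold passed to
#'   \code{\link{classify_and_time_fusion}}.
#' @return Lag in seconds.
#' @export
measure_dual_label_lag <- function(dye_trace, protein_trace,
                                   sigma_mult = 2) {
  ev_d <- classify_and_time_fusion(dye_trace, "small_dye",
                                   sigma_mult = sigma_mult)
  ev_p <- classify_and_time_fusion(protein_trace, "protein",
                                   sigma_mult = sigma_mult)
  if (!ev_d$fused || !ev_p$fused)
    stop("dual-label lag undefined: one of the traces shows no fusion")
  ev_p$protein_onset_time - ev_d$pore_onset_time
}

#' Measure calcium arrival from an indicator trace
#'
#' Times the arrival of the calcium-containing buffer from the soluble
#' indicator channel: commencement is the first sustained crossing of 10%
#' of the baseline-to-plateau span, saturation the first crossing of 90%,
#' and the arrival reference time (used as time zero for fusion delays)
#' the first crossing of 50%.
#'
#' @param indicator_trace Numeric intensity series (spatial mean of the
#'   indicator channel), or a \code{particle_trace}.
#' @param frame_interval Frame interval in s (taken from the trace when a
#'   \code{particle_trace} is given).
#' @return A \code{calcium_arrival} list: \code{t_commence},
#'   \code{t_saturate}, \code{delta_t_ca}, \code{t_arrival}.
#' @export
measure_calcium_arrival <- function(indicator_trace, frame_interval) {
  if (inherits(indicator_trace, "particle_trace")) {
    frame_interval <- indicator_trace$frame_interval
    indicator_trace <- indicator_trace$central
  }
  x <- as.numeric(indicator_trace)
  n <- length(x)
  if (n < 10) stop("indicator trace too short")
  baseline <- stats::median(x[1:5])
  plateau <- stats::median(x[(n - 4):n])
  span <- plateau - baseline
  noise <- .robust_sd(x[1:5], x)
  if (span <= 3 * noise)
    stop("no plateau reached: indicator trace never rises above baseline")
  times <- (seq_len(n) - 1) * frame_interval
  crossing <- function(frac, sustained = FALSE) {
    thr <- baseline + frac * span
    idx <- which(x >= thr)
    if (sustained) idx <- idx[idx < n & (idx + 1) %in% which(x >= thr)]
    if (length(idx) == 0) NA_real_ else times[idx[1]]
  }
  t_c <- crossing(0.1, sustained = TRUE)
  t_s <- crossing(0.9)
  t_a <- crossing(0.5)
  if (is.na(t_c) || is.na(t_s))
    stop("no plateau reached within the trace")
  structure(list(t_commence = t_c, t_saturate = t_s,
                 delta_t_ca = t_s - t_c, t_arrival = t_a),
            class = "calcium_arrival")
}

#' @export
print.calcium_arrival <- function(x, ...) {
  cat(sprintf(
    "calcium arrival: commence %.3f s, saturate %.3f s (Delta-t-Ca %.3f s), arrival %.3f s\n",
    x$t_commence, x$t_saturate, x$delta_t_ca, x$t_arrival))
  invisible(x)
}

#' Build a delay table from classified events
#'
#' Computes per-vesicle fusion delays relative to the measured calcium
#' arrival time: \code{delay = fusion onset - t_arrival}, where the onset
#' is the dye onset when present, otherwise the protein onset. Fused
#' records whose onset precedes the arrival are treated as spontaneous and
#' excluded (their count is reported). Docked-only vesicles contribute to
#' \code{n_docked} (and hence the fusion probability) but carry no delay.
#'
#' @param events List of \code{event_record}s from one recording.
#' @param arrival A \code{calcium_arrival} shared by those events.
#' @param condition Condition label for the table.
#' @return A \code{delay_table}: list with \code{condition}, \code{delays}
#'   (s, fused vesicles only), \code{n_docked}, \code{n_fused},
#'   \code{n_excluded}.
#' @export
compute_delays <- function(events, arrival, condition = "condition") {
  stopifnot(inherits(arrival, "calcium_arrival"))
  onset <- vapply(events, function(e) {
    if (!e$fused) return(NA_real_)
    if (!is.na(e$pore_onset_time)) e$pore_onset_time else
      e$protein_onset_time
  }, numeric(1))
  fused <- !is.na(onset)
  delays <- onset[fused] - arrival$t_arrival
  excluded <- sum(delays < 0)
  if (excluded > 0)
    message(excluded,
            " event(s) with onset before calcium arrival excluded")
  delays <- delays[delays >= 0]
  structure(list(condition = condition, delays = delays,
                 n_docked = length(events), n_fused = length(delays),
                 n_excluded = excluded),
            class = "delay_table")
}

#' @export
print.delay_table <- function(x, ...) {
  cat(sprintf("delay_table '%s': %d fused / %d docked (P = %.2f)",
              x$condition, x$n_fused, x$n_docked,
              if (x$n_docked > 0) x$n_fused / x$n_docked else NA))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Normalized docking and fusion-probability statistics
#'
#' Normalizes docked-vesicle counts per condition to a reference condition
#' (conventionally the bare t-SNARE bilayer), and computes the fusion
#' probability of each condition as fused / docked.
#'
#' @param counts data.frame with columns \code{condition},
#'   \code{n_docked} and optionally \code{n_fused}.
#' @param reference_condition Name of the reference condition (its docked
#'   count must be > 0).
#' @return The input with added columns \code{normalized_docking} and
#'   (when \code{n_fused} is present) \code{fusion_probability}.
#' @export
docking_stats <- function(counts, reference_condition) {
  stopifnot(is.data.frame(counts),
            all(c("condition", "n_docked") %in% names(counts)))
  ref <- counts$n_docked[counts$condition == reference_condition]
  if (length(ref) != 1)
    stop("reference condition '", reference_condition, "' not found")
  if (ref <= 0) stop("reference docked count must be > 0")
  counts$normalized_docking <- counts$n_docked / ref
  if ("n_fused" %in% names(counts))
    counts$fusion_probability <-
      ifelse(counts$n_docked > 0, counts$n_fused / counts$n_docked, NA)
  counts
}
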