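#' Simulate a movie and write it with full provenance
#'
#' One-call front end over \code{\link{simulate_movie}}: renders the label
#' (and optional calcium-indicator) channel, writes multi-page TIFFs with
#' JSON sidecars carrying the resolved configuration, the seed, the ground
#' truth, and (in calcium mode) the true arrival parameters and
#' per-vesicle delays.
#'
#' @param out_dir Output directory (created if missing).
#' @param preset Preset name or \code{\link{vesicle_preset}}.
#' @param n_vesicles Number of vesicles.
#' @param duration Movie length, s (default: long enough for the preset's
#'   kinetics).
#' @param calcium Logical or a list of overrides for
#'   \code{\link{simulate_calcium_arrival}}; \code{TRUE} uses defaults.
#' @param seed Integer seed.
#' @param optics An \code{\link{optics_config}} (default: the preset's
#'   conventional acquisition settings).
#' @param noise Apply the camera noise model?
#' @param width,height Frame size, pixels.
#' @return Invisibly, a list with the \code{label} / \code{calcium} TIFF
#'   paths and the simulation result.
#' @export
run_simulate <- function(out_dir, preset = "SV", n_vesicles = 25,
                         duration = NULL, calcium = FALSE, seed = 1L,
                         optics = NULL, noise = TRUE,
                         width = 48, height = 48) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (is.null(optics)) optics <- default_optics(preset)
  if (is.null(duration))
    duration <- max(10, 6 / preset$fusion_rate_k + 4)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ca <- if (isTRUE(calcium)) list() else if (is.list(calcium)) calcium
        else NULL
  sim <- simulate_movie(preset, optics, n_vesicles, duration,
                        calcium = ca, seed = seed,
                        width = width, height = height, noise = noise)
  config <- list(preset = unclass(preset), n_vesicles = n_vesicles,
                 duration = duration, seed = seed, noise = noise,
                 width = width, height = height,
                 package_version = as.character(
                   utils::packageVersion("svfusion")))
  label_path <- file.path(out_dir, "label.tif")
  extra <- list(config = config,
                ground_truth = sim$truth)
  if (!is.null(sim$calcium)) {
    extra$calcium_truth <- list(
      t_start = sim$calcium$t_start,
      ramp_duration = sim$calcium$ramp_duration,
      t_arrival = sim$calcium$t_arrival)
    extra$true_delays <-
      sim$truth$pore_time[sim$truth$fused] - sim$calcium$t_arrival
  }
  write_image_stack(sim$label, label_path, extra = extra)
  ca_path <- NULL
  if (!is.null(sim$calcium)) {
    ca_path <- file.path(out_dir, "calcium.tif")
    write_image_stack(sim$calcium$stack, ca_path,
                      extra = list(truth = extra$calcium_truth))
  }
  invisible(list(label = label_path, calcium = ca_path, sim = sim))
}

#' Analyze a movie: detect, trace, time, and tabulate
#'
#' Runs the full image-analysis chain on a recorded or simulated movie:
#' temporal moving-average filtering, maximum-intensity projection,
#' spot detection on the projection, trace extraction from the unfiltered
#' stack, docking and fusion timing per trace, and (when an indicator
#' channel is given) calcium-arrival measurement and delay-table
#' construction. Stage-level counts are reported via \code{message()}.
#'
#' @param movie Path to a label-channel TIFF (with sidecar) or an
#'   \code{\link{image_stack}}.
#' @param out_dir Optional output directory for traces.csv, events.csv,
#'   positions.csv and delays.json.
#' @param label_kind \code{"small_dye"} or \code{"protein"}; label
#'   chemistry of the channel.
#' @param calcium Optional indicator-channel TIFF path or
#'   \code{image_stack}.
#' @param window Moving-average window, frames (odd).
#' @param threshold_sigma Spot-detection threshold, robust SDs.
#' @param dock_sigma,onset_sigma Event-timing thresholds, robust SDs.
#' @param pre_docked Were vesicles docked before the recording started?
#'   Defaults to \code{TRUE} for calcium-triggered acquisitions (an
#'   indicator channel is given), where docking is allowed to proceed for
#'   many minutes before triggering: docking steps are then not searched
#'   for and every detected particle counts as docked.
#' @param frame_interval Fallback frame interval when reading a TIFF
#'   without sidecar.
#' @param condition Condition label for the delay table.
#' @return List with \code{positions}, \code{traces}, \code{events},
#'   \code{arrival} (or NULL) and \code{delays} (a \code{delay_table} or
#'   NULL).
#' @export
run_analyze <- function(movie, out_dir = NULL,
                        label_kind = c("small_dye", "protein"),
                        calcium = NULL, window = 3L, threshold_sigma = 5,
                        dock_sigma = 3, onset_sigma = 2,
                        pre_docked = !is.null(calcium),
                        frame_interval = NULL, condition = "condition") {
  label_kind <- match.arg(label_kind)
  stack <- if (inherits(movie, "image_stack")) movie else
    read_image_stack(movie, frame_interval = frame_interval)
  filtered <- moving_average_filter(stack, window)
  proj <- max_projection(filtered)
  pos <- detect_particles(proj, threshold_sigma = threshold_sigma,
                          psf_sigma = stack$optics$psf_sigma)
  message("detected ", nrow(pos), " particle(s)")
  traces <- extract_traces(stack, pos)
  events <- lapply(traces, function(tr) {
    dock <- if (pre_docked) NA_real_ else detect_docking(tr, dock_sigma)
    classify_and_time_fusion(tr, label_kind, dock_time = dock,
                             sigma_mult = onset_sigma)
  })
  n_docked <- if (pre_docked) length(events) else
    sum(vapply(events, function(e) !is.na(e$dock_time), logical(1)))
  n_fused <- sum(vapply(events, `[[`, logical(1), "fused"))
  message(n_docked, " docked, ", n_fused, " fused")
  arrival <- NULL
  delays <- NULL
  if (!is.null(calcium)) {
    ca_stack <- if (inherits(calcium, "image_stack")) calcium else
      read_image_stack(calcium, frame_interval = frame_interval)
    ind <- apply(ca_stack$frames, 3, mean)
    arrival <- measure_calcium_arrival(ind,
                                       ca_stack$optics$frame_interval)
    delays <- compute_delays(events, arrival, condition = condition)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(pos),
                     file.path(out_dir, "positions.csv"),
                     row.names = FALSE)
    write_trace_table(traces, file.path(out_dir, "traces.csv"))
    write_event_table(events, file.path(out_dir, "events.csv"))
    if (!is.null(delays))
      write_delay_table(delays, file.path(out_dir, "delays.json"),
                        arrival = arrival,
                        thresholds = list(window = window,
                                          threshold_sigma = threshold_sigma,
                                          dock_sigma = dock_sigma,
                                          onset_sigma = onset_sigma))
  }
  list(positions = pos, traces = traces, events = events,
       arrival = arrival, delays = delays)
}

#' Fit kinetics (and optionally the curvature relation) across conditions
#'
#' Fits each delay table with the requested kinetic model and, when
#' diameter samples are given for at least two conditions, fits the
#' log-linear curvature-rate relation across conditions.
#'
#' @param delay_tables Named list of \code{delay_table}s or paths to
#'   delay-table JSON files.
#' @param diameters Optional named list (same names) of diameter vectors
#'   (nm) or CSV paths with a \code{diameter_nm} column.
#' @param model \code{"exponential"} or \code{"gamma"}.
#' @param n_steps Step count or \code{"auto"} (gamma model).
#' @param n_boot Bootstrap resamples for rate CIs.
#' @param seed Integer seed.
#' @param out Optional JSON report path.
#' @return List with \code{fits} (named \code{kinetic_fit} list),
#'   \code{comparison} (pairwise ratios, when >= 2 fits) and
#'   \code{curvature} (a \code{curvature_fit} or NULL).
#' @export
run_fit <- function(delay_tables, diameters = NULL,
                    model = c("exponential", "gamma"), n_steps = "auto",
                    n_boot = 1000L, seed = 1L, out = NULL) {
  model <- match.arg(model)
  if (inherits(delay_tables, "delay_table"))
    delay_tables <- list(delay_tables)
  tabs <- lapply(delay_tables, function(x)
    if (is.character(x)) read_delay_table(x) else x)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    names(tabs) <- vapply(tabs, `[[`, character(1), "condition")
  # distinct bootstrap seeds per condition keep resamples independent,
  # which the ratio CIs in compare_conditions() rely on
  fits <- lapply(seq_along(tabs), function(i) {
    tb <- tabs[[i]]
    if (model == "exponential")
      fit_single_exponential(tb$delays, n_boot = n_boot, seed = seed + i)
    else
      fit_sequential_steps(tb$delays, n_steps = n_steps,
                           n_boot = n_boot, seed = seed + i)
  })
  names(fits) <- names(tabs)
  comparison <- if (length(fits) >= 2) compare_conditions(fits) else NULL
  curvature <- NULL
  if (!is.null(diameters) && length(diameters) >= 2) {
    dia <- lapply(diameters, function(d) {
      if (is.character(d)) utils::read.csv(d)$diameter_nm else d
    })
    common <- intersect(names(fits), names(dia))
    if (length(common) >= 2) {
      pts <- data.frame(
        condition = common,
        curvature = vapply(dia[common], function(d)
          as.numeric(mean_curvature(d)), numeric(1)),
        rate_k = vapply(fits[common], `[[`, numeric(1), "rate_k"))
      curvature <- fit_curvature_model(pts)
    }
  }
  if (!is.null(out)) {
    report <- list(
      model = model,
      fits = lapply(fits, function(f)
        f[c("model", "rate_k", "tau", "n_steps", "ci_low", "ci_high",
            "n_obs", "censored_n", "loglik", "aic")]),
      comparison = comparison,
      curvature = if (!is.null(curvature))
        list(intercept_a = curvature$intercept_a,
             slope_b = curvature$slope_b,
             points = curvature$points))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(fits = fits, comparison = comparison, curvature = curvature)
}
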