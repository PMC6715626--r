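# counts are stored as 16-bit TIFF pages scaled by a recorded factor
.TIFF_MAX <- 65535

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are scaled into 16-bit range (the scale factor is recorded) and
#' written one page per frame. Acquisition metadata that TIFF tags do not
#' carry portably (frame interval, pixel size, penetration depth, channel,
#' seed) goes into \code{<path>.json}.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar (e.g. seeds, ground
#'   truth).
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "image_stack"))
  peak <- max(stack$frames, 1)
  scale <- .TIFF_MAX / peak
  pages <- lapply(seq_len(n_frames(stack)), function(j) {
    m <- stack$frames[, , j] * scale
    round(pmin(pmax(m, 0), .TIFF_MAX)) / .TIFF_MAX
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- c(list(channel = stack$channel,
                    scale = scale,
                    frame_interval = stack$optics$frame_interval,
                    pixel_size = stack$optics$pixel_size,
                    penetration_depth = stack$optics$penetration_depth,
                    psf_sigma = stack$optics$psf_sigma,
                    em_gain = stack$optics$em_gain,
                    read_noise_sd = stack$optics$read_noise_sd,
                    background_rate = stack$optics$background_rate),
               extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by \code{\link{write_image_stack}}
#'
#' @param path TIFF path; \code{<path>.json} must exist unless
#'   \code{frame_interval} is supplied.
#' @param frame_interval Override/fallback frame interval, s.
#' @return An \code{\link{image_stack}} with the sidecar attached as
#'   attribute \code{"sidecar"}.
#' @export
read_image_stack <- function(path, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  if (is.null(sidecar) && is.null(frame_interval))
    stop("no sidecar found for '", path,
         "'; pass frame_interval explicitly")
  fi <- if (!is.null(frame_interval)) frame_interval else
    sidecar$frame_interval
  optics <- optics_config(
    penetration_depth = sidecar$penetration_depth %||% 100,
    psf_sigma = sidecar$psf_sigma %||% 1,
    pixel_size = sidecar$pixel_size %||% 160,
    frame_interval = fi,
    em_gain = sidecar$em_gain %||% 200,
    read_noise_sd = sidecar$read_noise_sd %||% 10,
    background_rate = sidecar$background_rate %||% 100)
  scale <- sidecar$scale %||% 1
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (j in seq_along(pages))
    frames[, , j] <- pages[[j]] * .TIFF_MAX / scale
  out <- image_stack(frames,
                     channel = sidecar$channel %||% "label",
                     optics = optics)
  attr(out, "sidecar") <- sidecar
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write particle traces as a tidy CSV
#'
#' One row per particle and frame, columns \code{particle_id},
#' \code{frame}, \code{time_s}, \code{central}, \code{roi_mean}.
#'
#' @param traces List of \code{particle_trace}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(particle_id = tr$particle_id,
               frame = seq_along(tr$central),
               time_s = tr$times,
               central = tr$central,
               roi_mean = tr$roi_mean)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(particle_id = integer(0), frame = integer(0),
               time_s = numeric(0), central = numeric(0),
               roi_mean = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write classified events as CSV
#'
#' One row per particle; unobserved times are blank.
#'
#' @param events List of \code{event_record}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_event_table <- function(events, path) {
  tab <- events_as_data_frame(events)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Convert a list of event records to a data.frame
#' @param events List of \code{event_record}.
#' @return data.frame with one row per event.
#' @export
events_as_data_frame <- function(events) {
  if (length(events) == 0)
    return(data.frame(particle_id = integer(0), dock_time = numeric(0),
                      fused = logical(0), pore_onset_time = numeric(0),
                      protein_onset_time = numeric(0),
                      collapse_time = numeric(0),
                      label_kind = character(0)))
  do.call(rbind, lapply(events, function(e)
    data.frame(particle_id = e$particle_id, dock_time = e$dock_time,
               fused = e$fused, pore_onset_time = e$pore_onset_time,
               protein_onset_time = e$protein_onset_time,
               collapse_time = e$collapse_time,
               label_kind = e$label_kind)))
}

#' Write a delay table (plus its calcium arrival) as JSON
#'
#' @param table A \code{delay_table}.
#' @param path Output JSON path.
#' @param arrival Optional \code{calcium_arrival} to embed.
#' @param thresholds Optional named list of analysis thresholds, echoed
#'   for provenance.
#' @return \code{path}, invisibly.
#' @export
write_delay_table <- function(table, path, arrival = NULL,
                              thresholds = NULL) {
  stopifnot(inherits(table, "delay_table"))
  obj <- unclass(table)
  if (!is.null(arrival)) obj$calcium_arrival <- unclass(arrival)
  if (!is.null(thresholds)) obj$thresholds <- thresholds
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a delay table written by \code{\link{write_delay_table}}
#'
#' @param path JSON path.
#' @return A \code{delay_table} (with \code{$calcium_arrival} when it was
#'   embedded).
#' @export
read_delay_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- structure(list(condition = obj$condition,
                        delays = as.numeric(obj$delays %||% numeric(0)),
                        n_docked = obj$n_docked,
                        n_fused = obj$n_fused,
                        n_excluded = obj$n_excluded %||% 0L),
                   class = "delay_table")
  if (!is.null(obj$calcium_arrival))
    out$calcium_arrival <- structure(obj$calcium_arrival,
                                     class = "calcium_arrival")
  out
}
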