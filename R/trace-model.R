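#' Ground-truth record for a single simulated vesicle
#'
#' Encodes the four phases of a single-vesicle fusion event: (I) absent,
#' (II) docked, (III) fusion pore open, (IV) collapsed into the planar
#' membrane. Non-fused vesicles carry \code{NA} pore/onset/collapse times.
#'
#' @param radius Vesicle radius, nm.
#' @param dock_time Docking time, s.
#' @param fused Logical; did the vesicle fuse?
#' @param pore_time Fusion-pore opening time, s (small-dye efflux onset).
#' @param protein_onset_time Protein-efflux onset, s
#'   (\code{pore_time + pore_widen_lag}).
#' @param collapse_time Collapse time, s
#'   (\code{protein_onset_time + collapse_lag}).
#' @param row,col Pixel position (1-based) when the record belongs to a
#'   rendered movie; \code{NA} for bare traces.
#' @return A one-row data.frame.
#' @export
ground_truth_record <- function(radius, dock_time, fused = TRUE,
                                pore_time = NA_real_,
                                protein_onset_time = NA_real_,
                                collapse_time = NA_real_,
                                row = NA_integer_, col = NA_integer_) {
  if (fused) {
    tt <- c(dock_time, pore_time, protein_onset_time, collapse_time)
    tt <- tt[!is.na(tt)]
    if (is.unsorted(tt))
      stop("fused record must satisfy dock <= pore <= onset <= collapse")
  } else {
    pore_time <- protein_onset_time <- collapse_time <- NA_real_
  }
  data.frame(row = row, col = col, radius = radius, dock_time = dock_time,
             fused = fused, pore_time = pore_time,
             protein_onset_time = protein_onset_time,
             collapse_time = collapse_time)
}

# 2D point-source fraction remaining inside a disc of radius a (um) after
# diffusing for dt seconds with coefficient D (um^2/s); 1 at dt <= 0.
.fraction_remaining <- function(dt, a, D) {
  out <- rep(1, length(dt))
  pos <- dt > 0
  out[pos] <- 1 - exp(-a^2 / (4 * D * dt[pos]))
  out
}

#' Noise-free intensity line shape of a single fusion event
#'
#' Evaluates the characteristic ROI intensity trace of a labeled vesicle
#' docking to, and fusing with, a planar-supported membrane under TIRF
#' illumination. Docked vesicles sit one radius above the membrane, so
#' their label is attenuated by the evanescent factor
#' \code{exp(-radius/penetration_depth)}; released label sits at the
#' surface (attenuation 1) and leaves the ROI by lateral diffusion in the
#' cleft between the supported membrane and the substrate.
#'
#' Protein cargo: constant docked plateau, then slow exponential efflux
#' through the narrow pore from \code{protein_onset_time} (time constant
#' \code{collapse_lag}), then an upward jump by \code{exp(radius/d)} at
#' \code{collapse_time} as the remaining content moves into the evanescent
#' field, followed by diffusive escape from the ROI. Small dye (acridine
#' orange-like): a self-quenched docked plateau
#' (\code{quench_factor * exp(-radius/d)}), then an instantaneous
#' dequenched surface-proximal peak at \code{pore_time}, followed by the
#' same diffusive decay.
#'
#' @param preset A \code{\link{vesicle_preset}}.
#' @param optics An \code{\link{optics_config}}.
#' @param truth One \code{\link{ground_truth_record}} row.
#' @param times Sorted (ascending) sample times, s.
#' @param label_kind Optional override of \code{preset$label_kind}.
#' @return Numeric matrix \code{length(times) x n_components} with column
#'   names \code{"dye"} and/or \code{"protein"}.
#' @examples
#' pre <- get_preset("DCV")
#' tr <- trace_model(pre, default_optics("DCV"),
#'                   example_truth(pre), seq(0, 6, by = 0.05))
#' head(tr)
#' @export
trace_model <- function(preset, optics, truth, times,
                        label_kind = preset$label_kind) {
  stopifnot(inherits(preset, "vesicle_preset"),
            inherits(optics, "optics_config"))
  if (is.unsorted(times)) stop("times must be sorted ascending")
  truth <- as.list(truth)
  d <- optics$penetration_depth
  zbar <- truth$radius                       # docked label height, nm
  ev <- exp(-zbar / d)
  a_um <- 2.5 * optics$pixel_size / 1000     # ROI half-width, um (5x5 ROI)
  D <- preset$cleft_diffusion_D
  B <- preset$brightness
  fused <- isTRUE(truth$fused)

  protein_component <- function() {
    out <- numeric(length(times))
    docked <- times >= truth$dock_time
    out[docked] <- B * ev
    if (fused && !is.na(truth$protein_onset_time)) {
      onset <- truth$protein_onset_time
      coll <- truth$collapse_time
      ph3 <- times >= onset & times < coll
      out[ph3] <- B * ev * exp(-(times[ph3] - onset) / preset$collapse_lag)
      ph4 <- times >= coll
      content_at_collapse <- B * exp(-(coll - onset) / preset$collapse_lag)
      out[ph4] <- content_at_collapse *
        .fraction_remaining(times[ph4] - coll, a_um, D)
    }
    out
  }
  dye_component <- function() {
    out <- numeric(length(times))
    docked <- times >= truth$dock_time
    out[docked] <- B * preset$quench_factor * ev
    if (fused && !is.na(truth$pore_time)) {
      ph3 <- times >= truth$pore_time
      out[ph3] <- B * .fraction_remaining(times[ph3] - truth$pore_time,
                                          a_um, D)
    }
    out
  }

  cols <- switch(label_kind,
                 protein = list(protein = protein_component()),
                 small_dye = list(dye = dye_component()),
                 dual = list(dye = dye_component(),
                             protein = protein_component()))
  do.call(cbind, cols)
}

#' Canonical single-event ground truth for a preset
#'
#' Builds the worked-example event of a vesicle type: docking at
#' \code{dock_time}, pore opening after the preset's typical
#' \code{dock_to_pore} interval, protein efflux \code{pore_widen_lag}
#' later, collapse \code{collapse_lag} after that. The default dock time
#' is deliberately off the usual frame grids so that frame quantisation of
#' measured times behaves generically.
#'
#' @param preset A \code{\link{vesicle_preset}}.
#' @param dock_time Docking time, s.
#' @param radius Vesicle radius, nm (default: preset mean).
#' @return A \code{\link{ground_truth_record}} row.
#' @export
example_truth <- function(preset, dock_time = 1.013,
                          radius = preset$radius_mean) {
  pore <- dock_time + preset$dock_to_pore
  ground_truth_record(radius = radius, dock_time = dock_time, fused = TRUE,
                      pore_time = pore,
                      protein_onset_time = pore + preset$pore_widen_lag,
                      collapse_time = pore + preset$pore_widen_lag +
                        preset$collapse_lag)
}

#' Packaged worked-example synaptic-vesicle trace
#'
#' The canonical noise-free acridine-orange synaptic-vesicle event: docking
#' followed by fusion onset ~250 ms later, sampled at 40 ms frames.
#'
#' @param duration Trace length, s.
#' @return A \code{particle_trace} (see \code{\link{extract_traces}}) whose
#'   central-pixel and ROI series are the model line shape.
#' @export
sv_example_trace <- function(duration = 4) {
  preset <- get_preset("SV")
  optics <- default_optics("SV")
  times <- seq(0, duration, by = optics$frame_interval)
  tr <- trace_model(preset, optics, example_truth(preset), times)
  new_particle_trace(particle_id = 1L, row = NA_integer_, col = NA_integer_,
                     central = tr[, "dye"], roi_mean = tr[, "dye"],
                     frame_interval = optics$frame_interval)
}
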