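# shared fixtures: everything is generated in code at test time

# match detected positions (matrix row/col) to ground-truth rows; returns
# index into truth for each position, NA when no vesicle within tol px
match_truth <- function(positions, truth, tol = 1.5) {
  vapply(seq_len(nrow(positions)), function(i) {
    d2 <- (truth$row - positions[i, "row"])^2 +
      (truth$col - positions[i, "col"])^2
    j <- which.min(d2)
    if (length(j) == 0 || d2[j] > tol^2) NA_integer_ else j
  }, integer(1))
}

quiet_analyze <- function(...) suppressMessages(run_analyze(...))

# noise-free single-label trace pair for a dual-labeled vesicle
dual_traces <- function(preset, frame_interval = 0.05, dock_time = 1.013,
                        duration = 8) {
  opt <- optics_config(frame_interval = frame_interval)
  times <- seq(0, duration, by = frame_interval)
  tr <- trace_model(preset, opt, example_truth(preset, dock_time), times,
                    label_kind = "dual")
  list(dye = new_particle_trace(1L, NA, NA, tr[, "dye"], tr[, "dye"],
                                frame_interval),
       protein = new_particle_trace(1L, NA, NA, tr[, "protein"],
                                    tr[, "protein"], frame_interval))
}
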