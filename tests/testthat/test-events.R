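step_trace <- function(step_frame, lo = 0, hi = 100, n = 40,
                       frame_interval = 0.04) {
  x <- c(rep(lo, step_frame - 1), rep(hi, n - step_frame + 1))
  new_particle_trace(1L, NA, NA, x, x, frame_interval)
}

test_that("docking detection times a clean step and ignores flat traces", {
  tr <- step_trace(11)
  expect_equal(detect_docking(tr), 10 * 0.04)

  set.seed(3)
  flat <- new_particle_trace(1L, NA, NA, stats::rnorm(60, 100, 5),
                             stats::rnorm(60, 100, 5), 0.04)
  expect_true(is.na(detect_docking(flat)))

  short <- new_particle_trace(1L, NA, NA, 1:5, 1:5, 0.04)
  expect_error(detect_docking(short), ">= 10 frames")
})

test_that("docking times match ground truth on a noise-free movie", {
  pre <- get_preset("DCV")
  opt <- default_optics("DCV")
  sim <- simulate_movie(pre, opt, 6, 25, seed = 11, noise = FALSE)
  res <- quiet_analyze(sim$label, label_kind = "protein")
  m <- match_truth(res$positions, sim$truth)
  ev <- events_as_data_frame(res$events)
  expect_false(any(is.na(m)))
  expect_true(all(abs(ev$dock_time - sim$truth$dock_time[m]) <=
                    opt$frame_interval + 1e-9))
})

test_that("worked synaptic-vesicle trace times dock-to-onset at ~250 ms", {
  sv <- sv_example_trace()
  dock <- detect_docking(sv)
  ev <- classify_and_time_fusion(sv, "small_dye", dock_time = dock)
  expect_true(ev$fused)
  interval <- ev$pore_onset_time - dock
  expect_lte(abs(interval - 0.25), 0.04 + 1e-9)
})

test_that("flat post-dock traces are classified docked-only", {
  tr <- step_trace(11, lo = 0, hi = 80, n = 60)
  ev <- classify_and_time_fusion(tr, "small_dye")
  expect_false(ev$fused)
  ev2 <- classify_and_time_fusion(tr, "protein")
  expect_false(ev2$fused)
})

test_that("dual-label lags reproduce the preset pore and collapse lags", {
  pre <- get_preset("DCV")
  trs <- dual_traces(pre, frame_interval = 0.05)
  # dye leads protein by exactly the pore-widening lag (noise-free)
  expect_equal(measure_dual_label_lag(trs$dye, trs$protein), 0.2)
  # protein onset to collapse equals the collapse lag
  ev <- classify_and_time_fusion(trs$protein, "protein")
  expect_true(ev$fused)
  expect_equal(ev$collapse_time - ev$protein_onset_time, 0.6)

  # zero pore-widening lag gives zero dual-label lag
  pre0 <- vesicle_preset("x", 50, 8, "dual", fusion_rate_k = 1 / 3.3,
                         pore_widen_lag = 0)
  trs0 <- dual_traces(pre0, frame_interval = 0.05)
  expect_equal(measure_dual_label_lag(trs0$dye, trs0$protein), 0)

  # undefined when one channel shows no fusion
  flat <- step_trace(11, n = length(trs$dye$central),
                     frame_interval = 0.05)
  expect_error(measure_dual_label_lag(trs$dye, flat), "no fusion")
})

test_that("calcium arrival measurement handles step, ramp and no-rise", {
  x <- c(rep(0, 50), rep(1000, 50))
  m <- measure_calcium_arrival(x, 0.04)
  expect_lte(m$delta_t_ca, 0.04)
  expect_lt(abs(m$t_arrival - 50 * 0.04), 0.04 + 1e-9)

  opt <- optics_config(frame_interval = 0.04)
  ca <- simulate_calcium_arrival(opt, t_start = 2.013,
                                 ramp_duration = 0.4, noise_sd = 0)
  m2 <- measure_calcium_arrival(apply(ca$stack$frames, 3, mean), 0.04)
  expect_lt(abs(m2$delta_t_ca - 0.4), 0.08 + 1e-9)

  expect_error(measure_calcium_arrival(rep(5, 100), 0.04), "plateau")
})

fake_event <- function(id, onset = NA, dock = 0) {
  structure(list(particle_id = id, dock_time = dock,
                 fused = !is.na(onset), pore_onset_time = onset,
                 protein_onset_time = NA_real_,
                 collapse_time = NA_real_, label_kind = "small_dye"),
            class = "event_record")
}

fake_arrival <- function(t) {
  structure(list(t_commence = t - 0.1, t_saturate = t + 0.1,
                 delta_t_ca = 0.2, t_arrival = t),
            class = "calcium_arrival")
}

test_that("delay tables count, exclude and shift correctly", {
  arr <- fake_arrival(2)
  evs <- list(fake_event(1, onset = 2), fake_event(2, onset = 3.5),
              fake_event(3, onset = 2.7), fake_event(4), fake_event(5))
  tab <- compute_delays(evs, arr, condition = "test")
  expect_equal(tab$n_docked, 5)
  expect_equal(tab$n_fused, 3)
  expect_equal(sort(tab$delays), c(0, 0.7, 1.5))
  expect_equal(tab$n_fused / tab$n_docked, 0.6)

  # onsets before arrival are excluded as spontaneous, with a count
  evs2 <- c(evs, list(fake_event(6, onset = 1.5)))
  expect_message(tab2 <- compute_delays(evs2, arr), "excluded")
  expect_equal(tab2$n_excluded, 1)
  expect_equal(tab2$n_fused, 3)

  # invariance to a uniform time shift of events and arrival
  shift <- 11.3
  evs_s <- lapply(evs, function(e) {
    if (e$fused) e$pore_onset_time <- e$pore_onset_time + shift
    e
  })
  tab_s <- compute_delays(evs_s, fake_arrival(2 + shift))
  expect_equal(sort(tab_s$delays), sort(tab$delays))
})

test_that("docking statistics normalize to the reference condition", {
  counts <- data.frame(condition = c("tSNARE", "noSNAP25", "Munc18"),
                       n_docked = c(200, 100, 150),
                       n_fused = c(150, 10, 30))
  st <- docking_stats(counts, "tSNARE")
  expect_equal(st$normalized_docking, c(1, 0.5, 0.75))
  expect_equal(st$fusion_probability, c(0.75, 0.1, 0.2))

  zero <- data.frame(condition = "ref", n_docked = 0)
  expect_error(docking_stats(zero, "ref"), "> 0")
  expect_error(docking_stats(counts, "missing"), "not found")

  # docking disabled (count 0) normalizes to 0
  none <- data.frame(condition = c("ref", "noSNARE"),
                     n_docked = c(120, 0))
  expect_equal(docking_stats(none, "ref")$normalized_docking, c(1, 0))
})

test_that("noise-free calcium-mode movies are timed within one frame", {
  pre <- get_preset("SV")
  opt <- default_optics("SV")
  sim <- simulate_movie(pre, opt, 6, 12,
                        calcium = list(t_start = 2, ramp_duration = 0.3,
                                       noise_sd = 0),
                        seed = 21, noise = FALSE)
  res <- quiet_analyze(sim$label, label_kind = "small_dye",
                       calcium = sim$calcium$stack)
  m <- match_truth(res$positions, sim$truth)
  ev <- events_as_data_frame(res$events)
  expect_false(any(is.na(m)))
  expect_equal(sum(ev$fused), sum(sim$truth$fused))
  fi <- opt$frame_interval
  fused <- which(sim$truth$fused[m])
  err <- ev$pore_onset_time[fused] - sim$truth$pore_time[m][fused]
  expect_true(all(abs(err) <= fi + 1e-9))
  # delays referenced to measured arrival match truth within 2 frames
  # (onset and arrival each quantized by at most one frame)
  true_delay <- sim$truth$pore_time[m][fused] - sim$calcium$t_arrival
  expect_true(all(abs(sort(res$delays$delays) - sort(true_delay)) <=
                    2 * fi + 1e-9))
})

test_that("noisy movies keep recall and timing within tolerance", {
  pre <- get_preset("DCV")
  opt <- default_optics("DCV")
  fi <- opt$frame_interval
  n_found <- 0; n_total <- 0; time_ok <- 0; time_all <- 0
  for (s in 1:10) {
    sim <- simulate_movie(pre, opt, 5, 20,
                          calcium = list(t_start = 2,
                                         ramp_duration = 0.3),
                          seed = s, noise = TRUE)
    res <- quiet_analyze(sim$label, label_kind = "protein",
                         calcium = sim$calcium$stack)
    m <- match_truth(res$positions, sim$truth)
    n_found <- n_found + sum(!is.na(m))
    n_total <- n_total + 5
    ev <- events_as_data_frame(res$events)
    fused <- which(!is.na(m) & sim$truth$fused[m] & ev$fused)
    err <- abs(ev$protein_onset_time[fused] -
                 sim$truth$protein_onset_time[m][fused])
    time_all <- time_all + length(err)
    time_ok <- time_ok + sum(err <= 2 * fi + 1e-9)
  }
  expect_gte(n_found / n_total, 0.95)
  expect_gte(time_ok / time_all, 0.95)
})
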