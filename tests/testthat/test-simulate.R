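test_that("delay sampler follows the exponential law and fusion probability", {
  # mean of exponential delays at the synaptic-vesicle rate scale
  d <- sample_delay_times(k = 4.4, p_fuse = 1, n = 1e5, seed = 1)
  expect_true(all(d$fused))
  sem <- (1 / 4.4) / sqrt(1e5)
  expect_lt(abs(mean(d$delay) - 1 / 4.4), 3 * sem)

  # closed-form CDF oracle: ECDF at the median of Exp(2) is 1/2
  d2 <- sample_delay_times(k = 2, p_fuse = 1, n = 1e5, seed = 2)
  p_hat <- mean(d2$delay <= log(2) / 2)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 1e5))

  # zero fusion probability: nobody fuses, no delays
  d0 <- sample_delay_times(k = 1, p_fuse = 0, n = 50, seed = 3)
  expect_false(any(d0$fused))
  expect_true(all(is.na(d0$delay)))

  # seed determinism
  expect_identical(sample_delay_times(2, 0.5, 100, seed = 9),
                   sample_delay_times(2, 0.5, 100, seed = 9))

  expect_error(sample_delay_times(-1, 1, 10), "k must")
  expect_error(sample_delay_times(1, 1.5, 10), "p_fuse")
})

test_that("empirical delay CDF converges to 1 - exp(-k t)", {
  for (s in 1:3) {
    d <- sample_delay_times(k = 2, p_fuse = 1, n = 1e4, seed = s)
    ks <- suppressWarnings(
      stats::ks.test(d$delay, stats::pexp, rate = 2)$statistic)
    expect_lt(unname(ks), 0.02)
  }
})

test_that("trace model reproduces the four-phase line shape", {
  pre <- get_preset("DCV")
  opt <- optics_config(frame_interval = 0.05, penetration_depth = 100)
  tru <- example_truth(pre, dock_time = 1, radius = 50)
  times <- seq(0, 60, by = 0.01)
  tr <- trace_model(pre, opt, tru, times, label_kind = "dual")

  # phase I: baseline before docking
  expect_true(all(tr[times < tru$dock_time, ] == 0))

  # phase II: docked plateau attenuated by the evanescent factor
  ev <- exp(-50 / 100) # independent evaluation
  mid <- times > tru$dock_time & times < tru$pore_time
  expect_equal(unique(tr[mid, "protein"]), pre$brightness * ev)
  expect_equal(unique(tr[mid, "dye"]),
               pre$brightness * pre$quench_factor * ev)

  # dye jumps to the dequenched surface-proximal peak at pore opening
  at_pore <- which(times >= tru$pore_time)[1]
  expect_equal(unname(tr[at_pore, "dye"]), pre$brightness)

  # collapse jump multiplies remaining content by exp(zbar/d) = e^0.5
  before <- pre$brightness * ev *
    exp(-(tru$collapse_time - tru$protein_onset_time) / pre$collapse_lag)
  at_coll <- which(times >= tru$collapse_time)[1]
  expect_equal(unname(tr[at_coll, "protein"]) / before, exp(0.5),
               tolerance = 1e-6)

  # both labels decay to baseline long after collapse
  expect_lt(tr[length(times), "protein"], 0.01 * pre$brightness)
  expect_lt(tr[length(times), "dye"], 0.01 * pre$brightness)

  # ordering: dye onset precedes protein onset by pore_widen_lag
  expect_equal(tru$protein_onset_time - tru$pore_time, pre$pore_widen_lag)

  expect_error(trace_model(pre, opt, tru, c(2, 1, 3)), "sorted")
})

test_that("non-fused vesicles keep the docked plateau", {
  pre <- get_preset("INSULIN")
  opt <- default_optics("INSULIN")
  tru <- ground_truth_record(radius = 120, dock_time = 2, fused = FALSE)
  times <- seq(0, 30, by = 0.2)
  tr <- trace_model(pre, opt, tru, times)
  plateau <- pre$brightness * exp(-120 / opt$penetration_depth)
  expect_equal(unique(tr[times >= 2, "protein"]), plateau)
})

test_that("calcium arrival simulation is measurable and within bounds", {
  opt <- optics_config(frame_interval = 0.04)

  # degenerate step: measured spread within one frame
  ca0 <- simulate_calcium_arrival(opt, t_start = 2, ramp_duration = 0,
                                  noise_sd = 0)
  m0 <- measure_calcium_arrival(apply(ca0$stack$frames, 3, mean), 0.04)
  expect_lte(m0$delta_t_ca, 0.04)
  expect_lt(abs(m0$t_arrival - 2), 0.04 + 1e-9)

  # 0.4 s linear ramp recovered within 2 frames (10-90% threshold proxy)
  ca <- simulate_calcium_arrival(opt, t_start = 2.013,
                                 ramp_duration = 0.4, noise_sd = 0)
  m <- measure_calcium_arrival(apply(ca$stack$frames, 3, mean), 0.04)
  expect_lt(abs(m$delta_t_ca - 0.4), 0.08 + 1e-9)
  expect_equal(ca$ramp_duration, 0.4)

  # default perfusion presets stay under the 0.5 s bound at both frame
  # intervals used in the assay
  for (fi in c(0.04, 0.2)) {
    ca <- simulate_calcium_arrival(optics_config(frame_interval = fi),
                                   seed = 3)
    m <- measure_calcium_arrival(apply(ca$stack$frames, 3, mean), fi)
    expect_lt(m$delta_t_ca, 0.5)
  }

  expect_error(simulate_calcium_arrival(opt, ramp_duration = -1),
               "durations")
})

test_that("diameter sampler matches its truncated-normal law", {
  pre <- get_preset("DCV")
  degen <- vesicle_preset("x", radius_mean = 50, radius_sd = 0,
                          label_kind = "protein", fusion_rate_k = 1)
  expect_equal(sample_diameters(degen, 5, seed = 1), rep(100, 5))

  d <- sample_diameters(pre, 1e5, seed = 1)
  expect_true(all(d > 0))
  sem <- 2 * pre$radius_sd / sqrt(1e5)
  expect_lt(abs(mean(d) - 2 * pre$radius_mean), 3 * sem)

  # curvature ordering across the packaged presets
  curv <- vapply(default_presets(), function(p)
    as.numeric(mean_curvature(sample_diameters(p, 2000, seed = 4))),
    numeric(1))
  expect_true(curv[["SV"]] > curv[["DCV"]])
  expect_true(curv[["DCV"]] > curv[["INSULIN"]])
})

test_that("movie generator is deterministic and conserves photons", {
  pre <- get_preset("DCV")
  opt <- default_optics("DCV")

  # empty field: frames are pure background noise, nothing detected
  sim0 <- simulate_movie(pre, opt, n_vesicles = 0, duration = 5, seed = 1)
  pos0 <- detect_particles(max_projection(sim0$label))
  expect_identical(nrow(pos0), 0L)

  # seed determinism: bit-identical frames and ground truth
  a <- simulate_movie(pre, opt, 5, 15, seed = 42)
  b <- simulate_movie(pre, opt, 5, 15, seed = 42)
  expect_identical(a$label$frames, b$label$frames)
  expect_identical(a$truth, b$truth)

  # photon conservation: noise-free, zero-background single vesicle -
  # the summed field equals the trace at every frame (PSF mass ~ 1)
  opt0 <- optics_config(frame_interval = 0.2, background_rate = 0,
                        read_noise_sd = 0)
  sim1 <- simulate_movie(pre, opt0, 1, 15, seed = 5, noise = FALSE)
  times <- frame_times(sim1$label)
  tr <- trace_model(pre, opt0, sim1$truth[1, ], times,
                    label_kind = "protein")[, "protein"]
  field_sum <- apply(sim1$label$frames, 3, sum)
  nz <- tr > 0
  expect_lt(max(abs(field_sum[nz] - tr[nz]) / tr[nz]), 1e-3)

  # placement failure on an impossibly small field
  expect_error(simulate_movie(pre, opt, 50, 5, width = 20, height = 20),
               "field too small")
})
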