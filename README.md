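# svfusion

Simulation and kinetic analysis of single-vesicle supported-membrane fusion
assays.

In these assays, secretory vesicles purified from native sources — synaptic
vesicles, dense-core (chromaffin-type) vesicles, insulin vesicles — dock onto
a planar bilayer reconstituted with plasma-membrane SNAREs and are imaged one
at a time by TIRF microscopy. The content label of each vesicle traces a
characteristic intensity line shape through docking, fusion-pore opening and
collapse into the planar membrane; after triggering docked vesicles with a
calcium perfusion, the per-vesicle delays between calcium arrival and fusion
onset follow (near-)exponential distributions whose rate constant `k`
characterizes the vesicle type. Across types, the fitted rates test an
Arrhenius picture in which the fusion activation energy is linear in
membrane curvature, `ln k = a + b·(1/R)`.

The package is aimed at people building or validating analysis pipelines for
such assays. It provides:

- **simulation** — per-vesicle line shapes (`trace_model()`), delay and
  diameter samplers, calcium-perfusion traces, and full movies with Gaussian
  PSF spots and EMCCD-like noise plus ground truth (`simulate_movie()`),
  with packaged presets for the three vesicle types
  (`default_presets()`: time constants 0.23, 3.3 and 9.1 s);
- **detection** — temporal moving-average filter, maximum-intensity
  projection, robust spot detection, and central-pixel / 5×5-ROI trace
  extraction (`detect_particles()`, `extract_traces()`);
- **event timing** — docking, fusion onset (dye rise / protein fall),
  collapse, dual-label lag, calcium arrival, and delay tables
  (`classify_and_time_fusion()`, `measure_calcium_arrival()`,
  `compute_delays()`, `docking_stats()`);
- **kinetics** — maximum-likelihood single-exponential fits with right
  censoring and bootstrap CIs, sequential-step (gamma) fits with AIC step
  selection, rate-ratio comparisons, and the curvature–rate fit
  (`fit_single_exponential()`, `fit_sequential_steps()`,
  `fit_curvature_model()`);
- **pipeline** — `run_simulate()` / `run_analyze()` / `run_fit()` writing
  TIFF + JSON sidecars, CSV tables and JSON reports, plus a thin CLI at
  `inst/cli/svfusion`.

## Worked example

Recover the three fusion time constants from the packaged presets and fit
the curvature relation:

```r
library(svfusion)

presets <- default_presets()
fits <- list()
for (i in seq_along(presets)) {
  p <- presets[[i]]
  d <- sample_delay_times(p$fusion_rate_k, p_fuse = 1, n = 500, seed = i)
  fits[[p$name]] <- fit_single_exponential(d$delay, n_boot = 1000,
                                           seed = 10 + i)
}
fits$SV
#> single_exponential fit: k = 4.36 1/s (tau = 0.2294 s), 95% CI [4.021, 4.764] 1/s
#>   n = 500 events, logLik = 236.18, AIC = -470.36
fits$DCV
#> single_exponential fit: k = 0.293 1/s (tau = 3.412 s), 95% CI [0.2718, 0.3175] 1/s
#>   n = 500 events, logLik = -1113.72, AIC = 2229.44
fits$INSULIN
#> single_exponential fit: k = 0.11 1/s (tau = 9.092 s), 95% CI [0.1006, 0.1206] 1/s
#>   n = 500 events, logLik = -1603.72, AIC = 3209.45
```

Each fit recovers its generating time constant (0.23, 3.3, 9.1 s) inside the
bootstrap CI. Reducing cryo-EM-style diameter samples to mean curvatures and
regressing `ln k` on `1/R`:

```r
pts <- data.frame(
  condition = names(presets),
  curvature = sapply(presets, function(p)
    as.numeric(mean_curvature(sample_diameters(p, 2000, seed = 2)))),
  rate_k = sapply(fits, `[[`, "rate_k"))
fit_curvature_model(pts)
#> curvature fit: ln k = -2.968 + 89.09 * (1/R)  [3 vesicle types]

compare_conditions(fits)
#>   numerator denominator     ratio   ci_low   ci_high
#> 1        SV         DCV 14.876737 13.27269 16.768781
#> 2        SV     INSULIN 39.638676 35.00621 44.597316
#> 3       DCV     INSULIN  2.664474  2.34805  3.027646
```

The positive slope says smaller (higher-curvature) vesicles fuse faster;
synaptic vesicles are ~15-fold faster than dense-core vesicles and ~40-fold
faster than insulin vesicles under these conditions. A movie-level round
trip — simulate, detect, time, fit — is a three-liner:

```r
r <- run_simulate(tempfile(), preset = "DCV", n_vesicles = 8,
                  duration = 20, calcium = TRUE, seed = 7)
a <- run_analyze(r$label, label_kind = "protein", calcium = r$calcium)
run_fit(list(DCV = a$delays), n_boot = 500)$fits$DCV
```

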