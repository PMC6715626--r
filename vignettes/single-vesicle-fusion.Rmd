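---
title: "Modeling and measuring single-vesicle fusion with svfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring single-vesicle fusion with svfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfusion)
```

## The assay and its observables

In the single-vesicle supported-membrane fusion assay, purified secretory
vesicles (synaptic vesicles, dense-core vesicles, insulin vesicles) are
allowed to dock onto a planar bilayer reconstituted with the plasma-membrane
SNAREs, under prism-TIRF illumination. The evanescent excitation field decays
as $e^{-z/d}$ with a penetration depth $d \approx 100$ nm, so the fluorescence
of a vesicle's content label reports its distance from the surface. Docking,
fusion-pore opening, and final collapse of the vesicle into the planar
membrane each leave a characteristic signature in the intensity trace of the
diffraction-limited spot. When vesicles are first arrested in a docked state
(Munc18/complexin) and then triggered by perfusing calcium, the distribution
of per-vesicle delays between calcium arrival and fusion onset defines the
fusion rate constant $k$; comparing $k$ across vesicle types of different
radius $R$ probes whether the fusion activation energy scales with membrane
curvature $1/R$.

`svfusion` implements this entire chain twice over: a generative model
(simulator) that encodes the line-shape physics and the study conditions, and
an analysis chain (detection, event timing, kinetics) that must recover the
generator's ground truth. The tests hold the two against each other.

## The intensity line-shape model

`trace_model()` evaluates the noise-free ROI intensity of one vesicle through
four phases:

1. **Absent** -- baseline (0 above background) before `dock_time`.
2. **Docked** -- the label sits at its center of mass, one vesicle radius
   above the membrane, so the plateau is $B\,e^{-R/d}$ for a protein label
   and $B\,q\,e^{-R/d}$ for a self-quenched intralumenal dye with residual
   fluorescence fraction $q$ (acridine orange self-quenches in the acidic
   lumen).
3. **Pore open** -- a narrow fusion pore passes small dye immediately: the
   dye dequenches ($q \to 1$) and drops to the surface ($z \to 0$), an
   instantaneous jump to $B$, followed by diffusive escape from the ROI.
   Protein cargo is too bulky for the narrow pore; its signal instead
   *decreases* from `protein_onset_time = pore_time + pore_widen_lag` as
   content slowly escapes. We model that slow efflux as a single exponential
   with time constant equal to `collapse_lag` -- the minimal one-parameter
   form, since no functional form is known.
4. **Collapse** -- at `collapse_time` the vesicle flattens into the bilayer:
   remaining protein content moves from height $R$ to the surface, an upward
   jump by exactly $e^{R/d}$, followed by the same diffusive ROI escape.

Released label diffuses laterally in the thin cleft between the supported
membrane and the substrate, a quasi-2D space. For a 2D point source, the
fraction still inside a disc of radius $a$ after time $t$ is
$1 - e^{-a^2/(4Dt)}$; we use $a = 2.5$ pixels (the half-width of the standard
5x5 ROI) in physical units. The cleft diffusion coefficient $D$ is not
experimentally constrained; the default $D = 0.1\ \mu m^2/s$ gives an ROI
residence time $a^2/4D \approx 0.4$ s, consistent with the ~1 s decay of spot
fluorescence after fusion seen at 200 ms frame intervals. With
$D = 1\ \mu m^2/s$ the ROI would empty within a fraction of one frame and the
collapse spike would be invisible at the standard acquisition rate -- this is
what fixes the scale of a free parameter.

```{r lineshape}
pre <- get_preset("DCV")
opt <- optics_config(frame_interval = 0.05)
times <- seq(0, 5, by = 0.05)
tr <- trace_model(pre, opt, example_truth(pre), times, label_kind = "dual")
matplot(times, tr, type = "l", lty = 1, col = c("red", "black"),
        xlab = "time (s)", ylab = "ROI intensity (counts/frame)")
legend("topright", c("small dye", "protein"), lty = 1,
       col = c("red", "black"))
```

## Presets: the study conditions

`default_presets()` encodes the three vesicle types with their published
fusion time constants; these are the generator's defaults and are never tuned:

| preset | label | $\tau = 1/k$ | radius (nm) | frames |
|---|---|---|---|---|
| SV | small dye | 0.23 s | 20 +/- 2.5 | 40 ms |
| DCV | dual (protein + dye) | 3.3 s | 50 +/- 8 | 200 ms |
| INSULIN | protein | 9.1 s | 120 +/- 15 | 200 ms |

Radii follow conventional literature scales for the three organelles
(~40, ~100, ~240 nm diameters); only their ordering matters downstream
(smaller vesicle, higher curvature, faster fusion). The pore-widening lag
(dye leads protein by 0.2 s) and collapse lag (0.6 s) are the characteristic
dual-label intervals of dense-core vesicle events; `dock_to_pore = 0.25` s is
the canonical dock-to-onset interval of the worked synaptic-vesicle example
trace. Fusion probability defaults to 0.9 (calcium triggers fusion of nearly
all docked vesicles); brightness (2000 counts/frame), quench factor (0.2),
and the EMCCD noise model (Poisson shot noise then additive Gaussian read
noise of SD 10 on a background of 100 counts/pixel/frame, EM-gain excess
noise folded into the read noise) are realistic scales chosen once. Movies
place spots at least $6\sigma_{PSF}$ apart by rejection sampling.

In calcium-triggered mode all vesicles are docked before frame 0 (docking is
allowed to proceed for many minutes before the triggering injection in the
experiment) and the fusion clock starts at the true arrival midpoint. Fusion
events that would not complete within the recording are counted docked-only
(right-censored).

## Calcium arrival

The perfusion channel is spatially uniform: zero, a monotone linear rise of
duration `ramp_duration`, then saturation. `measure_calcium_arrival()` reads
commencement at a sustained 10% crossing of the baseline-to-plateau span,
saturation at 90%, and the arrival reference time at 50% -- a symmetric,
frame-robust proxy. On a linear ramp the 10-90% width is 0.8x the full ramp,
so the measured $\Delta t_{Ca}$ slightly under-reports the nominal ramp; this
known bias is within the assay's two-frame reading tolerance and well inside
the < 0.5 s operating bound of the default perfusion settings (0.4 s ramp).

## Event detection and timing conventions

Detection follows the standard chain: temporal moving-average filter
(default window 3 frames; the value is not prescribed anywhere, 3 is the
smallest centered window), per-pixel maximum projection, Gaussian smoothing
matched to the PSF, robust threshold (median + $n\sigma$ MAD, default 5), and
3x3 local maxima merged below a minimum separation. Event *timing* always
uses the unfiltered central-pixel series: filtering would blur onsets.
Positions are 1-based `(row, col)` integer pixel centers -- the natural
indexing convention in R; the 5x5 ROI is centered on the detected pixel.

Timing rules, all on the central pixel:

- **Docking**: first of 2 consecutive frames above the causal baseline
  median + $3\sigma$.
- **Fusion onset**: first of 3 consecutive frames beyond the docked-plateau
  median $\pm 2\sigma$ (up for dye, down for protein), searched from 4 frames
  after docking so the plateau level is stable.
- **Collapse**: the largest upward frame-to-frame jump after the protein
  onset, accepted above $2\sqrt{2}\sigma$.
- $\sigma$ is a trace-wide robust noise scale, MAD of successive
  differences divided by $\sqrt 2$, floored so that noise-free traces
  respond to any real change. Estimating $\sigma$ per-window from a short
  growing plateau, with only 2 sustained frames required, produced
  seconds-early false onsets in a large fraction of noisy traces; the
  trace-wide estimate with a 3-frame criterion meets the package's timing
  invariant (all onsets within 1 frame noise-free, 95% within 2 frames at
  SNR >= 10) while leaving noise-free timing exact.

When no docking step exists in the recording (calcium-triggered mode), the
recording start is taken as the docked plateau and `dock_time` stays `NA`.
All measured times are quantized to the frame grid (the first frame at or
after the true event), so every deterministic check in the package carries a
one-frame tolerance. A 250 ms dock-to-onset interval sampled at 40 ms frames,
for instance, reads 240 ms (6.25 frames cannot be observed; the ceiling
difference gives 6 frames for the packaged example's dock phase).

Delays are `onset - t_arrival`, using the dye onset when available (it marks
pore opening directly; the protein onset trails it by the pore-widening lag).
Fused events with onset before the measured arrival are excluded as
spontaneous, with a reported count. Docked-only vesicles enter `n_docked`
(hence fusion probability) but not the delay distribution; the kinetics
module can treat them as right-censored.

## Kinetics

Rates are estimated by maximum likelihood on the delays themselves rather
than least squares on the plotted CDF: the ML estimator is efficient and
makes right censoring principled. For the exponential model
$\hat k = n_{events} / (\sum t_i + \sum c_j)$ with censoring times $c_j$;
adding censored observations can only lower $\hat k$. Uncertainties are
percentile bootstrap intervals (default 1000 resamples, seeded). Sequential
priming steps are modeled as a gamma distribution with integer shape
$m$ = step count and one free rate; for each candidate $m \in 1..5$ the rate
MLE is $m/\bar t$, and AIC (one free parameter per candidate) selects $m$.
$m = 1$ reproduces the single-exponential fit exactly, AIC included, so a
sigmoidal (multi-step) shape is never inferred from exponential data.

The curvature relation assumes the fusion activation energy is linear in
membrane curvature, giving $\ln k = a + b\,(1/R)$, fitted by least squares
through the per-type points. Mean curvature defaults to $1/\bar R$ (the
reciprocal of the mean radius); the alternative $\overline{1/R}$ is
implemented and recorded in the output, since the reduction of a diameter
distribution to "mean curvature" is ambiguous. No physical activation energy
is reported: the Arrhenius prefactor is unknown, so only the log-linear
relation and its sign are meaningful.

No time offset for the perfusion spread is subtracted before fitting: for
the fastest vesicles the calcium rise time is on the same scale as $1/k$, so
the fitted SV rate is a lower bound on the instantaneous-calcium rate. A
shifted-exponential mode would deconvolve this but is deliberately not the
default, matching how the measured delays are defined.

## What the simulator does and does not emulate

It emulates: evanescent-field attenuation of docked labels, the
dye-before-protein pore signature, the collapse spike, cleft-confined 2D
diffusive escape, exponential (or censored) fusion delays, a docked
non-fusing subpopulation, perfusion ramps, Gaussian PSF rendering, and
Poisson + Gaussian camera noise at EMCCD-like scales.

It does not emulate: bleaching, hindered or anomalous diffusion in the
cleft, 3D sectioning or polarization effects, drift, vesicle mobility before
docking, EM-gain register stochastics, or spatial background structure.
Passing tests therefore demonstrate correctness of the measurement chain
under the modeled physics, not robustness to every artifact of real
recordings.

Problem sizes used in the test-suite simulations (48x48 to 128x128 pixel
fields, 5-10 vesicles, 60-125 frames, n = 300-10^4 delays, 20-50 fit
replicates) are the package's chosen desk-scale study conditions: large
enough that every estimator is exercised in its asymptotic regime, small
enough to iterate on quickly.

## Numerical choices and degenerate inputs

- Robust statistics throughout (median/MAD) make detection invariant to
  constant background offsets.
- All SD estimates are floored (at $10^{-6}$ of the trace scale) so
  noise-free traces never divide by zero and respond to any real change.
- The 2D escape fraction is clamped to 1 at $t \le 0$ (the jump instant).
- Zero fusion probability, empty fields, blank movies, step (zero-width)
  calcium ramps, and all-censored delay sets are all defined, tested cases.
- Ties in spot merging resolve to the brighter peak; equal-brightness ties
  follow detection order (row-major).
- Every stochastic routine takes an explicit integer seed and is
  bit-reproducible; movie sidecars record seeds and resolved configs.

## Known limitations

- Frame quantization bounds all timing accuracy at one frame interval; no
  sub-frame interpolation is attempted (onsets are steps or kinks, where
  interpolation is ill-posed).
- The dual-label movie renderer writes only the protein channel; dual-label
  *trace* analysis is fully supported, movie-level two-channel rendering is
  not.
- The gamma step model fixes integer shapes 1-5; fractional-shape fits are
  out of scope.
- `mean_curvature()` reduces a full diameter distribution to one number; if
  rate heterogeneity within a vesicle population correlates with size, the
  pooled fit hides it.
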