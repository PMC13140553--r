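---
title: "Estimating persistent inward current contributions from paired motor units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating persistent inward current contributions from paired motor units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Spinal motoneurons do not translate synaptic drive into firing linearly.
Monoaminergic input (serotonin, noradrenaline) from the brainstem opens
dendritic L-type Ca^2+^ and persistent Na^+^ channels, producing
*persistent inward currents* (PICs) that accelerate, amplify and prolong
firing for a given excitatory input. In humans PIC activity can only be
estimated indirectly, from the discharge patterns of motor units (MUs)
decomposed from multi-channel surface EMG during slow ramp contractions.

`picmetrics` implements the standard estimation chain for triangular
isometric ramps (here: dorsiflexion to 20 % of maximal voluntary torque,
MVT, at 2 %MVT/s; 10 s up, 10 s down):

* **ΔF** (paired-MU analysis): the drop in a lower-threshold *control*
  unit's smoothed discharge rate between a higher-threshold *test* unit's
  recruitment and derecruitment. Because the control unit's rate proxies
  the common synaptic drive, ΔF measures the test unit's
  recruitment–derecruitment hysteresis in units of drive-equivalent firing
  rate (pps) — the classic signature of PIC-assisted self-sustained
  firing.
* **Brace height**: the maximal orthogonal deviation of the ascending
  smoothed rate from the straight line joining recruitment to peak,
  normalised as a percentage of the corresponding right-triangle vertex
  distance (% rTri). It captures the concave acceleration–saturation
  profile that strong neuromodulation imposes on firing, and is read as a
  proxy for neuromodulatory drive.
* **Attenuation slope**: the least-squares slope of smoothed rate against
  torque (%MVT) from the brace-height insertion point to the ascending
  peak (pps/%MVT), read as a proxy for the pattern of inhibitory input.
* **Peak discharge rate** and **recruitment/derecruitment thresholds**
  (torque, % of peak, at first/last discharge).
* **Contraction impulse** (∫F dt, trapezoidal rule) for the interspersed
  handgrip prescriptions; 40 % × 30 s and 80 % × 15 s are impulse matched
  and each carries twice the impulse of 40 % × 15 s.

Before/after changes across the four conditions (Control, 40%15s, 40%30s,
80%15s) are then contrasted with linear mixed-effects models.

## Pipeline stages and their assumptions

1. **Torque processing.** The torque trace is low-pass filtered with a
   fifth-order Butterworth at 10 Hz, applied forward–backward. Zero-phase
   filtering is used so that recruitment/derecruitment thresholds read off
   the torque record are not delayed by the filter; the effective
   magnitude response is the squared single-pass response
   |H(f)|² = 1/(1+(f/10)^10). The trace is point-reflect padded (10·fs/fc
   samples) to suppress start-up transients. Ramp quality control fails a
   trial when |performed − target| exceeds 5 % of peak torque anywhere on
   the ramp, evaluated on the filtered trace; the time-integrated absolute
   deviation is reported as a tracking-consistency metric.
2. **Discharge-rate smoothing.** Instantaneous rates (1/ISI) are smoothed
   by ε-insensitive support vector regression with a radial-basis kernel
   and evaluated on a 0.01 s grid over the unit's firing span. Landmarks:
   recruitment = first firing, derecruitment = last firing, peak = the
   earliest grid time attaining the maximum.
3. **Pairing and ΔF.** Every ordered (control, test) pair with the control
   recruited first is screened by the four standard criteria:
   rate–rate correlation of the smoothed curves ≥ 0.7 on the common
   support; recruitment-time gap > 1 s; control-unit rate modulation
   (peak − rate at test recruitment) > 0.5 pps; control derecruits after
   the test unit. Pairwise ΔF values are averaged per test unit.
4. **Geometry.** The ascending segment is mapped to the unit square (time
   and rate each affinely scaled over recruitment→peak); brace height is
   100·√2·max signed orthogonal deviation from the (0,0)→(1,1) chord.
   This normalisation makes the measure exactly invariant to separate
   affine rescaling of either axis, which is what allows "% rTri" to be
   compared across units and sessions.
5. **Contrasts.** REML linear mixed-effects fit per outcome with phase,
   condition and their interaction as fixed effects, response-specific
   covariates, and random intercepts for participant and for unit nested
   in participant and condition (units are only tracked across the two
   phases of one condition, never across conditions). Marginal means are
   evaluated at the covariates' grand means; after − before differences
   are reported with Wald 95 % and 90 % intervals, and Cohen's
   d = difference/σ with σ the square root of the summed random-effect and
   residual variances.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| SVR cost C | 50 | – | strong data fidelity; smoothness comes from the kernel scale |
| SVR ε | 0.01 | pps | kept near zero: a wide insensitivity tube caps curve accuracy at ~ε even on clean data; smoothing is the kernel's job |
| SVR length-scale | 0.4 | s | tracks rate modulations on the seconds scale, rejects ISI jitter |
| grid step Δt | 0.01 | s | finer than any landmark tolerance used downstream |
| pairing r | ≥ 0.7 | – | standard common-drive screen |
| recruitment gap | > 1 | s | guarantees separable recruitment |
| control modulation | > 0.5 | pps | control must still modulate when the test unit recruits |
| QC deviation | 5 | % peak torque | trial exclusion threshold for abrupt tracking errors |
| PNR gate | ≥ 30 | dB | decomposition reliability cut-off on provided metadata |

Two rate-placement conventions exist for instantaneous rates.
`instantaneous_rates()` reports the conventional end-of-interval
timestamps (rate 1/ISI at the interval's closing spike). For the
*regression*, `smooth_train()` places each rate at its interval midpoint:
end placement lags a changing rate by half an ISI, which would bias every
landmark read from the smoothed curve in the direction of the local rate
trend (for ΔF, a systematic underestimate of order gain × ramp-rate ×
ISI). Midpoint placement is the standard first-order correction and makes
the smoothed curve an unbiased estimate of the underlying rate profile.

One printed form of the third pairing criterion ("discharge rate at test
unit recruitment minus the control unit's peak discharge rate > 0.5 pps")
is negative for any control unit whose rate still rises after the test
unit recruits; it is implemented here in its standard form — peak rate
minus rate at test-unit recruitment > 0.5 pps — i.e. as a minimum
remaining modulation range of the control unit.

## The synthetic motoneuron pool

The simulator exists so that every estimator in the package can be tested
against known ground truth. It is phenomenological, not biophysical: the
pipeline consumes firing-rate phenomenology, so the generator produces
exactly that, with controllable hysteresis.

* Common drive E(t) = the triangular target path (%MVT) plus smooth
  tracking noise (spline through 1 Hz Gaussian knots, SD 0.3 %MVT).
* Unit i fires while E ≥ θ_i on the ascent and until E < θ_i − δ_i on the
  descent; δ_i (%MVT) is the ground-truth hysteresis.
* Rate model r(E) = r_min + g·(E − θ_i) + A·(1 − e^{−(E−θ_i)/s}) above
  threshold: a linear drive gain plus a saturating PIC-like acceleration.
  For a linear control unit the true pairwise ΔF is exactly
  g_control · δ_test; with A > 0 the closed-form rate model still gives
  the exact truth (`true_delta_f()`).
* Spikes are drawn by time rescaling as a gamma-renewal **bridge**
  conditioned on discharges at both window edges, so recruitment and
  derecruitment timing carry no ISI quantisation offset while ISI
  variability keeps the configured coefficient of variation (default
  0.15).
* Defaults are conventions for human tibialis anterior at a 20 %MVT ramp:
  g = 0.5 pps/%MVT, r_min = 6 pps, thresholds spread over 5–18 %MVT,
  hysteresis ~2 %MVT, acceleration amplitude 2 pps saturating over
  5 %MVT; participant-level variation in r_min and hysteresis creates the
  nesting structure the mixed models expect.
* Condition effects are additive shifts of δ and of the discharge rate
  applied to "after" trials of configured conditions. The defaults shift
  hysteresis in the two high-impulse conditions (+0.66 and +0.48 %MVT,
  chosen via the linear conversion g·δ to emulate observed ΔF effect
  sizes of about +0.3 and +0.25 pps; with the default acceleration term
  active the realised effects run somewhat larger) and raise rates
  slightly in the high-intensity condition.

What the simulator does **not** emulate: EMG decomposition errors and
spike-train editing, non-renewal ISI structure (doublets, synchronisation),
drive nonstationarities beyond smooth tracking error, fatigue within a
ramp, and any condition effect on the acceleration amplitude (so simulated
brace-height contrasts are near zero by design). Passing tests therefore
demonstrate correctness of the estimators under controlled firing-rate
phenomenology — not robustness to decomposition artefacts, which must be
handled upstream.

## Numerical choices

* SVR boundary handling: data within 3 length-scales of each support edge
  are point-reflected (odd reflection) about the edge before fitting;
  this preserves local linear trends and prevents the kernel smoother
  from flattening at recruitment/derecruitment. Times are centred at
  recruitment before fitting, making the curve equivariant under time
  translation up to solver tolerance.
* Degenerate inputs: trains shorter than 4 discharges are dropped
  (counted); rate sets whose range is within 2ε return the constant mean
  curve; monotone-decreasing smoothed curves have no ascending phase and
  are excluded from the geometry metrics; zero rate range makes brace
  height undefined for that unit.
* Ties at the smoothed maximum resolve to the earliest grid time.
* ΔF landmark reads use the nearest grid point (grid 0.01 s makes the
  interpolation error negligible); thresholds interpolate the filtered
  torque linearly at the landmark times.
* Mixed-model fits retry with the bobyqa optimiser before reporting
  non-convergence; a singular unit-level intercept triggers a documented
  refit without it. An iteratively-reweighted Huber refit
  (`robust = TRUE`, k = 1.345, residuals scaled by their MAD) is
  available for outlier-heavy tables; the default is the plain Gaussian
  REML fit.
* The "random intercept and slope per participant" formulation of the
  source models is ambiguous about the slope variable; the package
  interprets it as a phase (time) slope and leaves it off by default
  (`random_slope_time = FALSE`), since the intercept-only structure is
  what the remaining outcomes use.

## Validation problem sizes

The shipped validation uses: noiseless pools of 10 units for the exact
ΔF oracle; 30-unit pools × 20 seeds per hysteresis level (1–4 %MVT) at
ISI CV 0.15 for stochastic recovery; 5-point acceleration-amplitude grids
for brace-height monotonicity; 30 participants × 15 units for
injected-effect recovery (+0.30 pps, recovered to ±0.05); and 50
replicates of a 12 × 6 null design for CI calibration (observed coverage
≈ 94–96 %). These sizes are the package's choices, balancing Monte-Carlo
error against turnaround.

## Known limitations

* The mixed-model stage is a standard Gaussian REML fit; heavy-tailed
  per-unit outcome distributions are only addressed by the optional
  Huber refit, which is not a full robust-estimation framework.
* ΔF is read from SVR-smoothed curves; in regions of strong curvature
  (e.g. immediately around the ramp apex) kernel smoothing rounds the
  curve and can shift reads by up to ~0.1 pps for units recruited very
  close to the apex.
* Brace height assumes time on the abscissa of the unit square (rate vs
  time), matching the usual presentation of the ascending phase; an
  abscissa in torque would differ only through tracking error, since the
  ramp is linear in time.
* The derecruitment threshold reads the filtered descending-limb torque
  at the last discharge; no window averaging is applied.
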