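# picmetrics

Estimation of persistent inward current (PIC) contributions to human
motoneuron firing from motor-unit spike trains recorded during triangular
isometric ramp contractions — for motor-control and neurophysiology
researchers working with decomposed high-density surface EMG.

Spinal motoneurons amplify their synaptic input through dendritic
persistent inward currents under monoaminergic control. `picmetrics`
implements the standard non-invasive estimation chain for this
amplification and its modulation by interventions (here: remote handgrip
contractions of varying intensity, duration and impulse between paired
ramps):

* **ΔF** (paired motor-unit analysis): for a *control* unit c recruited
  before a *test* unit t,

  ΔF = r̂_c(t_rec,t) − r̂_c(t_derec,t)   [pps]

  where r̂_c is the control unit's discharge rate smoothed by support
  vector regression and t_rec/t_derec are the test unit's
  recruitment/derecruitment times. Pairs must satisfy the four standard
  criteria (rate–rate correlation r ≥ 0.7, recruitment gap > 1 s, control
  modulation > 0.5 pps, control derecruits last); pairwise values are
  averaged per test unit.
* **Brace height** (% rTri): maximal orthogonal deviation of the
  ascending smoothed rate from the recruitment→peak chord, normalised to
  the right-triangle vertex distance in the unit square — a geometry
  proxy for neuromodulatory drive.
* **Attenuation slope** (pps/%MVT): OLS slope of smoothed rate vs torque
  from the brace-height insertion to the ascending peak — a proxy for
  inhibitory input pattern.
* **Peak discharge rate**, **recruitment/derecruitment thresholds**
  (torque at first/last discharge, % of peak) and **handgrip impulse**
  (trapezoidal ∫F dt).
* **Condition contrasts**: linear mixed-effects models
  (phase × condition + covariates + participant and unit random
  intercepts) with estimated marginal after − before differences, 90/95 %
  Wald CIs and Cohen's d = difference/σ (σ from the summed variance
  components).

A synthetic motoneuron-pool generator with known recruitment thresholds,
rate gains and recruitment–derecruitment hysteresis (δ, %MVT) provides
exact ground truth — for a linear control unit the true pairwise ΔF is
gain × δ — so every stage is testable without external recordings.

## Worked example

Simulate a small study (6 participants, 8 units per ramp, hysteresis
raised in the two high-impulse handgrip conditions after the
intervention), run the per-unit pipeline and contrast the conditions:

```r
library(picmetrics)
cfg <- pipeline_config(
  pool = pool_config(n_participants = 6, units_per_trial = 8, seed = 7))
res <- run_end_to_end(cfg)
res
#> <pipeline_result>
#>   units: 384 loaded, 384 analysed, 0 short-train
#>   trials failing QC: 0
#>   delta_f after-before contrasts:
#>  condition after_minus_before ci95_lo ci95_hi cohens_d
#>    Control             -0.111 -0.5617   0.339   -0.111
#>     40%15s              0.451 -0.0156   0.917    0.450
#>     40%30s              0.330 -0.1216   0.782    0.330
#>     80%15s              0.610  0.1510   1.070    0.610
```

The `after_minus_before` column is the estimated marginal mean change in
ΔF (pps) per condition: at this small scale the two high-impulse
conditions (40%30s, 80%15s) show the injected PIC facilitation (the
simulator shifts hysteresis by +0.66 and +0.48 %MVT at a rate gain of
0.5 pps/%MVT, plus an acceleration-term contribution), while Control is
compatible with zero. `cohens_d` standardises the change by the
model-estimated population SD.

The full-scale analysis (21 participants, 14 units per ramp) is scripted:

```sh
Rscript analysis/01_simulate_study.R    # fixtures -> results/fixtures/
Rscript analysis/02_per_unit_metrics.R  # per-unit table -> results/outcomes.csv
Rscript analysis/03_contrasts.R         # mixed-model contrasts -> results/*.csv
Rscript analysis/04_validation.R        # ground-truth recovery checks
```

Stage 3 at that scale recovers ΔF contrasts of +0.43 (95% CI 0.30–0.56)
and +0.35 (0.22–0.48) pps in the two high-impulse conditions and null
contrasts elsewhere; stage 4 recovers gain × hysteresis across δ = 1–4
%MVT with median errors below 0.04 pps and shows 94.5 % null CI coverage.

Re-analysing an externally deposited per-unit results table goes through
`read_deposited_table()` (column/label remapping) followed by
`fit_contrasts()`.

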