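#' Configuration of the synthetic motoneuron pool
#'
#' Defines the simulated study: a triangular common drive (default 20 \%MVT
#' peak at 2 \%MVT/s, 10 s up / 10 s down), a pool of units with distributed
#' recruitment thresholds, a phenomenological firing-rate model
#' (linear drive gain plus a saturating PIC-like acceleration term),
#' recruitment-derecruitment hysteresis of configurable magnitude, and
#' gamma-renewal inter-spike-interval variability. Condition effects shift
#' each unit's hysteresis and discharge rate additively in the "after"
#' phase of the configured conditions, giving known before/after contrasts.
#'
#' The rate model for unit i at drive E (\%MVT) is
#' `r(E) = r_min + gain * (E - theta_i) + amp * (1 - exp(-(E - theta_i)/sat))`
#' with the acceleration term active only above threshold. The unit fires
#' from the ascending crossing of `theta_i` until the drive falls below
#' `theta_i - delta_i` on the descent; `delta_i` (\%MVT) is the hysteresis,
#' so the true pairwise delta F of a linear-rate control unit equals
#' `gain_control * delta_test`.
#'
#' Defaults are conventions for human tibialis anterior at a 20 \%MVT ramp:
#' `gain = 0.5` pps/\%MVT, `r_min = 6` pps, `isi_cv = 0.15`, recruitment
#' thresholds spread over 5-18 \%MVT. Default condition effects mirror the
#' studied design: hysteresis raised in the two high-impulse handgrip
#' conditions (+0.66 and +0.48 \%MVT, i.e. +0.33 and +0.24 pps of delta F
#' at the default gain) and a small peak-rate rise in the high-intensity
#' condition.
#'
#' @param n_participants Number of simulated participants.
#' @param units_per_trial Units decomposed per contraction.
#' @param ramp_peak Ramp peak (\%MVT).
#' @param ramp_rate Ramp slope (\%MVT/s).
#' @param fs Torque sampling rate (Hz).
#' @param threshold_range Recruitment-threshold span (\%MVT).
#' @param gain Rate gain (pps per \%MVT); `gain_cv` its unit-level
#'   lognormal coefficient of variation.
#' @param r_min Rate at recruitment (pps).
#' @param pic_amplitude,pic_saturation Amplitude (pps) and saturation
#'   scale (\%MVT) of the PIC-like acceleration term.
#' @param hysteresis_mean,hysteresis_sd,hysteresis_range Mean, SD and
#'   clamp interval (\%MVT) of per-unit hysteresis.
#' @param isi_cv Coefficient of variation of inter-spike intervals.
#' @param tracking_noise_sd SD (\%MVT) of the smooth drive-tracking error.
#' @param torque_noise_sd SD (\%MVT) of white torque measurement noise.
#' @param peak_torque_mean,peak_torque_sd Participant peak torque (N·m).
#' @param participant_rmin_sd,participant_delta_sd Between-participant SDs
#'   of `r_min` (pps) and hysteresis (\%MVT).
#' @param pnr_range Simulated pulse-to-noise ratios are drawn uniformly
#'   from this interval (dB).
#' @param condition_effects Named list (by condition) of
#'   `list(delta_shift, rate_shift)` applied to "after" trials.
#' @param seed Integer seed making [simulate_study()] reproducible.
#' @return A list of class `pool_config`.
#' @export
pool_config <- function(n_participants = 21, units_per_trial = 14,
                        ramp_peak = 20, ramp_rate = 2, fs = 200,
                        threshold_range = c(5, 18),
                        gain = 0.5, gain_cv = 0.1, r_min = 6,
                        pic_amplitude = 2, pic_saturation = 5,
                        hysteresis_mean = 2, hysteresis_sd = 0.5,
                        hysteresis_range = c(0.5, 3.5),
                        isi_cv = 0.15,
                        tracking_noise_sd = 0.3, torque_noise_sd = 0.05,
                        peak_torque_mean = 54, peak_torque_sd = 6,
                        participant_rmin_sd = 0.5,
                        participant_delta_sd = 0.2,
                        pnr_range = c(32, 42),
                        condition_effects = list(
                          "40%30s" = list(delta_shift = 0.66, rate_shift = 0),
                          "80%15s" = list(delta_shift = 0.48, rate_shift = 0.2)),
                        seed = 1L) {
  stopifnot(ramp_peak > 0, ramp_rate > 0, fs > 0,
            threshold_range[1] > 0, threshold_range[2] < ramp_peak,
            hysteresis_range[1] >= 0, isi_cv >= 0, gain > 0, r_min > 0)
  structure(as.list(environment()), class = "pool_config")
}

# triangular drive path in %MVT on a uniform grid
ramp_drive <- function(cfg) {
  t_up <- cfg$ramp_peak / cfg$ramp_rate
  t <- seq(0, 2 * t_up, by = 1 / cfg$fs)
  list(time = t, drive = ifelse(t <= t_up, cfg$ramp_rate * t,
                                pmax(2 * cfg$ramp_peak - cfg$ramp_rate * t, 0)))
}

# smooth tracking error: spline through 1 Hz gaussian knots, zero at ends
tracking_noise <- function(time, sd) {
  if (sd <= 0) return(numeric(length(time)))
  knots <- seq(min(time), max(time), by = 1)
  vals <- c(0, rnorm(length(knots) - 2, 0, sd), 0)
  spline(knots, vals, xout = time)$y
}

#' Per-unit ground-truth parameters for one participant x condition cell
#'
#' Thresholds are evenly spread over `threshold_range` with jitter then
#' sorted, so recruitment order follows threshold order. Hysteresis is
#' normal, clamped to `hysteresis_range`. A configuration in which any
#' unit's hysteresis reaches its threshold (the unit would never
#' derecruit) is a fatal error.
#'
#' @param cfg A [pool_config()].
#' @param participant_effects List with `r_min_shift`, `delta_shift`.
#' @return Tibble: `unit_id`, `theta`, `gain`, `delta`, `r_min`,
#'   `pic_amplitude`, `pic_saturation`.
#' @export
draw_unit_params <- function(cfg, participant_effects = list(r_min_shift = 0,
                                                             delta_shift = 0)) {
  n <- cfg$units_per_trial
  jit <- min(diff(cfg$threshold_range) / max(n - 1, 1) / 4, 0.5)
  theta <- sort(seq(cfg$threshold_range[1], cfg$threshold_range[2],
                    length.out = n) + runif(n, -jit, jit))
  delta <- pmin(pmax(rnorm(n, cfg$hysteresis_mean + participant_effects$delta_shift,
                           cfg$hysteresis_sd),
                     cfg$hysteresis_range[1]), cfg$hysteresis_range[2])
  if (any(delta >= theta)) {
    stop("invalid pool config: unit hysteresis >= recruitment threshold (never derecruits)",
         call. = FALSE)
  }
  tibble::tibble(
    unit_id = sprintf("u%02d", seq_len(n)), theta = theta,
    gain = cfg$gain * exp(rnorm(n, 0, cfg$gain_cv)),
    delta = delta,
    r_min = cfg$r_min + participant_effects$r_min_shift,
    pic_amplitude = cfg$pic_amplitude, pic_saturation = cfg$pic_saturation)
}

# rate model: linear drive gain + saturating acceleration, floored at 0.5 pps
unit_rate <- function(E, theta, gain, r_min, amp, sat, rate_shift = 0) {
  x <- E - theta
  accel <- if (amp > 0) amp * (1 - exp(-pmax(x, 0) / sat)) else 0
  pmax(r_min + gain * x + accel + rate_shift, 0.5)
}

#' True delta F implied by the rate model for one (control, test) pair
#'
#' The control unit's model rate at drive `theta_test` minus its rate at
#' `theta_test - delta_test` (the drive levels at test-unit recruitment
#' and derecruitment). Reduces to `gain_control * delta_test` for a linear
#' (zero-acceleration) control unit.
#'
#' @param control,test One-row data frames (or lists) of unit parameters
#'   as produced by [draw_unit_params()].
#' @return True delta F (pps).
#' @export
true_delta_f <- function(control, test) {
  r <- function(E) unit_rate(E, control$theta, control$gain, control$r_min,
                             control$pic_amplitude, control$pic_saturation)
  r(test$theta) - r(test$theta - test$delta)
}

# Inhomogeneous gamma-renewal spikes over a firing window, by time
# rescaling. The process is conditioned on discharging at both window
# edges (a renewal bridge): the unit's first spike marks the ascending
# threshold crossing and its last the hysteresis crossing where firing
# collapses, so recruitment/derecruitment timing carries no ISI
# quantisation offset. Gamma increments normalised to the window's total
# integrated rate give ISIs with the requested coefficient of variation.
draw_spikes <- function(time, rate, isi_cv) {
  lam <- pracma::cumtrapz(time, rate)[, 1]
  total <- lam[length(lam)]
  n_isi <- round(total)
  if (n_isi < 1) return(time[1])
  g <- if (isi_cv > 0) {
    k <- 1 / isi_cv^2
    rgamma(n_isi, shape = k, rate = k)
  } else {
    rep(1, n_isi)
  }
  u <- pmin(total * cumsum(g) / sum(g), total)
  u[length(u)] <- total  # pin the bridge endpoint against round-off
  c(time[1], approx(lam, time, xout = u, ties = "ordered")$y)
}

#' Simulate one triangular-ramp contraction
#'
#' The common drive is the triangular target path plus smooth tracking
#' noise. Unit i fires from the first ascending crossing of its threshold
#' until the drive last falls below threshold minus hysteresis; spike
#' times follow an inhomogeneous gamma-renewal process (time rescaling) at
#' the configured ISI coefficient of variation. The performed torque is
#' the drive (plus measurement noise) scaled by the participant's peak
#' torque. In "after" trials of conditions named in
#' `cfg$condition_effects`, each unit's hysteresis and rate receive the
#' configured additive shifts.
#'
#' @param cfg A [pool_config()].
#' @param participant_id,condition,phase Trial metadata.
#' @param unit_params Tibble from [draw_unit_params()] (shared by the
#'   before/after phases of a condition so units are matched).
#' @param peak_torque Participant peak torque (N·m).
#' @return List: `trial` (a [ramp_trial()]), `trains` (a [mu_trains()]
#'   tibble), `ground_truth` (unit parameters with the phase-effective
#'   hysteresis and rate shift).
#' @export
simulate_trial <- function(cfg, participant_id, condition, phase,
                           unit_params, peak_torque = cfg$peak_torque_mean) {
  rd <- ramp_drive(cfg)
  E <- rd$drive + tracking_noise(rd$time, cfg$tracking_noise_sd)
  eff <- cfg$condition_effects[[condition]]
  delta_shift <- if (phase == "after" && !is.null(eff)) eff$delta_shift else 0
  rate_shift <- if (phase == "after" && !is.null(eff)) eff$rate_shift else 0
  up <- unit_params
  up$delta <- pmin(up$delta + delta_shift, up$theta - 0.1)
  up$rate_shift <- rate_shift
  trains <- list(); keep <- logical(nrow(up))
  for (i in seq_len(nrow(up))) {
    on_idx <- which(E >= up$theta[i])
    off_idx <- which(E >= up$theta[i] - up$delta[i])
    if (!length(on_idx) || !length(off_idx)) next
    i0 <- min(on_idx); i1 <- max(off_idx)
    if (i1 - i0 < 2) next
    win <- i0:i1
    r <- unit_rate(E[win], up$theta[i], up$gain[i], up$r_min[i],
                   up$pic_amplitude[i], up$pic_saturation[i], rate_shift)
    spk <- draw_spikes(rd$time[win], r, cfg$isi_cv)
    spk <- spk[!is.na(spk)]
    if (length(spk) < 2) next
    keep[i] <- TRUE
    trains[[up$unit_id[i]]] <- spk
  }
  torque_pct <- E + rnorm(length(E), 0, cfg$torque_noise_sd)
  trial <- ramp_trial(participant_id, condition, phase,
                      torque_raw = peak_torque * torque_pct / 100,
                      fs = cfg$fs, peak_torque = peak_torque,
                      target_path = peak_torque * rd$drive / 100)
  tr <- mu_trains(unit_id = up$unit_id[keep], participant_id = participant_id,
                  condition = condition, phase = phase,
                  firing_times = trains[up$unit_id[keep]],
                  pnr_db = runif(sum(keep), cfg$pnr_range[1], cfg$pnr_range[2]),
                  duration = trial_duration(trial))
  gt <- up[keep, ]
  gt$participant_id <- participant_id
  gt$condition <- condition
  gt$phase <- phase
  list(trial = trial, trains = tr, ground_truth = gt)
}

#' Simulate a full study (all participants x conditions x phases)
#'
#' Reproducible given `cfg$seed`: participant characteristics, unit
#' parameters (drawn once per participant x condition, shared across the
#' two phases so units are matched) and all spike/noise sampling descend
#' from the single seed. Condition effects are injected only in the
#' conditions named in `cfg$condition_effects`.
#'
#' @param cfg A [pool_config()].
#' @param conditions Conditions to simulate (default all four).
#' @return List of class `pool_study`: `trials` (bundles for
#'   [analyze_study()]), `ground_truth` (per unit x phase parameter
#'   table), `config`.
#' @export
simulate_study <- function(cfg, conditions = pic_conditions()) {
  set.seed(cfg$seed)
  trials <- list(); gt <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    peak <- max(rnorm(1, cfg$peak_torque_mean, cfg$peak_torque_sd), 20)
    pe <- list(r_min_shift = rnorm(1, 0, cfg$participant_rmin_sd),
               delta_shift = rnorm(1, 0, cfg$participant_delta_sd))
    for (cond in conditions) {
      up <- draw_unit_params(cfg, pe)
      for (ph in pic_phases()) {
        sim <- simulate_trial(cfg, pid, cond, ph, up, peak)
        trials[[length(trials) + 1L]] <- sim[c("trial", "trains")]
        gt[[length(gt) + 1L]] <- sim$ground_truth
      }
    }
  }
  structure(list(trials = trials, ground_truth = dplyr::bind_rows(gt),
                 config = cfg), class = "pool_study")
}

#' Simulate a per-test-unit outcome table directly
#'
#' Draws outcome rows straight from a nested random-effects model
#' (participant and unit intercepts plus residual noise), bypassing the
#' spike-train pipeline. Used to validate the contrast stage on its own:
#' null behaviour, confidence-interval coverage and covariate-model
#' selection, where hundreds of replicate fits are needed.
#'
#' @param n_participants,units_per_participant Design size.
#' @param response Response column name to fill.
#' @param grand_mean Baseline response level.
#' @param effects Named per-condition after-minus-before shifts.
#' @param participant_sd,unit_sd,resid_sd Variance components.
#' @param covariate_effect Slope of the response on the simulated
#'   `recruitment_threshold` covariate (0 = no covariate effect).
#' @return Tibble shaped like the [analyze_study()] output.
#' @export
simulate_outcome_table <- function(n_participants = 16,
                                   units_per_participant = 8,
                                   response = "delta_f", grand_mean = 5.4,
                                   effects = c("Control" = 0, "40%15s" = 0,
                                               "40%30s" = 0, "80%15s" = 0),
                                   participant_sd = 0.5, unit_sd = 0.4,
                                   resid_sd = 0.5, covariate_effect = 0) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    bp <- rnorm(1, 0, participant_sd)
    for (cond in pic_conditions()) {
      bu <- rnorm(units_per_participant, 0, unit_sd)
      rt <- runif(units_per_participant, 2, 15)
      pdr <- rnorm(units_per_participant, 17, 1.5)
      for (ph in pic_phases()) {
        shift <- if (ph == "after") unname(effects[cond]) else 0
        y <- grand_mean + bp + bu + shift + covariate_effect * (rt - 8.5) +
          rnorm(units_per_participant, 0, resid_sd)
        r <- tibble::tibble(
          unit_id = sprintf("u%02d", seq_len(units_per_participant)),
          participant_id = sprintf("P%02d", p),
          condition = cond, phase = ph,
          delta_f = NA_real_, brace_height = NA_real_,
          attenuation_slope = NA_real_, peak_discharge_rate = pdr,
          recruitment_threshold = rt, derecruitment_threshold = rt - 0.5,
          n_control_units = 1L)
        r[[response]] <- y
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  dplyr::bind_rows(rows)
}
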