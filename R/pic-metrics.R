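#' Paired-motor-unit acceptance criteria
#'
#' The four standard criteria for admitting a (control, test) pair into the
#' delta F analysis: (i) rate-to-rate correlation of the smoothed curves
#' r >= `r_min`; (ii) test-minus-control recruitment time > `gap_min` s;
#' (iii) control-unit rate modulation (peak rate minus rate at test-unit
#' recruitment) > `mod_min` pps, ensuring the control unit still has
#' modulation range when the test unit recruits; (iv) control unit
#' derecruits after the test unit.
#'
#' @param r_min Minimum Pearson correlation (default 0.7).
#' @param gap_min Minimum recruitment-time gap in seconds (default 1).
#' @param mod_min Minimum control-unit rate modulation in pps (default 0.5).
#' @return A list of class `pairing_criteria`.
#' @export
pairing_criteria <- function(r_min = 0.7, gap_min = 1, mod_min = 0.5) {
  stopifnot(r_min > 0, gap_min > 0, mod_min > 0)
  structure(list(r_min = r_min, gap_min = gap_min, mod_min = mod_min),
            class = "pairing_criteria")
}

# correlation of two smoothed curves resampled onto their common support
rate_rate_correlation <- function(control, test, dt = 0.01) {
  lo <- max(control$t_rec, test$t_rec)
  hi <- min(control$t_derec, test$t_derec)
  if (hi - lo < 2 * dt) return(NA_real_)
  g <- seq(lo, hi, by = dt)
  rc <- approx(control$time, control$rate, xout = g, rule = 2)$y
  rt <- approx(test$time, test$rate, xout = g, rule = 2)$y
  if (anyNA(rc) || anyNA(rt) || sd(rc) == 0 || sd(rt) == 0) return(NA_real_)
  stats::cor(rc, rt)
}

#' Evaluate and filter motor-unit pairs for the delta F analysis
#'
#' Every ordered (control, test) pair with control recruited before test is
#' scored against the four [pairing_criteria()]; only pairs passing all
#' four are returned. Per-criterion rejection counts are attached as the
#' `"rejections"` attribute (a pair failing several criteria counts once
#' under each).
#'
#' @param srs Named list of `smoothed_rate` objects for one trial (names
#'   are unit ids).
#' @param criteria A [pairing_criteria()].
#' @return Tibble of valid pairs: `control_id`, `test_id`, `r_rate`,
#'   `recruit_gap`, `control_mod`, `derec_order_ok`. Attributes:
#'   `"rejections"` (named integer vector), `"n_evaluated"`.
#' @export
pair_units <- function(srs, criteria = pairing_criteria()) {
  ids <- names(srs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  rows <- list()
  rej <- c(r_rate = 0L, recruit_gap = 0L, control_mod = 0L, derec_order = 0L)
  n_eval <- 0L
  for (ci in seq_along(srs)) {
    for (ti in seq_along(srs)) {
      if (ci == ti) next
      ctrl <- srs[[ci]]; test <- srs[[ti]]
      gap <- test$t_rec - ctrl$t_rec
      if (gap <= 0) next  # control must be the earlier-recruited unit
      n_eval <- n_eval + 1L
      r <- rate_rate_correlation(ctrl, test)
      mod <- ctrl$peak_rate - rate_at_or_na(ctrl, test$t_rec)
      derec_ok <- ctrl$t_derec > test$t_derec
      ok_r <- isTRUE(r >= criteria$r_min)
      ok_gap <- gap > criteria$gap_min
      ok_mod <- isTRUE(mod > criteria$mod_min)
      if (!ok_r) rej["r_rate"] <- rej["r_rate"] + 1L
      if (!ok_gap) rej["recruit_gap"] <- rej["recruit_gap"] + 1L
      if (!ok_mod) rej["control_mod"] <- rej["control_mod"] + 1L
      if (!derec_ok) rej["derec_order"] <- rej["derec_order"] + 1L
      if (ok_r && ok_gap && ok_mod && derec_ok) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          control_id = ids[ci], test_id = ids[ti], r_rate = r,
          recruit_gap = gap, control_mod = mod, derec_order_ok = derec_ok)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    control_id = character(), test_id = character(), r_rate = numeric(),
    recruit_gap = numeric(), control_mod = numeric(),
    derec_order_ok = logical())
  attr(out, "rejections") <- rej
  attr(out, "n_evaluated") <- n_eval
  out
}

rate_at_or_na <- function(sr, t) {
  if (t < sr$t_rec - 1e-9 || t > sr$t_derec + 1e-9) return(NA_real_)
  rate_at(sr, t)
}

#' Delta F for one (control, test) pair
#'
#' The change in the control unit's smoothed discharge rate between the
#' test unit's recruitment and its derecruitment, in pps. Positive values
#' index recruitment-derecruitment hysteresis attributed to persistent
#' inward currents.
#'
#' @param control,test `smoothed_rate` objects for the control (lower
#'   threshold) and test (higher threshold) unit.
#' @return Delta F (pps).
#' @export
delta_f <- function(control, test) {
  if (test$t_derec > control$t_derec + 1e-9) {
    stop("test unit derecruits after control unit: pair violates criterion (iv)",
         call. = FALSE)
  }
  rate_at(control, test$t_rec) - rate_at(control, test$t_derec)
}

#' Average pairwise delta F into one value per test unit
#'
#' @param pair_dfs Numeric vector of pairwise delta F values for one test
#'   unit (one per admissible control unit).
#' @return Their unweighted mean (pps); `NA` for an empty vector.
#' @export
delta_f_per_test_unit <- function(pair_dfs) {
  if (!length(pair_dfs)) return(NA_real_)
  mean(pair_dfs)
}

#' Brace height of the ascending discharge-rate curve
#'
#' The ascending phase is mapped to the unit square (time and rate each
#' affinely scaled to 0..1 between recruitment and the smoothed peak). The
#' chord from (0,0) to (1,1) is the hypotenuse of a right triangle whose
#' right-angle vertex sits at (0,1). Brace height is the maximal signed
#' orthogonal deviation of the curve from the hypotenuse, as a percentage
#' of the vertex's orthogonal distance (1/sqrt(2)), i.e.
#' 100 * sqrt(2) * max((y - x) / sqrt(2)). Curves bowed above the chord
#' (concave, PIC-like acceleration-saturation) score positive; a curve
#' through the vertex scores 100. Negative deviations are reported as
#' negative, not clipped. The unit-square construction makes the measure
#' invariant to separate affine rescaling of either axis.
#'
#' @param asc An [ascending_phase()] segment.
#' @return List of class `brace_geometry`: `brace_height` (\% rTri),
#'   `d_max` (unit-square orthogonal units), `insertion_time` (s, time of
#'   the maximal deviation; earliest grid time on ties), or all-`NA` when
#'   the segment is degenerate (no time span or zero rate range).
#' @export
brace_height <- function(asc) {
  na <- structure(list(brace_height = NA_real_, d_max = NA_real_,
                       insertion_time = NA_real_), class = "brace_geometry")
  if (isTRUE(asc$degenerate)) return(na)
  tspan <- asc$t_peak - asc$t_rec
  rspan <- asc$rate[length(asc$rate)] - asc$rate[1]
  if (tspan <= 0 || rspan <= 0) return(na)
  x <- (asc$time - asc$t_rec) / tspan
  y <- (asc$rate - asc$rate[1]) / rspan
  d <- (y - x) / sqrt(2)          # signed orthogonal distance to chord y = x
  i <- which.max(d)
  structure(list(brace_height = 100 * sqrt(2) * d[i], d_max = d[i],
                 insertion_time = asc$time[i]), class = "brace_geometry")
}

#' Attenuation slope: rate vs torque from brace insertion to peak
#'
#' Ordinary least-squares slope of the smoothed discharge rate (pps)
#' against torque (\% of peak torque, i.e. \%MVT) over the grid samples
#' between the brace-height insertion point and the ascending-phase peak.
#' Torque is linearly interpolated onto the rate grid. Flatter (smaller)
#' slopes indicate rate saturation over the late ascending phase.
#'
#' @param asc An [ascending_phase()] segment.
#' @param insertion_time Insertion time from [brace_height()] (s).
#' @param filtered A [filter_torque()] result covering the window.
#' @return Slope in pps/\%MVT, or `NA` if fewer than 3 samples fall in the
#'   window or the torque does not vary.
#' @export
attenuation_slope <- function(asc, insertion_time, filtered) {
  if (isTRUE(asc$degenerate) || is.na(insertion_time)) return(NA_real_)
  keep <- asc$time >= insertion_time - 1e-12
  if (sum(keep) < 3) return(NA_real_)
  tq <- approx(filtered$time, filtered$torque_pct, xout = asc$time[keep])$y
  if (anyNA(tq) || var(tq) == 0) return(NA_real_)
  unname(coef(lm(asc$rate[keep] ~ tq))[2])
}

#' Recruitment/derecruitment thresholds and peak discharge rate
#'
#' The recruitment (derecruitment) threshold is the filtered torque, in \%
#' of peak torque, produced at the unit's first (last) discharge. The peak
#' discharge rate is the maximum of the smoothed curve.
#'
#' @param sr A `smoothed_rate`.
#' @param filtered A [filter_torque()] result whose record covers the
#'   unit's firing span.
#' @return List: `recruitment_threshold`, `derecruitment_threshold` (\% of
#'   peak torque), `peak_discharge_rate` (pps).
#' @export
unit_thresholds <- function(sr, filtered) {
  t0 <- filtered$time[1]; t1 <- filtered$time[length(filtered$time)]
  if (sr$t_rec < t0 - 1e-9 || sr$t_derec > t1 + 1e-9) {
    stop("unit firing span extends outside the torque record", call. = FALSE)
  }
  th <- approx(filtered$time, filtered$torque_pct,
               xout = c(sr$t_rec, sr$t_derec))$y
  list(recruitment_threshold = th[1], derecruitment_threshold = th[2],
       peak_discharge_rate = sr$peak_rate)
}

#' Analyse one ramp trial
#'
#' Runs the full per-unit pipeline for one contraction: torque filtering
#' and QC, discharge-rate smoothing, thresholds and peak rate, the
#' brace-height geometry and attenuation slope, pairing, and per-test-unit
#' delta F. A trial failing QC yields no rows.
#'
#' @param bundle List with elements `trial` (a [ramp_trial()]) and
#'   `trains` (a [mu_trains()] tibble).
#' @param criteria A [pairing_criteria()].
#' @param svr An [svr_control()].
#' @param qc_threshold Maximum tolerated tracking deviation (\% of peak).
#' @param min_firings Minimum discharges per unit.
#' @return Tibble of per-unit outcomes (one row per smoothed unit), with
#'   attributes `"qc"` (the trial's `qc_result`) and `"accounting"`
#'   (named counts of exclusions).
#' @export
analyze_trial <- function(bundle, criteria = pairing_criteria(),
                          svr = svr_control(), qc_threshold = 5,
                          min_firings = 4) {
  trial <- bundle$trial; trains <- bundle$trains
  filtered <- filter_torque(trial)
  qc <- ramp_qc(filtered, target_pct(trial), threshold = qc_threshold)
  acc <- c(units_loaded = nrow(trains), units_short_train = 0L,
           units_analysed = 0L, units_in_qc_failed_trials = 0L,
           test_units_without_pairs = 0L,
           trial_qc_failed = as.integer(!qc$passed))
  empty <- tibble::tibble(
    unit_id = character(), participant_id = character(),
    condition = character(), phase = character(), delta_f = numeric(),
    brace_height = numeric(), attenuation_slope = numeric(),
    peak_discharge_rate = numeric(), recruitment_threshold = numeric(),
    derecruitment_threshold = numeric(), n_control_units = integer())
  if (!qc$passed) {
    acc["units_in_qc_failed_trials"] <- nrow(trains)
    attr(empty, "qc") <- qc; attr(empty, "accounting") <- acc
    return(empty)
  }
  srs <- list()
  for (i in seq_len(nrow(trains))) {
    sr <- smooth_train(trains$firing_times[[i]], control = svr,
                       min_firings = min_firings)
    if (is.null(sr)) acc["units_short_train"] <- acc["units_short_train"] + 1L
    else srs[[trains$unit_id[i]]] <- sr
  }
  acc["units_analysed"] <- length(srs)
  if (!length(srs)) {
    attr(empty, "qc") <- qc; attr(empty, "accounting") <- acc
    return(empty)
  }
  pairs <- pair_units(srs, criteria)
  pair_df <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pair_df[k] <- delta_f(srs[[pairs$control_id[k]]], srs[[pairs$test_id[k]]])
  }
  rows <- lapply(names(srs), function(id) {
    sr <- srs[[id]]
    th <- unit_thresholds(sr, filtered)
    asc <- ascending_phase(sr)
    geo <- brace_height(asc)
    slope <- attenuation_slope(asc, geo$insertion_time, filtered)
    mine <- which(pairs$test_id == id)
    tibble::tibble(
      unit_id = id, participant_id = trial$participant_id,
      condition = trial$condition, phase = trial$phase,
      delta_f = delta_f_per_test_unit(pair_df[mine]),
      brace_height = geo$brace_height, attenuation_slope = slope,
      peak_discharge_rate = th$peak_discharge_rate,
      recruitment_threshold = th$recruitment_threshold,
      derecruitment_threshold = th$derecruitment_threshold,
      n_control_units = length(mine))
  })
  out <- dplyr::bind_rows(rows)
  acc["test_units_without_pairs"] <-
    sum(out$n_control_units == 0 & vapply(srs, function(s) s$t_rec,
        numeric(1)) > min(vapply(srs, function(s) s$t_rec, numeric(1))))
  attr(out, "qc") <- qc
  attr(out, "accounting") <- acc
  attr(out, "pair_rejections") <- attr(pairs, "rejections")
  out
}

#' Analyse a whole study
#'
#' Applies [analyze_trial()] to every trial bundle and stacks the per-unit
#' outcome rows. Exclusion accounting is aggregated across trials and
#' conserves counts (loaded = analysed + short-train exclusions, per
#' trial).
#'
#' @param study List with a `trials` element (bundles), e.g. from
#'   [simulate_study()] or [read_study_inputs()].
#' @inheritParams analyze_trial
#' @return Tibble of per-unit outcomes with attribute `"accounting"`.
#' @export
analyze_study <- function(study, criteria = pairing_criteria(),
                          svr = svr_control(), qc_threshold = 5,
                          min_firings = 4) {
  res <- lapply(study$trials, analyze_trial, criteria = criteria, svr = svr,
                qc_threshold = qc_threshold, min_firings = min_firings)
  accs <- lapply(res, attr, "accounting")
  acc <- Reduce(`+`, accs)
  out <- dplyr::bind_rows(res)
  attr(out, "accounting") <- acc
  out
}
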