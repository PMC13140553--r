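#' Instantaneous discharge rates from firing times
#'
#' Each inter-spike interval is converted to a rate 1/ISI (pps) assigned at
#' the interval's closing firing time, the standard convention for
#' discharge-rate analysis.
#'
#' @param firing_times Strictly increasing firing times (s).
#' @return Tibble with `time` (s) and `rate` (pps); one row per ISI.
#' @export
instantaneous_rates <- function(firing_times) {
  ft <- as.numeric(firing_times)
  if (length(ft) >= 2 && any(diff(ft) == 0)) {
    stop("duplicate firing times (zero inter-spike interval)", call. = FALSE)
  }
  if (length(ft) >= 2 && any(diff(ft) < 0)) {
    stop("firing times must be increasing", call. = FALSE)
  }
  tibble::tibble(time = ft[-1], rate = 1 / diff(ft))
}

#' Smoothing hyperparameters for the discharge-rate fit
#'
#' Defaults: radial-basis-kernel support vector regression with
#' regularisation `cost = 50` and a kernel length-scale of 0.4 s
#' (gamma = 1/(2 * 0.4^2)), chosen to track physiological rate
#' modulations on the seconds scale while rejecting ISI jitter. The
#' insensitivity `epsilon` is kept near zero (0.01 pps): smoothness is
#' governed by the kernel scale, and a wide tube would cap the curve's
#' accuracy at ~epsilon even on clean data. `dt` is the uniform
#' evaluation grid step; `pad` is the span of point-reflected boundary
#' data appended before fitting so the smoother does not flatten at the
#' recruitment/derecruitment edges.
#'
#' @param cost,epsilon,lengthscale,dt,pad Numeric hyperparameters (see
#'   Details).
#' @return A list of class `svr_control`.
#' @export
svr_control <- function(cost = 50, epsilon = 0.01, lengthscale = 0.4,
                        dt = 0.01, pad = 3 * lengthscale) {
  stopifnot(cost > 0, epsilon >= 0, lengthscale > 0, dt > 0, pad >= 0)
  structure(list(cost = cost, epsilon = epsilon, lengthscale = lengthscale,
                 dt = dt, pad = pad), class = "svr_control")
}

#' Smooth instantaneous discharge rates by support vector regression
#'
#' Fits an epsilon-insensitive support vector regression with a
#' radial-basis kernel to (time, rate) points and evaluates it on a
#' uniform grid over the unit's firing span. Landmarks extracted from the
#' grid: recruitment time (`t_rec`, the first firing), derecruitment time
#' (`t_derec`, the last firing), the smoothed peak (`t_peak`, earliest
#' grid time attaining the maximum) and `peak_rate`.
#'
#' Degenerate inputs whose rates vary by no more than `2 * epsilon` return
#' the constant mean curve.
#'
#' @param times Rate sample times (s), increasing.
#' @param rates Instantaneous rates (pps).
#' @param t_rec,t_derec Support endpoints; default to the span of `times`.
#'   Pass the unit's first firing time as `t_rec` (the rate samples start
#'   at the second firing).
#' @param control An [svr_control()].
#' @return An object of class `smoothed_rate`: `time`, `rate` (on the
#'   grid), `t_rec`, `t_derec`, `t_peak`, `peak_rate`.
#' @export
svr_smooth <- function(times, rates, t_rec = min(times), t_derec = max(times),
                       control = svr_control()) {
  stopifnot(length(times) == length(rates), length(times) >= 3)
  if (any(diff(times) <= 0)) stop("times must be increasing", call. = FALSE)
  grid <- seq(t_rec, t_derec, by = control$dt)
  if (diff(range(rates)) <= 2 * control$epsilon) {
    sm <- rep(mean(rates), length(grid))
  } else {
    t0 <- t_rec; t1 <- t_derec
    li <- which(times <= t0 + control$pad)
    ri <- which(times >= t1 - control$pad)
    # odd (point) reflection about the support endpoints preserves local
    # linear trends, avoiding edge flattening of the kernel smoother
    y0 <- rates[1]; y1 <- rates[length(rates)]
    tp <- c(2 * t0 - times[li], times, 2 * t1 - times[ri])
    yp <- c(2 * y0 - rates[li], rates, 2 * y1 - rates[ri])
    o <- order(tp)
    # times are centred at recruitment so the fit (and hence the curve) is
    # exactly equivariant under time translation
    fit <- tryCatch(
      e1071::svm(x = matrix(tp[o] - t0), y = yp[o], type = "eps-regression",
                 kernel = "radial", cost = control$cost,
                 epsilon = control$epsilon,
                 gamma = 1 / (2 * control$lengthscale^2), scale = FALSE),
      error = function(e) NULL)
    sm <- if (is.null(fit) || fit$tot.nSV == 0) {
      rep(mean(rates), length(grid))
    } else {
      as.numeric(predict(fit, matrix(grid - t0)))
    }
  }
  ipk <- which.max(sm)  # ties -> earliest grid time
  structure(list(time = grid, rate = sm, t_rec = t_rec, t_derec = t_derec,
                 t_peak = grid[ipk], peak_rate = sm[ipk]),
            class = "smoothed_rate")
}

#' Smooth one motor-unit train
#'
#' Convenience wrapper around [svr_smooth()] with the unit's first/last
#' firing as the support. For the regression each 1/ISI rate is placed at
#' its interval's midpoint: end-of-interval placement (the convention
#' [instantaneous_rates()] reports) lags a changing rate by half an ISI,
#' which would bias every landmark read from the smoothed curve in the
#' direction of the rate trend. Units with fewer than `min_firings`
#' discharges cannot be smoothed meaningfully and return `NULL`.
#'
#' @param firing_times Strictly increasing firing times (s).
#' @param control An [svr_control()].
#' @param min_firings Minimum number of discharges (default 4).
#' @return A `smoothed_rate`, or `NULL` if the train is too short.
#' @export
smooth_train <- function(firing_times, control = svr_control(),
                         min_firings = 4) {
  if (length(firing_times) < min_firings) return(NULL)
  ir <- instantaneous_rates(firing_times)
  n <- length(firing_times)
  mid <- (firing_times[-1] + firing_times[-n]) / 2
  svr_smooth(mid, ir$rate, t_rec = firing_times[1],
             t_derec = firing_times[n], control = control)
}

#' Rate read off the smoothed grid at a time point (nearest grid sample)
#' @param sr A `smoothed_rate`.
#' @param t Time (s); must lie within the support.
#' @return Rate (pps).
#' @export
rate_at <- function(sr, t) {
  if (t < sr$t_rec - 1e-9 || t > sr$t_derec + 1e-9) {
    stop(sprintf("time %.3f s outside smoothed support [%.3f, %.3f]",
                 t, sr$t_rec, sr$t_derec), call. = FALSE)
  }
  sr$rate[which.min(abs(sr$time - t))]
}

#' Ascending phase of a smoothed discharge-rate curve
#'
#' Restriction of the curve to [t_rec, t_peak], the segment the
#' brace-height and attenuation-slope geometry operates on. A curve whose
#' maximum sits at recruitment has no ascending phase and is flagged
#' degenerate (such units are excluded from the geometry metrics).
#'
#' @param sr A `smoothed_rate`.
#' @return A list of class `ascending_phase`: `time`, `rate`, `t_rec`,
#'   `t_peak`, `degenerate`.
#' @export
ascending_phase <- function(sr) {
  keep <- sr$time <= sr$t_peak + 1e-12
  structure(list(time = sr$time[keep], rate = sr$rate[keep],
                 t_rec = sr$t_rec, t_peak = sr$t_peak,
                 degenerate = sum(keep) < 3 || sr$t_peak <= sr$t_rec),
            class = "ascending_phase")
}
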