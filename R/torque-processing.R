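#' Low-pass filter a torque trace and normalise to \% of peak torque
#'
#' Applies a fifth-order low-pass Butterworth filter with a 10 Hz cut-off,
#' forward and backward (zero-phase), so that recruitment/derecruitment
#' timing read off the torque record is not biased by filter delay. The
#' effective magnitude response is the squared single-pass response,
#' |H(f)|^2 = 1 / (1 + (f/fc)^(2 * order)). The trace is reflect-padded
#' (point reflection about each end sample) before filtering to suppress
#' start-up transients.
#'
#' @param trial A [ramp_trial()].
#' @param fc Cut-off frequency (Hz).
#' @param order Filter order.
#' @return An object of class `filtered_torque`: list with `time` (s),
#'   `torque_pct` (\% of peak torque) and `fs` (Hz).
#' @export
filter_torque <- function(trial, fc = 10, order = 5) {
  fs <- trial$fs
  if (fs <= 2 * fc) {
    stop(sprintf("sampling rate %g Hz too low: cut-off %g Hz must be below Nyquist",
                 fs, fc), call. = FALSE)
  }
  x <- trial$torque_raw
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  npad <- min(length(x) - 1L, ceiling(10 * fs / fc))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xp)[(npad + 1):(npad + length(x))]
  structure(list(time = trial_time(trial),
                 torque_pct = 100 * y / trial$peak_torque,
                 fs = fs),
            class = "filtered_torque")
}

#' Target path in \% of peak torque
#' @param trial A [ramp_trial()].
#' @return Numeric vector, same grid as the torque trace.
#' @export
target_pct <- function(trial) 100 * trial$target_path / trial$peak_torque

#' Ramp tracking quality control
#'
#' Trials where the performed torque deviates abruptly from the requested
#' triangular path by more than `threshold` (\% of peak torque) at any point
#' are failed and excluded from analysis. The time-integrated absolute
#' deviation (trapezoidal rule) is also reported as a tracking-consistency
#' metric, in (\% of peak)·s.
#'
#' @param filtered A [filter_torque()] result.
#' @param target Target path in \% of peak torque, on the same grid.
#' @param threshold Maximum tolerated deviation (\% of peak torque).
#' @return A list of class `qc_result`: `passed`, `max_abrupt_deviation`,
#'   `tracking_error_area`.
#' @export
ramp_qc <- function(filtered, target, threshold = 5) {
  stopifnot(length(filtered$torque_pct) == length(target))
  dev <- abs(filtered$torque_pct - target)
  structure(list(passed = max(dev) <= threshold,
                 max_abrupt_deviation = max(dev),
                 tracking_error_area = pracma::trapz(filtered$time, dev)),
            class = "qc_result")
}

#' Contraction impulse (area under the force curve)
#'
#' Time-integral of force by the trapezoidal rule. For the handgrip
#' conditions this is the quantity that the 40\%-for-30 s and 80\%-for-15 s
#' prescriptions match (each twice the 40\%-for-15 s impulse).
#'
#' @param force Numeric vector of force samples (N).
#' @param fs Sampling frequency (Hz).
#' @return Impulse in N·s.
#' @export
impulse <- function(force, fs) {
  if (!isTRUE(fs > 0)) stop("fs must be positive", call. = FALSE)
  stopifnot(length(force) >= 2)
  pracma::trapz(seq(0, by = 1 / fs, length.out = length(force)), force)
}
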