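# Shared fixture builders. Everything is generated in code; no stored data.

# a smoothed_rate object built directly from a rate function, bypassing the
# SVR stage, for geometry/pairing tests with exactly known curves
make_sr <- function(rate_fun, t_rec, t_derec, dt = 0.01) {
  grid <- seq(t_rec, t_derec, by = dt)
  r <- rate_fun(grid)
  ipk <- which.max(r)
  structure(list(time = grid, rate = r, t_rec = t_rec, t_derec = t_derec,
                 t_peak = grid[ipk], peak_rate = r[ipk]),
            class = "smoothed_rate")
}

# an ascending_phase object directly from samples in the unit square (or any
# time/rate pairing)
make_asc <- function(time, rate) {
  structure(list(time = time, rate = rate, t_rec = time[1],
                 t_peak = time[length(time)], degenerate = FALSE),
            class = "ascending_phase")
}

# deterministic spike train realising a given rate profile (noise-free
# time rescaling; spikes at unit increments of the integrated rate)
spikes_from_rate <- function(rate_fun, t0, t1, dt = 1e-4) {
  tt <- seq(t0, t1, by = dt)
  lam <- pracma::cumtrapz(tt, rate_fun(tt))[, 1]
  c(t0, approx(lam, tt, xout = seq(1, floor(max(lam))))$y)
}

# a minimal ramp trial whose performed torque equals the target triangle
ideal_trial <- function(participant = "P01", condition = "Control",
                        phase = "before", peak = 50, fs = 200) {
  t <- seq(0, 20, by = 1 / fs)
  tgt <- peak * 0.20 * ifelse(t <= 10, t / 10, pmax((20 - t) / 10, 0))
  ramp_trial(participant, condition, phase, torque_raw = tgt, fs = fs,
             peak_torque = peak, target_path = tgt)
}

# a small outcome table with exactly known participant-level differences
toy_outcomes <- function(n_participants = 6, units = 4, seed = 1,
                         effects = c("Control" = 0, "40%15s" = 0,
                                     "40%30s" = 0, "80%15s" = 0)) {
  set.seed(seed)
  simulate_outcome_table(n_participants = n_participants,
                         units_per_participant = units, effects = effects)
}
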