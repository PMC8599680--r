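# Independent oracles and fixture generators. These re-derive expected
# results from first principles (definitional scans, closed forms,
# Monte-Carlo) and deliberately share no code with the package internals.

# Definitional local-minima scan: walk runs of equal values; a run is a
# minimum when both distinct neighbours are larger; report the run
# midpoint (lower index on even runs).
oracle_local_minima <- function(v) {
  n <- length(v)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (i > 1L && j < n && v[i - 1L] > v[i] && v[j + 1L] > v[i]) {
      out <- c(out, (i + j) %/% 2L)
    }
    i <- j + 1L
  }
  out
}

# Exhaustive pulse characterization: peak = in-window sample of largest
# absolute value; sign-flip for negative peaks; nearest definitional
# local minima on each side over the full trace (epoch edge fallback).
oracle_characterize <- function(t, v, window) {
  in_win <- which(t >= window[1] & t <= window[2])
  i_peak <- in_win[which.max(abs(v[in_win]))]
  u <- if (v[i_peak] < 0) -v else v
  mins <- oracle_local_minima(u)
  lefts <- mins[mins < i_peak]
  rights <- mins[mins > i_peak]
  i_l <- if (length(lefts)) max(lefts) else 1L
  i_r <- if (length(rights)) min(rights) else length(u)
  list(t_peak = t[i_peak], t_min_left = t[i_l], t_min_right = t[i_r],
       w = t[i_r] - t[i_l], A = u[i_peak] - mean(c(u[i_l], u[i_r])))
}

# Random piecewise-smooth trace: a handful of signed Gaussian bumps plus
# a slow sinusoidal drift, on a 1 ms grid.
make_smooth_fixture <- function(seed, t = seq(0, 300)) {
  set.seed(seed)
  k <- sample(3:8, 1)
  v <- 0.5 * sin(2 * pi * t / runif(1, 200, 500) + runif(1, 0, 2 * pi))
  for (i in seq_len(k)) {
    v <- v + runif(1, -10, 10) *
      exp(-(t - runif(1, 20, 280))^2 / (2 * runif(1, 5, 30)^2))
  }
  v
}

# Evoked response built from iid-noise trials around a fixed signal.
make_evoked_from_trials <- function(signal, n_trials, noise_sd, time_ms,
                                    channel = "fixture") {
  x <- matrix(rnorm(n_trials * length(signal), 0, noise_sd), n_trials)
  x <- sweep(x, 2L, signal, `+`)
  evoked_response(colMeans(x), apply(x, 2L, sd) / sqrt(n_trials),
                  time_ms = time_ms, channel = channel,
                  n_trials = n_trials)
}

# Small dual-site flash config used by several preprocessing/timing tests.
quiet_flash_config <- function(run_duration = 20, jitter_sd = 0,
                               noise = 0, line = 0, seed = 1,
                               components = default_components(jitter_sd = jitter_sd)) {
  synthetic_config(
    run_duration = run_duration, components = components,
    sensors = list(
      sensor_spec("Oz", "OPM", noise_density = noise, line_noise_amplitude = line),
      sensor_spec("POz", "OPM", noise_density = noise, line_noise_amplitude = line)),
    seed = seed)
}
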