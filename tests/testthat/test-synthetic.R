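test_that("flash schedule follows the frame-quantized ISI arithmetic", {
  # deterministic when isi_min == isi_max: gaps all flash_len + isi
  sch <- generate_flash_schedule(10, 0.08, 1.0, 1.0, 60, seed = 1)
  expect_equal(sch$onsets, seq(0, 9.72, by = 1.08))
  expect_identical(sch$protocol, "flash")

  # event count bounded by the gap range (enumeration bound)
  n <- lengths(lapply(1:5, function(s) {
    generate_flash_schedule(300, 0.08, 0.92, 1.00, 60, seed = s)$onsets
  }))
  expect_true(all(n >= floor(300 / 1.08) & n <= floor(300 / 1.00)))

  # degenerate durations
  expect_error(generate_flash_schedule(0, 0.08, 0.92, 1.00, 60),
               class = "opmvef_empty_schedule")
  expect_error(generate_flash_schedule(0.5, 0.08, 0.92, 1.00, 60),
               class = "opmvef_empty_schedule")
})

test_that("flash inter-onset gaps stay inside [flash_len+isi_min, flash_len+isi_max]", {
  for (s in 1:20) {
    sch <- generate_flash_schedule(120, 0.08, 0.92, 1.00, 60, seed = s)
    gaps <- diff(sch$onsets)
    expect_true(all(gaps >= 0.08 + 0.92 - 1e-9))
    expect_true(all(gaps <= 0.08 + 1.00 + 1e-9))
    # last event fully inside the run
    expect_lte(max(sch$onsets) + 0.08, 120)
    # reproducible per seed
    expect_identical(sch$onsets,
                     generate_flash_schedule(120, seed = s)$onsets)
  }
})

test_that("pattern-reversal schedule enumerates reversals with margin clipping", {
  expect_equal(generate_pr_schedule(1, 0.5)$onsets, c(0, 0.5))
  expect_equal(generate_pr_schedule(0.4, 0.5)$onsets, 0)
  expect_length(generate_pr_schedule(280, 0.5, margin = 0.25)$onsets, 560)
  # a margin of one full interval does clip the last reversal
  expect_length(generate_pr_schedule(280, 0.5, margin = 0.5)$onsets, 559)
  expect_error(generate_pr_schedule(280, 0))
  expect_error(generate_pr_schedule(280, -1))
})

test_that("evoked waveform synthesis matches the Gaussian closed form", {
  t <- seq(-45, 350)
  expect_equal(synthesize_evoked_waveform(list(), t), numeric(length(t)))

  cmp <- component_spec("P2", t0 = c(Oz = 120), sigma = 15,
                        amplitude = list(Oz = c(z = -480)), jitter_sd = 0)
  tr <- synthesize_evoked_waveform(list(cmp), t, "Oz", "z")
  expect_equal(tr[t == 120], -480)                       # peak value is A
  expect_equal(tr[t == 135], -480 * exp(-0.5))           # value at t0 + sigma
  expect_equal(tr[t == 105], -480 * exp(-0.5))
  # unknown axis is a channel mismatch, not silence
  expect_error(synthesize_evoked_waveform(list(cmp), t, "Oz", "y"),
               class = "opmvef_channel_mismatch")
})

test_that("noiseless simulated epochs reproduce the synthesized waveform exactly", {
  cfg <- quiet_flash_config(run_duration = 15, seed = 11)
  raw <- simulate_run(cfg)
  expect_equal(sum(raw$trigger != 0), length(attr(raw, "schedule")$onsets))
  ep <- suppressMessages(epoch(raw, window = c(-45, 350)))
  for (ch in c("Oz_z", "POz_y")) {
    ev <- average_evoked(ep, ch)
    ref <- synthesize_evoked_waveform(cfg$components, ev$time_ms,
                                      sub("_.*", "", ch), sub(".*_", "", ch))
    expect_lt(max(abs(ev$mean - ref)), 1e-9)
    expect_equal(ev$sem, numeric(length(ev$sem)))
  }
})

test_that("identical config and seed give a bit-identical recording", {
  cfg <- synthetic_config(run_duration = 8, seed = 42)
  r1 <- simulate_run(cfg)
  r2 <- simulate_run(cfg)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$trigger, r2$trigger)
  r3 <- simulate_run(synthetic_config(run_duration = 8, seed = 43))
  expect_false(identical(r1$channels, r3$channels))
})

test_that("sensor-only channels carry white noise at the configured RMS", {
  rho <- 10
  cfg <- synthetic_config(run_duration = 60, components = list(),
                          sensors = list(sensor_spec("Oz", "OPM", axes = "z",
                                                     noise_density = rho,
                                                     line_noise_amplitude = 0)),
                          seed = 7)
  x <- simulate_run(cfg)$channels[, 1]
  expect_equal(sqrt(mean(x^2)), rho * sqrt(1000 / 2), tolerance = 0.05)
})

test_that("50 Hz line interference is injected at the configured amplitude", {
  amp <- 30
  cfg <- synthetic_config(run_duration = 100, components = list(),
                          sensors = list(sensor_spec("Oz", "OPM", axes = "z",
                                                     noise_density = 5,
                                                     line_noise_amplitude = amp)),
                          seed = 3)
  raw <- simulate_run(cfg)
  x <- raw$channels[, 1]
  # complex demodulation at 50 Hz recovers the sinusoid amplitude
  est <- 2 * Mod(mean(x * exp(-2i * pi * 50 * raw$time)))
  expect_equal(est, amp, tolerance = 0.2)
})

test_that("an excess-noise knee boosts low-frequency power, not the white floor", {
  mk <- function(knee) {
    cfg <- synthetic_config(run_duration = 60, components = list(),
                            sensors = list(sensor_spec("Oz", "OPM", axes = "z",
                                                       noise_density = 10,
                                                       line_noise_amplitude = 0,
                                                       one_over_f_knee = knee)),
                            seed = 17)
    simulate_run(cfg)$channels[, 1]
  }
  pgram <- function(x) Mod(stats::fft(x))^2 / length(x)
  f <- (seq_len(60000) - 1) / 60
  lo <- f > 0.2 & f < 2
  hi <- f > 100 & f < 400
  p0 <- pgram(mk(0)); p1 <- pgram(mk(20))
  expect_gt(mean(p1[lo]) / mean(p0[lo]), 5)          # ~1 + 20/f below 2 Hz
  expect_equal(mean(p1[hi]), mean(p0[hi]), tolerance = 0.15)
})

test_that("evoked amplitude decays with stand-off by the power law", {
  peak_at <- function(standoff) {
    cfg <- synthetic_config(
      run_duration = 3, isi_min = 1, isi_max = 1,
      components = default_components(jitter_sd = 0),
      sensors = list(sensor_spec("Oz", "OPM", axes = "z", standoff = standoff,
                                 noise_density = 0, line_noise_amplitude = 0)),
      seed = 1)
    max(abs(simulate_run(cfg)$channels[, 1]))
  }
  amps <- vapply(c(5, 10, 20, 50), peak_at, numeric(1))
  expect_true(all(diff(amps) < 0))
  expect_equal(amps[1] / amps[4], 100, tolerance = 1e-6) # (50/5)^2
})
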