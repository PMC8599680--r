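make_raw <- function(channels, fs = 1000, onsets = numeric(0)) {
  n <- nrow(channels)
  trigger <- integer(n)
  trigger[as.integer(round(onsets * fs)) + 1L] <- 1L
  opmvef:::new_raw_recording((seq_len(n) - 1L) / fs, channels,
                             labels = colnames(channels) %||% paste0("ch", seq_len(ncol(channels))),
                             trigger = trigger, sampling_rate = fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("band filters pass 20 Hz untouched, kill 50 Hz and DC, stay linear", {
  fs <- 1000
  t <- (0:(100 * fs - 1)) / fs
  spec <- filter_spec()
  zero <- make_raw(matrix(0, length(t), 1))
  expect_equal(apply_filters(zero, spec)$channels[, 1], numeric(length(t)))

  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  x50 <- make_raw(matrix(sin(2 * pi * 50 * t), ncol = 1))
  y50 <- apply_filters(x50, spec)$channels[, 1]
  expect_lt(sqrt(mean(y50[mid]^2)), 0.1 * sqrt(0.5))

  x20 <- make_raw(matrix(sin(2 * pi * 20 * t), ncol = 1))
  y20 <- apply_filters(x20, spec)$channels[, 1]
  expect_equal(max(abs(y20[mid])), 1, tolerance = 0.05)
  # steady-state peak positions shift by less than one sample
  lag <- which.max(stats::ccf(y20[mid], x20$channels[mid, 1], lag.max = 5,
                              plot = FALSE)$acf) - 6L
  expect_equal(lag, 0L)

  # DC removal
  dc <- make_raw(matrix(7, length(t), 1))
  expect_lt(max(abs(apply_filters(dc, spec)$channels[mid, 1])), 1e-6)

  # linearity
  set.seed(1)
  a <- rnorm(5000); b <- rnorm(5000)
  fa <- apply_filters(make_raw(matrix(a, ncol = 1)), spec)$channels[, 1]
  fb <- apply_filters(make_raw(matrix(b, ncol = 1)), spec)$channels[, 1]
  fab <- apply_filters(make_raw(matrix(2 * a - 3 * b, ncol = 1)), spec)$channels[, 1]
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-4) # recursive-filter roundoff

  # band edges above Nyquist are refused
  slow <- make_raw(matrix(rnorm(500), ncol = 1), fs = 100)
  expect_error(apply_filters(slow, spec), class = "opmvef_filter_band")
})

test_that("zero-phase filtering leaves the latency of an in-band pulse unchanged", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  pulse <- exp(-(t - 10)^2 / (2 * 0.05^2)) * cos(2 * pi * 10 * (t - 10))
  y <- apply_filters(make_raw(matrix(pulse, ncol = 1)), filter_spec())$channels[, 1]
  expect_lte(abs(which.max(y) - which.max(pulse)), 1L)
})

test_that("epoching counts trials and drops out-of-bounds onsets", {
  fs <- 1000
  set.seed(2)
  raw <- make_raw(matrix(rnorm(10 * fs), ncol = 1), fs = fs,
                  onsets = seq(1, by = 0.9, length.out = 10))
  ep <- epoch(raw, window = c(-45, 350))
  expect_equal(dim(ep$trials)[1], 10L)
  expect_equal(dim(ep$trials)[2], round((350 - -45) * fs / 1000) + 1L)
  expect_equal(ep$time_ms[1], -45)
  expect_equal(ep$time_ms[length(ep$time_ms)], 350)

  # an onset whose post-window overruns the recording is dropped
  raw2 <- make_raw(matrix(rnorm(10 * fs), ncol = 1), fs = fs,
                  onsets = c(seq(1, by = 0.9, length.out = 10), 9.9))
  expect_message(ep2 <- epoch(raw2, window = c(-45, 350)), "dropped")
  expect_equal(dim(ep2$trials)[1], 10L)
  expect_equal(ep2$n_dropped, 1L)

  expect_error(epoch(make_raw(matrix(rnorm(100), ncol = 1)),
                     window = c(-45, 350)),
               class = "opmvef_empty_schedule")
})

test_that("trial rejection removes non-finite, flatlined and over-ceiling trials", {
  fs <- 1000
  set.seed(3)
  n_tr <- 100L
  trials <- array(rnorm(n_tr * 200 * 1), c(n_tr, 200, 1))
  ep <- opmvef:::new_epoch_set(trials, time_ms = 0:199, labels = "Oz_z",
                               sampling_rate = fs, onsets = seq_len(n_tr))
  expect_identical(dim(suppressMessages(reject_trials(ep))$trials), dim(trials))

  # plant 7 trials with 60 ms flat segments, one NA trial, one spike trial
  bad_flat <- c(3, 10, 22, 47, 61, 80, 99)
  for (tr in bad_flat) ep$trials[tr, 50:110, 1] <- 1.234
  ep$trials[5, 17, 1] <- NA_real_
  ep$trials[8, 100, 1] <- 2e4
  out <- suppressMessages(reject_trials(ep))
  expect_equal(dim(out$trials)[1], n_tr - 9L)
  expect_equal(out$rejection$flatline, 7L)
  expect_equal(out$rejection$nonfinite, 1L)
  expect_equal(out$rejection$amplitude, 1L)

  # a 40 ms flat segment is below the dropout threshold
  ep2 <- opmvef:::new_epoch_set(trials, time_ms = 0:199, labels = "Oz_z",
                                sampling_rate = fs, onsets = seq_len(n_tr))
  ep2$trials[1, 50:90, 1] <- 1.234
  expect_equal(dim(suppressMessages(reject_trials(ep2))$trials)[1], n_tr)

  all_bad <- opmvef:::new_epoch_set(array(NA_real_, c(2, 10, 1)), 0:9, "x",
                                    fs, 1:2)
  expect_error(reject_trials(all_bad), class = "opmvef_all_rejected")
})

test_that("trial averaging produces the mean and per-timepoint standard error", {
  mk <- function(trials) {
    opmvef:::new_epoch_set(trials, time_ms = seq_len(dim(trials)[2]) - 1,
                           labels = "Oz_z", sampling_rate = 1000,
                           onsets = seq_len(dim(trials)[1]))
  }
  # identical trials: mean is the trial, SE identically zero
  tr <- array(rep(sin(1:50), each = 4), c(4, 50, 1))
  ev <- average_evoked(mk(tr))
  expect_equal(ev$mean, sin(1:50))
  expect_equal(ev$sem, numeric(50))

  # hand-computed two-trial case: SE = sd/sqrt(2) = 1 everywhere
  tr2 <- array(c(0, 2, 2, 0), c(2, 2, 1))
  ev2 <- average_evoked(mk(tr2))
  expect_equal(ev2$mean, c(1, 1))
  expect_equal(ev2$sem, c(1, 1))

  # Monte-Carlo: n = 100 iid N(0, sigma^2) trials -> SE ~ sigma/10; the
  # per-timepoint SE estimate itself has ~7% sampling noise at n = 100
  set.seed(4)
  sigma <- 3
  tr3 <- array(rnorm(100 * 400, 0, sigma), c(100, 400, 1))
  ev3 <- average_evoked(mk(tr3))
  rel <- abs(ev3$sem - sigma / 10) / (sigma / 10)
  expect_lt(mean(rel > 0.15), 0.05)
  expect_lt(max(rel), 0.35)
  expect_equal(mean(ev3$sem), sigma / 10, tolerance = 0.02)

  expect_error(average_evoked(mk(array(0, c(1, 5, 1)))),
               class = "opmvef_too_few_trials")
  expect_error(average_evoked(mk(tr2), "nope"))
})

test_that("standard error of pure-noise averages scales as 1/sqrt(n)", {
  set.seed(5)
  trials <- array(rnorm(256 * 300), c(256, 300, 1))
  mk <- function(n) {
    ep <- opmvef:::new_epoch_set(trials[seq_len(n), , , drop = FALSE],
                                 time_ms = 0:299, labels = "x",
                                 sampling_rate = 1000, onsets = seq_len(n))
    mean(average_evoked(ep)$sem)
  }
  ns <- c(4, 16, 64, 256)
  eps <- vapply(ns, mk, numeric(1))
  slope <- unname(coef(lm(log(eps) ~ log(ns)))[2])
  expect_equal(slope, -0.5, tolerance = 0.05)
})
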