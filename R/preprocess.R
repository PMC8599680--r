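#' Filter specification for evoked-field preprocessing
#'
#' A zero-phase Butterworth band-pass (isolating the evoked-field band)
#' plus band-stop (suppressing mains interference). Filters are applied
#' forward and backward ([signal::filtfilt()]) so that the passband group
#' delay is zero: any causal filter would bias the peak latencies that are
#' this pipeline's product.
#'
#' @param bandpass numeric `(low, high)` in Hz; default 5--60 Hz.
#' @param bandstop numeric `(low, high)` in Hz; default 49--51 Hz.
#' @param order Butterworth order of each filter (doubled in effect by the
#'   forward-backward pass).
#' @return A `filter_spec`.
#' @export
filter_spec <- function(bandpass = c(5, 60), bandstop = c(49, 51), order = 4L) {
  stopifnot(length(bandpass) == 2L, length(bandstop) == 2L,
            bandpass[1] > 0, bandpass[1] < bandpass[2],
            bandstop[1] > 0, bandstop[1] < bandstop[2],
            order >= 1L)
  structure(list(bandpass = as.numeric(bandpass),
                 bandstop = as.numeric(bandstop),
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Zero-phase band-pass and band-stop filtering of a raw recording
#'
#' Applied to the continuous record (before epoching) so that filter edge
#' transients stay outside the epochs; use the `guard` argument of
#' [epoch()] to exclude the record ends. DC is removed by the band-pass
#' high-pass edge.
#'
#' @param raw a `raw_recording`.
#' @param spec a [filter_spec()].
#' @return The recording with every channel filtered; trigger untouched.
#' @export
apply_filters <- function(raw, spec = filter_spec()) {
  stopifnot(inherits(raw, "raw_recording"), inherits(spec, "filter_spec"))
  nyq <- raw$sampling_rate / 2
  if (max(spec$bandpass, spec$bandstop) >= nyq) {
    stop_opmvef("filter band edges must lie below the Nyquist frequency (",
                nyq, " Hz)", class = "opmvef_filter_band")
  }
  bp <- signal::butter(spec$order, spec$bandpass / nyq, type = "pass")
  bs <- signal::butter(spec$order, spec$bandstop / nyq, type = "stop")
  out <- raw
  for (j in seq_len(ncol(raw$channels))) {
    x <- signal::filtfilt(bp, raw$channels[, j])
    out$channels[, j] <- signal::filtfilt(bs, x)
  }
  out
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One trial per onset, time 0 aligned to the sample nearest the onset.
#' Onsets whose window (plus guard band) does not fit inside the recording
#' are dropped with a message.
#'
#' @param raw a `raw_recording` (typically after [apply_filters()]).
#' @param onsets event times in seconds; defaults to the trigger channel.
#' @param window `(t_pre, t_post)` in ms relative to onset; flash epochs
#'   use `c(-45, 350)`, pattern-reversal `c(0, 250)`.
#' @param guard guard band in seconds excluded at both record ends
#'   (protects epochs from filter edge transients).
#' @return An `epoch_set`: `trials` array `[n_trials, n_samples,
#'   n_channels]` (fT), `time_ms` relative to onset, `labels`,
#'   `sampling_rate`, kept `onsets` and the `n_dropped` count.
#' @export
epoch <- function(raw, onsets = NULL, window = c(-45, 350), guard = 0) {
  stopifnot(inherits(raw, "raw_recording"), length(window) == 2L,
            window[1] < window[2], guard >= 0)
  if (is.null(onsets)) {
    onsets <- raw$time[raw$trigger != 0]
  } else if (inherits(onsets, "stimulus_schedule")) {
    onsets <- onsets$onsets
  }
  if (!length(onsets)) {
    stop_opmvef("empty schedule: no onsets to epoch",
                class = "opmvef_empty_schedule")
  }
  fs <- raw$sampling_rate
  n <- nrow(raw$channels)
  i_on <- as.integer(round(onsets * fs)) + 1L
  pre <- as.integer(round(window[1] / 1000 * fs))
  post <- as.integer(round(window[2] / 1000 * fs))
  g <- as.integer(ceiling(guard * fs))
  lo <- i_on + pre
  hi <- i_on + post
  ok <- lo >= 1L + g & hi <= n - g
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " onset(s) dropped: epoch window out of bounds")
  }
  if (!any(ok)) {
    stop_opmvef("no epoch fits inside the recording",
                class = "opmvef_empty_epochs")
  }
  i_on <- i_on[ok]
  n_samp <- post - pre + 1L
  n_chan <- ncol(raw$channels)
  trials <- array(NA_real_, c(length(i_on), n_samp, n_chan))
  for (tr in seq_along(i_on)) {
    idx <- (i_on[tr] + pre):(i_on[tr] + post)
    trials[tr, , ] <- raw$channels[idx, , drop = FALSE]
  }
  new_epoch_set(trials, time_ms = (pre:post) / fs * 1000,
                labels = raw$labels, sampling_rate = fs,
                onsets = onsets[ok], n_dropped = n_dropped)
}

new_epoch_set <- function(trials, time_ms, labels, sampling_rate, onsets,
                          n_dropped = 0L, rejection = NULL) {
  stopifnot(length(dim(trials)) == 3L, dim(trials)[2] == length(time_ms),
            dim(trials)[3] == length(labels))
  structure(list(trials = trials, time_ms = time_ms, labels = labels,
                 sampling_rate = sampling_rate, onsets = onsets,
                 n_dropped = n_dropped, rejection = rejection),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples x %d channels, %g..%g ms at %g Hz\n",
              dim(x$trials)[1], dim(x$trials)[2], dim(x$trials)[3],
              min(x$time_ms), max(x$time_ms), x$sampling_rate))
  if (!is.null(x$rejection)) {
    cat(sprintf("  rejected: %d non-finite, %d flatline, %d amplitude\n",
                x$rejection$nonfinite, x$rejection$flatline,
                x$rejection$amplitude))
  }
  invisible(x)
}

#' Remove interrupted or corrupted trials
#'
#' A trial is rejected when any channel contains non-finite samples, a
#' flatlined (constant) segment of at least `flat_ms`, or samples beyond
#' an absolute amplitude ceiling. Counts per reason are recorded in the
#' returned set's `rejection` field and messaged.
#'
#' @param epochs an `epoch_set`.
#' @param ceiling absolute amplitude ceiling in fT (default 10 pT).
#' @param flat_ms minimal flatline duration in ms that marks a dropout.
#' @return The `epoch_set` restricted to kept trials.
#' @export
reject_trials <- function(epochs, ceiling = 1e4, flat_ms = 50) {
  stopifnot(inherits(epochs, "epoch_set"), ceiling > 0, flat_ms > 0)
  fs <- epochs$sampling_rate
  n_tr <- dim(epochs$trials)[1]
  n_ch <- dim(epochs$trials)[3]
  bad_nf <- bad_flat <- bad_amp <- logical(n_tr)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      x <- epochs$trials[tr, , ch]
      if (anyNA(x) || any(!is.finite(x))) {
        bad_nf[tr] <- TRUE
        next
      }
      if (any(abs(x) > ceiling)) bad_amp[tr] <- TRUE
      d0 <- rle(diff(x) == 0)
      flat_run <- if (any(d0$values)) max(d0$lengths[d0$values]) else 0L
      # a run of L zero differences spans L / fs seconds of constant signal
      if (flat_run / fs * 1000 >= flat_ms) bad_flat[tr] <- TRUE
    }
  }
  bad <- bad_nf | bad_flat | bad_amp
  if (all(bad)) {
    stop_opmvef("all trials rejected", class = "opmvef_all_rejected")
  }
  rejection <- list(nonfinite = sum(bad_nf), flatline = sum(bad_flat),
                    amplitude = sum(bad_amp))
  if (any(bad)) {
    message(sum(bad), " trial(s) rejected (", rejection$nonfinite,
            " non-finite, ", rejection$flatline, " flatline, ",
            rejection$amplitude, " over ceiling)")
  }
  keep <- which(!bad)
  new_epoch_set(epochs$trials[keep, , , drop = FALSE], epochs$time_ms,
                epochs$labels, fs, epochs$onsets[keep],
                n_dropped = epochs$n_dropped, rejection = rejection)
}

#' Trial average with a per-timepoint standard-error band
#'
#' @param epochs an `epoch_set` with at least two kept trials.
#' @param channel channel label (e.g. `"Oz_z"`) or index.
#' @param baseline if `TRUE`, subtract each trial's pre-stimulus
#'   (`time_ms < 0`) mean before averaging; off by default.
#' @return An `evoked_response`: `mean` and `sem` traces (fT) on
#'   `time_ms`, with `n_trials` and the channel label.
#' @export
average_evoked <- function(epochs, channel = 1L, baseline = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- if (is.character(channel)) match(channel, epochs$labels) else as.integer(channel)
  if (is.na(ch) || ch < 1L || ch > length(epochs$labels)) {
    stop("unknown channel: ", channel)
  }
  x <- epochs$trials[, , ch, drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = dim(epochs$trials)[1])
  n <- nrow(x)
  if (n < 2L) {
    stop_opmvef("need at least 2 trials to form a standard-error band",
                class = "opmvef_too_few_trials")
  }
  if (baseline) {
    pre <- epochs$time_ms < 0
    if (any(pre)) x <- x - rowMeans(x[, pre, drop = FALSE])
  }
  m <- colMeans(x)
  sem <- apply(x, 2L, sd) / sqrt(n)
  new_evoked_response(m, sem, n_trials = n, channel = epochs$labels[ch],
                      time_ms = epochs$time_ms,
                      sampling_rate = epochs$sampling_rate)
}

new_evoked_response <- function(mean, sem, n_trials, channel, time_ms,
                                sampling_rate) {
  stopifnot(length(mean) == length(time_ms), length(sem) == length(mean),
            all(sem >= 0))
  structure(list(mean = mean, sem = sem, n_trials = as.integer(n_trials),
                 channel = channel, time_ms = time_ms,
                 sampling_rate = sampling_rate),
            class = "evoked_response")
}

#' Construct an evoked response directly from traces
#'
#' Mainly for theoretical checks and tests, where the mean trace and its
#' uncertainty band are prescribed rather than estimated from trials.
#'
#' @param mean,sem traces in fT (`sem` recycled if scalar).
#' @param time_ms time grid in ms.
#' @param channel label.
#' @param n_trials nominal trial count.
#' @return An `evoked_response`.
#' @export
evoked_response <- function(mean, sem = 0, time_ms = seq_along(mean) - 1,
                            channel = "synthetic", n_trials = 2L) {
  sem <- rep_len(sem, length(mean))
  fs <- if (length(time_ms) > 1L) 1000 / median(diff(time_ms)) else NA_real_
  new_evoked_response(mean, sem, n_trials, channel, time_ms, fs)
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> %s: %d points %g..%g ms, %d trials, peak |m| %.4g fT\n",
              x$channel, length(x$mean), min(x$time_ms), max(x$time_ms),
              x$n_trials, max(abs(x$mean))))
  invisible(x)
}
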