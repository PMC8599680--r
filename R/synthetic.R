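#' Stimulus schedule for a flash protocol
#'
#' Events are short full-field flashes separated by a dark period whose
#' length varies pseudo-randomly on the projector frame grid, so that the
#' participant cannot anticipate the next flash. Defaults follow standard
#' clinical evoked-potential practice: 0.08 s flashes, dark periods of
#' 0.92--1.00 s quantized to a 60 Hz frame clock, 300 s runs.
#'
#' @param run_duration total run length in seconds.
#' @param flash_len flash (event) duration in seconds.
#' @param isi_min,isi_max bounds of the dark inter-stimulus interval in
#'   seconds. Draws are uniform over whole projector frames, restricted to
#'   frame counts whose duration lies inside `[isi_min, isi_max]`.
#' @param frame_rate projector frame rate in Hz.
#' @param seed optional integer seed; the schedule is reproducible per seed.
#' @return A `stimulus_schedule` with fields `protocol`, `onsets` (s),
#'   `event_duration` (s), `run_duration` (s) and `frame_rate` (Hz).
#' @details Onsets start at 0 s; successive gaps equal
#'   `flash_len + isi` with `isi` drawn on the frame grid, and the last
#'   flash ends at or before `run_duration`.
#' @examples
#' sch <- generate_flash_schedule(30, seed = 1)
#' diff(sch$onsets)
#' @export
generate_flash_schedule <- function(run_duration, flash_len = 0.08,
                                    isi_min = 0.92, isi_max = 1.00,
                                    frame_rate = 60, seed = NULL) {
  stopifnot(is_scalar_num(run_duration), is_scalar_num(flash_len),
            is_scalar_num(isi_min), is_scalar_num(isi_max),
            is_scalar_num(frame_rate))
  if (flash_len <= 0) stop("`flash_len` must be positive")
  if (isi_min > isi_max) stop("`isi_min` must not exceed `isi_max`")
  if (run_duration < flash_len + isi_min) {
    stop_opmvef("run too short: no flash event fits in ", run_duration,
                " s (needs at least flash_len + isi_min = ",
                flash_len + isi_min, " s)", class = "opmvef_empty_schedule")
  }
  f_min <- as.integer(ceiling(isi_min * frame_rate - 1e-9))
  f_max <- as.integer(floor(isi_max * frame_rate + 1e-9))
  if (f_min > f_max) stop("no whole frame count lies inside [isi_min, isi_max]")
  onsets <- with_seed(seed, {
    on <- 0
    acc <- numeric(0)
    repeat {
      acc <- c(acc, on)
      frames <- if (f_min == f_max) f_min else
        sample.int(f_max - f_min + 1L, 1L) + f_min - 1L
      nxt <- on + flash_len + frames / frame_rate
      if (nxt + flash_len > run_duration) break
      on <- nxt
    }
    acc
  })
  new_stimulus_schedule("flash", onsets, event_duration = flash_len,
                        run_duration = run_duration, frame_rate = frame_rate)
}

#' Stimulus schedule for a pattern-reversal protocol
#'
#' Checkerboard contrast inversions at a fixed interval; every reversal is
#' an event. Defaults: 0.5 s (30 frame) reversal interval, 280 s runs.
#'
#' @param run_duration run length in seconds.
#' @param interval reversal interval in seconds.
#' @param margin post-event epoch margin in seconds; onsets with
#'   `onset + margin >= run_duration` are clipped so the epoch window of
#'   every retained event fits inside the run.
#' @param frame_rate projector frame rate in Hz (metadata only).
#' @return A `stimulus_schedule`.
#' @export
generate_pr_schedule <- function(run_duration, interval = 0.5, margin = 0,
                                 frame_rate = 60) {
  stopifnot(is_scalar_num(run_duration), is_scalar_num(interval),
            is_scalar_num(margin))
  if (interval <= 0) stop("`interval` must be positive")
  if (run_duration <= 0) {
    stop_opmvef("run too short: no reversal fits",
                class = "opmvef_empty_schedule")
  }
  onsets <- seq(0, run_duration, by = interval)
  onsets <- onsets[onsets + margin < run_duration]
  if (!length(onsets)) {
    stop_opmvef("margin leaves no usable reversal events",
                class = "opmvef_empty_schedule")
  }
  new_stimulus_schedule("pattern_reversal", onsets, event_duration = interval,
                        run_duration = run_duration, frame_rate = frame_rate)
}

new_stimulus_schedule <- function(protocol, onsets, event_duration,
                                  run_duration, frame_rate) {
  stopifnot(all(diff(onsets) > 0) || length(onsets) <= 1L)
  structure(list(protocol = protocol, onsets = onsets,
                 event_duration = event_duration,
                 run_duration = run_duration, frame_rate = frame_rate),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %s: %d onsets over %.4g s (first %.3g s, last %.4g s)\n",
              x$protocol, length(x$onsets), x$run_duration,
              x$onsets[1], x$onsets[length(x$onsets)]))
  invisible(x)
}

#' Specify one evoked component (P1, P2/P100, P3)
#'
#' An evoked component is modelled as a Gaussian pulse
#' \eqn{A \exp(-(t - t_0)^2 / 2\sigma^2)} with site-specific latency and
#' site/axis-specific signed amplitude. Trial-to-trial latency jitter is
#' Gaussian and shared across sensors within a trial (it is physiological,
#' not instrumental).
#'
#' @param name component label: `"P1"`, `"P2"` or `"P3"`.
#' @param t0 named numeric, per-site peak latency in ms post-onset,
#'   e.g. `c(Oz = 120, POz = 110)`.
#' @param sigma Gaussian width parameter in ms (`> 0`).
#' @param amplitude named list per site of named numeric per axis, signed
#'   amplitudes in fT at the reference stand-off,
#'   e.g. `list(Oz = c(y = -290, z = -480), POz = c(y = -260, z = -430))`.
#' @param jitter_sd trial-to-trial latency jitter standard deviation in ms.
#' @return A `component_spec`.
#' @export
component_spec <- function(name, t0, sigma, amplitude, jitter_sd = 5) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(t0), !is.null(names(t0)),
            is_scalar_num(sigma), is.list(amplitude),
            is_scalar_num(jitter_sd), jitter_sd >= 0)
  if (sigma <= 0) stop("`sigma` must be positive")
  structure(list(name = name, t0 = t0, sigma = sigma,
                 amplitude = amplitude, jitter_sd = jitter_sd),
            class = "component_spec")
}

#' Default evoked components for a flash response
#'
#' A bipolar three-component visually evoked field: positive early P1,
#' negative main P2, positive late P3, with the main component's Oz
#' amplitude at the few-hundred-fT scale seen in on-scalp recordings and
#' the associative cortex (POz) leading the primary cortex (Oz) by 10 ms
#' (P2) and 20 ms (P3). Latencies sit inside the literature component
#' windows (35--60, 83--152, 160--230 ms).
#'
#' @param p2_delay,p3_delay POz lead over Oz in ms for the main and late
#'   components.
#' @param jitter_sd trial-to-trial latency jitter sd in ms.
#' @param t0_oz named numeric, Oz latencies in ms for P1, P2, P3.
#' @return list of three [component_spec()] objects.
#' @export
default_components <- function(p2_delay = 10, p3_delay = 20, jitter_sd = 5,
                               t0_oz = c(P1 = 50, P2 = 120, P3 = 190)) {
  list(
    component_spec("P1",
                   t0 = c(Oz = unname(t0_oz["P1"]), POz = unname(t0_oz["P1"])),
                   sigma = 8,
                   amplitude = list(Oz = c(y = 90, z = 150),
                                    POz = c(y = 70, z = 120)),
                   jitter_sd = jitter_sd),
    component_spec("P2",
                   t0 = c(Oz = unname(t0_oz["P2"]),
                          POz = unname(t0_oz["P2"]) - p2_delay),
                   sigma = 15,
                   amplitude = list(Oz = c(y = -290, z = -480),
                                    POz = c(y = -260, z = -430)),
                   jitter_sd = jitter_sd),
    component_spec("P3",
                   t0 = c(Oz = unname(t0_oz["P3"]),
                          POz = unname(t0_oz["P3"]) - p3_delay),
                   sigma = 15,
                   amplitude = list(Oz = c(y = 180, z = 300),
                                    POz = c(y = 160, z = 260)),
                   jitter_sd = jitter_sd)
  )
}

#' Specify one magnetometer
#'
#' @param site scalp position, `"Oz"` or `"POz"` (10--10 system).
#' @param modality `"OPM"` (wearable, ~5 mm stand-off, 1 kHz) or `"SQUID"`
#'   (in-dewar, ~50 mm stand-off, 2 kHz).
#' @param axes measured field axes, subset of `c("y", "z")` (`z` radial,
#'   `y` tangential); OPMs default to both, SQUIDs to radial only.
#' @param standoff scalp-to-sensor distance in mm.
#' @param noise_density white sensor noise density in fT/sqrt(Hz);
#'   defaults 15 (OPM specified typical sensitivity) and 5 (SQUID).
#' @param sampling_rate DAQ rate in Hz (1000 OPM, 2000 SQUID).
#' @param line_noise_amplitude 50 Hz line interference amplitude in fT.
#' @param one_over_f_knee corner frequency in Hz below which the noise
#'   power density rises as `1 + knee/f`; `0` (the default) keeps the
#'   noise white across the band.
#' @return A `sensor_spec`.
#' @export
sensor_spec <- function(site, modality = c("OPM", "SQUID"), axes = NULL,
                        standoff = NULL, noise_density = NULL,
                        sampling_rate = NULL, line_noise_amplitude = 20,
                        one_over_f_knee = 0) {
  modality <- match.arg(modality)
  site <- match.arg(site, c("Oz", "POz"))
  if (is.null(axes)) axes <- if (modality == "OPM") c("y", "z") else "z"
  stopifnot(all(axes %in% c("y", "z")), length(axes) >= 1L)
  if (is.null(standoff)) standoff <- if (modality == "OPM") 5 else 50
  if (is.null(noise_density)) noise_density <- if (modality == "OPM") 15 else 5
  if (is.null(sampling_rate)) sampling_rate <- if (modality == "OPM") 1000 else 2000
  stopifnot(standoff > 0, noise_density >= 0, line_noise_amplitude >= 0,
            one_over_f_knee >= 0)
  structure(list(site = site, modality = modality, axes = axes,
                 standoff = standoff, noise_density = noise_density,
                 sampling_rate = sampling_rate,
                 line_noise_amplitude = line_noise_amplitude,
                 one_over_f_knee = one_over_f_knee),
            class = "sensor_spec")
}

#' Full generative description of a synthetic run
#'
#' Everything needed to reproduce a raw recording bit-exactly given the
#' seed: stimulus schedule parameters, evoked components, sensors, the
#' stand-off amplitude-scaling law and the line frequency. Component
#' amplitudes are defined at `reference_standoff` and scaled by
#' `(reference_standoff / standoff)^standoff_exponent` per sensor.
#'
#' @param protocol `"flash"` or `"pattern_reversal"`.
#' @param run_duration run length in s (default 300 flash, 280 reversal).
#' @param flash_len,isi_min,isi_max,frame_rate flash schedule parameters,
#'   see [generate_flash_schedule()].
#' @param reversal_interval pattern-reversal interval in s.
#' @param components list of [component_spec()].
#' @param sensors list of [sensor_spec()]; all must share one sampling rate.
#' @param reference_standoff stand-off (mm) at which amplitudes are defined.
#' @param standoff_exponent power-law decay exponent `p`; the far field of
#'   a current dipole motivates the default `p = 2`.
#' @param line_freq mains frequency in Hz.
#' @param seed integer RNG seed.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(protocol = c("flash", "pattern_reversal"),
                             run_duration = NULL,
                             flash_len = 0.08, isi_min = 0.92, isi_max = 1.00,
                             frame_rate = 60, reversal_interval = 0.5,
                             components = default_components(),
                             sensors = list(sensor_spec("Oz", "OPM"),
                                            sensor_spec("POz", "OPM")),
                             reference_standoff = 5, standoff_exponent = 2,
                             line_freq = 50, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(run_duration)) {
    run_duration <- if (protocol == "flash") 300 else 280
  }
  fs <- unique(vapply(sensors, function(s) s$sampling_rate, numeric(1)))
  if (length(fs) != 1L) {
    stop("all sensors in one run must share a sampling rate; simulate ",
         "modalities as separate runs")
  }
  stopifnot(reference_standoff > 0, is_scalar_num(standoff_exponent))
  structure(list(protocol = protocol, run_duration = run_duration,
                 flash_len = flash_len, isi_min = isi_min, isi_max = isi_max,
                 frame_rate = frame_rate, reversal_interval = reversal_interval,
                 components = components, sensors = sensors,
                 reference_standoff = reference_standoff,
                 standoff_exponent = standoff_exponent,
                 line_freq = line_freq, seed = seed),
            class = "synthetic_config")
}

#' Noise-free evoked waveform for one site and axis
#'
#' Sums the Gaussian pulses of all components at their programmed latencies:
#' \eqn{\sum_k A_k \exp(-(t - t_{0,k})^2 / 2\sigma_k^2)}.
#'
#' @param components list of [component_spec()].
#' @param time_ms numeric epoch time grid in ms post-onset.
#' @param site,axis which amplitude entry to use.
#' @return numeric trace in fT on `time_ms`.
#' @export
synthesize_evoked_waveform <- function(components, time_ms, site = "Oz",
                                       axis = "z") {
  stopifnot(is.numeric(time_ms))
  trace <- numeric(length(time_ms))
  for (cmp in components) {
    if (cmp$sigma <= 0) stop("component sigma must be positive")
    amp <- component_amplitude(cmp, site, axis)
    t0 <- component_t0(cmp, site)
    trace <- trace + amp * exp(-(time_ms - t0)^2 / (2 * cmp$sigma^2))
  }
  trace
}

component_amplitude <- function(cmp, site, axis) {
  a <- cmp$amplitude[[site]]
  if (is.null(a) || is.na(match(axis, names(a)))) {
    stop_opmvef("component '", cmp$name, "' defines no amplitude for ",
                site, " axis ", axis, class = "opmvef_channel_mismatch")
  }
  unname(a[[axis]])
}

component_t0 <- function(cmp, site) {
  t0 <- cmp$t0[site]
  if (is.na(t0)) {
    stop_opmvef("component '", cmp$name, "' defines no latency for site ",
                site, class = "opmvef_channel_mismatch")
  }
  unname(t0)
}

#' Simulate a raw two-site magnetometer run
#'
#' Composes the stimulus schedule, per-trial jittered Gaussian evoked
#' components (amplitudes scaled by the stand-off power law), white sensor
#' noise with RMS `noise_density * sqrt(sampling_rate / 2)` (the full
#' Nyquist bandwidth) and a 50 Hz line sinusoid with a random phase per
#' channel. The result is bit-reproducible for a given config and seed.
#'
#' @param config a [synthetic_config()].
#' @return A `raw_recording`: list with `time` (s), `channels`
#'   (samples x channels matrix, fT), `labels` (`"<site>_<axis>"`),
#'   `trigger` (event code 1 at onset samples), `sampling_rate` (Hz) and
#'   the generating `schedule` and `config` as attributes.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sensors[[1]]$sampling_rate
  n <- as.integer(round(config$run_duration * fs))
  time <- (seq_len(n) - 1L) / fs
  with_seed(config$seed, {
    schedule <- if (config$protocol == "flash") {
      generate_flash_schedule(config$run_duration, config$flash_len,
                              config$isi_min, config$isi_max,
                              config$frame_rate, seed = NULL)
    } else {
      generate_pr_schedule(config$run_duration, config$reversal_interval,
                           frame_rate = config$frame_rate)
    }
    onset_idx <- as.integer(round(schedule$onsets * fs)) + 1L
    onset_idx <- onset_idx[onset_idx >= 1L & onset_idx <= n]
    trigger <- integer(n)
    trigger[onset_idx] <- 1L
    n_trials <- length(onset_idx)
    n_comp <- length(config$components)
    # physiological latency jitter: one draw per trial and component,
    # shared across sensors and axes
    jitter <- matrix(0, n_trials, max(n_comp, 1L))
    for (k in seq_len(n_comp)) {
      sdk <- config$components[[k]]$jitter_sd
      if (sdk > 0) jitter[, k] <- rnorm(n_trials, 0, sdk)
    }
    labels <- unlist(lapply(config$sensors, function(s) {
      paste(s$site, s$axes, sep = "_")
    }))
    channels <- matrix(0, n, length(labels))
    colnames(channels) <- labels
    col <- 0L
    for (sensor in config$sensors) {
      scale <- (config$reference_standoff / sensor$standoff)^config$standoff_exponent
      for (axis in sensor$axes) {
        col <- col + 1L
        sig <- numeric(n)
        for (k in seq_len(n_comp)) {
          cmp <- config$components[[k]]
          amp <- component_amplitude(cmp, sensor$site, axis) * scale
          if (amp == 0) next
          t0_ms <- component_t0(cmp, sensor$site)
          half <- as.integer(ceiling(9 * cmp$sigma / 1000 * fs))
          for (tr in seq_len(n_trials)) {
            centre <- (onset_idx[tr] - 1L) / fs * 1000 + t0_ms + jitter[tr, k]
            c_idx <- as.integer(round(centre / 1000 * fs)) + 1L
            lo <- max(1L, c_idx - half)
            hi <- min(n, c_idx + half)
            if (lo > hi) next
            tt <- (seq.int(lo, hi) - 1L) / fs * 1000
            sig[lo:hi] <- sig[lo:hi] +
              amp * exp(-(tt - centre)^2 / (2 * cmp$sigma^2))
          }
        }
        if (sensor$noise_density > 0) {
          noise <- rnorm(n, 0, sensor$noise_density * sqrt(fs / 2))
          if (sensor$one_over_f_knee > 0) {
            # shape the white floor to PSD * (1 + knee/f) in the frequency
            # domain; the density parameter keeps describing the flat floor
            freq <- (seq_len(n) - 1L) / n * fs
            freq <- pmin(freq, fs - freq)       # two-sided spectrum
            gain <- sqrt(1 + sensor$one_over_f_knee / pmax(freq, fs / n))
            noise <- Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE)) / n
          }
          sig <- sig + noise
        }
        if (sensor$line_noise_amplitude > 0) {
          phase <- runif(1, 0, 2 * pi)
          sig <- sig + sensor$line_noise_amplitude *
            sin(2 * pi * config$line_freq * time + phase)
        }
        channels[, col] <- sig
      }
    }
    new_raw_recording(time, channels, labels, trigger, fs,
                      schedule = schedule, config = config)
  })
}

new_raw_recording <- function(time, channels, labels, trigger, sampling_rate,
                              schedule = NULL, config = NULL) {
  stopifnot(is.matrix(channels), length(time) == nrow(channels),
            length(trigger) == length(time),
            length(labels) == ncol(channels))
  structure(list(time = time, channels = channels, labels = labels,
                 trigger = trigger, sampling_rate = sampling_rate),
            schedule = schedule, config = config, class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples x %d channels at %g Hz (%.4g s), %d trigger events\n",
              nrow(x$channels), ncol(x$channels), x$sampling_rate,
              length(x$time) / x$sampling_rate, sum(x$trigger != 0)))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
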