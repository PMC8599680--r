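# File interchange: raw recordings as TSV + JSON sidecar, evoked responses
# as TSV + JSON sidecar. Desk-scale data volumes make human-readable text
# practical; units are always fT and ms in-file. Doubles are written with
# 15 significant digits (relative round-trip error < 1e-14).

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a raw recording as TSV with a JSON sidecar
#'
#' Columns: `time_s`, `trigger`, then one column per channel labeled
#' `<site>_<axis>` with values in fT. The sidecar (`<path>.json`) carries
#' the sampling rate and, for simulated runs, the generating schedule
#' parameters and seed. The round trip preserves 15 significant digits.
#'
#' @param raw a `raw_recording`.
#' @param path TSV file path.
#' @return `write_raw` returns `path` invisibly; `read_raw` a
#'   `raw_recording`.
#' @export
write_raw <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  df <- data.table::data.table(time_s = raw$time, trigger = raw$trigger)
  for (j in seq_along(raw$labels)) df[[raw$labels[j]]] <- raw$channels[, j]
  data.table::fwrite(df, path, sep = "\t")
  cfg <- attr(raw, "config")
  sch <- attr(raw, "schedule")
  meta <- list(format = "opmvef_raw_tsv", units = list(field = "fT", time = "s"),
               sampling_rate = raw$sampling_rate, channels = raw$labels)
  if (!is.null(cfg)) {
    meta$modality <- cfg$sensors[[1]]$modality
    meta$standoff_mm <- vapply(cfg$sensors, function(s) s$standoff, numeric(1))
    meta$seed <- cfg$seed
    meta$protocol <- cfg$protocol
  }
  if (!is.null(sch)) {
    meta$schedule <- list(protocol = sch$protocol,
                          run_duration = sch$run_duration,
                          event_duration = sch$event_duration,
                          frame_rate = sch$frame_rate,
                          n_onsets = length(sch$onsets))
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  need <- c("time_s", "trigger")
  if (!all(need %in% names(df))) {
    stop_opmvef("malformed raw TSV: missing column(s) ",
                paste(setdiff(need, names(df)), collapse = ", "),
                class = "opmvef_schema")
  }
  labels <- setdiff(names(df), need)
  if (!length(labels)) {
    stop_opmvef("malformed raw TSV: no channel columns",
                class = "opmvef_schema")
  }
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  fs <- if (!is.null(meta$sampling_rate)) meta$sampling_rate else {
    1 / median(diff(df$time_s))
  }
  new_raw_recording(df$time_s,
                    as.matrix(df[, labels, with = FALSE]),
                    labels, as.integer(df$trigger), fs)
}

#' Write / read an evoked response as TSV with a JSON sidecar
#'
#' Columns `time_ms`, `mean_ft`, `sem_ft`; the sidecar carries the channel
#' label, trial count and sampling rate.
#'
#' @param evoked an `evoked_response`.
#' @param path TSV file path.
#' @return `write_evoked` returns `path` invisibly; `read_evoked` an
#'   `evoked_response`.
#' @export
write_evoked <- function(evoked, path) {
  stopifnot(inherits(evoked, "evoked_response"))
  data.table::fwrite(
    data.table::data.table(time_ms = evoked$time_ms, mean_ft = evoked$mean,
                           sem_ft = evoked$sem),
    path, sep = "\t")
  jsonlite::write_json(
    list(format = "opmvef_evoked_tsv", units = list(field = "fT", time = "ms"),
         channel = evoked$channel, n_trials = evoked$n_trials,
         sampling_rate = evoked$sampling_rate),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_evoked
#' @export
read_evoked <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  need <- c("time_ms", "mean_ft", "sem_ft")
  if (!all(need %in% names(df))) {
    stop_opmvef("malformed evoked TSV: missing column(s) ",
                paste(setdiff(need, names(df)), collapse = ", "),
                class = "opmvef_schema")
  }
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  new_evoked_response(df$mean_ft, df$sem_ft,
                      n_trials = if (!is.null(meta$n_trials)) meta$n_trials else 2L,
                      channel = if (!is.null(meta$channel)) meta$channel else "unknown",
                      time_ms = df$time_ms,
                      sampling_rate = if (!is.null(meta$sampling_rate)) {
                        meta$sampling_rate
                      } else 1000 / median(diff(df$time_ms)))
}
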