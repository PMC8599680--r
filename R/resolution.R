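#' Exact temporal-resolution limit of a Gaussian pulse
#'
#' For a Gaussian pulse of width parameter `sigma` and amplitude `A` whose
#' mean trace carries a constant standard error `epsilon`, the temporal
#' resolution is the interval after (or before) the peak by which the
#' signal has dropped significantly -- i.e. by `epsilon` -- below the peak:
#' \deqn{t_{res} = \sigma \sqrt{-2 \ln(1 - \varepsilon / A)}.}
#' Valid only for `epsilon / A < 1`, i.e. signal-to-noise ratio
#' `SnR = A / epsilon > 1`.
#'
#' @param sigma Gaussian width parameter in ms (`> 0`).
#' @param epsilon standard error of the mean trace in fT (`>= 0`).
#' @param A pulse amplitude in fT (`> 0`).
#' @return temporal resolution in ms (vectorized over inputs).
#' @seealso [t_res_taylor()] for the first-order small-`epsilon/A` form,
#'   [temporal_uncertainty()] for the empirical band-crossing analogue.
#' @export
t_res_exact <- function(sigma, epsilon, A) {
  check_tres_args(sigma, epsilon, A)
  sigma * sqrt(-2 * log(1 - epsilon / A))
}

#' First-order temporal-resolution limit
#'
#' Taylor expansion of [t_res_exact()] in the logarithm:
#' \deqn{t_{res} \approx \sigma \sqrt{2 \varepsilon / A},}
#' i.e. \eqn{t_{res} \propto w / \sqrt{SnR}}, which also holds for
#' non-Gaussian pulses of width `w`. Always a lower bound on the exact
#' value (since `-log(1 - x) >= x`).
#'
#' @inheritParams t_res_exact
#' @return temporal resolution in ms.
#' @export
t_res_taylor <- function(sigma, epsilon, A) {
  check_tres_args(sigma, epsilon, A)
  sigma * sqrt(2 * epsilon / A)
}

check_tres_args <- function(sigma, epsilon, A) {
  stopifnot(is.numeric(sigma), is.numeric(epsilon), is.numeric(A))
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  if (any(epsilon < 0)) stop("`epsilon` must be non-negative")
  if (any(A <= 0)) stop("`A` must be positive")
  if (any(epsilon / A >= 1)) {
    stop_opmvef("temporal resolution is defined only for epsilon/A < 1 ",
                "(SnR > 1)", class = "opmvef_snr_domain")
  }
  invisible(TRUE)
}

#' Figure of merit for temporal resolution, with uncertainty
#'
#' \eqn{\eta = \sqrt{A} / w}: larger `eta` means a sharper, stronger pulse
#' and hence finer temporal resolution at a given noise level. The
#' uncertainty is first-order propagation from the amplitude and width
#' errors, assumed independent:
#' \deqn{\delta\eta = \eta \sqrt{(\delta A / 2A)^2 + (\delta w / w)^2}.}
#'
#' @param A pulse amplitude in fT (`> 0`).
#' @param w pulse width in ms (`> 0`), the span between the adjacent
#'   local minima.
#' @param delta_A,delta_w standard uncertainties of `A` (fT) and `w` (ms).
#' @return list with `eta` and `delta_eta` (sqrt(fT)/ms).
#' @export
eta_with_uncertainty <- function(A, w, delta_A = 0, delta_w = 0) {
  stopifnot(is.numeric(A), is.numeric(w), delta_A >= 0, delta_w >= 0)
  if (any(A <= 0)) stop("`A` must be positive")
  if (any(w <= 0)) stop("`w` must be positive")
  eta <- sqrt(A) / w
  delta_eta <- eta * sqrt((delta_A / (2 * A))^2 + (delta_w / w)^2)
  list(eta = eta, delta_eta = delta_eta)
}

#' Characterize a pulse by its adjacent local minima
#'
#' Functional fits to multi-component evoked fields are often unreliable,
#' so the pulse is characterized non-parametrically on the mean trace: the
#' peak is the extremum of largest absolute deflection inside
#' `search_window`; the width `w` is the time between the two local minima
#' adjacent to the peak (searched over the full epoch); the amplitude `A`
#' is the difference between the peak value and the mean of those two
#' minima. Negative-going pulses are sign-flipped before the minima
#' search and the polarity recorded.
#'
#' @param evoked an `evoked_response`.
#' @param search_window `(lo, hi)` in ms; the peak is sought here.
#' @param smooth if `TRUE`, a 3-sample running median is applied before
#'   extrema detection (guard for very noisy traces; off by default).
#' @return A `pulse_feature`: `t_peak`, `t_min_left`, `t_min_right`, `w`
#'   (ms), `A` and its standard error `delta_A` (fT), the band-crossing
#'   time error `delta_t` (ms, full two-sided span), `eta` and
#'   `delta_eta` (sqrt(fT)/ms), `polarity`, and an `edge_truncated` flag
#'   set when a bracketing minimum had to fall back to an epoch edge.
#' @seealso [find_component_peaks()] for window-constrained component
#'   selection, [temporal_uncertainty()] for the time error alone.
#' @export
characterize_pulse <- function(evoked, search_window, smooth = FALSE) {
  stopifnot(inherits(evoked, "evoked_response"), length(search_window) == 2L,
            search_window[1] < search_window[2])
  t <- evoked$time_ms
  in_win <- which(t >= search_window[1] & t <= search_window[2])
  if (length(in_win) < 3L) {
    stop_opmvef("search window must contain at least 3 samples inside the ",
                "epoch grid", class = "opmvef_window")
  }
  m <- evoked$mean
  if (smooth) m <- stats::runmed(m, 3L)
  i_peak <- in_win[which.max(abs(m[in_win]))]
  characterize_at(evoked, i_peak, flip = m[i_peak] < 0, trace = m)
}

# Characterize the pulse whose peak is at grid index `i_peak`; `flip`
# selects the negative-polarity branch (trace sign-flipped before the
# minima search).
characterize_at <- function(evoked, i_peak, flip = FALSE, trace = NULL) {
  t <- evoked$time_ms
  m <- if (is.null(trace)) evoked$mean else trace
  v <- if (flip) -m else m
  mins <- local_minima_idx(v)
  left <- mins[mins < i_peak]
  right <- mins[mins > i_peak]
  edge <- FALSE
  if (length(left)) {
    i_l <- max(left)
  } else {
    i_l <- 1L
    edge <- TRUE
  }
  if (length(right)) {
    i_r <- min(right)
  } else {
    i_r <- length(v)
    edge <- TRUE
  }
  w <- t[i_r] - t[i_l]
  A <- v[i_peak] - mean(c(v[i_l], v[i_r]))
  delta_A <- evoked$sem[i_peak]
  # time error at the peak: full two-sided band-crossing span
  peak_band <- band_span(t, v, i_peak, evoked$sem[i_peak])
  # width error: band-crossing spans at each bracketing minimum, combined
  # in quadrature
  span_l <- band_span(t, -v, i_l, evoked$sem[i_l])
  span_r <- band_span(t, -v, i_r, evoked$sem[i_r])
  delta_w <- sqrt(span_l$span^2 + span_r$span^2)
  if (A > 0 && w > 0) {
    e <- eta_with_uncertainty(A, w, delta_A, delta_w)
  } else {
    e <- list(eta = NA_real_, delta_eta = NA_real_)
  }
  structure(list(t_peak = t[i_peak], t_min_left = t[i_l],
                 t_min_right = t[i_r], w = w, A = A, delta_A = delta_A,
                 delta_t = peak_band$span, delta_w = delta_w,
                 eta = e$eta, delta_eta = e$delta_eta,
                 polarity = if (flip) "negative" else "positive",
                 edge_truncated = edge || peak_band$truncated,
                 channel = evoked$channel),
            class = "pulse_feature")
}

#' @export
print.pulse_feature <- function(x, ...) {
  cat(sprintf("<pulse_feature> %s peak at %.4g ms (minima %.4g / %.4g ms)\n",
              x$polarity, x$t_peak, x$t_min_left, x$t_min_right))
  cat(sprintf("  w = %.4g ms, A = %.4g +/- %.3g fT, dt = %.3g ms, eta = %.4g +/- %.3g sqrt(fT)/ms%s\n",
              x$w, x$A, x$delta_A, x$delta_t, x$eta, x$delta_eta,
              if (isTRUE(x$edge_truncated)) " [edge-truncated]" else ""))
  invisible(x)
}

# Width of the uncertainty band at the extremum `i` of trace `v`
# (a maximum of v): the interval between the first crossings, on each
# side of i, of the level v[i] - eps, with sub-sample linear
# interpolation. Returns list(span, t_left, t_right, truncated).
band_span <- function(t, v, i, eps) {
  if (eps <= 0) {
    return(list(span = 0, t_left = t[i], t_right = t[i], truncated = FALSE))
  }
  thr <- v[i] - eps
  truncated <- FALSE
  t_left <- t[1]
  if (i > 1L) {
    below <- which(v[seq_len(i - 1L)] < thr)
    if (length(below)) {
      j <- max(below)
      t_left <- t[j] + (t[j + 1L] - t[j]) * (thr - v[j]) / (v[j + 1L] - v[j])
    } else truncated <- TRUE
  } else truncated <- TRUE
  t_right <- t[length(t)]
  if (i < length(v)) {
    below <- which(v[(i + 1L):length(v)] < thr)
    if (length(below)) {
      j <- i + min(below)
      t_right <- t[j - 1L] + (t[j] - t[j - 1L]) * (thr - v[j - 1L]) / (v[j] - v[j - 1L])
    } else truncated <- TRUE
  } else truncated <- TRUE
  list(span = t_right - t_left, t_left = t_left, t_right = t_right,
       truncated = truncated)
}

#' Empirical time error of a peak from the uncertainty band
#'
#' The time span around the peak over which the mean trace stays within
#' `sem(t_peak)` of the peak value: the distance between the first
#' crossings of `peak - sem` on each side (trace sign-flipped first for a
#' negative peak). For a Gaussian pulse with a constant standard-error
#' band this equals twice [t_res_exact()]. Crossings are located with
#' sub-sample linear interpolation.
#'
#' @param evoked an `evoked_response`.
#' @param feature a `pulse_feature` (only `t_peak` and `polarity` are
#'   used), or a peak time in ms.
#' @return the full two-sided span in ms, with attribute `edge_truncated`
#'   set to `TRUE` when the band is never crossed on one side inside the
#'   epoch (the epoch edge is used instead).
#' @export
temporal_uncertainty <- function(evoked, feature) {
  stopifnot(inherits(evoked, "evoked_response"))
  if (inherits(feature, "pulse_feature")) {
    t_peak <- feature$t_peak
    flip <- identical(feature$polarity, "negative")
  } else {
    stopifnot(is_scalar_num(feature))
    t_peak <- feature
    flip <- NA
  }
  i <- which.min(abs(evoked$time_ms - t_peak))
  if (abs(evoked$time_ms[i] - t_peak) > 1000 / evoked$sampling_rate) {
    stop_opmvef("feature peak lies outside the evoked time grid",
                class = "opmvef_window")
  }
  if (is.na(flip)) flip <- evoked$mean[i] < 0
  v <- if (flip) -evoked$mean else evoked$mean
  bs <- band_span(evoked$time_ms, v, i, evoked$sem[i])
  structure(bs$span, edge_truncated = bs$truncated)
}
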