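#' Literature latency windows for evoked components
#'
#' Peak-time constraints for the early (P1), main (P2 for flash, P100 for
#' pattern reversal) and late (P3) components, from the clinical
#' evoked-potential literature. Windows constrain only the peak time; the
#' bracketing minima that define a pulse's width may lie outside them.
#'
#' @param P1,P2,P3 numeric `(lo, hi)` windows in ms post-stimulus.
#' @return A `component_windows` list.
#' @export
component_windows <- function(P1 = c(35, 60), P2 = c(83, 152),
                              P3 = c(160, 230)) {
  w <- list(P1 = as.numeric(P1), P2 = as.numeric(P2), P3 = as.numeric(P3))
  for (x in w) stopifnot(length(x) == 2L, x[1] < x[2])
  bounds <- unlist(w)
  if (any(diff(bounds) < 0)) {
    stop("component windows must be non-overlapping and increasing")
  }
  structure(w, class = "component_windows")
}

#' Select and characterize the dominant peak of each component
#'
#' Within each latency window, every local extremum of the mean trace is
#' characterized with the adjacent-minima rule and the one with the
#' largest characterized amplitude `A` is selected (tie broken by earlier
#' latency). Dominance by `A` rather than by raw trace value keeps
#' baseline offsets from deciding the winner. Components with no local
#' extremum inside their window are reported absent (`NULL`), never
#' fabricated.
#'
#' @param evoked an `evoked_response` whose grid covers all windows.
#' @param windows a [component_windows()].
#' @param positive_only if `TRUE`, only positive-going peaks are
#'   considered (for planar magnitude traces, which are non-negative by
#'   construction).
#' @param smooth passed to the characterization step.
#' @return named list of `pulse_feature` or `NULL` per component.
#' @export
find_component_peaks <- function(evoked, windows = component_windows(),
                                 positive_only = FALSE, smooth = FALSE) {
  stopifnot(inherits(evoked, "evoked_response"),
            inherits(windows, "component_windows"))
  t <- evoked$time_ms
  hi_need <- max(vapply(windows, `[`, numeric(1), 2L))
  lo_need <- min(vapply(windows, `[`, numeric(1), 1L))
  if (min(t) > lo_need || max(t) < hi_need) {
    stop_opmvef("evoked grid (", min(t), "..", max(t),
                " ms) does not cover the component windows",
                class = "opmvef_window")
  }
  m <- if (smooth) stats::runmed(evoked$mean, 3L) else evoked$mean
  maxima <- local_maxima_idx(m)
  minima <- if (positive_only) integer(0) else local_minima_idx(m)
  out <- stats::setNames(vector("list", length(windows)), names(windows))
  for (comp in names(windows)) {
    win <- windows[[comp]]
    cand <- c(maxima[t[maxima] >= win[1] & t[maxima] <= win[2]],
              minima[t[minima] >= win[1] & t[minima] <= win[2]])
    flips <- rep(c(FALSE, TRUE),
                 c(sum(t[maxima] >= win[1] & t[maxima] <= win[2]),
                   sum(t[minima] >= win[1] & t[minima] <= win[2])))
    if (!length(cand)) next
    feats <- lapply(seq_along(cand), function(k) {
      characterize_at(evoked, cand[k], flip = flips[k], trace = m)
    })
    amps <- vapply(feats, function(f) f$A, numeric(1))
    tps <- vapply(feats, function(f) f$t_peak, numeric(1))
    keep <- which(amps > 0)
    if (!length(keep)) next
    best <- keep[order(-amps[keep], tps[keep])][1]
    out[[comp]] <- feats[[best]]
  }
  out
}

#' Inter-site delay of one evoked component
#'
#' The POz-to-Oz latency difference of a component's peak,
#' `delta_tau = t_peak(Oz) - t_peak(POz)`, so that a positive delay means
#' the associative cortex (POz) leads the primary cortex (Oz). The
#' uncertainty combines each site's band-crossing half-width in
#' quadrature, assuming independence between sites.
#'
#' @param evoked_oz,evoked_poz `evoked_response` at the two sites.
#' @param component which component (`"P1"`, `"P2"`, `"P3"`).
#' @param windows a [component_windows()].
#' @param positive_only passed to [find_component_peaks()].
#' @return A `delay_estimate` with `delta_tau` (ms), `delta` (ms), the
#'   site pair and the per-site features. When the component is absent at
#'   either site the estimate is flagged not estimable (`delta_tau` is
#'   `NA` and `reason` says which site).
#' @export
compute_delay <- function(evoked_oz, evoked_poz, component = "P2",
                          windows = component_windows(),
                          positive_only = FALSE) {
  component <- match.arg(component, names(windows))
  f_oz <- find_component_peaks(evoked_oz, windows, positive_only)[[component]]
  f_poz <- find_component_peaks(evoked_poz, windows, positive_only)[[component]]
  if (is.null(f_oz) || is.null(f_poz)) {
    missing_at <- c("Oz"[is.null(f_oz)], "POz"[is.null(f_poz)])
    return(structure(list(component = component, delta_tau = NA_real_,
                          delta = NA_real_, sites = c("Oz", "POz"),
                          features = list(Oz = f_oz, POz = f_poz),
                          estimable = FALSE,
                          reason = paste("component absent at",
                                         paste(missing_at, collapse = " and "))),
                     class = "delay_estimate"))
  }
  delta_tau <- f_oz$t_peak - f_poz$t_peak
  delta <- sqrt((f_oz$delta_t / 2)^2 + (f_poz$delta_t / 2)^2)
  structure(list(component = component, delta_tau = delta_tau, delta = delta,
                 sites = c("Oz", "POz"),
                 features = list(Oz = f_oz, POz = f_poz),
                 estimable = TRUE, reason = NULL),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<delay_estimate> %s: not estimable (%s)\n",
                x$component, x$reason))
  } else {
    cat(sprintf("<delay_estimate> %s: delta_tau = %.4g +/- %.3g ms (%s -> %s, positive = POz leads)\n",
                x$component, x$delta_tau, x$delta, x$sites[2], x$sites[1]))
  }
  invisible(x)
}

#' Planar field magnitude from two measured axes
#'
#' Pointwise magnitude of the field projected on the measurement plane,
#' \eqn{|B_{yz}| = \sqrt{B_y^2 + B_z^2}}. A magnitude trace cannot
#' confuse a rotation of the field vector with a change of its size, which
#' reduces timing artefacts present in any single measured component;
#' its peaks are always non-negative.
#'
#' @param by,bz numeric traces (fT) on a common grid, or two
#'   `evoked_response` objects from the two axes of one sensor (grids
#'   must match; the returned object then carries a first-order
#'   propagated standard-error band).
#' @return numeric trace, or an `evoked_response` for evoked input.
#' @export
planar_magnitude <- function(by, bz) {
  if (inherits(by, "evoked_response") || inherits(bz, "evoked_response")) {
    stopifnot(inherits(by, "evoked_response"), inherits(bz, "evoked_response"))
    if (length(by$time_ms) != length(bz$time_ms) ||
        any(abs(by$time_ms - bz$time_ms) > 1e-9)) {
      stop_opmvef("axis traces are on different time grids",
                  class = "opmvef_grid_mismatch")
    }
    mag <- sqrt(by$mean^2 + bz$mean^2)
    sem <- ifelse(mag > 0,
                  sqrt((by$mean * by$sem)^2 + (bz$mean * bz$sem)^2) / mag,
                  sqrt((by$sem^2 + bz$sem^2) / 2))
    site <- sub("_[yz]$", "", by$channel)
    return(new_evoked_response(mag, sem,
                               n_trials = min(by$n_trials, bz$n_trials),
                               channel = paste0(site, "_yz"),
                               time_ms = by$time_ms,
                               sampling_rate = by$sampling_rate))
  }
  stopifnot(is.numeric(by), is.numeric(bz))
  if (length(by) != length(bz)) {
    stop_opmvef("axis traces have different lengths",
                class = "opmvef_grid_mismatch")
  }
  sqrt(by^2 + bz^2)
}
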