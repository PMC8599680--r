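#' Pearson correlation between two evoked traces, with uncertainty
#'
#' Run-to-run and participant-to-participant consistency of evoked fields
#' is summarized by the Pearson correlation of the averaged traces. Two
#' uncertainty conventions are supported: the large-sample standard error
#' `sqrt((1 - r^2) / (n - 2))`, and the half-width of the 95% confidence
#' interval from the Fisher z-transform.
#'
#' @param x,y numeric traces of equal length (`>= 3`), or
#'   `evoked_response` objects (their mean traces are used).
#' @param uncertainty_kind which uncertainty populates the `uncertainty`
#'   field; both are always computed and stored.
#' @param pair optional label for the pair.
#' @return A `correlation_result`: `r`, `uncertainty`,
#'   `uncertainty_kind`, `se`, `ci95_halfwidth`, `n`, `pair`.
#' @export
pearson_r <- function(x, y,
                      uncertainty_kind = c("standard_error", "ci95_halfwidth"),
                      pair = NULL) {
  uncertainty_kind <- match.arg(uncertainty_kind)
  if (inherits(x, "evoked_response")) x <- x$mean
  if (inherits(y, "evoked_response")) y <- y$mean
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x)
  if (n != length(y)) stop("traces must have equal length")
  if (n < 3L) stop("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_opmvef("correlation undefined for a zero-variance trace",
                class = "opmvef_zero_variance")
  }
  r <- cor(x, y)
  se <- sqrt((1 - r^2) / (n - 2))
  ci <- if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    hw <- stats::qnorm(0.975) / sqrt(n - 3)
    (tanh(z + hw) - tanh(z - hw)) / 2
  } else if (abs(r) == 1) 0 else NA_real_
  structure(list(r = r,
                 uncertainty = if (uncertainty_kind == "standard_error") se else ci,
                 uncertainty_kind = uncertainty_kind,
                 se = se, ci95_halfwidth = ci, n = n, pair = pair),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result>%s r = %.3f +/- %.3f (%s, n = %d)\n",
              if (is.null(x$pair)) "" else paste0(" ", x$pair, ":"),
              x$r, x$uncertainty, x$uncertainty_kind, x$n))
  invisible(x)
}

#' Pairwise correlation table across runs or participants
#'
#' Within mode quantifies run-to-run reproducibility for one participant:
#' all run pairs are correlated (standard-error uncertainty per pair) and
#' the summary is the mean pairwise `r` with the standard error of that
#' mean. Between mode quantifies participant-to-participant consistency:
#' traces belonging to the same participant (per `groups`) are first
#' averaged, then participant pairs are correlated with 95%
#' confidence-interval half-widths. Grids are aligned by the intersection
#' of the epochs; `range_ms` optionally restricts the compared span.
#'
#' @param traces named list of `evoked_response` (or plain numeric traces
#'   on a shared grid).
#' @param mode `"within"` (runs of one participant) or `"between"`
#'   (participants).
#' @param groups for between mode, a character vector mapping each trace
#'   to its participant; defaults to one trace per participant.
#' @param range_ms optional `(lo, hi)` in ms restricting the compared span.
#' @return data.frame with columns `pair`, `r`, `uncertainty`, `kind`,
#'   `n`, of class `correlation_table`; within mode carries `mean_r` and
#'   `mean_r_se` attributes.
#' @export
correlation_table <- function(traces, mode = c("within", "between"),
                              groups = NULL, range_ms = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(traces), length(traces) >= 2L)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- paste0(if (mode == "within") "run" else "subject",
                            seq_along(traces))
  }
  aligned <- align_traces(traces, range_ms)
  if (mode == "between") {
    if (is.null(groups)) groups <- names(aligned)
    stopifnot(length(groups) == length(aligned))
    aligned <- lapply(split(seq_along(aligned), groups), function(idx) {
      rowMeans(do.call(cbind, aligned[idx]))
    })
    kind <- "ci95_halfwidth"
  } else {
    kind <- "standard_error"
  }
  nm <- names(aligned)
  pairs <- utils::combn(length(aligned), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cr <- pearson_r(aligned[[i]], aligned[[j]], uncertainty_kind = kind,
                    pair = paste(nm[i], nm[j], sep = "-"))
    data.frame(pair = cr$pair, r = cr$r, uncertainty = cr$uncertainty,
               kind = cr$uncertainty_kind, n = cr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", "data.frame")
  if (mode == "within") {
    attr(out, "mean_r") <- mean(out$r)
    attr(out, "mean_r_se") <- if (nrow(out) > 1L) {
      sd(out$r) / sqrt(nrow(out))
    } else {
      out$uncertainty[1]
    }
  }
  out
}

# Restrict every trace to the common (intersection) time grid.
align_traces <- function(traces, range_ms = NULL) {
  is_ev <- vapply(traces, inherits, logical(1), "evoked_response")
  if (!any(is_ev)) {
    len <- unique(lengths(traces))
    if (length(len) != 1L) {
      stop_opmvef("plain traces must share one grid",
                  class = "opmvef_grid_mismatch")
    }
    return(lapply(traces, as.numeric))
  }
  stopifnot(all(is_ev))
  grids <- lapply(traces, function(e) round(e$time_ms, 9))
  common <- Reduce(intersect, grids)
  if (!is.null(range_ms)) {
    common <- common[common >= range_ms[1] & common <= range_ms[2]]
  }
  if (length(common) < 3L) {
    stop_opmvef("no overlapping time grid across traces",
                class = "opmvef_grid_mismatch")
  }
  lapply(traces, function(e) e$mean[match(common, round(e$time_ms, 9))])
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("<correlation_table>\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  if (!is.null(attr(x, "mean_r"))) {
    cat(sprintf("  mean pairwise r = %.3f +/- %.3f (SE of mean)\n",
                attr(x, "mean_r"), attr(x, "mean_r_se")))
  }
  invisible(x)
}
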