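# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. `seed = NULL` uses the
# current stream (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Indices of strict local minima of `v` on the discrete grid, defined by a
# sign change of the first difference from negative to positive. A plateau
# (zero differences) flanked by a descent and an ascent counts as one
# minimum at the plateau midpoint (lower index on ties).
local_minima_idx <- function(v) {
  stopifnot(is.numeric(v))
  n <- length(v)
  if (n < 3L) return(integer(0))
  d <- diff(v)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  out <- integer(0)
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]
    j <- nz[k + 1L]
    if (d[i] < 0 && d[j] > 0) {
      out <- c(out, (i + 1L + j) %/% 2L)
    }
  }
  out
}

# Local maxima by the mirrored rule.
local_maxima_idx <- function(v) local_minima_idx(-v)

stop_opmvef <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "opmvef_error")))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
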