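# Internal helpers shared across modules.

# Classed error so callers can branch on failure modes
# (e.g. "pupiltrack_no_valley", "pupiltrack_undefined_shift").
.pt_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pupiltrack_error", "error", "condition")))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    .pt_abort(sprintf("'%s' must be a single positive finite number", name),
              "pupiltrack_invalid_parameter")
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    .pt_abort(sprintf("'%s' must be a single non-negative finite number", name),
              "pupiltrack_invalid_parameter")
  }
  invisible(x)
}

# Derive a stream of reproducible sub-seeds (< 2^31) from one master seed.
.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# First downward crossing of y(x) through `level`, linearly interpolated.
# Returns NA_real_ when the curve never drops below `level`.
.first_crossing_below <- function(x, y, level) {
  below <- which(y < level)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(x[1L])
  x[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}

# First upward crossing of y(x) through `level`, linearly interpolated.
.first_crossing_above <- function(x, y, level) {
  above <- which(y >= level)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(x[1L])
  x[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}
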