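# Internal validation and seeding helpers shared across modules.

# Deterministic sub-stream seeds: one root seed expands into per-animal /
# per-purpose streams so adding an animal never shifts another's stream.
# Arithmetic stays below 2^53 so the modulus is exact in doubles.
sub_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(k) * 30269) %% 2147483629 + 1)
}

# Evaluate `expr` under `seed` (restoring RNG state), or as-is when seed is NULL.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single finite probability strictly inside (0, 1), got %s.",
                  name, deparse(substitute(x))),
          class = "quiescreen_parameter_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "quiescreen_parameter_error")
  }
  invisible(as.integer(x))
}

assert_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")),
          class = "quiescreen_format_error")
  }
  invisible(data)
}

# Regular-sampling check; returns the sampling interval. Tolerance is relative
# to the median interval so second- and millisecond-scale clocks both pass.
check_regular_times <- function(time_s, tol = 1e-3, what = "time series") {
  if (length(time_s) < 2L) {
    abort(sprintf("%s must contain at least 2 time points.", what),
          class = "quiescreen_input_error")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    abort(sprintf("%s has non-increasing timestamps (first offence at row %d).", what, bad),
          class = "quiescreen_format_error")
  }
  dt0 <- stats::median(dt)
  off <- which(abs(dt - dt0) > tol * dt0)
  if (length(off) > 0L) {
    abort(sprintf("%s is irregularly sampled beyond tolerance (rows %s; median interval %.6g s).",
                  what, paste(head(off + 1L, 5L), collapse = ", "), dt0),
          class = "quiescreen_format_error")
  }
  dt0
}

state_to_int <- function(state) {
  if (is.logical(state)) state <- as.integer(state)
  if (!all(state %in% c(0L, 1L, NA))) {
    abort("Quiescence state must be binary (0 = active, 1 = quiescent).",
          class = "quiescreen_input_error")
  }
  as.integer(state)
}
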