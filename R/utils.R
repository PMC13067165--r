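# Internal validation helpers shared across the package.

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "swellkin_validation_error")
}

check_finite_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort_bad_arg(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort_bad_arg(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_times <- function(times, positive = FALSE) {
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times))) {
    abort_bad_arg("`times` must be a non-empty finite numeric vector.")
  }
  if (positive) {
    if (any(times <= 0)) abort_bad_arg("`times` must be strictly positive.")
  } else if (any(times < 0)) {
    abort_bad_arg("`times` must be non-negative.")
  }
  invisible(times)
}

# exp(-u) with the exponent clamped so extreme rate * time products cannot
# overflow; for u >= 700 the result is indistinguishable from 0 in double
# precision anyway.
exp_neg_clamped <- function(u) {
  exp(-pmin(u, 700))
}

check_curve_df <- function(data, time_col = "time_h", value_col = "swelling",
                           min_points = 4L) {
  if (!is.data.frame(data)) abort_bad_arg("`data` must be a data frame.")
  for (col in c(time_col, value_col)) {
    if (!col %in% names(data)) {
      abort_bad_arg(sprintf("`data` must have a `%s` column.", col))
    }
  }
  t <- data[[time_col]]
  y <- data[[value_col]]
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    abort_bad_arg("times and values must all be finite.")
  }
  if (length(t) < min_points) {
    abort_bad_arg(sprintf("at least %d points are required.", min_points))
  }
  if (any(t < 0)) abort_bad_arg("times must be non-negative.")
  if (is.unsorted(t, strictly = TRUE)) {
    abort_bad_arg("times must be strictly increasing within a curve.")
  }
  invisible(data)
}
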