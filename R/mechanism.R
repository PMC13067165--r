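#' Time-resolved Fickian and relaxational contributions
#'
#' The diffusion/relaxation decomposition of the swelling equation gives the
#' Fickian contribution in closed form,
#' \deqn{CF(t) = \frac{1}{1 + (b^*/a^*)\sqrt{t}}, \qquad CR = 1 - CF,}
#' independent of the rate constant `k` by construction: the mechanism is set
#' entirely by the network parameters. For `a_star = 0` the pure-relaxation
#' limit `CF = 0` is returned. Where the closed form leaves `[0, 1]` (mixed
#' parameter signs, as in overshoot-shaped curves) the point is flagged
#' invalid rather than reinterpreted.
#'
#' @param times Strictly positive times in hours.
#' @param a_star Diffusive-amplitude parameter.
#' @param b_star Relaxational-amplitude parameter. Not both zero.
#' @return A tibble with columns `time_h`, `CF`, `CR` and `valid`; class
#'   `"mechanism_profile"` for plotting.
#' @examples
#' fickian_contribution(c(1, 4, 25), a_star = 1, b_star = 10)
#' @export
fickian_contribution <- function(times, a_star, b_star) {
  check_times(times, positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  if (a_star == 0 && b_star == 0) {
    abort_bad_arg("at least one of `a_star`, `b_star` must be nonzero.")
  }
  CF <- if (a_star == 0) {
    rep(0, length(times))
  } else {
    1 / (1 + (b_star / a_star) * sqrt(times))
  }
  out <- tibble::tibble(
    time_h = times,
    CF = CF,
    CR = 1 - CF,
    valid = is.finite(CF) & CF >= 0 & CF <= 1
  )
  class(out) <- c("mechanism_profile", class(out))
  out
}

#' Fickian contribution from the truncated component series
#'
#' Computes `CF = f_N / (f_N + r_N)` from the termwise diffusion/relaxation
#' component sums of [component_series()]. Serves as the independent series
#' oracle for the closed form of [fickian_contribution()], to which it
#' converges as `order` grows (at order 1 the shared `k t` factor already
#' cancels exactly).
#'
#' @inheritParams component_series
#' @return Numeric vector of Fickian contribution values.
#' @export
cf_series_oracle <- function(times, k, a_star, b_star, order = 40) {
  comp <- component_series(times, k, a_star, b_star, order)
  comp$f / (comp$f + comp$r)
}

#' Classify the transport mechanism from the a*/b* ratio
#'
#' Places a fitted parameter pair on the mechanism scale: relaxational
#' uptake dominates when `b_star` is about ten times `a_star` or more
#' (ratio at or below `lower`, default 0.1), Fickian diffusion when
#' `a_star` exceeds about a hundred times `b_star` (ratio at or above
#' `upper`, default 100), anomalous transport in between. A second,
#' time-resolved label reports which mechanism contributes more than half
#' of the uptake at `reference_time`. Negative `a_star` marks the overshoot
#' regime, which is associated with macromolecular relaxation and makes the
#' closed-form CF invalid.
#'
#' @param k Rate constant (carried through for reporting; the mechanism is
#'   k-independent).
#' @param a_star,b_star Network parameters of the swelling equation.
#' @param reference_time Time (h) at which dominance is evaluated.
#' @param lower,upper Ratio thresholds for the hard classification.
#' @return A one-row tibble: `ratio`, `hard_label`, `dominance_label`,
#'   `reference_time`, `overshoot_regime`, `ratio_defined`.
#' @export
classify_from_ratio <- function(k, a_star, b_star, reference_time = 1,
                                lower = 0.1, upper = 100) {
  check_finite_scalar(k, "k", positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  check_finite_scalar(reference_time, "reference_time", positive = TRUE)
  if (lower >= upper) abort_bad_arg("`lower` must be below `upper`.")
  if (a_star == 0 && b_star == 0) {
    abort_bad_arg("at least one of `a_star`, `b_star` must be nonzero.")
  }
  overshoot <- a_star < 0 && b_star > 0
  if (b_star == 0) {
    # pure-diffusive limit: the ratio diverges
    return(tibble::tibble(
      ratio = NA_real_, hard_label = "fickian_diffusion",
      dominance_label = "fickian_diffusion",
      reference_time = reference_time,
      overshoot_regime = overshoot, ratio_defined = FALSE))
  }
  ratio <- a_star / b_star
  hard <- if (ratio >= upper) {
    "fickian_diffusion"
  } else if (ratio >= 0 && ratio <= lower) {
    "macromolecular_relaxation"
  } else {
    "anomalous"
  }
  if (overshoot) {
    dominance <- "macromolecular_relaxation"
  } else {
    cf <- fickian_contribution(reference_time, a_star, b_star)
    dominance <- if (isTRUE(cf$valid[1]) && cf$CF[1] > 0.5) {
      "fickian_diffusion"
    } else {
      "macromolecular_relaxation"
    }
  }
  tibble::tibble(
    ratio = ratio, hard_label = hard, dominance_label = dominance,
    reference_time = reference_time, overshoot_regime = overshoot,
    ratio_defined = TRUE)
}

#' Classify the transport mechanism from the power-law exponent
#'
#' Standard diffusional-exponent ranges: `n` in `[0.43, 0.50]` is Fickian
#' diffusion, `n` in `[0.85, 1.0]` macromolecular relaxation, values in
#' between anomalous transport. Exponents outside `[0.43, 1.0]` are labelled
#' `out_of_range` with the nearest class noted.
#'
#' @param n Power-law diffusional exponent, > 0.
#' @return A one-row tibble with `n`, `label` and `nearest` (the nearest
#'   class when out of range, otherwise equal to `label`).
#' @export
classify_from_exponent <- function(n) {
  check_finite_scalar(n, "n", positive = TRUE)
  if (n < 0.43) {
    label <- "out_of_range"; nearest <- "fickian_diffusion"
  } else if (n <= 0.50) {
    label <- nearest <- "fickian_diffusion"
  } else if (n < 0.85) {
    label <- nearest <- "anomalous"
  } else if (n <= 1.0) {
    label <- nearest <- "macromolecular_relaxation"
  } else {
    label <- "out_of_range"; nearest <- "macromolecular_relaxation"
  }
  tibble::tibble(n = n, label = label, nearest = nearest)
}
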