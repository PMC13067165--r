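#' Evaluate the unified swelling-kinetics equation
#'
#' Computes the swelling degree predicted by the three-parameter model
#' \deqn{S(t) = (1 - e^{-k t})\,(a^* \sqrt{t} + b^*)}
#' in which `k` (1/h) sets the speed of solvent penetration while the two
#' network parameters `a_star` ((g/g) h^-1/2, diffusive amplitude) and
#' `b_star` (g/g, relaxational amplitude) fix the transport mechanism.
#' A negative `a_star` with positive `b_star` produces an overshoot-shaped
#' curve (a transient uptake maximum above the long-time plateau); for
#' `a_star = 0` the model collapses exactly to first-order kinetics with
#' plateau `b_star`.
#'
#' @param times Non-negative times in hours.
#' @param k Solvent-penetration rate constant, 1/h, > 0.
#' @param a_star Diffusive-amplitude parameter, any sign.
#' @param b_star Relaxational-amplitude parameter, any sign. At least one of
#'   `a_star`, `b_star` must be nonzero.
#' @return Numeric vector of swelling degrees (g water per g dry gel), with
#'   `S(0) = 0` exactly.
#' @examples
#' eval_swelling_eq(c(0, 1, 4, 25), k = 0.1, a_star = 1, b_star = 10)
#' @export
eval_swelling_eq <- function(times, k, a_star, b_star) {
  check_times(times)
  check_finite_scalar(k, "k", positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  if (a_star == 0 && b_star == 0) {
    abort_bad_arg("at least one of `a_star`, `b_star` must be nonzero.")
  }
  (1 - exp_neg_clamped(k * times)) * (a_star * sqrt(times) + b_star)
}

#' Evaluate the power-law (Korsmeyer-Peppas) swelling model
#'
#' `S(t) = k_pl * t^n`, the classical early-time model whose diffusional
#' exponent `n` classifies the transport mechanism (about 0.43-0.50 Fickian,
#' 0.85-1.0 relaxation-controlled, anomalous in between).
#'
#' @param times Non-negative times in hours.
#' @param k_pl Prefactor, (g/g) h^-n, > 0.
#' @param n Dimensionless diffusional exponent, > 0.
#' @return Numeric vector of swelling degrees.
#' @export
eval_power_law <- function(times, k_pl, n) {
  check_times(times)
  check_finite_scalar(k_pl, "k_pl", positive = TRUE)
  check_finite_scalar(n, "n", positive = TRUE)
  k_pl * times^n
}

#' Evaluate first-order swelling kinetics
#'
#' `S(t) = S_inf * (1 - exp(-k t))`, the relaxation-controlled limit; it is
#' recovered exactly from the unified equation when `a_star = 0` with
#' `S_inf = b_star`.
#'
#' @param times Non-negative times in hours.
#' @param S_inf Equilibrium swelling degree, g/g, > 0.
#' @param k Rate constant, 1/h, > 0.
#' @return Numeric vector of swelling degrees.
#' @export
eval_first_order <- function(times, S_inf, k) {
  check_times(times)
  check_finite_scalar(S_inf, "S_inf", positive = TRUE)
  check_finite_scalar(k, "k", positive = TRUE)
  S_inf * (1 - exp_neg_clamped(k * times))
}

#' Evaluate the two-term Peppas-Sahlin model
#'
#' `S(t) = k_d * sqrt(t) + k_r * t`: a diffusive square-root term plus a
#' relaxational linear term. It arises from the unified equation by the
#' first-order Taylor linearisation of its exponential factor, with
#' `k_d = k * a_star` and `k_r = k * b_star`.
#'
#' @param times Non-negative times in hours.
#' @param k_d Diffusive-term coefficient, (g/g) h^-1/2.
#' @param k_r Relaxational-term coefficient, (g/g) h^-1. Not both zero.
#' @return Numeric vector of swelling degrees.
#' @export
eval_peppas_sahlin <- function(times, k_d, k_r) {
  check_times(times)
  check_finite_scalar(k_d, "k_d")
  check_finite_scalar(k_r, "k_r")
  if (k_d == 0 && k_r == 0) {
    abort_bad_arg("at least one of `k_d`, `k_r` must be nonzero.")
  }
  k_d * sqrt(times) + k_r * times
}

#' Short-time Fickian fractional-uptake approximation
#'
#' For a gel of characteristic radius `r` and diffusion coefficient `D`, the
#' early-time fractional uptake is, with \eqn{x = D t / (\pi r^2)},
#' \deqn{S/S_{eq} = 4 x^{1/2} - \pi x - (\pi/3)\, x^{3/2}.}
#' The truncation is only trustworthy at small `x`; each point carries a
#' validity flag (`x <= valid_max`, default 0.15).
#'
#' @param times Non-negative times in hours.
#' @param D Diffusion coefficient, length^2/h, > 0.
#' @param r Characteristic radius, length, > 0.
#' @param valid_max Largest `x` at which the truncated series is flagged
#'   valid. Default 0.15.
#' @return A tibble with columns `time_h`, `x`, `fraction` (S/S_eq) and
#'   `valid`.
#' @export
eval_short_time <- function(times, D, r, valid_max = 0.15) {
  check_times(times)
  check_finite_scalar(D, "D", positive = TRUE)
  check_finite_scalar(r, "r", positive = TRUE)
  check_finite_scalar(valid_max, "valid_max", positive = TRUE)
  x <- D * times / (pi * r^2)
  tibble::tibble(
    time_h = times,
    x = x,
    fraction = 4 * sqrt(x) - pi * x - (pi / 3) * x^1.5,
    valid = x <= valid_max
  )
}

#' Evaluate the network-density decay law
#'
#' During swelling the network density (dry mass over current swollen volume)
#' relaxes toward its equilibrium value as
#' \deqn{\rho_{net}(t) = \beta\, t^{-1/2} + \rho_{eq},}
#' linear in the inverse square root of time; `beta` measures polymer-solvent
#' affinity and the law decays strictly toward `rho_eq`.
#'
#' @param times Strictly positive times in hours (the regressor diverges at 0).
#' @param beta Density-decay slope, density-units h^1/2, > 0.
#' @param rho_eq Equilibrium network density, mass/volume, >= 0.
#' @return Numeric vector of network densities.
#' @export
eval_density_law <- function(times, beta, rho_eq) {
  check_times(times, positive = TRUE)
  check_finite_scalar(beta, "beta", positive = TRUE)
  check_finite_scalar(rho_eq, "rho_eq", nonneg = TRUE)
  beta / sqrt(times) + rho_eq
}

#' Taylor partial sums of the swelling equation
#'
#' Replaces the factor `1 - exp(-k t)` by its alternating Taylor partial sum
#' \eqn{\sum_{m=1}^{N} (-1)^{m+1} (kt)^m / m!} and multiplies by
#' `(a_star sqrt(t) + b_star)`. Order 1 is the Peppas-Sahlin linearisation;
#' as `order` grows the sum converges to [eval_swelling_eq()], with
#' truncation error bounded by the first omitted term,
#' `(kt)^(order+1)/(order+1)! * |a_star sqrt(t) + b_star|`.
#'
#' @inheritParams eval_swelling_eq
#' @param order Truncation order, integer >= 1.
#' @return Numeric vector of approximate swelling degrees.
#' @export
taylor_partial_sum <- function(times, k, a_star, b_star, order) {
  check_times(times)
  check_finite_scalar(k, "k", positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    abort_bad_arg("`order` must be an integer >= 1.")
  }
  kt <- k * times
  bracket <- rep(0, length(times))
  term <- rep(1, length(times))      # (kt)^m / m!, built recursively
  for (m in seq_len(order)) {
    term <- term * kt / m
    bracket <- bracket + (-1)^(m + 1) * term
  }
  bracket * (a_star * sqrt(times) + b_star)
}

#' Termwise diffusion/relaxation component series
#'
#' The series expansion of the swelling equation splits into a diffusive
#' component `f` and a relaxational component `r`, summed termwise:
#' \deqn{f = a^* \sum_{n=1}^{N} (-1)^{n+1} k^n t^{n-1/2}/n!, \qquad
#'       r = b^* \sum_{n=1}^{N} (-1)^{n+1} k^n t^{n}/n!.}
#' As `N` grows, `r` converges to `b_star (1 - exp(-kt))` and `f` to
#' `a_star t^(-1/2) (1 - exp(-kt))`, so that `f/(f+r)` converges to the
#' closed-form Fickian contribution of [fickian_contribution()]. Used as the
#' internal oracle for the mechanism decomposition.
#'
#' @inheritParams taylor_partial_sum
#' @param times Strictly positive times (the diffusive component's leading
#'   term carries `t^(1/2)` only termwise; `t = 0` is rejected).
#' @return A tibble with columns `time_h`, `f` and `r`.
#' @export
component_series <- function(times, k, a_star, b_star, order = 40) {
  check_times(times, positive = TRUE)
  check_finite_scalar(k, "k", positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    abort_bad_arg("`order` must be an integer >= 1.")
  }
  kt <- k * times
  s <- rep(0, length(times))         # sum of (-1)^(n+1) (kt)^n / n!
  term <- rep(1, length(times))
  for (n in seq_len(order)) {
    term <- term * kt / n
    s <- s + (-1)^(n + 1) * term
  }
  tibble::tibble(
    time_h = times,
    f = a_star * s / sqrt(times),
    r = b_star * s
  )
}

#' Locate the overshoot maximum of a swelling curve
#'
#' For parameter sets with `a_star < 0 < b_star` the swelling equation rises
#' to a single interior maximum and then decays toward the envelope
#' `a_star sqrt(t) + b_star`; this finds that peak by bracketed root-finding
#' on dS/dt. For `a_star >= 0, b_star >= 0` the curve is non-decreasing
#' (every term of dS/dt is non-negative) and no peak exists.
#'
#' @inheritParams eval_swelling_eq
#' @param t_max Upper end of the initial search window in hours; extended
#'   automatically until the derivative has changed sign.
#' @return A tibble with columns `t_peak` and `S_peak` (one row), or a
#'   zero-row tibble when the curve is monotone.
#' @export
overshoot_peak <- function(k, a_star, b_star, t_max = 100) {
  check_finite_scalar(k, "k", positive = TRUE)
  check_finite_scalar(a_star, "a_star")
  check_finite_scalar(b_star, "b_star")
  check_finite_scalar(t_max, "t_max", positive = TRUE)
  empty <- tibble::tibble(t_peak = numeric(0), S_peak = numeric(0))
  if (a_star >= 0 && b_star >= 0) return(empty)
  if (!(a_star < 0 && b_star > 0)) return(empty)
  dS <- function(t) {
    e <- exp_neg_clamped(k * t)
    k * e * (a_star * sqrt(t) + b_star) + (1 - e) * a_star / (2 * sqrt(t))
  }
  # dS/dt -> k * b_star > 0 as t -> 0+ and -> a_star/(2 sqrt(t)) < 0 at
  # large t, so a sign change exists; extend the bracket until found.
  lo <- .Machine$double.eps^0.5
  hi <- t_max
  while (dS(hi) > 0 && hi < 1e12) hi <- hi * 2
  root <- stats::uniroot(dS, lower = lo, upper = hi, tol = 1e-12)$root
  tibble::tibble(
    t_peak = root,
    S_peak = eval_swelling_eq(root, k, a_star, b_star)
  )
}
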