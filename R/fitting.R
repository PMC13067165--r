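# Fitting of swelling and density time series. All fitters take a data frame
# holding one curve (one sample/replicate), return a "swell_fit" object, and
# follow the study protocol: the unified equation is fitted on the full
# curve, the power-law and two-term models only on the early window up to
# 60% of the equilibrium uptake.

new_swell_fit <- function(model_id, params, stderr, r2, r2_adj, rss,
                          n_points, window, converged, n_starts_used = 1L,
                          data = NULL, note = NULL) {
  structure(
    list(
      model_id = model_id, params = params, stderr = stderr,
      r2 = unname(r2), r2_adj = unname(r2_adj), rss = unname(rss),
      n_points = n_points,
      window = window, converged = converged,
      n_starts_used = n_starts_used, data = data, note = note
    ),
    class = "swell_fit"
  )
}

#' @export
print.swell_fit <- function(x, ...) {
  cat(sprintf("<swell_fit: %s>\n", x$model_id))
  est <- format(signif(unlist(x$params), 4))
  se <- format(signif(unlist(x$stderr), 4))
  for (i in seq_along(est)) {
    cat(sprintf("  %-8s %s (se %s)\n", names(est)[i], est[i], se[i]))
  }
  cat(sprintf("  R2 %.4f  adj. R2 %.4f  n %d  window [%.3g, %.3g]  %s\n",
              x$r2, x$r2_adj, x$n_points, x$window[1], x$window[2],
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

r_squared <- function(observed, fitted) {
  rss <- sum((observed - fitted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) return(c(r2 = 0, rss = rss))
  c(r2 = 1 - rss / tss, rss = rss)
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Convert wet-mass measurements to swelling degree
#'
#' The swelling degree normalises water uptake by the dry gel mass:
#' `S(t) = (w(t) - w0) / w0`. Values below zero are kept (drainage after an
#' overshoot, or measurement noise).
#'
#' @param data Data frame with columns `time_h` and `mass_g` (wet mass);
#'   other columns (e.g. `sample_id`, `replicate_id`) are carried through.
#' @param w0 Dry gel mass in grams, > 0.
#' @return The input as a tibble with a `swelling` column added.
#' @export
swelling_degree_from_mass <- function(data, w0) {
  if (!is.data.frame(data) || !all(c("time_h", "mass_g") %in% names(data))) {
    abort_bad_arg("`data` must have `time_h` and `mass_g` columns.")
  }
  check_finite_scalar(w0, "w0", positive = TRUE)
  dplyr::mutate(tibble::as_tibble(data),
                swelling = (.data$mass_g - w0) / w0)
}

#' Network density from dry mass and swollen volume
#'
#' `rho_net(t) = w0 / V(t)`: the dry mass divided by the current swollen
#' volume, the quantity whose decay toward equilibrium follows the inverse
#' square-root law fitted by [fit_density()].
#'
#' @param w0 Dry gel mass in grams, > 0.
#' @param volumes Swollen volumes in mL, all > 0.
#' @param times Times in hours, same length as `volumes`.
#' @return A tibble with columns `time_h` and `density`.
#' @export
network_density_from_mass_volume <- function(w0, volumes, times) {
  check_finite_scalar(w0, "w0", positive = TRUE)
  check_times(times)
  if (!is.numeric(volumes) || length(volumes) != length(times) ||
      any(!is.finite(volumes)) || any(volumes <= 0)) {
    abort_bad_arg("`volumes` must be positive and match `times` in length.")
  }
  tibble::tibble(time_h = times, density = w0 / volumes)
}

#' Estimate the equilibrium plateau of a swelling curve
#'
#' The plateau is the mean swelling over the final `tail_fraction` of the
#' points. A curve is flagged as overshooting when its maximum lies before
#' the tail window (an interior peak) and exceeds the plateau by more than
#' `overshoot_factor` (relative).
#'
#' @param data Data frame with `time_h` and `swelling` columns, times
#'   strictly increasing.
#' @param tail_fraction Fraction of trailing points averaged. Default 0.2.
#' @param overshoot_factor Relative excess of max over plateau that flags an
#'   overshoot. Default 0.05.
#' @return A list with `S_eq` and logical `overshoot`.
#' @export
estimate_equilibrium <- function(data, tail_fraction = 0.2,
                                 overshoot_factor = 0.05) {
  check_curve_df(data, min_points = 2L)
  check_finite_scalar(tail_fraction, "tail_fraction", positive = TRUE)
  n <- nrow(data)
  n_tail <- max(2L, ceiling(tail_fraction * n))
  if (n_tail > n) abort_bad_arg("too few points for the tail window.")
  S <- data$swelling
  S_eq <- mean(S[(n - n_tail + 1L):n])
  interior_peak <- which.max(S) < n - n_tail + 1L
  list(S_eq = S_eq,
       overshoot = interior_peak && S_eq > 0 &&
         max(S) > S_eq * (1 + overshoot_factor))
}

# Shared Levenberg-Marquardt driver: minimises unweighted squared residuals,
# returns estimates, linearised standard errors and convergence info.
lm_fit_once <- function(resid_fn, start, lower, upper) {
  out <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, maxfev = 10000, ftol = 1e-10, ptol = 1e-10)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  out
}

lm_stderr <- function(fit, n, p) {
  dof <- n - p
  sigma2 <- fit$deviance / max(dof, 1L)
  cov <- try(sigma2 * solve(fit$hessian / 2), silent = TRUE)
  if (inherits(cov, "try-error")) return(rep(NA_real_, p))
  se <- suppressWarnings(sqrt(diag(cov)))
  se
}

#' Fit the unified swelling equation to one curve
#'
#' Least-squares estimation of `(k, a_star, b_star)` on the full curve (no
#' early-time window). Because the surface is multimodal when the diffusive
#' and relaxational amplitudes trade off, five deterministic starts are used:
#' a first-order start (`a_star = 0`), a pure-diffusive start (`b_star = 0`),
#' and three jittered combinations seeded by `seed`; the best residual sum of
#' squares wins, ties broken toward the smallest `k`.
#'
#' @param data Data frame with `time_h` and `swelling` for a single curve,
#'   at least 4 points, times strictly increasing.
#' @param init Optional named list/vector with starting values `k`,
#'   `a_star`, `b_star`; used as an additional start.
#' @param n_starts Number of starts (>= 1). Default 5.
#' @param seed Integer seed making the jittered starts reproducible.
#' @return A `swell_fit` with `model_id = "swelling_eq"`; see [tidy.swell_fit()].
#' @export
fit_swelling_eq <- function(data, init = NULL, n_starts = 5, seed = 1L) {
  check_curve_df(data, min_points = 4L)
  t <- data$time_h
  S <- data$swelling
  if (stats::sd(S) == 0) abort_bad_arg("degenerate flat curve: no signal to fit.")
  eq <- estimate_equilibrium(data)
  S_eq <- max(eq$S_eq, max(abs(S)) * 0.1, .Machine$double.eps)

  resid_fn <- function(p) {
    (1 - exp_neg_clamped(p[1] * t)) * (p[2] * sqrt(t) + p[3]) - S
  }
  lower <- c(1e-6, -Inf, -Inf)
  upper <- c(1e3, Inf, Inf)

  # first-order start: plateau + crude rate from the half-rise time
  t_half <- t[which.min(abs(S - 0.5 * S_eq))]
  k0 <- if (t_half > 0) log(2) / t_half else 1
  k0 <- min(max(k0, 1e-4), 1e2)
  starts <- list(c(k0, 0, S_eq),
                 c(k0, S_eq / max(sqrt(max(t)), 1), 0))
  if (!is.null(init)) {
    starts <- c(starts, list(as.numeric(init[c("k", "a_star", "b_star")])))
  }
  rng <- local({
    set.seed(seed)
    matrix(stats::runif(3 * max(0L, n_starts), 0.25, 4), ncol = 3)
  })
  i <- 1L
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <-
      c(k0 * rng[i, 1], S_eq / max(sqrt(max(t)), 1) * rng[i, 2] *
          sign(rng[i, 2] - 2), S_eq * rng[i, 3] / 2)
    i <- i + 1L
  }
  starts <- starts[seq_len(max(n_starts, length(starts)))]

  best <- NULL
  n_used <- 0L
  for (s in starts) {
    n_used <- n_used + 1L
    s[1] <- min(max(s[1], lower[1] * 2), upper[1] / 2)
    f <- lm_fit_once(resid_fn, s, lower, upper)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance - 1e-12 ||
        (abs(f$deviance - best$deviance) <= 1e-12 && f$par[1] < best$par[1])) {
      best <- f
    }
  }
  if (is.null(best)) {
    return(new_swell_fit(
      "swelling_eq",
      params = list(k = NA_real_, a_star = NA_real_, b_star = NA_real_),
      stderr = list(k = NA_real_, a_star = NA_real_, b_star = NA_real_),
      r2 = NA_real_, r2_adj = NA_real_, rss = NA_real_,
      n_points = length(t), window = range(t), converged = FALSE,
      n_starts_used = n_used, data = data,
      note = "no start converged"))
  }
  p <- best$par
  fitted <- eval_swelling_eq(t, p[1], p[2], p[3])
  gof <- r_squared(S, fitted)
  se <- lm_stderr(best, length(t), 3L)
  new_swell_fit(
    "swelling_eq",
    params = list(k = p[1], a_star = p[2], b_star = p[3]),
    stderr = list(k = se[1], a_star = se[2], b_star = se[3]),
    r2 = gof["r2"], r2_adj = adj_r2(gof["r2"], length(t), 3L),
    rss = gof["rss"], n_points = length(t), window = range(t),
    converged = best$info %in% 1:4, n_starts_used = n_used, data = data)
}

window_curve <- function(data, window_fraction) {
  eq <- estimate_equilibrium(data)
  keep <- data$swelling <= window_fraction * eq$S_eq
  # the window is the initial rising portion: stop at the first excluded point
  first_out <- which(!keep)
  if (length(first_out) > 0) keep[seq(min(first_out), nrow(data))] <- FALSE
  data[keep, , drop = FALSE]
}

#' Fit the power-law model on the early-uptake window
#'
#' Fits `S = k_pl * t^n` restricted to the initial portion of the curve with
#' `S <= window_fraction * S_eq` (the customary first ~60% of total uptake),
#' where `S_eq` comes from [estimate_equilibrium()]. The default estimator
#' is the classical one for diffusional exponents: linear regression of
#' `log(S)` on `log(t)` (t = 0 and non-positive S excluded), which weights
#' the early decades of the window evenly and reproduces the standard
#' exponent ranges on clean limiting-case data. `method = "nls"` instead
#' refines that solution by least squares on the original scale, which
#' weights late, large-S points more heavily.
#'
#' @inheritParams fit_swelling_eq
#' @param window_fraction Fraction of the equilibrium uptake defining the
#'   fitting window. Default 0.60.
#' @param method `"loglog"` (classical, default) or `"nls"`.
#' @return A `swell_fit` with `model_id = "power_law"` and parameters
#'   `k_pl`, `n`. The `window` field records the time range actually fitted;
#'   `r2` is computed on the original swelling scale.
#' @export
fit_power_law <- function(data, window_fraction = 0.60,
                          method = c("loglog", "nls")) {
  method <- match.arg(method)
  check_curve_df(data, min_points = 4L)
  check_finite_scalar(window_fraction, "window_fraction", positive = TRUE)
  win <- window_curve(data, window_fraction)
  win <- win[win$time_h > 0 & win$swelling > 0, , drop = FALSE]
  if (nrow(win) < 3L) {
    abort_bad_arg(paste0(
      "power-law window (S <= ", window_fraction,
      " * S_eq, t > 0) leaves fewer than 3 points."))
  }
  t <- win$time_h
  S <- win$swelling
  ll <- stats::lm(log(S) ~ log(t))
  cf <- unname(stats::coef(ll))
  if (method == "loglog") {
    p <- c(exp(cf[1]), cf[2])
    se_ll <- unname(sqrt(diag(suppressWarnings(stats::vcov(ll)))))
    se <- c(p[1] * se_ll[1], se_ll[2]) # delta method for the prefactor
    converged <- TRUE
  } else {
    start <- c(exp(cf[1]), min(max(cf[2], 0.05), 5))
    fit <- lm_fit_once(function(p) p[1] * t^p[2] - S, start,
                       lower = c(1e-12, 1e-3), upper = c(Inf, 10))
    if (is.null(fit)) abort_bad_arg("power-law fit failed to converge.")
    p <- fit$par
    se <- lm_stderr(fit, length(t), 2L)
    converged <- fit$info %in% 1:4
  }
  gof <- r_squared(S, p[1] * t^p[2])
  new_swell_fit(
    "power_law",
    params = list(k_pl = p[1], n = p[2]),
    stderr = list(k_pl = se[1], n = se[2]),
    r2 = gof["r2"], r2_adj = adj_r2(gof["r2"], length(t), 2L),
    rss = gof["rss"], n_points = length(t), window = range(t),
    converged = converged, data = win)
}

#' Fit first-order swelling kinetics
#'
#' Least-squares fit of `S = S_inf * (1 - exp(-k t))` on the full curve.
#' Initialised with `S_inf` at the plateau estimate and `k` from a
#' log-linear regression of `1 - S/S_eq`.
#'
#' @inheritParams fit_swelling_eq
#' @return A `swell_fit` with `model_id = "first_order"` and parameters
#'   `S_inf`, `k`.
#' @export
fit_first_order <- function(data) {
  check_curve_df(data, min_points = 3L)
  t <- data$time_h
  S <- data$swelling
  eq <- estimate_equilibrium(data)
  S_eq <- max(eq$S_eq, max(abs(S)) * 0.1, .Machine$double.eps)
  frac <- 1 - S / S_eq
  ok <- frac > 1e-8 & t > 0
  k0 <- if (sum(ok) >= 2) {
    max(1e-4, -stats::coef(stats::lm(log(frac[ok]) ~ 0 + t[ok]))[1])
  } else 1
  fit <- lm_fit_once(
    function(p) p[1] * (1 - exp_neg_clamped(p[2] * t)) - S,
    c(S_eq, k0), lower = c(1e-12, 1e-6), upper = c(Inf, 1e3))
  if (is.null(fit)) abort_bad_arg("first-order fit failed to converge.")
  p <- fit$par
  gof <- r_squared(S, eval_first_order(t, p[1], p[2]))
  se <- lm_stderr(fit, length(t), 2L)
  new_swell_fit(
    "first_order",
    params = list(S_inf = p[1], k = p[2]),
    stderr = list(S_inf = se[1], k = se[2]),
    r2 = gof["r2"], r2_adj = adj_r2(gof["r2"], length(t), 2L),
    rss = gof["rss"], n_points = length(t), window = range(t),
    converged = fit$info %in% 1:4, data = data)
}

#' Fit the Peppas-Sahlin two-term model on the early-uptake window
#'
#' Linear least squares of `S` on the basis `(sqrt(t), t)` (no intercept)
#' over the same early window as [fit_power_law()]; the coefficients are the
#' diffusive and relaxational rate terms `k_d`, `k_r`.
#'
#' @inheritParams fit_power_law
#' @return A `swell_fit` with `model_id = "peppas_sahlin"` and parameters
#'   `k_d`, `k_r`.
#' @export
fit_peppas_sahlin <- function(data, window_fraction = 0.60) {
  check_curve_df(data, min_points = 4L)
  win <- window_curve(data, window_fraction)
  win <- win[win$time_h > 0, , drop = FALSE]
  if (nrow(win) < 3L) {
    abort_bad_arg("Peppas-Sahlin window leaves fewer than 3 points.")
  }
  t <- win$time_h
  S <- win$swelling
  fit <- stats::lm(S ~ 0 + sqrt(t) + t)
  p <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit)))))
  gof <- r_squared(S, stats::fitted(fit))
  new_swell_fit(
    "peppas_sahlin",
    params = list(k_d = p[1], k_r = p[2]),
    stderr = list(k_d = se[1], k_r = se[2]),
    r2 = gof["r2"], r2_adj = adj_r2(gof["r2"], length(t), 2L),
    rss = gof["rss"], n_points = length(t), window = range(t),
    converged = TRUE, data = win)
}

#' Fit the network-density decay law
#'
#' Ordinary linear regression of density on `t^(-1/2)`: the slope is the
#' decay coefficient `beta`, the intercept the equilibrium density `rho_eq`.
#' A constant density series is degenerate: `beta = 0`, `r2 = 0`, flagged in
#' the note.
#'
#' @param data Data frame with columns `time_h` (> 0) and `density`.
#' @return A `swell_fit` with `model_id = "density"` and parameters `beta`,
#'   `rho_eq`, reporting both R2 and adjusted R2.
#' @export
fit_density <- function(data) {
  if (!is.data.frame(data) || !all(c("time_h", "density") %in% names(data))) {
    abort_bad_arg("`data` must have `time_h` and `density` columns.")
  }
  if (nrow(data) < 3L) abort_bad_arg("at least 3 points are required.")
  if (any(data$time_h <= 0)) abort_bad_arg("density times must be > 0.")
  t <- data$time_h
  rho <- data$density
  x <- 1 / sqrt(t)
  if (stats::sd(rho) == 0) {
    return(new_swell_fit(
      "density", params = list(beta = 0, rho_eq = rho[1]),
      stderr = list(beta = NA_real_, rho_eq = NA_real_),
      r2 = 0, r2_adj = 0, rss = 0, n_points = length(t),
      window = range(t), converged = TRUE, data = data,
      note = "degenerate constant series"))
  }
  fit <- stats::lm(rho ~ x)
  p <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit)))))
  gof <- r_squared(rho, stats::fitted(fit))
  new_swell_fit(
    "density",
    params = list(beta = p[2], rho_eq = p[1]),
    stderr = list(beta = se[2], rho_eq = se[1]),
    r2 = gof["r2"], r2_adj = adj_r2(gof["r2"], length(t), 2L),
    rss = gof["rss"], n_points = length(t), window = range(t),
    converged = TRUE, data = data)
}

#' Estimate the diffusion coefficient from a power-law fit
#'
#' Uses `D = pi * r^2 * (k_pl / 4)^(1/n)` with the prefactor and exponent of
#' a converged power-law fit and the characteristic gel radius.
#'
#' @param power_fit A `swell_fit` from [fit_power_law()].
#' @param r Characteristic radius (same length unit as D^(1/2) h^(1/2)), > 0.
#' @return The diffusion coefficient D, length^2/h.
#' @export
estimate_diffusion_coefficient <- function(power_fit, r) {
  if (!inherits(power_fit, "swell_fit") || power_fit$model_id != "power_law") {
    abort_bad_arg("`power_fit` must be a power-law swell_fit.")
  }
  if (!isTRUE(power_fit$converged)) abort_bad_arg("power-law fit did not converge.")
  check_finite_scalar(r, "r", positive = TRUE)
  k_pl <- power_fit$params$k_pl
  n <- power_fit$params$n
  if (!is.finite(k_pl) || k_pl <= 0 || !is.finite(n) || n <= 0) {
    abort_bad_arg("power-law parameters must be positive.")
  }
  pi * r^2 * (k_pl / 4)^(1 / n)
}
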