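test_that("swelling degree from mass applies the dry-mass normalisation", {
  d <- tibble::tibble(time_h = c(0, 1), mass_g = c(0.1, 0.5))
  out <- swelling_degree_from_mass(d, w0 = 0.1)
  expect_equal(out$swelling, c(0, 4))
  expect_error(swelling_degree_from_mass(d, w0 = 0),
               class = "swellkin_validation_error")
  # round-trip with the mass generator recovers its swelling input exactly
  tt <- time_grid(0, 30, 12)
  ms <- simulate_mass_series(tt, k = 0.4, a_star = 1, b_star = 6, w0 = 0.25,
                             noise_sd = 0.1, replicates = 2, seed = 9)
  sw <- swelling_degree_from_mass(ms, w0 = 0.25)
  ref <- simulate_curve(tt, 0.4, 1, 6, noise_sd = 0.1, replicates = 2,
                        seed = 9)
  expect_equal(sw$swelling, ref$swelling, tolerance = 1e-12)
})

test_that("network density is dry mass over swollen volume", {
  out <- network_density_from_mass_volume(0.1, volumes = 2, times = 1)
  expect_equal(out$density, 0.05)
  out2 <- network_density_from_mass_volume(0.1, volumes = 4, times = 1)
  expect_equal(out2$density, out$density / 2)
  expect_error(network_density_from_mass_volume(0.1, volumes = -1, times = 1),
               class = "swellkin_validation_error")
})

test_that("equilibrium estimation finds plateaus and flags interior peaks", {
  tt <- time_grid(0, 100, 40)
  d <- tibble::tibble(time_h = tt, swelling = eval_first_order(tt, 8, 0.3))
  eq <- estimate_equilibrium(d)
  expect_equal(eq$S_eq, 8, tolerance = 1e-3)
  expect_false(eq$overshoot)
  # overshoot-shaped curve with a peak well above the plateau
  d2 <- make_curve(c(0, time_grid(0.2, 60, 39, "log")),
                   k = 0.5, a_star = -2.5, b_star = 30)
  eq2 <- estimate_equilibrium(d2)
  expect_true(eq2$overshoot)
  expect_gt(max(d2$swelling), 1.05 * eq2$S_eq)
  expect_error(estimate_equilibrium(d[1, ]), class = "swellkin_validation_error")
})

test_that("the unified-equation fitter recovers noise-free parameters to optimizer tolerance", {
  d <- make_curve(time_grid(0, 20, 30), k = 0.5, a_star = 2, b_star = 8)
  f <- fit_swelling_eq(d)
  expect_true(f$converged)
  expect_equal(f$params$k, 0.5, tolerance = 1e-6)
  expect_equal(f$params$a_star, 2, tolerance = 1e-6)
  expect_equal(f$params$b_star, 8, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
  expect_lte(f$r2_adj, f$r2)
})

test_that("a first-order truth is recovered as a nested special case", {
  tt <- time_grid(0, 60, 30)
  d <- tibble::tibble(time_h = tt, swelling = eval_first_order(tt, 10, 0.15))
  f <- fit_swelling_eq(d)
  tol <- max(3 * f$stderr$a_star, 1e-6, na.rm = TRUE)
  expect_lt(abs(f$params$a_star), tol)
  expect_gt(f$r2, 0.999999)
})

test_that("overshoot curves are fitted with a negative diffusive amplitude", {
  tt <- c(0, time_grid(0.25, 50, 39, "log"))
  fx <- simulate_curve(tt, k = 0.3, a_star = -0.8, b_star = 30,
                       noise_frac = 0.02, replicates = 1, seed = 21)
  f <- fit_swelling_eq(fx)
  expect_true(f$converged)
  expect_lt(f$params$a_star, 0)
  truth_peak <- overshoot_peak(0.3, -0.8, 30)
  fit_peak <- overshoot_peak(f$params$k, f$params$a_star, f$params$b_star)
  expect_lt(abs(fit_peak$t_peak - truth_peak$t_peak) / truth_peak$t_peak, 0.10)
})

test_that("degenerate flat curves are rejected, not silently fitted", {
  d <- tibble::tibble(time_h = 0:5, swelling = rep(2, 6))
  expect_error(fit_swelling_eq(d), class = "swellkin_validation_error")
})

test_that("the power-law fitter is exact on power-law data and windows correctly", {
  tt <- time_grid(0, 16, 20)
  d <- tibble::tibble(time_h = tt, swelling = 3 * sqrt(tt))
  f <- fit_power_law(d, window_fraction = 1)
  expect_equal(f$params$k_pl, 3, tolerance = 1e-8)
  expect_equal(f$params$n, 0.5, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  d2 <- tibble::tibble(time_h = tt, swelling = 2 * tt)
  f2 <- fit_power_law(d2, window_fraction = 1)
  expect_equal(f2$params$n, 1, tolerance = 1e-8)

  # relaxation-controlled truth (a* = 0), windowed at 60% of uptake:
  # the effective exponent falls in the relaxation band (0.85, 1.0]
  tt3 <- c(0, time_grid(0.5, 80, 39, "log"))
  d3 <- make_curve(tt3, k = 0.08, a_star = 0, b_star = 12)
  f3 <- fit_power_law(d3)
  expect_gt(f3$params$n, 0.85)
  expect_lte(f3$params$n, 1.0)
  expect_lt(max(f3$data$swelling), 0.6 * 12 + 0.2)

  # a window leaving too few points is an explanatory error
  d4 <- make_curve(time_grid(0, 50, 5), k = 1, a_star = 0, b_star = 10)
  expect_error(fit_power_law(d4, window_fraction = 0.1),
               "fewer than 3 points")
})

test_that("the first-order fitter recovers exact and noisy truths", {
  tt <- time_grid(0, 40, 25)
  d <- tibble::tibble(time_h = tt, swelling = eval_first_order(tt, 7, 0.2))
  f <- fit_first_order(d)
  expect_equal(f$params$S_inf, 7, tolerance = 1e-8)
  expect_equal(f$params$k, 0.2, tolerance = 1e-8)

  # strongly relaxational unified-equation data is first-order-like
  d2 <- make_curve(tt, k = 0.2, a_star = 0.007, b_star = 7)
  f2 <- fit_first_order(d2)
  expect_gt(f2$r2, 0.999)

  # 2% noise, n = 30: estimates within 3 standard errors of truth
  fx <- simulate_curve(time_grid(0, 40, 30), k = 0.2, a_star = 0,
                       b_star = 7, noise_sd = 0.14, replicates = 1,
                       seed = 31)
  f3 <- fit_first_order(fx)
  expect_lt(abs(f3$params$S_inf - 7), 3 * f3$stderr$S_inf)
  expect_lt(abs(f3$params$k - 0.2), 3 * f3$stderr$k)
})

test_that("the Peppas-Sahlin fitter is exact in its linear basis and unbiased under noise", {
  tt <- time_grid(0, 10, 15)
  d <- tibble::tibble(time_h = tt, swelling = sqrt(tt) + 2 * tt)
  f <- fit_peppas_sahlin(d, window_fraction = 1)
  expect_equal(f$params$k_d, 1, tolerance = 1e-10)
  expect_equal(f$params$k_r, 2, tolerance = 1e-10)

  d2 <- tibble::tibble(time_h = tt, swelling = 3 * sqrt(tt))
  f2 <- fit_peppas_sahlin(d2, window_fraction = 1)
  expect_lt(abs(f2$params$k_r), 1e-10)

  # unbiased recovery across 200 seeded replications, mean bias <= 2%
  set.seed(77)
  ests <- t(replicate(200, {
    y <- sqrt(tt) + 2 * tt + rnorm(length(tt), 0, 0.3)
    fit <- stats::lm(y ~ 0 + sqrt(tt) + tt)
    stats::coef(fit)
  }))
  expect_lt(abs(mean(ests[, 1]) - 1) / 1, 0.02)
  expect_lt(abs(mean(ests[, 2]) - 2) / 2, 0.02)
  # and the package fitter agrees with the direct linear solve
  y1 <- sqrt(tt) + 2 * tt
  y1[1] <- 0
  f3 <- fit_peppas_sahlin(tibble::tibble(time_h = tt, swelling = y1),
                          window_fraction = 1)
  ref <- stats::coef(stats::lm(y1[-1] ~ 0 + sqrt(tt[-1]) + tt[-1]))
  expect_equal(unname(unlist(f3$params)), unname(ref), tolerance = 1e-10)
})

test_that("the density regression matches the inverse-sqrt-time line exactly", {
  tt <- time_grid(1, 64, 12)
  d <- tibble::tibble(time_h = tt, density = eval_density_law(tt, 0.3, 0.05))
  f <- fit_density(d)
  expect_equal(f$params$beta, 0.3, tolerance = 1e-10)
  expect_equal(f$params$rho_eq, 0.05, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # adjusted R2 follows the standard small-sample correction
  expect_equal(f$r2_adj,
               1 - (1 - f$r2) * (f$n_points - 1) / (f$n_points - 2 - 1))

  # mean-zero noise leaves the slope estimate unbiased over seeded reps
  slopes <- vapply(1:60, function(s) {
    sim <- simulate_density_series(tt, beta = 0.3, rho_eq = 0.05,
                                   noise_sd = 0.01, replicates = 1, seed = s)
    fit_density(sim)$params$beta
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.3) / 0.3, 0.02)

  # constant series is degenerate and flagged
  dc <- tibble::tibble(time_h = tt, density = rep(0.08, length(tt)))
  fc <- fit_density(dc)
  expect_equal(fc$params$beta, 0)
  expect_equal(fc$r2, 0)
  expect_match(fc$note, "degenerate")
  expect_error(fit_density(tibble::tibble(time_h = c(0, 1, 2),
                                          density = c(1, 2, 3))),
               class = "swellkin_validation_error")
})

test_that("diffusion-coefficient estimation follows the power-law formula", {
  tt <- time_grid(0, 16, 20)
  f <- fit_power_law(tibble::tibble(time_h = tt, swelling = 0.2 * sqrt(tt)),
                     window_fraction = 1)
  expect_equal(estimate_diffusion_coefficient(f, r = 1), pi * 0.05^2,
               tolerance = 1e-6)
  expect_equal(estimate_diffusion_coefficient(f, r = 3),
               9 * estimate_diffusion_coefficient(f, r = 1))
  f4 <- fit_power_law(tibble::tibble(time_h = tt, swelling = 4 * tt^0.7),
                      window_fraction = 1)
  expect_equal(estimate_diffusion_coefficient(f4, r = 1), pi,
               tolerance = 1e-6)
  expect_error(estimate_diffusion_coefficient(f, r = 0),
               class = "swellkin_validation_error")
})

test_that("tidy, glance and augment expose fits in broom shape", {
  d <- make_curve(time_grid(0, 20, 30), k = 0.5, a_star = 2, b_star = 8)
  f <- fit_swelling_eq(d)
  td <- tidy(f)
  expect_identical(td$term, c("k", "a_star", "b_star"))
  expect_identical(names(td), c("term", "estimate", "std.error"))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$r.squared, f$r2)
  au <- augment(f)
  expect_true(all(c(".fitted", ".resid") %in% names(au)))
  expect_equal(au$.fitted + au$.resid, d$swelling)
  expect_s3_class(print(f), "swell_fit")
})
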