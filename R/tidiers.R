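#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a swelling-model fit
#'
#' @param x A `swell_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.swell_fit <- function(x, ...) {
  est <- unlist(x$params)
  se <- unlist(x$stderr)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' Glance at a swelling-model fit
#'
#' @param x A `swell_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model_id`, `r.squared`, `adj.r.squared`,
#'   `rss`, `n.points`, `window.min`, `window.max`, `converged`,
#'   `n.starts.used`.
#' @export
glance.swell_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, r.squared = x$r2, adj.r.squared = x$r2_adj,
    rss = x$rss, n.points = x$n_points,
    window.min = x$window[1], window.max = x$window[2],
    converged = x$converged, n.starts.used = x$n_starts_used)
}

predict_swell_fit <- function(fit, times) {
  p <- fit$params
  switch(fit$model_id,
         swelling_eq = eval_swelling_eq(times, p$k, p$a_star, p$b_star),
         power_law = eval_power_law(times, p$k_pl, p$n),
         first_order = eval_first_order(times, p$S_inf, p$k),
         peppas_sahlin = eval_peppas_sahlin(times, p$k_d, p$k_r),
         density = eval_density_law(times, max(p$beta, .Machine$double.xmin),
                                    p$rho_eq),
         abort_bad_arg("unknown model_id."))
}

#' Augment curve data with fitted values and residuals
#'
#' @param x A `swell_fit` object.
#' @param data Data frame with a `time_h` column; defaults to the data the
#'   model was fitted on.
#' @param ... Unused.
#' @return The data as a tibble with `.fitted` and (when the observed column
#'   is present) `.resid` columns added.
#' @export
augment.swell_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) data <- x$data
  if (is.null(data)) abort_bad_arg("no data stored in the fit; supply `data`.")
  out <- tibble::as_tibble(data)
  out$.fitted <- predict_swell_fit(x, out$time_h)
  obs_col <- if (x$model_id == "density") "density" else "swelling"
  if (obs_col %in% names(out)) out$.resid <- out[[obs_col]] - out$.fitted
  out
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return The per-sample summary tibble (mean, sd, n, Tukey letters).
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' Glance at a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the ANOVA p-value, alpha, number of groups
#'   and the compared parameter.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, anova_p = x$anova_p,
                 alpha = x$alpha, n_groups = nrow(x$summary))
}
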