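#' Plot a fitted swelling curve over its data
#'
#' @param object A `swell_fit` object (with its fitting data stored).
#' @param n_grid Number of grid points for the fitted line.
#' @param ... Unused.
#' @return A ggplot object: observed points and the fitted curve.
#' @export
autoplot.swell_fit <- function(object, n_grid = 200, ...) {
  data <- object$data
  if (is.null(data)) abort_bad_arg("no data stored in the fit.")
  obs_col <- if (object$model_id == "density") "density" else "swelling"
  t_min <- if (object$model_id == "density") min(data$time_h) else 0
  grid <- tibble::tibble(
    time_h = seq(max(t_min, min(data$time_h)), max(data$time_h),
                 length.out = n_grid))
  grid$.fitted <- predict_swell_fit(object, grid$time_h)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h,
                                     y = .data[[obs_col]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$.fitted),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "time (h)",
      y = if (obs_col == "density") "network density" else
        "swelling degree (g/g)",
      title = sprintf("%s fit  (R² = %.4f)", object$model_id,
                      object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a CF/CR mechanism profile
#'
#' @param object A `mechanism_profile` tibble from [fickian_contribution()].
#' @param ... Unused.
#' @return A ggplot object with the Fickian and relaxational contribution
#'   curves over time (invalid points dropped).
#' @export
autoplot.mechanism_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(object), .data$valid),
    c("CF", "CR"), names_to = "component", values_to = "contribution")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h,
                                     y = .data$contribution,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(CF = "steelblue", CR = "darkorange"),
      labels = c(CF = "Fickian diffusion",
                 CR = "macromolecular relaxation")) +
    ggplot2::labs(x = "time (h)", y = "contribution", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot every curve of a study with its fitted swelling equation
#'
#' @param study A `study_fit` object from [fit_study()].
#' @param data The curve tibble the study was fitted on.
#' @return A ggplot faceted by sample: points per replicate plus the
#'   per-replicate fitted unified-equation curves.
#' @export
plot_study_fits <- function(study, data) {
  if (!inherits(study, "study_fit")) {
    abort_bad_arg("`study` must be a study_fit object.")
  }
  grids <- purrr::pmap_dfr(
    study$fits[, c("sample_id", "replicate_id", "k", "a_star", "b_star")],
    function(sample_id, replicate_id, k, a_star, b_star) {
      tt <- seq(0, max(data$time_h[data$sample_id == sample_id]),
                length.out = 150)
      tibble::tibble(sample_id = sample_id, replicate_id = replicate_id,
                     time_h = tt,
                     swelling = eval_swelling_eq(tt, k, a_star, b_star))
    })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h, y = .data$swelling,
                                     colour = .data$replicate_id)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = grids) +
    ggplot2::facet_wrap(~sample_id, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "swelling degree (g/g)",
                  colour = "replicate") +
    ggplot2::theme_minimal()
}
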