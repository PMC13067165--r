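# Study-table I/O. The on-disk dialect is a long (tidy) CSV with one row
# per (sample, replicate, time): columns sample_id, replicate_id, time_h and
# exactly one of {swelling} or {mass_g + dry_mass_g}; density tables use a
# density_g_per_mL column with the same keys.

#' Read a long-format swelling study CSV
#'
#' Expects columns `sample_id`, `replicate_id`, `time_h` and exactly one of
#' `swelling` or `mass_g` (the latter with a `dry_mass_g` column giving the
#' per-replicate dry mass). Rows are canonicalised by sorting on
#' (sample, replicate, time); duplicate or non-finite times are rejected
#' with the offending rows named. Mass input is converted to swelling degree
#' on read.
#'
#' @param path Path to a CSV file (UTF-8, header, decimal point).
#' @return A tibble with `sample_id`, `replicate_id`, `time_h`, `swelling`.
#' @export
read_study <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "replicate_id", "time_h")
  if (!all(need %in% names(raw))) {
    abort_bad_arg(sprintf("study file must have columns: %s.",
                          paste(need, collapse = ", ")))
  }
  has_s <- "swelling" %in% names(raw)
  has_m <- "mass_g" %in% names(raw)
  if (has_s && has_m) {
    abort_bad_arg("study file mixes `swelling` and `mass_g` columns; supply one.")
  }
  if (!has_s && !has_m) {
    abort_bad_arg("study file needs a `swelling` or `mass_g` column.")
  }
  if (has_m && !"dry_mass_g" %in% names(raw)) {
    abort_bad_arg("`mass_g` input requires a `dry_mass_g` column.")
  }
  raw <- dplyr::arrange(raw, .data$sample_id, .data$replicate_id, .data$time_h)
  if (any(!is.finite(raw$time_h))) {
    bad <- which(!is.finite(raw$time_h))[1]
    abort_bad_arg(sprintf("non-finite time_h at sorted row %d.", bad))
  }
  dup <- duplicated(raw[, c("sample_id", "replicate_id", "time_h")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort_bad_arg(sprintf(
      "duplicated (sample, replicate, time) at sorted row %d: %s / %s / t = %g.",
      i, raw$sample_id[i], raw$replicate_id[i], raw$time_h[i]))
  }
  if (has_m) {
    if (any(!is.finite(raw$dry_mass_g) | raw$dry_mass_g <= 0)) {
      abort_bad_arg("`dry_mass_g` must be positive for every row.")
    }
    raw <- dplyr::group_by(raw, .data$sample_id, .data$replicate_id)
    raw <- dplyr::mutate(raw,
                         swelling = (.data$mass_g - .data$dry_mass_g) /
                           .data$dry_mass_g)
    raw <- dplyr::ungroup(raw)
  }
  dplyr::select(raw, "sample_id", "replicate_id", "time_h", "swelling")
}

#' Read a long-format density study CSV
#'
#' Expects columns `sample_id`, `replicate_id`, `time_h` (> 0) and
#' `density_g_per_mL`.
#'
#' @inheritParams read_study
#' @return A tibble with `sample_id`, `replicate_id`, `time_h`, `density`.
#' @export
read_density_study <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "replicate_id", "time_h", "density_g_per_mL")
  if (!all(need %in% names(raw))) {
    abort_bad_arg(sprintf("density file must have columns: %s.",
                          paste(need, collapse = ", ")))
  }
  if (any(!is.finite(raw$time_h) | raw$time_h <= 0)) {
    abort_bad_arg("density times must be finite and > 0.")
  }
  raw <- dplyr::arrange(raw, .data$sample_id, .data$replicate_id, .data$time_h)
  tibble::tibble(sample_id = raw$sample_id, replicate_id = raw$replicate_id,
                 time_h = raw$time_h, density = raw$density_g_per_mL)
}

#' Write a simulated study to CSV (with a JSON truth side file)
#'
#' @param data A curve tibble (e.g. from [make_study_fixture()]).
#' @param path Output CSV path; the generating truth, when attached, is
#'   written next to it as `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_study <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  truth <- curve_truth(data)
  if (!is.null(truth)) {
    truth <- purrr::discard(as.list(truth), is.function)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

fit_row <- function(fit) {
  est <- unlist(fit$params)
  se <- unlist(fit$stderr)
  tibble::tibble(
    model_id = fit$model_id,
    term = names(est), estimate = unname(est), std_error = unname(se),
    r2 = fit$r2, r2_adj = fit$r2_adj, rss = fit$rss,
    n_points = fit$n_points,
    window_min = fit$window[1], window_max = fit$window[2],
    converged = fit$converged)
}

#' Fit the full study pipeline to a multi-curve table
#'
#' Per (sample, replicate): unified swelling-equation fit on the full curve
#' plus a power-law fit on the early window; per replicate, the mechanism is
#' classified from the fitted a*/b* ratio and from the power-law exponent.
#' Parameters are then compared across samples (ANOVA + Tukey letters) when
#' at least two samples with two replicates each are present.
#'
#' @param data Long curve tibble: `sample_id`, `replicate_id`, `time_h`,
#'   `swelling`.
#' @param window_fraction Early-uptake window for the power-law fit.
#' @param reference_time Dominance reference time for the mechanism call;
#'   `NULL` (default) uses the midpoint of each curve's time range.
#' @param alpha Significance level for the group comparisons.
#' @param seed Seed forwarded to the multi-start optimiser.
#' @return A list of class `"study_fit"`: `fits` (tidy per-replicate
#'   parameter table), `summary` (per-sample means +/- sd with mechanism
#'   labels and Tukey letters), `comparisons` (list of `group_comparison`).
#' @export
fit_study <- function(data, window_fraction = 0.60, reference_time = NULL,
                      alpha = 0.05, seed = 1L) {
  if (!is.data.frame(data) ||
      !all(c("sample_id", "replicate_id", "time_h", "swelling") %in%
           names(data))) {
    abort_bad_arg(
      "`data` must have sample_id, replicate_id, time_h, swelling columns.")
  }
  groups <- dplyr::group_split(dplyr::group_by(
    tibble::as_tibble(data), .data$sample_id, .data$replicate_id))
  rows <- purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$time_h)
    sw <- fit_swelling_eq(g, seed = seed)
    pl <- fit_power_law(g, window_fraction = window_fraction)
    ref_t <- if (is.null(reference_time)) {
      (min(g$time_h) + max(g$time_h)) / 2
    } else reference_time
    ref_t <- max(ref_t, .Machine$double.eps)
    call <- classify_from_ratio(sw$params$k, sw$params$a_star,
                                sw$params$b_star, reference_time = ref_t)
    expo <- classify_from_exponent(pl$params$n)
    eq <- estimate_equilibrium(g)
    tibble::tibble(
      sample_id = g$sample_id[1], replicate_id = g$replicate_id[1],
      k = sw$params$k, a_star = sw$params$a_star, b_star = sw$params$b_star,
      ratio = call$ratio, r2_swelling = sw$r2,
      converged = sw$converged,
      mechanism_ratio = call$hard_label,
      mechanism_dominance = call$dominance_label,
      overshoot_regime = call$overshoot_regime,
      overshoot_observed = eq$overshoot,
      S_eq = eq$S_eq,
      n = pl$params$n, k_pl = pl$params$k_pl, r2_power = pl$r2,
      mechanism_exponent = expo$label)
  })
  per_sample <- dplyr::summarise(
    dplyr::group_by(rows, .data$sample_id),
    dplyr::across(c("n", "k", "ratio", "S_eq"),
                  list(mean = mean, sd = stats::sd)),
    r2_swelling = mean(.data$r2_swelling),
    r2_power = mean(.data$r2_power),
    mechanism_exponent = names(sort(table(.data$mechanism_exponent),
                                    decreasing = TRUE))[1],
    mechanism_ratio = names(sort(table(.data$mechanism_ratio),
                                 decreasing = TRUE))[1],
    overshoot = any(.data$overshoot_regime | .data$overshoot_observed),
    .groups = "drop")
  comparisons <- list()
  n_reps <- table(rows$sample_id)
  if (length(n_reps) >= 2 && all(n_reps >= 2)) {
    for (param in c("k", "n", "ratio")) {
      d <- tibble::tibble(sample_id = rows$sample_id, value = rows[[param]])
      if (all(is.finite(d$value))) {
        comparisons[[param]] <- compare_groups(d, alpha = alpha)
        letcol <- paste0(param, "_letters")
        per_sample[[letcol]] <-
          comparisons[[param]]$summary$letters[
            match(per_sample$sample_id,
                  comparisons[[param]]$summary$sample_id)]
      }
    }
  }
  structure(list(fits = rows, summary = per_sample,
                 comparisons = comparisons),
            class = "study_fit")
}

#' @export
print.study_fit <- function(x, ...) {
  cat(sprintf("<study_fit: %d curves, %d samples>\n",
              nrow(x$fits), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Write a study-fit report (JSON + CSV summary)
#'
#' Serialises a [fit_study()] result as a machine-readable JSON report and a
#' per-sample CSV summary shaped like the customary swelling-parameter
#' tables (power-law n +/- sd with its mechanism label, k +/- sd, a*/b*
#' +/- sd, R2, mechanism call, Tukey letters). Numbers are stored at full
#' precision; re-running on identical inputs gives byte-identical files.
#'
#' @param study A `study_fit` object.
#' @param path Base output path without extension; writes `<path>.json` and
#'   `<path>.csv`.
#' @param schema_version Report schema identifier embedded in the JSON.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(study, path, schema_version = "1.0") {
  if (!inherits(study, "study_fit")) {
    abort_bad_arg("`study` must be a study_fit object.")
  }
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  report <- list(
    schema = list(name = "swellkin_report", version = schema_version),
    fits = study$fits,
    summary = study$summary,
    comparisons = purrr::map(study$comparisons, function(cmp) {
      list(parameter = cmp$parameter, anova_p = cmp$anova_p,
           alpha = cmp$alpha, summary = cmp$summary, tukey = cmp$tukey)
    }))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  readr::write_csv(study$summary, csv_path, progress = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Write a CF/CR mechanism profile to CSV
#'
#' @param profile A tibble from [fickian_contribution()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
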