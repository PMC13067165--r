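#' Compare a fitted parameter across samples (ANOVA + Tukey HSD letters)
#'
#' One-way analysis of variance of a per-replicate parameter value across
#' samples, followed by Tukey honest-significant-difference pairwise tests
#' and a compact letter display: samples sharing a letter are not
#' significantly different at the `1 - alpha` confidence level. This mirrors
#' the usual triplicate reporting of swelling studies (mean +/- sd with
#' superscript letters).
#'
#' @param data Data frame with one row per replicate: a grouping column
#'   (default `sample_id`) and a numeric `value` column.
#' @param value Name of the numeric column holding the parameter values.
#' @param group Name of the grouping column.
#' @param alpha Significance level for the Tukey tests. Default 0.05.
#' @return A list of class `"group_comparison"`: `summary` (tibble with per
#'   sample mean, sd, n and letters), `anova_p`, `tukey` (pairwise tibble),
#'   `alpha` and `parameter`.
#' @examples
#' d <- tibble::tibble(
#'   sample_id = rep(c("A", "B", "C"), each = 3),
#'   value = c(1.1, 1.0, 0.9, 1.2, 1.1, 1.0, 5.1, 5.0, 4.9))
#' compare_groups(d)
#' @export
compare_groups <- function(data, value = "value", group = "sample_id",
                           alpha = 0.05) {
  if (!is.data.frame(data) || !all(c(value, group) %in% names(data))) {
    abort_bad_arg(sprintf("`data` must have `%s` and `%s` columns.",
                          group, value))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_bad_arg("`alpha` must be in (0, 1).")
  }
  g <- factor(data[[group]])
  y <- data[[value]]
  if (any(!is.finite(y))) abort_bad_arg("parameter values must be finite.")
  counts <- table(g)
  if (length(counts) < 2L) abort_bad_arg("at least 2 groups are required.")
  if (any(counts < 2L)) {
    abort_bad_arg("every group needs at least 2 replicates.")
  }
  df <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  letters <- compact_letter_display(levels(g), pairs, alpha)
  summary_tbl <- tibble::tibble(
    !!group := levels(g),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, stats::sd)),
    n = as.integer(counts),
    letters = letters[levels(g)]
  )
  structure(
    list(summary = summary_tbl, anova_p = anova_p, tukey = pairs,
         alpha = alpha, parameter = value),
    class = "group_comparison")
}

# Insert-and-absorb compact letter display from pairwise adjusted p-values.
# Starts from one letter covering all groups; each significant pair splits
# every letter containing both; duplicate/contained letter sets are absorbed.
compact_letter_display <- function(groups, pairs, alpha) {
  sets <- list(groups)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) > 0) {
    split_pairs <- strsplit(sig$contrast, "-", fixed = TRUE)
    for (pr in split_pairs) {
      new_sets <- list()
      for (s in sets) {
        if (all(pr %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, pr[1])),
                        list(setdiff(s, pr[2])))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i != j && keep[i] && keep[j] &&
              all(new_sets[[i]] %in% new_sets[[j]]) &&
              !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j)) {
            keep[i] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letter sets by their first group for a stable display
  first_idx <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_idx)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) lab <- paste0(lab, (i - 1L) %/% 26L)
    for (gname in sets[[i]]) out[gname] <- paste0(out[gname], lab)
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s> ANOVA p = %.4g (alpha = %g)\n",
              x$parameter, x$anova_p, x$alpha))
  print(x$summary)
  invisible(x)
}
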