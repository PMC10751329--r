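## Relative expression from qPCR Ct tables (2^-ddCt), midparent value,
## nonadditivity test, and the group / time-course comparisons.

.check_ct_table <- function(ct) {
  ct <- .check_df_cols(ct, c("sample_id", "group", "gene", "ct"), "ct")
  if (!is.numeric(ct$ct) || any(!is.finite(ct$ct))) {
    abort("column `ct` must be finite numeric")
  }
  bad_gene <- setdiff(unique(ct$gene), c("target", "reference"))
  if (length(bad_gene)) {
    abort(sprintf("column `gene` must be 'target' or 'reference' (found: %s)",
                  paste(bad_gene, collapse = ", ")))
  }
  if (any(ct$ct < 10 | ct$ct > 40)) {
    warn("some Ct values fall outside the typical 10-40 cycle range")
  }
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, technical replicates are averaged on the Ct scale, then
#' dCt = Ct(target) - Ct(reference). ddCt is taken relative to the arithmetic
#' mean dCt of the calibrator group, and the relative expression is
#' `2^-ddCt` (amplification efficiency assumed 100%). By construction the
#' geometric mean of the calibrator group's values is exactly 1.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene` ("target" /
#'   "reference"), `ct`, and optionally `condition` and `time_h` (kept and
#'   used as part of the sample key).
#' @param calibrator Group whose mean dCt anchors the scale (default "B");
#'   `NULL` uses the grand mean dCt of all samples (scale choice does not
#'   affect any downstream ratio or test).
#' @return Tibble with one row per sample: key columns plus `delta_ct`,
#'   `delta_delta_ct` and `value` (fold, `2^-delta_delta_ct`).
#' @export
relative_expression <- function(ct, calibrator = "B") {
  ct <- .check_ct_table(ct)
  keys <- intersect(c("sample_id", "group", "condition", "time_h"), names(ct))
  wide <- ct |>
    group_by(across(all_of(c(keys, "gene")))) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!all(c("target", "reference") %in% names(wide))) {
    abort("every sample needs both a target and a reference Ct")
  }
  incomplete <- is.na(wide$target) | is.na(wide$reference)
  if (any(incomplete)) {
    abort(sprintf("sample %s is missing a target or reference Ct",
                  wide$sample_id[which(incomplete)[1L]]))
  }
  wide <- mutate(wide, delta_ct = .data$target - .data$reference)
  cal_dct <- if (is.null(calibrator)) {
    wide$delta_ct
  } else {
    wide$delta_ct[wide$group == calibrator]
  }
  if (!length(cal_dct)) {
    abort(sprintf("calibrator group '%s' has no samples", calibrator))
  }
  wide |>
    mutate(delta_delta_ct = .data$delta_ct - mean(cal_dct),
           value = 2^(-.data$delta_delta_ct)) |>
    select(all_of(keys), "delta_ct", "delta_delta_ct", "value")
}

#' Midparent value
#'
#' The additive expectation for hybrid expression: the average of the two
#' parental group means, on the linear fold scale.
#'
#' @param n_values,b_values Numeric vectors of per-individual relative
#'   expression for the maternal and paternal parent lines.
#' @return Single number, `(mean(n_values) + mean(b_values)) / 2`.
#' @export
midparent_value <- function(n_values, b_values) {
  if (!length(n_values) || !length(b_values)) {
    abort("both parental groups must be non-empty")
  }
  (mean(n_values) + mean(b_values)) / 2
}

#' Test hybrid expression against the midparent value
#'
#' Two-sided one-sample t-test of the hybrid's per-individual relative
#' expression against the (constant) midparent value. Expression is called
#' nonadditive when p < alpha, with the direction given by the sign of the
#' departure. Parental sampling variance in the MPV estimate is deliberately
#' ignored (the classical formulation); see the methods vignette for the
#' calibration consequences.
#'
#' @param nb_values Numeric vector (>= 2 values, nonzero variance) of hybrid
#'   relative expression.
#' @param mpv Midparent value (fold scale).
#' @param alpha Significance level.
#' @return Object of class `additivity_test` with fields `mpv`, `nb_mean`,
#'   `n`, `t_statistic`, `df`, `p_value`, `category` ("additive" /
#'   "nonadditive") and `direction` ("above_mpv", "below_mpv" or "none").
#' @export
test_additivity <- function(nb_values, mpv, alpha = 0.05) {
  if (length(nb_values) < 2L || sd(nb_values) == 0) {
    abort("need >= 2 hybrid values with nonzero variance for the t-test")
  }
  if (!is.numeric(mpv) || length(mpv) != 1L || !is.finite(mpv)) {
    abort("`mpv` must be a single finite number")
  }
  tt <- t.test(nb_values, mu = mpv)
  nonadd <- tt$p.value < alpha
  structure(
    list(
      mpv = mpv,
      nb_mean = mean(nb_values),
      n = length(nb_values),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      alpha = alpha,
      category = if (nonadd) "nonadditive" else "additive",
      direction = if (!nonadd) "none"
                  else if (mean(nb_values) > mpv) "above_mpv" else "below_mpv"
    ),
    class = "additivity_test"
  )
}

#' @export
print.additivity_test <- function(x, ...) {
  cat(sprintf(
    "Midparent test: NB mean %.3f vs MPV %.3f | t = %.3f (df = %g), p = %.4g\n",
    x$nb_mean, x$mpv, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  call: %s%s (alpha = %g)\n", x$category,
              if (x$direction == "none") "" else paste0(", ", x$direction),
              x$alpha))
  invisible(x)
}

#' One-way ANOVA across groups with a compact letter display
#'
#' One-way ANOVA of a response across groups, followed by Tukey HSD pairwise
#' comparisons summarised as a compact letter display at level `alpha`
#' (groups sharing no letter differ significantly).
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor; defaults `"value"` and `"group"` match [relative_expression()]
#'   output. Every group needs >= 2 values.
#' @param alpha Significance level for the letters.
#' @return Object of class `group_anova` with the F statistic, degrees of
#'   freedom, p-value, per-group summary (n, mean, sd, letter) and the Tukey
#'   pairwise table.
#' @export
group_anova <- function(data, value = "value", group = "group", alpha = 0.05) {
  data <- .check_df_cols(data, c(value, group), "data")
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  sizes <- table(df$g)
  if (length(sizes) < 2L) abort("need >= 2 groups")
  if (any(sizes < 2L)) {
    abort(sprintf("every group needs >= 2 values (group '%s' has %d)",
                  names(sizes)[which(sizes < 2L)[1L]],
                  min(sizes)))
  }
  fit <- aov(y ~ g, data = df)
  tab <- summary(fit)[[1L]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
  tukey <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairwise <- tibble(
    contrast = rownames(tukey),
    estimate = tukey[, "diff"],
    p_value = tukey[, "p adj"]
  )
  summary_tbl <- df |>
    group_by(.data$g) |>
    summarise(n = n(), mean = mean(.data$y), sd = sd(.data$y),
              .groups = "drop") |>
    rename(group = "g") |>
    mutate(group = as.character(.data$group),
           letter = unname(letters[.data$group]))
  structure(
    list(
      f_statistic = tab[1L, "F value"],
      df = c(tab[1L, "Df"], tab[2L, "Df"]),
      p_value = tab[1L, "Pr(>F)"],
      alpha = alpha,
      groups = summary_tbl,
      pairwise = pairwise
    ),
    class = "group_anova"
  )
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' Compare feeding conditions across a time course
#'
#' Computes relative expression (grand-mean calibrated; the calibrator choice
#' cancels from every comparison), then runs a two-sided two-sample t-test
#' between the two conditions at each time point plus a two-way ANOVA with
#' condition, time and their interaction. Time points observed in only one
#' condition are excluded with a warning. Per-time p-values are reported
#' unadjusted by default, mirroring common per-time asterisk reporting; Holm
#' correction is available.
#'
#' @param ct Ct table (see [relative_expression()]) with a `condition` column
#'   holding exactly two levels and a numeric `time_h` column.
#' @param alpha Significance level.
#' @param adjust Multiple-testing correction across time points: `"none"`
#'   (default) or `"holm"`.
#' @param var_equal Pooled-variance t-tests (default TRUE); FALSE for Welch.
#' @return Object of class `timecourse_comparison` with `per_time` (tibble of
#'   per-time tests) and `anova` (two-way ANOVA table).
#' @export
timecourse_compare <- function(ct, alpha = 0.05, adjust = c("none", "holm"),
                               var_equal = TRUE) {
  adjust <- match.arg(adjust)
  ct <- .check_df_cols(ct, c("condition", "time_h"), "ct")
  rel <- relative_expression(ct, calibrator = NULL)
  conds <- sort(unique(rel$condition))
  if (length(conds) != 2L) {
    abort(sprintf("`condition` must have exactly two levels (found %d)",
                  length(conds)))
  }
  counts <- rel |>
    group_by(.data$time_h) |>
    summarise(n_cond = length(unique(.data$condition)), .groups = "drop")
  dropped <- counts$time_h[counts$n_cond < 2L]
  if (length(dropped)) {
    warn(sprintf("time point(s) %s present in only one condition; excluded",
                 paste(dropped, collapse = ", ")))
    rel <- filter(rel, !.data$time_h %in% dropped)
  }
  times <- sort(unique(rel$time_h))
  per_time <- purrr::map_dfr(times, function(tp) {
    x <- rel$value[rel$time_h == tp & rel$condition == conds[1L]]
    y <- rel$value[rel$time_h == tp & rel$condition == conds[2L]]
    tt <- t.test(x, y, var.equal = var_equal)
    tibble(
      time_h = tp,
      mean_1 = mean(x), mean_2 = mean(y),
      n_1 = length(x), n_2 = length(y),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  names(per_time)[names(per_time) == "mean_1"] <- paste0("mean_", conds[1L])
  names(per_time)[names(per_time) == "mean_2"] <- paste0("mean_", conds[2L])
  names(per_time)[names(per_time) == "n_1"] <- paste0("n_", conds[1L])
  names(per_time)[names(per_time) == "n_2"] <- paste0("n_", conds[2L])
  per_time$p_adjusted <- p.adjust(per_time$p_value, method = adjust)
  per_time$significant <- per_time$p_adjusted < alpha
  fit <- aov(value ~ condition * factor(time_h), data = rel)
  tab <- summary(fit)[[1L]]
  anova_tbl <- tibble(
    term = trimws(rownames(tab)),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  structure(
    list(per_time = per_time, anova = anova_tbl, conditions = conds,
         alpha = alpha, adjust = adjust),
    class = "timecourse_comparison"
  )
}

#' @export
print.timecourse_comparison <- function(x, ...) {
  cat(sprintf("Time-course comparison (%s vs %s), alpha = %g, adjust = %s\n",
              x$conditions[1L], x$conditions[2L], x$alpha, x$adjust))
  print(x$per_time)
  cat("\nTwo-way ANOVA:\n")
  print(x$anova)
  invisible(x)
}
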