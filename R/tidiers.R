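## broom-style tidiers for the package's result objects.

#' Tidy an additivity (midparent) test
#' @param x An `additivity_test`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.additivity_test <- function(x, ...) {
  tibble(mpv = x$mpv, nb_mean = x$nb_mean, n = x$n,
         t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
         category = x$category, direction = x$direction)
}

#' @rdname tidy.additivity_test
#' @export
glance.additivity_test <- function(x, ...) tidy(x)

#' Tidy an ASE t-test
#' @param x An `ase_test`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.ase_test <- function(x, ...) {
  tibble(n = x$n, mean_fraction = x$mean_fraction, null = x$null,
         t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
         biased = x$biased, bias_direction = x$bias_direction)
}

#' @rdname tidy.ase_test
#' @export
glance.ase_test <- function(x, ...) tidy(x)

#' Tidy a cis/trans classification
#' @param x A `cis_trans`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.cis_trans <- function(x, ...) {
  tibble(A = x$A, B = x$B, trans = x$trans, category = x$category,
         magnitude_category = x$magnitude_category,
         rule_agreement = x$rule_agreement,
         p_A = x$p_A, p_B = x$p_B)
}

#' @rdname tidy.cis_trans
#' @export
glance.cis_trans <- function(x, ...) tidy(x)

#' Tidy a one-way group ANOVA
#'
#' `tidy()` returns the per-group summary with compact letters; `glance()`
#' the overall F test.
#' @param x A `group_anova`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.group_anova <- function(x, ...) x$groups

#' @rdname tidy.group_anova
#' @export
glance.group_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_between = x$df[1L],
         df_within = x$df[2L], p_value = x$p_value)
}

#' Tidy a time-course comparison
#'
#' `tidy()` returns the per-time t-test table; `glance()` the two-way ANOVA
#' terms as one row per term.
#' @param x A `timecourse_comparison`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.timecourse_comparison <- function(x, ...) x$per_time

#' @rdname tidy.timecourse_comparison
#' @export
glance.timecourse_comparison <- function(x, ...) x$anova

#' Tidy an ASE condition comparison
#'
#' `tidy()` returns the per-cell bias calls; `glance()` the stability
#' verdict and ANOVA p-values.
#' @param x An `ase_condition_comparison`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.ase_condition_comparison <- function(x, ...) x$per_cell

#' @rdname tidy.ase_condition_comparison
#' @export
glance.ase_condition_comparison <- function(x, ...) {
  out <- tibble(stable = x$stable)
  if (!is.null(x$anova)) {
    for (i in seq_len(nrow(x$anova) - 1L)) {
      out[[paste0("p_", gsub("[^a-zA-Z0-9]+", "_", x$anova$term[i]))]] <-
        x$anova$p_value[i]
    }
  }
  out
}

#' Tidy a parameter-recovery result
#' @param x A `parameter_recovery`.
#' @param ... Unused.
#' @return One-row tibble of estimates, truth and errors.
#' @export
tidy.parameter_recovery <- function(x, ...) {
  tibble(A_hat = x$A_hat, A_true = x$A_true, error_A = x$error_A,
         B_hat = x$B_hat, B_true = x$B_true, error_B = x$error_B,
         category = x$category, category_true = x$category_true,
         category_match = x$category_match,
         nonadditive = x$additivity$category == "nonadditive",
         direction = x$additivity$direction,
         maternal_biased = all(x$ase$bias_direction == "maternal"))
}

#' @rdname tidy.parameter_recovery
#' @export
glance.parameter_recovery <- function(x, ...) tidy(x)
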