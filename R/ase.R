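## Allele-specific expression: maternal allelic fractions from
## pyrosequencing-style read counts and tests against balanced (50:50)
## expression, overall and across feeding conditions.

#' Maternal allelic fraction
#'
#' @param maternal,paternal Non-negative read counts (vectorised); every
#'   record needs a positive total.
#' @return `maternal / (maternal + paternal)`.
#' @examples
#' maternal_fraction(80, 20)  # 0.8
#' @export
maternal_fraction <- function(maternal, paternal) {
  if (any(maternal < 0) || any(paternal < 0)) {
    abort("read counts must be non-negative")
  }
  total <- maternal + paternal
  if (any(total <= 0)) {
    abort(sprintf("zero total read count in record %s",
                  which(total <= 0)[1L]))
  }
  maternal / total
}

#' Add maternal fractions to an allele-count table
#'
#' @param counts Data frame with `maternal_count` and `paternal_count`.
#' @param pseudocount Haldane-Anscombe pseudocount added to both counts
#'   before the ratio (default 0; use 0.5 ahead of log-ratio work so zero
#'   counts stay finite).
#' @return Input tibble with a `fraction` column appended.
#' @export
allele_fractions <- function(counts, pseudocount = 0) {
  counts <- .check_df_cols(counts, c("maternal_count", "paternal_count"),
                           "counts")
  mutate(counts, fraction = maternal_fraction(
    .data$maternal_count + pseudocount,
    .data$paternal_count + pseudocount))
}

#' t-test of allelic fractions against balanced expression
#'
#' Two-sided one-sample t-test of per-individual maternal fractions against
#' 0.5 (mathematically equivalent to a paired test on the two allele
#' percentages). Bias direction is taken from the sign of the departure when
#' significant.
#'
#' @param fractions Numeric vector of maternal fractions in \[0, 1\]; >= 2
#'   values with nonzero variance.
#' @param alpha Significance level.
#' @param null Null fraction (default 0.5).
#' @return Object of class `ase_test` with `n`, `mean_fraction`,
#'   `t_statistic`, `df`, `p_value`, `biased` and `bias_direction`
#'   ("maternal" / "paternal" / "none").
#' @export
ase_test_t <- function(fractions, alpha = 0.05, null = 0.5) {
  if (any(fractions < 0 | fractions > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (length(fractions) < 2L || sd(fractions) == 0) {
    abort(paste("need >= 2 fractions with nonzero variance;",
                "for constant counts use ase_test_binomial()"))
  }
  tt <- t.test(fractions, mu = null)
  biased <- tt$p.value < alpha
  structure(
    list(
      n = length(fractions),
      mean_fraction = mean(fractions),
      null = null,
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      alpha = alpha,
      biased = biased,
      bias_direction = if (!biased) "none"
                       else if (mean(fractions) > null) "maternal"
                       else "paternal"
    ),
    class = "ase_test"
  )
}

#' @export
print.ase_test <- function(x, ...) {
  cat(sprintf(
    "ASE t-test: mean maternal fraction %.3f (n = %d) vs %.2f | t = %.3f, p = %.4g\n",
    x$mean_fraction, x$n, x$null, x$t_statistic, x$p_value))
  cat(sprintf("  call: %s%s (alpha = %g)\n",
              if (x$biased) "biased" else "unbiased",
              if (x$bias_direction == "none") ""
              else paste0(" (", x$bias_direction, ")"),
              x$alpha))
  invisible(x)
}

#' Exact binomial test of allelic balance, per record
#'
#' Exact two-sided binomial p-value against p = 0.5 for each maternal /
#' paternal count pair: the sum of probabilities of all outcomes no more
#' likely than the observed count. The per-sample complement to
#' [ase_test_t()].
#'
#' @param maternal,paternal Non-negative read counts (vectorised), positive
#'   totals.
#' @return Numeric vector of p-values.
#' @examples
#' ase_test_binomial(10, 0)  # 2 * 0.5^10
#' @export
ase_test_binomial <- function(maternal, paternal) {
  if (any(maternal + paternal <= 0)) {
    abort("zero total read count")
  }
  purrr::map2_dbl(maternal, paternal,
                  function(m, p) binom.test(m, m + p, p = 0.5)$p.value)
}

#' Compare allele-specific expression across conditions and times
#'
#' Two-way ANOVA of maternal fractions on time and SNP site (plus their
#' interaction), with a per-cell one-sample t-test against 0.5. The ASE is
#' called "stable" across the design when neither the time main effect nor
#' any interaction involving time is significant at `alpha`.
#'
#' @param counts Allele-count table with `sample_id`, `site_label`,
#'   `maternal_count`, `paternal_count`, `time_h`. Cells ((time, site)) with
#'   fewer than 2 samples are excluded with a warning.
#' @param alpha Significance level.
#' @return Object of class `ase_condition_comparison` with `anova` (or NULL
#'   for a degenerate single-cell design), `per_cell` bias calls and a
#'   `stable` flag.
#' @export
ase_condition_compare <- function(counts, alpha = 0.05) {
  counts <- .check_df_cols(
    counts,
    c("sample_id", "site_label", "maternal_count", "paternal_count", "time_h"),
    "counts")
  fr <- allele_fractions(counts)
  cell_n <- fr |>
    group_by(.data$time_h, .data$site_label) |>
    summarise(n = n(), .groups = "drop")
  small <- cell_n[cell_n$n < 2L, ]
  if (nrow(small)) {
    warn(sprintf("excluding %d cell(s) with < 2 samples", nrow(small)))
    fr <- dplyr::anti_join(fr, small[, c("time_h", "site_label")],
                           by = c("time_h", "site_label"))
  }
  if (!nrow(fr)) abort("no analyzable cells")
  n_times <- length(unique(fr$time_h))
  n_sites <- length(unique(fr$site_label))
  anova_tbl <- NULL
  if (n_times < 2L && n_sites < 2L) {
    warn("single-cell design: no ANOVA possible, per-cell tests only")
  } else {
    form <- if (n_times >= 2L && n_sites >= 2L) {
      fraction ~ factor(time_h) * factor(site_label)
    } else if (n_times >= 2L) {
      fraction ~ factor(time_h)
    } else {
      fraction ~ factor(site_label)
    }
    tab <- summary(aov(form, data = fr))[[1L]]
    anova_tbl <- tibble(
      term = trimws(rownames(tab)),
      df = tab$Df,
      sumsq = tab$`Sum Sq`,
      meansq = tab$`Mean Sq`,
      statistic = tab$`F value`,
      p_value = tab$`Pr(>F)`
    )
  }
  per_cell <- fr |>
    group_by(.data$time_h, .data$site_label) |>
    summarise(
      n = n(),
      mean_fraction = mean(.data$fraction),
      p_value = tryCatch(t.test(.data$fraction, mu = 0.5)$p.value,
                         error = function(e) NA_real_),
      .groups = "drop"
    ) |>
    mutate(
      biased = !is.na(.data$p_value) & .data$p_value < alpha,
      bias_direction = case_when(
        !.data$biased ~ "none",
        .data$mean_fraction > 0.5 ~ "maternal",
        TRUE ~ "paternal"
      )
    )
  time_terms <- !is.null(anova_tbl) &
    grepl("time_h", anova_tbl$term, fixed = TRUE)
  stable <- !any(time_terms & anova_tbl$p_value < alpha, na.rm = TRUE)
  structure(
    list(anova = anova_tbl, per_cell = per_cell, stable = stable,
         alpha = alpha),
    class = "ase_condition_comparison"
  )
}

#' @export
print.ase_condition_comparison <- function(x, ...) {
  cat("ASE across conditions: ",
      if (x$stable) "stable" else "time-dependent",
      sprintf(" (alpha = %g)\n", x$alpha), sep = "")
  print(x$per_cell)
  if (!is.null(x$anova)) {
    cat("\nANOVA:\n")
    print(x$anova)
  }
  invisible(x)
}
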