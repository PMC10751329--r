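# Independent oracles used across the suite. Each recomputes a quantity by
# the most direct route available -- textbook formulas, explicit sums of
# squares, exhaustive enumeration, or a second library's implementation --
# never by calling the code path under test.

# One-sample t, textbook formula.
oracle_t_one_sample <- function(x, mu) {
  n <- length(x)
  t_stat <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t_stat, df = n - 1,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# One-way ANOVA from explicit between/within sums of squares.
oracle_anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(unlist(tapply(values, groups, function(v) {
    (v - mean(v))^2
  })))
  df_b <- length(unique(groups)) - 1
  df_w <- length(values) - length(unique(groups))
  f_stat <- (ss_between / df_b) / (ss_within / df_w)
  list(ss_between = ss_between, ss_within = ss_within,
       f = f_stat, p = stats::pf(f_stat, df_b, df_w, lower.tail = FALSE))
}

# Balanced two-way ANOVA sums of squares from cell/marginal means.
oracle_anova_twoway <- function(values, fa, fb) {
  fa <- as.character(fa); fb <- as.character(fb)
  grand <- mean(values)
  la <- sort(unique(fa)); lb <- sort(unique(fb))
  n_cell <- length(values) / (length(la) * length(lb))
  ma <- tapply(values, fa, mean)[la]
  mb <- tapply(values, fb, mean)[lb]
  ss_a <- n_cell * length(lb) * sum((ma - grand)^2)
  ss_b <- n_cell * length(la) * sum((mb - grand)^2)
  cell <- tapply(values, list(fa, fb), mean)[la, lb]
  ss_int <- n_cell * sum((sweep(sweep(cell, 1, ma - grand), 2, mb - grand) -
                            grand)^2)
  ss_res <- sum((values - ave(values, fa, fb))^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_interaction = ss_int,
       ss_residual = ss_res)
}

# Exact two-sided binomial p vs 0.5: enumerate the full pmf and sum every
# outcome whose probability does not exceed that of the observed count.
oracle_binom_two_sided <- function(k, n) {
  pmf <- stats::dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-07)])
}

# 2^-ddCt by a literal spreadsheet-style recomputation from a long Ct table.
oracle_ddct <- function(ct, calibrator) {
  samples <- unique(ct$sample_id)
  dct <- vapply(samples, function(s) {
    mean(ct$ct[ct$sample_id == s & ct$gene == "target"]) -
      mean(ct$ct[ct$sample_id == s & ct$gene == "reference"])
  }, numeric(1))
  grp <- vapply(samples, function(s) {
    ct$group[ct$sample_id == s][1]
  }, character(1))
  ddct <- dct - mean(dct[grp == calibrator])
  data.frame(sample_id = samples, value = 2^(-ddct),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Minimal Ct table builder: one target and one reference row per sample.
make_ct_table <- function(groups, dct, ref_ct = 18) {
  n <- length(dct)
  data.frame(
    sample_id = rep(paste0("s", seq_len(n)), 2),
    group = rep(groups, 2),
    gene = rep(c("target", "reference"), each = n),
    condition = "none", time_h = 0,
    ct = c(ref_ct + dct, rep(ref_ct, n))
  )
}
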