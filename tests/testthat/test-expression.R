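# 2^-ddCt quantification, midparent value, nonadditivity test and the
# group / time-course comparisons.

test_that("relative expression matches a spreadsheet-style oracle", {
  set.seed(31)
  ct <- make_ct_table(groups = c("N", "N", "B", "B", "NB", "NB"),
                      dct = round(rnorm(6, 8, 1), 3))
  rel <- relative_expression(ct, calibrator = "B")
  expected <- oracle_ddct(ct, calibrator = "B")
  expect_equal(rel$value[match(expected$sample_id, rel$sample_id)],
               expected$value, tolerance = 1e-12)
  # a calibrator sample sitting exactly at the calibrator mean dCt -> 1.0
  flat <- make_ct_table(groups = c("B", "B", "N"), dct = c(5, 5, 3))
  expect_equal(relative_expression(flat, "B")$value[1:2], c(1, 1))
  # ddCt of -2 -> fold 4
  two <- make_ct_table(groups = c("B", "N"), dct = c(7, 5))
  expect_equal(relative_expression(two, "B")$value[2], 4)
})

test_that("calibrator geometric mean is 1 and a shared Ct shift cancels", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    ct <- make_ct_table(groups = sample(c("N", "B", "NB"), n, replace = TRUE,
                                        prob = c(1, 2, 1)),
                        dct = rnorm(n, 8, 1.5))
    if (!"B" %in% ct$group) next
    rel <- relative_expression(ct, "B")
    expect_equal(exp(mean(log(rel$value[rel$group == "B"]))), 1,
                 tolerance = 1e-12)
    shifted <- ct
    shifted$ct[shifted$gene == "target"] <-
      shifted$ct[shifted$gene == "target"] + 1.7
    shifted$ct[shifted$gene == "reference"] <-
      shifted$ct[shifted$gene == "reference"] + 1.7
    expect_equal(relative_expression(shifted, "B")$value, rel$value,
                 tolerance = 1e-12)
  }
})

test_that("technical replicates are averaged on the Ct scale", {
  ct <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    group = "B",
    gene = c("target", "target", "reference", "target", "reference"),
    ct = c(25, 27, 18, 27, 18)
  )
  rel <- relative_expression(ct, "B")
  expect_equal(rel$delta_ct, c(8, 9))
})

test_that("relative expression rejects incomplete or miscoded tables", {
  ct <- make_ct_table(groups = c("B", "N"), dct = c(5, 3))
  expect_error(relative_expression(ct[ct$gene == "target", ], "B"),
               "target and a reference")
  expect_error(relative_expression(ct, "NB"), "no samples")
  bad <- ct
  bad$gene[1] <- "actin"
  expect_error(relative_expression(bad, "B"), "gene")
  low <- ct
  low$ct[1] <- 5
  expect_warning(relative_expression(low, "B"), "10-40")
})

test_that("midparent value is the average of the parental means", {
  expect_equal(midparent_value(c(1.5, 2.5), c(3.5, 4.5)), 3)
  expect_equal(midparent_value(rep(2.2, 4), rep(2.2, 7)), 2.2)
  set.seed(33)
  for (i in 1:20) {
    a <- runif(sample(2:8, 1), 0, 5)
    b <- runif(sample(2:8, 1), 0, 5)
    expect_equal(midparent_value(a, b), (sum(a)/length(a) + sum(b)/length(b))/2)
    k <- runif(1, 0.1, 3)
    expect_equal(midparent_value(k * a, k * b), k * midparent_value(a, b))
  }
  expect_error(midparent_value(numeric(0), 1), "non-empty")
})

test_that("the nonadditivity call follows the one-sample t-test", {
  sym <- test_additivity(c(1.8, 2.2, 2.0, 1.9, 2.1), mpv = 2)
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$category, "additive")
  expect_equal(sym$direction, "none")

  high <- test_additivity(c(3.01, 2.99, 3.02, 2.98), mpv = 1.5)
  expect_equal(high$category, "nonadditive")
  expect_equal(high$direction, "above_mpv")

  set.seed(34)
  x <- rnorm(8, 2, 0.4)
  got <- test_additivity(x, mpv = 1.7)
  want <- oracle_t_one_sample(x, 1.7)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  expect_error(test_additivity(2, mpv = 1), "variance")
  expect_error(test_additivity(c(2, 2, 2), mpv = 1), "variance")
})

test_that("group ANOVA matches direct sums of squares and letters separate a
           shifted group", {
  set.seed(35)
  df <- data.frame(
    group = rep(c("N", "B", "NB"), each = 5),
    value = c(rnorm(5, 2, 0.2), rnorm(5, 1, 0.2), rnorm(5, 8, 0.2))
  )
  fit <- group_anova(df)
  want <- oracle_anova_oneway(df$value, df$group)
  expect_equal(fit$f_statistic, want$f, tolerance = 1e-10)
  expect_equal(fit$p_value, want$p, tolerance = 1e-10)
  letters <- setNames(fit$groups$letter, fit$groups$group)
  expect_false(letters[["NB"]] %in% letters[c("N", "B")])

  expect_error(group_anova(df[df$group == "N", ]), ">= 2 groups")
  expect_error(group_anova(df[-(1:4), ]), ">= 2 values")
})

test_that("group ANOVA p-values are uniform under the null", {
  set.seed(36)
  pvals <- replicate(400, {
    df <- data.frame(group = rep(c("N", "B", "NB"), each = 5),
                     value = rnorm(15, 2, 0.3))
    group_anova(df)$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("time-course comparison finds a planted fasting effect from 4 h on", {
  cfg <- sim_config(cis = 0, trans = 0, sigma_ct = 0.1,
                    fasting_multipliers = c("0" = 1, "4" = 2, "8" = 2,
                                            "12" = 2, "24" = 2, "48" = 2),
                    seed = 99)
  tc <- simulate_timecourse(cfg)
  cmp <- timecourse_compare(tc$ct)
  sig <- cmp$per_time$time_h[cmp$per_time$significant]
  expect_setequal(sig, c(4, 8, 12, 24, 48))
  expect_false(0 %in% sig)
  # condition and interaction terms must register in the two-way ANOVA
  p_cond <- cmp$anova$p_value[cmp$anova$term == "condition"]
  expect_lt(p_cond, 0.001)
})

test_that("time-course two-way ANOVA matches direct sums of squares", {
  set.seed(37)
  times <- c(0, 4, 8, 12, 24, 48)
  ct <- data.frame(
    sample_id = paste0("s", 1:(2 * 6 * 3)),
    group = "NB",
    condition = rep(c("feeding", "fasting"), each = 6 * 3),
    time_h = rep(rep(times, each = 3), 2),
    stringsAsFactors = FALSE
  )
  ct <- rbind(
    transform(ct, gene = "target", ct = 26 + rnorm(nrow(ct), 0, 0.5)),
    transform(ct, gene = "reference", ct = 18)
  )
  cmp <- timecourse_compare(ct)
  rel <- relative_expression(ct, calibrator = NULL)
  want <- oracle_anova_twoway(rel$value, rel$condition, rel$time_h)
  got <- setNames(cmp$anova$sumsq, cmp$anova$term)
  expect_equal(got[["condition"]], want$ss_a, tolerance = 1e-10)
  expect_equal(got[["factor(time_h)"]], want$ss_b, tolerance = 1e-10)
  expect_equal(got[["condition:factor(time_h)"]], want$ss_interaction,
               tolerance = 1e-10)
  expect_equal(got[["Residuals"]], want$ss_residual, tolerance = 1e-10)
  # per-time t equals the textbook two-sample pooled t
  t0 <- cmp$per_time[cmp$per_time$time_h == 0, ]
  x <- rel$value[rel$time_h == 0 & rel$condition == "fasting"]
  y <- rel$value[rel$time_h == 0 & rel$condition == "feeding"]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  expect_equal(t0$t_statistic, (mean(x) - mean(y)) / (sp * sqrt(1/length(x) +
                 1/length(y))), tolerance = 1e-12)
})

test_that("null time courses alarm at about the nominal rate", {
  cfg_null <- c("0" = 1, "4" = 1, "8" = 1, "12" = 1, "24" = 1, "48" = 1)
  set.seed(38)
  hits <- sapply(1:50, function(r) {
    cfg <- sim_config(fasting_multipliers = cfg_null, seed = 5000 + r)
    tc <- simulate_timecourse(cfg)
    sum(timecourse_compare(tc$ct)$per_time$significant)
  })
  rate <- mean(hits) / 6
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})

test_that("a time point observed in one condition is excluded with warning", {
  cfg <- sim_config(seed = 40)
  tc <- simulate_timecourse(cfg)
  ct <- tc$ct[!(tc$ct$condition == "feeding" & tc$ct$time_h == 48), ]
  expect_warning(cmp <- timecourse_compare(ct), "only one condition")
  expect_false(48 %in% cmp$per_time$time_h)
})
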