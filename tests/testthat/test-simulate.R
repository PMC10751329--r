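# The synthetic-study generator: reproducibility, planted-SNP round trips,
# noise-free inversion and Monte-Carlo consistency.

test_that("identical configs reproduce a study bit-exactly", {
  cfg <- sim_config(cis = 1.5, trans = -0.5, seed = 71)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_config(cis = 1.5, trans = -0.5, seed = 72))
  expect_false(identical(s1$ct, s3$ct))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_study(sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("planted parental SNPs are exactly recovered", {
  cfg <- sim_config(n_snps = 2, seed = 73)
  seqs <- simulate_parental_sequences(cfg)
  found <- find_fixed_differences(seqs$maternal, seqs$paternal)
  expect_equal(found, seqs$sites)

  none <- simulate_parental_sequences(sim_config(n_snps = 0, seed = 74))
  expect_identical(none$maternal, none$paternal)
  expect_equal(nrow(find_fixed_differences(none$maternal, none$paternal)), 0L)

  expect_error(sim_config(seq_length = 30, n_snps = 10), "smaller")
})

test_that("simulated parents are valid ORFs of the configured length", {
  for (seed in 75:78) {
    seqs <- simulate_parental_sequences(sim_config(seed = seed))
    expect_true(validate_orf(seqs$maternal)$valid)
    expect_true(validate_orf(seqs$paternal)$valid)
    expect_equal(nchar(translate_orf(seqs$maternal)), 107L)
  }
})

test_that("noise-free expression inverts exactly through the pipeline", {
  cfg <- sim_config(cis = 1.5, trans = 0.5, sigma_ct = 0, seed = 79)
  rel <- relative_expression(simulate_expression(cfg), calibrator = "B")
  expect_equal(divergence_A(rel$value[rel$group == "N"],
                            rel$value[rel$group == "B"]), 2,
               tolerance = 1e-12)
  null_cfg <- sim_config(cis = 0, trans = 0, sigma_ct = 0,
                         hybrid_trans_mode = "midparent", seed = 80)
  rel0 <- relative_expression(simulate_expression(null_cfg), "B")
  expect_equal(unique(round(rel0$value, 12)), 1)
})

test_that("deep noise-free allele counts recover the planted cis effect", {
  cfg <- sim_config(cis = 2, sigma_logit = 0, depth = 1e6, seed = 81)
  counts <- simulate_allele_counts(cfg)
  fr <- allele_fractions(counts, pseudocount = 0.5)
  expect_equal(mean(fr$fraction), 0.8, tolerance = 1e-2)
  expect_equal(cis_B(fr$fraction), 2, tolerance = 2e-2)
})

test_that("hybrid modes place the hybrid where intended", {
  mat <- sim_config(cis = 1.5, trans = -0.5, sigma_ct = 0,
                    hybrid_trans_mode = "maternal_like", seed = 82)
  rel <- relative_expression(simulate_expression(mat), "B")
  expect_equal(mean(rel$value[rel$group == "NB"]),
               mean(rel$value[rel$group == "N"]), tolerance = 1e-12)
  mid <- sim_config(cis = 1.5, trans = -0.5, sigma_ct = 0,
                    hybrid_trans_mode = "midparent", seed = 83)
  rel2 <- relative_expression(simulate_expression(mid), "B")
  expect_equal(mean(rel2$value[rel2$group == "NB"]),
               midparent_value(rel2$value[rel2$group == "N"],
                               rel2$value[rel2$group == "B"]),
               tolerance = 1e-12)
})

test_that("the planted truth classifies to its own category", {
  cases <- list(c(1.5, -0.5), c(0, 1.5), c(1, 0.5), c(0, 0), c(-1.2, 0.3))
  for (ct in cases) {
    s <- simulate_study(sim_config(cis = ct[1], trans = ct[2], seed = 84))
    expect_identical(
      classify_cis_trans(s$truth$A_true, s$truth$B_true)$category,
      s$truth$category_true)
  }
})

test_that("end-to-end recovery is near-exact without noise and unbiased with
           it", {
  exact <- simulate_study(sim_config(cis = 1.5, trans = -0.5, sigma_ct = 0,
                                     sigma_logit = 0, depth = 1e6,
                                     seed = 85))
  rec <- recover_parameters(exact)
  expect_equal(rec$A_hat, 1, tolerance = 1e-9)
  expect_equal(rec$B_hat, 1.5, tolerance = 1e-2)  # binomial rounding only
  expect_true(rec$category_match)

  ests <- sapply(1:60, function(r) {
    s <- simulate_study(sim_config(cis = 1.5, trans = -0.5, seed = 8000 + r))
    rec <- recover_parameters(s)
    c(rec$A_hat, rec$B_hat)
  })
  expect_lt(abs(mean(ests[1, ]) - 1), 0.1)
  expect_lt(abs(mean(ests[2, ]) - 1.5), 0.1)
})

test_that("a trans-only truth is recovered as trans_only in most runs", {
  calls <- sapply(1:40, function(r) {
    s <- simulate_study(sim_config(cis = 0, trans = 1.5, seed = 9000 + r))
    recover_parameters(s)$category
  })
  expect_gt(mean(calls == "trans_only"), 0.5)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(seq_length = 100), "multiple of 3")
  expect_error(sim_config(hybrid_trans_mode = "custom"), "multiplier")
  expect_error(sim_config(fasting_multipliers = c("4" = 2)), "time 0")
  expect_error(sim_config(fasting_multipliers = c("0" = 1, "4" = -2)),
               "positive")
})
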