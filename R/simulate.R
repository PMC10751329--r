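## Synthetic-study generator: parental ORFs with planted diagnostic SNPs,
## qPCR Ct tables, pyrosequencing-style allele counts and a feeding/fasting
## time course, all derived from known cis (c) and trans (t) ground truth so
## every pipeline stage can be tested end to end.
##
## Expression model (log2 fold relative to the paternal parent B):
##   N parent  : cis + trans
##   B parent  : 0
##   NB hybrid : depends on hybrid_trans_mode (see sim_config)
## Ct model: target Ct = ct_ref_mean + ct_offset - log2(expression) + noise,
## reference Ct = ct_ref_mean + noise, noise ~ Normal(0, sigma_ct) per
## measurement. Allelic model: per individual, maternal fraction
## f = 2^(cis + e) / (1 + 2^(cis + e)), e ~ Normal(0, sigma_logit), and
## maternal_count ~ Binomial(depth, f).

#' Simulation configuration
#'
#' Defines one synthetic study. Defaults mirror the study design the package
#' targets: n = 5 individuals per group, pyrosequencing depth 500, a 324-nt
#' ORF with 2 planted exonic SNPs, qPCR noise of 0.15 cycles per measurement,
#' and a fasting time course over 0-48 h.
#'
#' @param cis Planted cis effect c (log2 units): the true hybrid allelic
#'   log2 ratio B.
#' @param trans Planted trans effect t (log2 units); the true parental
#'   divergence is A = c + t.
#' @param hybrid_trans_mode How total hybrid expression relates to the
#'   parents: `"maternal_like"` (default; tracks the high parent, the
#'   above-midparent regime), `"midparent"` (additive), or `"custom"` (fold
#'   given by `hybrid_multiplier`, relative to the B parent).
#' @param hybrid_multiplier Positive fold for `hybrid_trans_mode = "custom"`.
#' @param n_per_group Individuals per group (default 5).
#' @param depth Pyrosequencing reads per sample (default 500).
#' @param sigma_ct Ct measurement noise sd, cycles (default 0.15).
#' @param sigma_logit Per-individual allelic log2-ratio sd (default 0.15).
#' @param ct_ref_mean Reference-gene Ct (default 18).
#' @param ct_offset Target-gene Ct offset above the reference (default 8).
#' @param seq_length ORF length in nt, a multiple of 3 (default 324).
#' @param n_snps Planted fixed differences (default 2).
#' @param fasting_multipliers Named numeric vector of fasting fold effects
#'   per time (h); the value at 0 h must be 1. Default
#'   `c("0" = 1, "4" = 2, "8" = 2.5, "12" = 3, "24" = 2.5, "48" = 2)`:
#'   fasting-induced upregulation from 4 h with a 12-h peak.
#' @param seed Integer seed; the generator derives a deterministic
#'   sub-stream per table, so regenerating with the same config is
#'   bit-exact.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(cis = 0, trans = 0,
                       hybrid_trans_mode = c("maternal_like", "midparent",
                                             "custom"),
                       hybrid_multiplier = NULL,
                       n_per_group = 5L, depth = 500L,
                       sigma_ct = 0.15, sigma_logit = 0.15,
                       ct_ref_mean = 18, ct_offset = 8,
                       seq_length = 324L, n_snps = 2L,
                       fasting_multipliers = c("0" = 1, "4" = 2, "8" = 2.5,
                                               "12" = 3, "24" = 2.5,
                                               "48" = 2),
                       seed = 1L) {
  hybrid_trans_mode <- match.arg(hybrid_trans_mode)
  stopifnot(
    is.numeric(cis), length(cis) == 1L, is.finite(cis),
    is.numeric(trans), length(trans) == 1L, is.finite(trans),
    n_per_group >= 1L, depth >= 1L,
    sigma_ct >= 0, sigma_logit >= 0,
    seq_length >= 9L, n_snps >= 0L
  )
  if (seq_length %% 3L != 0L) abort("`seq_length` must be a multiple of 3")
  if (n_snps >= seq_length / 3) {
    abort("`n_snps` must be smaller than the number of codons")
  }
  if (hybrid_trans_mode == "custom" &&
      (is.null(hybrid_multiplier) || hybrid_multiplier <= 0)) {
    abort("`hybrid_multiplier` must be a positive fold for custom mode")
  }
  if (is.null(names(fasting_multipliers)) ||
      anyNA(suppressWarnings(as.numeric(names(fasting_multipliers))))) {
    abort("`fasting_multipliers` must be named by time in hours")
  }
  if (!"0" %in% names(fasting_multipliers) ||
      fasting_multipliers[["0"]] != 1) {
    abort("`fasting_multipliers` must include time 0 with multiplier 1")
  }
  if (any(fasting_multipliers <= 0)) {
    abort("`fasting_multipliers` must be positive folds")
  }
  structure(
    list(cis = cis, trans = trans,
         hybrid_trans_mode = hybrid_trans_mode,
         hybrid_multiplier = hybrid_multiplier,
         n_per_group = as.integer(n_per_group), depth = as.integer(depth),
         sigma_ct = sigma_ct, sigma_logit = sigma_logit,
         ct_ref_mean = ct_ref_mean, ct_offset = ct_offset,
         seq_length = as.integer(seq_length), n_snps = as.integer(n_snps),
         fasting_multipliers = fasting_multipliers,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

## True log2 expression (relative to parent B) of the hybrid total.
.hybrid_log2 <- function(config) {
  A_true <- config$cis + config$trans
  switch(config$hybrid_trans_mode,
    maternal_like = max(A_true, 0),
    midparent = log2((2^A_true + 1) / 2),
    custom = log2(config$hybrid_multiplier)
  )
}

.ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"), paste0))

#' Simulate parental coding sequences with planted SNPs
#'
#' Draws a random valid ORF (ATG start, terminal stop, no internal stops)
#' for the maternal parent and plants exactly `n_snps` fixed differences at
#' third-codon positions of internal codons, choosing substitutions that
#' keep the paternal ORF valid.
#'
#' @param config A [sim_config()].
#' @return List with `maternal` and `paternal` sequence strings and `sites`,
#'   the planted-SNP tibble (`position` 1-based, `maternal_allele`,
#'   `paternal_allele`, `label`).
#' @export
simulate_parental_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_cod <- config$seq_length %/% 3L
  if (config$n_snps > n_cod - 2L) {
    abort("too many SNPs for the number of internal codons")
  }
  nonstop <- setdiff(.ALL_CODONS, .STOP_CODONS)
  internal <- sample(nonstop, n_cod - 2L, replace = TRUE)
  codons_m <- c("ATG", internal, sample(.STOP_CODONS, 1L))
  codons_p <- codons_m
  snp_idx <- sort(sample(seq(2L, n_cod - 1L), config$n_snps))
  sites <- purrr::map_dfr(snp_idx, function(i) {
    cod <- codons_m[i]
    cur <- substr(cod, 3L, 3L)
    cand <- setdiff(c("A", "C", "G", "T"), cur)
    ok <- cand[!paste0(substr(cod, 1L, 2L), cand) %in% .STOP_CODONS]
    alt <- ok[sample.int(length(ok), 1L)]
    codons_p[i] <<- paste0(substr(cod, 1L, 2L), alt)
    tibble(position = 3L * i, maternal_allele = cur, paternal_allele = alt,
           label = paste(cur, alt, sep = "/"))
  })
  if (!nrow(sites)) {
    sites <- tibble(position = integer(0), maternal_allele = character(0),
                    paternal_allele = character(0), label = character(0))
  }
  list(
    maternal = paste(codons_m, collapse = ""),
    paternal = paste(codons_p, collapse = ""),
    sites = sites
  )
}

.simulate_ct_rows <- function(ids, group, log2_expr, condition, time_h,
                              config) {
  n <- length(ids)
  target <- config$ct_ref_mean + config$ct_offset - log2_expr +
    rnorm(n, 0, config$sigma_ct)
  ref <- config$ct_ref_mean + rnorm(n, 0, config$sigma_ct)
  tibble(
    sample_id = rep(ids, 2L),
    group = group,
    gene = rep(c("target", "reference"), each = n),
    condition = condition,
    time_h = time_h,
    ct = c(target, ref)
  )
}

#' Simulate a qPCR Ct table for the two parents and the hybrid
#'
#' @param config A [sim_config()].
#' @return Ct tibble (`sample_id`, `group`, `gene`, `condition`, `time_h`,
#'   `ct`) for groups N, B and NB, ready for [relative_expression()].
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  A_true <- config$cis + config$trans
  n <- config$n_per_group
  bind_rows(
    .simulate_ct_rows(paste0("N", seq_len(n)), "N", A_true, "none", 0, config),
    .simulate_ct_rows(paste0("B", seq_len(n)), "B", 0, "none", 0, config),
    .simulate_ct_rows(paste0("NB", seq_len(n)), "NB", .hybrid_log2(config),
                      "none", 0, config)
  )
}

.simulate_count_rows <- function(ids, site_labels, condition, time_h,
                                 config) {
  purrr::map_dfr(site_labels, function(lab) {
    e <- rnorm(length(ids), 0, config$sigma_logit)
    f <- 2^(config$cis + e) / (1 + 2^(config$cis + e))
    m <- rbinom(length(ids), config$depth, f)
    tibble(
      sample_id = ids, site_label = lab,
      maternal_count = m, paternal_count = config$depth - m,
      condition = condition, time_h = time_h
    )
  })
}

#' Simulate pyrosequencing allele counts for the hybrid
#'
#' @param config A [sim_config()].
#' @param site_labels SNP site labels; defaults to `site1`, `site2`, ...
#'   matching `config$n_snps`.
#' @return Allele-count tibble (`sample_id`, `site_label`, `maternal_count`,
#'   `paternal_count`, `condition`, `time_h`).
#' @export
simulate_allele_counts <- function(config, site_labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(site_labels)) {
    site_labels <- sprintf("site%d", seq_len(max(config$n_snps, 1L)))
  }
  .simulate_count_rows(paste0("NB", seq_len(config$n_per_group)),
                       site_labels, "none", 0, config)
}

#' Simulate the feeding/fasting time course
#'
#' Hybrid expression over `{feeding, fasting}` at the configured times:
#' the fasting group's expression is multiplied per time by
#' `fasting_multipliers` while feeding stays flat. Allelic fractions are
#' held at the planted cis effect throughout (ASE independent of feeding
#' state), and allele counts are generated for the fasting group at 0 h and
#' 48 h.
#'
#' @param config A [sim_config()].
#' @param site_labels SNP site labels, as in [simulate_allele_counts()].
#' @return List with `ct` (time-course Ct tibble) and `allele_counts`
#'   (fasting-group counts at 0 h and 48 h).
#' @export
simulate_timecourse <- function(config, site_labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(site_labels)) {
    site_labels <- sprintf("site%d", seq_len(max(config$n_snps, 1L)))
  }
  times <- as.numeric(names(config$fasting_multipliers))
  base <- .hybrid_log2(config)
  n <- config$n_per_group
  ct <- purrr::map_dfr(seq_along(times), function(i) {
    tp <- times[i]
    bind_rows(
      .simulate_ct_rows(sprintf("NB_feeding_%gh_%d", tp, seq_len(n)), "NB",
                        base, "feeding", tp, config),
      .simulate_ct_rows(sprintf("NB_fasting_%gh_%d", tp, seq_len(n)), "NB",
                        base + log2(config$fasting_multipliers[[i]]),
                        "fasting", tp, config)
    )
  })
  ase_times <- intersect(c(0, 48), times)
  counts <- purrr::map_dfr(ase_times, function(tp) {
    .simulate_count_rows(sprintf("NB_fasting_%gh_%d", tp, seq_len(n)),
                         site_labels, "fasting", tp, config)
  })
  list(ct = ct, allele_counts = counts)
}

#' Simulate a complete study from planted ground truth
#'
#' Generates parental sequences, the three-group Ct table, hybrid allele
#' counts and the feeding/fasting time course from one [sim_config()], each
#' from a deterministic sub-stream of `config$seed` (bit-exact
#' reproducibility). The ground truth is carried alongside:
#' `A_true = cis + trans`, `B_true = cis`, and the category that
#' [classify_cis_trans()] assigns to the truth.
#'
#' @param config A [sim_config()].
#' @param epsilon Magnitude threshold used for `category_true`.
#' @return Object of class `hybrid_study`: list with `sequences` (tibble:
#'   `id`, `role`, `sequence`), `snp_truth`, `ct`, `allele_counts`,
#'   `timecourse` (list of `ct`, `allele_counts`), `truth` and `config`.
#' @export
simulate_study <- function(config, epsilon = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- .with_seed(config$seed + 101L, simulate_parental_sequences(config))
  # labels like "T/C" can collide between sites; anchor them by position
  labels <- if (nrow(seqs$sites)) {
    sprintf("%s@%d", seqs$sites$label, seqs$sites$position)
  } else {
    "site1"
  }
  ct <- .with_seed(config$seed + 211L, simulate_expression(config))
  counts <- .with_seed(config$seed + 307L,
                       simulate_allele_counts(config, labels))
  tc <- .with_seed(config$seed + 401L, simulate_timecourse(config, labels))
  A_true <- config$cis + config$trans
  B_true <- config$cis
  structure(
    list(
      sequences = tibble(
        id = c("N", "B"),
        role = c("maternal_parent", "paternal_parent"),
        sequence = c(seqs$maternal, seqs$paternal)
      ),
      snp_truth = seqs$sites,
      ct = ct,
      allele_counts = counts,
      timecourse = tc,
      truth = list(
        A_true = A_true,
        B_true = B_true,
        category_true = classify_cis_trans(A_true, B_true,
                                           epsilon = epsilon)$category
      ),
      config = config
    ),
    class = "hybrid_study"
  )
}

#' @export
print.hybrid_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic hybrid study: c = %g, t = %g (%s), n = %d, depth = %d\n",
    x$config$cis, x$config$trans, x$config$hybrid_trans_mode,
    x$config$n_per_group, x$config$depth))
  cat(sprintf("  truth: A = %g, B = %g, category = %s\n",
              x$truth$A_true, x$truth$B_true, x$truth$category_true))
  cat(sprintf("  %d planted SNP(s); %d Ct rows; %d allele-count rows\n",
              nrow(x$snp_truth), nrow(x$ct), nrow(x$allele_counts)))
  invisible(x)
}

#' Run the full pipeline on a simulated study and compare to truth
#'
#' Expression -> ASE -> cis/trans on a [simulate_study()] dataset: estimates
#' A from the parental groups, B from the hybrid allelic fractions
#' (Haldane-Anscombe pseudocount 0.5), tests nonadditivity against the
#' midparent value and allelic balance per site, classifies the regulatory
#' mode, and reports the estimation errors against the planted truth.
#'
#' @param study A `hybrid_study`.
#' @param config An [analysis_config()].
#' @return Object of class `parameter_recovery`: estimates (`A_hat`,
#'   `B_hat`), truth, absolute errors, the category call and whether it
#'   matches, plus the underlying `additivity_test`, per-site `ase` tibble,
#'   overall `ase_overall` and the `cis_trans` classification.
#' @export
recover_parameters <- function(study, config = analysis_config()) {
  stopifnot(inherits(study, "hybrid_study"),
            inherits(config, "analysis_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", what, conditionMessage(e)))
    })
  }
  rel <- stage("expression", relative_expression(
    study$ct, calibrator = config$calibrator_group))
  vN <- rel$value[rel$group == "N"]
  vB <- rel$value[rel$group == "B"]
  vNB <- rel$value[rel$group == "NB"]
  A_hat <- stage("cistrans", divergence_A(vN, vB))
  # two-sample t on log2 expression; undefined (NULL) for noise-free data
  p_A <- tryCatch(t.test(log2(vN), log2(vB), var.equal = TRUE)$p.value,
                  error = function(e) NULL)
  mpv <- midparent_value(vN, vB)
  add <- if (length(vNB) >= 2L && sd(vNB) > 0) {
    stage("expression", test_additivity(vNB, mpv, alpha = config$alpha))
  } else {
    # degenerate (noise-free) data: no test, report the raw departure
    structure(list(mpv = mpv, nb_mean = mean(vNB), n = length(vNB),
                   t_statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_, alpha = config$alpha,
                   category = "degenerate",
                   direction = if (mean(vNB) > mpv) "above_mpv"
                               else if (mean(vNB) < mpv) "below_mpv"
                               else "none"),
              class = "additivity_test")
  }
  fr <- stage("ase", allele_fractions(study$allele_counts, pseudocount = 0.5))
  per_site <- fr |>
    group_by(.data$site_label) |>
    summarise(
      n = n(),
      mean_fraction = mean(.data$fraction),
      B_hat = cis_B(.data$fraction),
      p_value = ase_test_t(.data$fraction, alpha = config$alpha)$p_value,
      .groups = "drop"
    ) |>
    mutate(
      biased = .data$p_value < config$alpha,
      bias_direction = case_when(
        !.data$biased ~ "none",
        .data$mean_fraction > 0.5 ~ "maternal",
        TRUE ~ "paternal"
      )
    )
  ase_overall <- stage("ase", ase_test_t(fr$fraction, alpha = config$alpha))
  B_hat <- mean(per_site$B_hat)
  cls <- stage("cistrans", classify_cis_trans(
    A_hat, B_hat, epsilon = config$epsilon,
    p_A = p_A, p_B = ase_overall$p_value, alpha = config$alpha))
  structure(
    list(
      A_hat = A_hat, B_hat = B_hat,
      A_true = study$truth$A_true, B_true = study$truth$B_true,
      error_A = abs(A_hat - study$truth$A_true),
      error_B = abs(B_hat - study$truth$B_true),
      category = cls$category,
      category_true = study$truth$category_true,
      category_match = identical(cls$category, study$truth$category_true),
      additivity = add,
      ase = per_site,
      ase_overall = ase_overall,
      classification = cls,
      expression = rel
    ),
    class = "parameter_recovery"
  )
}

#' @export
print.parameter_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: A = %.3f (true %.3f), B = %.3f (true %.3f)\n",
              x$A_hat, x$A_true, x$B_hat, x$B_true))
  cat(sprintf("  category: %s (true %s) -> %s\n",
              x$category, x$category_true,
              if (x$category_match) "match" else "MISMATCH"))
  cat(sprintf("  nonadditivity: %s %s (p = %.4g)\n",
              x$additivity$category, x$additivity$direction,
              x$additivity$p_value))
  invisible(x)
}
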