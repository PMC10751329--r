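## ggplot2 visualisations of the main result types.

#' Plot group expression with compact letters
#'
#' Bar chart of group mean relative expression with sd error bars and the
#' Tukey compact letter display; optionally a dashed midparent-value line.
#'
#' @param object A `group_anova`.
#' @param mpv Optional midparent value drawn as a dashed horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_anova <- function(object, mpv = NULL, ...) {
  g <- object$groups
  p <- ggplot(g, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey70", colour = "black", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.15) +
    geom_text(aes(y = .data$mean + .data$sd, label = .data$letter),
              vjust = -0.6) +
    labs(x = NULL, y = "relative expression (fold)") +
    theme_bw()
  if (!is.null(mpv)) {
    p <- p + geom_hline(yintercept = mpv, linetype = "dashed")
  }
  p
}

#' Plot a feeding/fasting time course
#'
#' Mean relative expression per condition over time with significance
#' asterisks at time points where the two conditions differ.
#'
#' @param object A `timecourse_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timecourse_comparison <- function(object, ...) {
  pt <- object$per_time
  conds <- object$conditions
  long <- tidyr::pivot_longer(
    pt[, c("time_h", paste0("mean_", conds))],
    cols = dplyr::starts_with("mean_"),
    names_to = "condition", names_prefix = "mean_", values_to = "mean")
  stars <- pt[pt$significant, c("time_h"), drop = FALSE]
  stars$y <- apply(pt[pt$significant, paste0("mean_", conds), drop = FALSE],
                   1L, max) * 1.05
  ggplot(long, aes(x = .data$time_h, y = .data$mean,
                   colour = .data$condition)) +
    geom_line() +
    geom_point() +
    geom_text(data = stars, aes(x = .data$time_h, y = .data$y, label = "*"),
              inherit.aes = FALSE, size = 6) +
    labs(x = "time (h)", y = "relative expression (fold)",
         colour = NULL) +
    theme_bw()
}

#' Plot a cis/trans classification in the (B, A) plane
#'
#' The point (B, A) with the pure-cis diagonal (A = B, trans = 0) and the
#' pure-trans vertical (B = 0); the shaded band marks the `epsilon`
#' magnitude threshold around both.
#'
#' @param object A `cis_trans`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cis_trans <- function(object, ...) {
  lim <- max(1, abs(object$A), abs(object$B)) * 1.3
  ggplot(tibble(B = object$B, A = object$A),
         aes(x = .data$B, y = .data$A)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    geom_hline(yintercept = 0, linetype = "dotted", colour = "grey40") +
    geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    labs(x = "B = log2 hybrid allelic ratio (cis)",
         y = "A = log2 parental ratio (cis + trans)",
         title = object$category,
         subtitle = sprintf("A - B (trans) = %.2f", object$trans)) +
    theme_bw()
}

#' Plot per-sample maternal allelic fractions
#'
#' Jittered per-sample maternal fractions by SNP site against the balanced
#' 0.5 line.
#'
#' @param counts Allele-count table (see [allele_fractions()]) with
#'   `site_label`.
#' @param pseudocount Passed to [allele_fractions()].
#' @return A ggplot.
#' @export
plot_allelic_fractions <- function(counts, pseudocount = 0) {
  fr <- allele_fractions(counts, pseudocount = pseudocount)
  fr <- .check_df_cols(fr, "site_label", "counts")
  ggplot(fr, aes(x = .data$site_label, y = .data$fraction)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "SNP site", y = "maternal allelic fraction") +
    theme_bw()
}
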