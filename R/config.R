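#' Analysis configuration
#'
#' Bundles the tuning parameters shared across the pipeline: the significance
#' level for every test, the log2 magnitude threshold below which a cis or
#' trans component is treated as absent, the calibrator group for the 2^-ddCt
#' normalisation, and a seed for any randomised step.
#'
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param epsilon Log2 magnitude threshold (>= 0) for cis/trans calls;
#'   default 0.25 (an ~19% expression difference).
#' @param calibrator_group Group whose mean dCt anchors ddCt; default "B",
#'   the low-expressing parent, so reported folds are >= ~1.
#' @param seed Integer seed.
#' @return Object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(alpha = 0.05, epsilon = 0.25,
                            calibrator_group = "B", seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1)")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    abort("`epsilon` must be a single number >= 0")
  }
  if (!is.character(calibrator_group) || length(calibrator_group) != 1L) {
    abort("`calibrator_group` must be a single group name")
  }
  structure(
    list(alpha = alpha, epsilon = epsilon,
         calibrator_group = calibrator_group, seed = as.integer(seed)),
    class = "analysis_config"
  )
}
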