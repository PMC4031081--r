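#' Analysis configuration
#'
#' Bundles the tuning parameters shared by the association and network
#' modules. The defaults encode the study design the package targets:
#' 10-minute sampling, a four-hour window for lagged relations
#' (`max_lag_tau = 24` lags of one sampling interval, tau = 10 min), a 5%
#' FDR for the static network and treatment tests, and a stricter 1% FDR
#' for the dynamic network whose optimum search is an explicit
#' optimization.
#'
#' @param max_lag_tau largest lag considered, in sampling intervals.
#' @param alpha_static FDR level for the static network.
#' @param alpha_dynamic FDR level for the dynamic network.
#' @param alpha_treatment FDR level for the treatment-effect test.
#' @param tendency_band open q-value interval reported as a "tendency"
#'   to a treatment effect (not significant, but noteworthy).
#' @param fisher_transform apply the variance-stabilizing Fisher z
#'   transform to correlations before cohort averaging and t-tests.
#' @param robustness_threshold minimal fraction of leave-two-out
#'   resamples whose optimum lag agrees (within +/- 1 tau) with the modal
#'   lag for an edge to be called robust.
#' @param min_defined_subjects minimal number of subjects with a defined
#'   correlation at a lag for the cohort mean to be defined there.
#' @param directionality_alpha p-value threshold below which an edge with
#'   nonzero lag is drawn directed.
#' @param directionality_method `"lag_contrast"` (default) tests, pairwise
#'   across subjects, the absolute association at the optimal lag against
#'   the absolute association at lag 0; `"subject_lags"` instead tests the
#'   per-subject optimum lags against zero.
#' @param optimum_correction `"sidak"` (default) corrects each candidate's
#'   one-sided p-value for the optimum search over the lag window
#'   (`p = 1 - (1 - p)^J`, `J` = number of lags searched) before the FDR
#'   step, so the dynamic network stays calibrated under the null;
#'   `"none"` tests the selected optimum directly and relies on the
#'   stricter `alpha_dynamic` alone to compensate for the search.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(max_lag_tau = 24L,
                            alpha_static = 0.05,
                            alpha_dynamic = 0.01,
                            alpha_treatment = 0.05,
                            tendency_band = c(0.05, 0.10),
                            fisher_transform = TRUE,
                            robustness_threshold = 0.8,
                            min_defined_subjects = 3L,
                            directionality_alpha = 0.05,
                            directionality_method = c("lag_contrast",
                                                      "subject_lags"),
                            optimum_correction = c("sidak", "none")) {
  directionality_method <- match.arg(directionality_method)
  optimum_correction <- match.arg(optimum_correction)
  stopifnot(max_lag_tau >= 1)
  for (a in c(alpha_static, alpha_dynamic, alpha_treatment))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("alpha levels must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(length(tendency_band) == 2L, tendency_band[1] < tendency_band[2],
            robustness_threshold > 0, robustness_threshold <= 1)
  structure(list(max_lag_tau = as.integer(max_lag_tau),
                 alpha_static = alpha_static,
                 alpha_dynamic = alpha_dynamic,
                 alpha_treatment = alpha_treatment,
                 tendency_band = tendency_band,
                 fisher_transform = isTRUE(fisher_transform),
                 robustness_threshold = robustness_threshold,
                 min_defined_subjects = as.integer(min_defined_subjects),
                 directionality_alpha = directionality_alpha,
                 directionality_method = directionality_method,
                 optimum_correction = optimum_correction),
            class = "analysis_config")
}

as_analysis_config <- function(config) {
  if (inherits(config, "analysis_config")) return(config)
  if (is.null(config)) return(analysis_config())
  do.call(analysis_config, config)
}
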