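#' Deconvolve every series of a concentration cohort
#'
#' Applies [deconvolve()] to each (subject, hormone, occasion) series of
#' a long concentration table. Half-lives may be fixed per hormone; any
#' hormone without one is estimated from its own profiles.
#'
#' @param conc long concentration table (`subject_id, hormone, occasion,
#'   time_min, value`).
#' @param half_lives named numeric vector of half-lives in minutes, by
#'   hormone; hormones absent from it get `half_life = "estimate"`.
#' @param settings a [deconvolution_settings()].
#' @param delta grid spacing in minutes.
#' @return A list with `secretions` (long table of secretion masses per
#'   bin) and `diagnostics` (one list per series).
#' @export
deconvolve_cohort <- function(conc, half_lives = NULL,
                              settings = deconvolution_settings(),
                              delta = 10) {
  check_cohort_columns(conc)
  key <- interaction(conc$subject_id, conc$hormone, conc$occasion,
                     drop = TRUE)
  out <- vector("list", 0L)
  diagnostics <- vector("list", 0L)
  for (g in split(conc, key)) {
    g <- g[order(g$time_min), , drop = FALSE]
    h <- g$hormone[1]
    st <- settings
    if (!is.null(half_lives) && h %in% names(half_lives))
      st$half_life <- unname(half_lives[[h]])
    cseries <- concentration_series(g$value, delta = delta,
                                    times = g$time_min,
                                    subject_id = g$subject_id[1],
                                    hormone = h, occasion = g$occasion[1])
    s <- deconvolve(cseries, st)
    out[[length(out) + 1L]] <- series_to_rows(s)
    diagnostics[[length(diagnostics) + 1L]] <-
      c(list(subject_id = s$subject_id, hormone = s$hormone,
             occasion = s$occasion, half_life = s$elim$half_life),
        s$diagnostics)
  }
  list(secretions = do.call(rbind, out), diagnostics = diagnostics)
}

#' Serialize simulator ground truth as JSON
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param path output JSON file.
#' @export
write_truth <- function(truth, path) {
  couplings <- lapply(truth$couplings, function(cps)
    lapply(cps, function(cp) unclass(cp)))
  jsonlite::write_json(
    list(couplings = couplings,
         hormones = truth$network$hormones,
         pulse_rate = as.list(truth$network$pulse_rate),
         mass_mean = as.list(truth$network$mass_mean),
         mass_cv = as.list(truth$network$mass_cv),
         half_life = as.list(truth$network$half_life),
         noise_cv = truth$noise_cv, seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
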