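#' Infer the static (instantaneous) association network
#'
#' Links hormones whose secretion patterns co-vary without a time lag.
#' For every unordered pair the lag-0 association is computed per subject
#' - either the plain Pearson correlation or the partial correlation
#' given all remaining hormones - Fisher-transformed (configurable), and
#' tested across the cohort with a two-sided one-sample t-test. The
#' family of all pairs in one run is corrected with Benjamini-Hochberg
#' FDR at `alpha_static`; correlation and partial networks form separate
#' FDR families. No optimum search takes place here, hence the two-sided
#' test and the milder FDR level than the dynamic network's.
#'
#' @param secretion long cohort table of secretion values with columns
#'   `subject_id, hormone, occasion, time_min, value`, one occasion (or
#'   use `occasion` to select one).
#' @param config an [analysis_config()].
#' @param method `"correlation"` or `"partial"`.
#' @param occasion occasion label to restrict to, if the table has more
#'   than one.
#' @return An object of class `static_network`: a list with `table` (all
#'   pairs: `hormone_a, hormone_b, method, mean_assoc, t_stat, p, q,
#'   significant`), `edges` (significant subset), `method`, `occasion`
#'   and `config`.
#' @export
infer_static_network <- function(secretion, config = analysis_config(),
                                 method = c("correlation", "partial"),
                                 occasion = NULL) {
  method <- match.arg(method)
  config <- as_analysis_config(config)
  cs <- cohort_series_list(secretion, occasion)
  m <- length(cs$hormones)
  if (m < 2L) stop("need at least two hormones", call. = FALSE)
  if (length(cs$subjects) < 3L) stop("need at least three subjects",
                                     call. = FALSE)
  # per-subject association matrices (hormone x hormone)
  assoc <- lapply(cs$series, function(mat) {
    keep <- !apply(is.na(mat), 1L, any) &
      apply(mat, 1L, function(v) var(v) > 0)
    out <- matrix(NA_real_, m, m, dimnames = list(cs$hormones, cs$hormones))
    if (sum(keep) >= 2L) {
      x <- t(mat[keep, , drop = FALSE])
      out[keep, keep] <- if (method == "partial")
        partial_correlation_matrix(x) else cor(x)
    }
    out
  })
  pairs <- utils::combn(cs$hormones, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    r <- vapply(assoc, function(am) am[a, b], numeric(1))
    dropped <- sum(is.na(r))
    if (dropped > 0L)
      warning(sprintf("pair %s-%s: %d subject(s) dropped (missing data)",
                      a, b, dropped), call. = FALSE)
    vals <- if (config$fisher_transform) fisher_z_quiet(r) else r
    tt <- cohort_t_test(vals, sided = "two")
    mean_assoc <- if (config$fisher_transform)
      inverse_fisher_z(tt$mean) else tt$mean
    data.frame(hormone_a = a, hormone_b = b, method = method,
               mean_assoc = mean_assoc, t_stat = tt$statistic,
               p = tt$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  fdr <- bh_fdr(tab$p, config$alpha_static)
  tab$q <- fdr$q_values
  tab$significant <- fdr$reject
  structure(list(table = tab, edges = tab[tab$significant, , drop = FALSE],
                 method = method, occasion = cs$occasion, config = config,
                 n_subjects = length(cs$subjects)),
            class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  cat(sprintf("<static %s network> %d hormone pairs tested, %d significant (FDR %.2g), occasion \"%s\", n = %d subjects\n",
              x$method, nrow(x$table), nrow(x$edges),
              x$config$alpha_static, x$occasion, x$n_subjects))
  if (nrow(x$edges) > 0L)
    print(x$edges[, c("hormone_a", "hormone_b", "mean_assoc", "q")],
          row.names = FALSE)
  invisible(x)
}
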