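#' Cohort-average cross-correlation function
#'
#' Averages per-subject cross-correlation functions into a cohort CCF.
#' By default the per-lag mean is taken on the Fisher z scale and
#' back-transformed to the correlation scale (raw averaging is available
#' via the config). Lags at which fewer than `min_defined_subjects`
#' subjects have a defined value are undefined in the result.
#'
#' @param ccf_matrix numeric matrix of per-subject correlations, rows =
#'   subjects, columns = lags; column names give the lags (as produced
#'   internally from [cross_correlation()] values).
#' @param config an [analysis_config()].
#' @return A `ccf_fn` list with `lags` and `values`.
#' @export
mean_ccf <- function(ccf_matrix, config = analysis_config()) {
  config <- as_analysis_config(config)
  lags <- as.integer(colnames(ccf_matrix))
  vals <- apply(ccf_matrix, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < config$min_defined_subjects) return(NA_real_)
    if (config$fisher_transform) inverse_fisher_z(mean(fisher_z_quiet(col)))
    else mean(col)
  })
  structure(list(lags = lags, values = unname(vals), tau_minutes = 10),
            class = "ccf_fn")
}

#' Locate the dual optima of a cross-correlation function
#'
#' The extremes of the CCF within the lag window define candidate
#' relations: the positive optimum is the largest value (reported only if
#' it is positive), the negative optimum the smallest (reported only if
#' negative). Exact ties are broken toward the smaller absolute lag,
#' then toward the positive lag.
#'
#' @param ccf a `ccf_fn` (from [cross_correlation()] or [mean_ccf()]).
#' @param config an [analysis_config()]; `max_lag_tau` bounds the window.
#' @return A list of class `optimum_pair` with components `positive` and
#'   `negative`, each either `NULL` or `list(lag, value)`.
#' @export
find_optima <- function(ccf, config = analysis_config()) {
  config <- as_analysis_config(config)
  keep <- abs(ccf$lags) <= config$max_lag_tau & !is.na(ccf$values)
  lags <- ccf$lags[keep]
  vals <- ccf$values[keep]
  if (length(vals) == 0L)
    return(structure(list(positive = NULL, negative = NULL),
                     class = "optimum_pair"))
  pick <- function(v) {
    # among the tied extreme values prefer small |lag|, then positive lag
    i <- which(v == max(v))
    i <- i[order(abs(lags[i]), -sign(lags[i]))][1L]
    list(lag = lags[i], value = v[i])
  }
  pos <- pick(vals)
  neg <- pick(-vals)
  neg$value <- -neg$value
  structure(list(positive = if (pos$value > 0) pos else NULL,
                 negative = if (neg$value < 0) neg else NULL),
            class = "optimum_pair")
}

#' Leave-two-out robustness of an optimum
#'
#' Recomputes the cohort CCF and its sign-matched optimum for every
#' subset that leaves two subjects out (all `choose(n, 2)` of them) and
#' summarizes the distribution of optimum lags. The optimum is robust
#' when at least `robustness_threshold` of the resamples land within one
#' sampling interval of the modal lag.
#'
#' @param ccf_matrix per-subject CCF matrix (rows = subjects, columns
#'   named by lag).
#' @param sign `"+"` or `"-"`: which optimum to follow.
#' @param config an [analysis_config()].
#' @return A list of class `robustness_summary`: `resample_lags`,
#'   `modal_lag`, `modal_fraction`, `robust`, `n_resamples`.
#' @export
leave_two_out_robustness <- function(ccf_matrix, sign = "+",
                                     config = analysis_config()) {
  config <- as_analysis_config(config)
  n <- nrow(ccf_matrix)
  if (n < 5L) stop("leave-two-out robustness needs at least 5 subjects",
                   call. = FALSE)
  lags <- as.integer(colnames(ccf_matrix))
  Z <- if (config$fisher_transform) fisher_z_quiet(ccf_matrix) else ccf_matrix
  def <- !is.na(Z)
  Z0 <- ifelse(def, Z, 0)
  tot <- colSums(Z0)
  cnt <- colSums(def)
  combs <- utils::combn(n, 2L)
  res_lags <- vapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1L, ci]
    j <- combs[2L, ci]
    m_cnt <- cnt - def[i, ] - def[j, ]
    m_sum <- tot - Z0[i, ] - Z0[j, ]
    vals <- ifelse(m_cnt >= config$min_defined_subjects, m_sum / m_cnt, NA)
    if (config$fisher_transform) vals <- inverse_fisher_z(vals)
    opt <- find_optima(structure(list(lags = lags, values = vals,
                                      tau_minutes = 10), class = "ccf_fn"),
                       config)
    o <- if (sign == "+") opt$positive else opt$negative
    if (is.null(o)) NA_integer_ else as.integer(o$lag)
  }, integer(1))
  defined <- res_lags[!is.na(res_lags)]
  if (length(defined) == 0L) {
    modal <- NA_integer_
    frac <- 0
  } else {
    tab <- table(defined)
    cand <- as.integer(names(tab)[tab == max(tab)])
    modal <- cand[order(abs(cand), -base::sign(cand))][1L]
    frac <- mean(!is.na(res_lags) & abs(res_lags - modal) <= 1L)
  }
  structure(list(resample_lags = res_lags, modal_lag = modal,
                 modal_fraction = frac,
                 robust = is.finite(frac) && frac >= config$robustness_threshold,
                 n_resamples = ncol(combs)),
            class = "robustness_summary")
}

#' Test a relation at its cross-correlation optimum
#'
#' One-sample cohort t-test of the per-subject associations at the
#' cohort-optimal lag against zero. The test is one-sided because the
#' optimum's sign is fixed by construction (a positive optimum can only
#' support a positive relation, and vice versa).
#'
#' @param values per-subject correlations at the optimum lag.
#' @param direction `"+"` or `"-"`, the optimum's sign.
#' @param config an [analysis_config()].
#' @return A p-value (with the underlying test as attributes `t_stat`
#'   and `df`).
#' @export
test_relation <- function(values, direction = "+",
                          config = analysis_config()) {
  config <- as_analysis_config(config)
  vals <- if (config$fisher_transform) fisher_z_quiet(values) else values
  tt <- cohort_t_test(vals, sided = "one", direction = direction)
  structure(tt$p_value, t_stat = tt$statistic, df = tt$df)
}

#' Test directionality of a lagged relation
#'
#' A relation is drawn as directed when its optimal lag is credibly
#' different from zero. The default operationalization contrasts, within
#' each subject, the absolute association at the optimal lag with the
#' absolute association at lag 0 (one-sided paired t-test in the
#' direction `|r(k*)| > |r(0)|`); an alternative tests the per-subject
#' optimum lags against zero. Lag-0 relations have no direction by
#' definition and return `NA`.
#'
#' @param ccf_matrix per-subject CCF matrix for the pair (columns named
#'   by lag, oriented so that the optimum sits at `k_star`).
#' @param k_star the cohort-optimal lag (signed, in the matrix's
#'   orientation).
#' @param sign the optimum's sign, `"+"` or `"-"` (used by the
#'   `subject_lags` method).
#' @param config an [analysis_config()].
#' @return A p-value, or `NA` when `k_star == 0`.
#' @export
test_directionality <- function(ccf_matrix, k_star, sign = "+",
                                config = analysis_config()) {
  config <- as_analysis_config(config)
  if (k_star == 0L) return(NA_real_)
  lags <- as.integer(colnames(ccf_matrix))
  if (config$directionality_method == "lag_contrast") {
    r_k <- ccf_matrix[, match(k_star, lags)]
    r_0 <- ccf_matrix[, match(0L, lags)]
    keep <- !is.na(r_k) & !is.na(r_0)
    d <- abs(fisher_z_quiet(r_k[keep])) - abs(fisher_z_quiet(r_0[keep]))
    cohort_t_test(d, sided = "one", direction = "+")$p_value
  } else {
    subj_lags <- apply(ccf_matrix, 1L, function(v) {
      opt <- find_optima(structure(list(lags = lags, values = v,
                                        tau_minutes = 10),
                                   class = "ccf_fn"), config)
      o <- if (sign == "+") opt$positive else opt$negative
      if (is.null(o)) NA_real_ else o$lag
    })
    dir <- if (k_star > 0) "+" else "-"
    cohort_t_test(subj_lags, sided = "one", direction = dir)$p_value
  }
}

#' Re-express a candidate relation with a non-negative lag
#'
#' An optimum of the ordered pair `(a, b)` at a negative lag is the same
#' relation as `(b, a)` at the corresponding positive lag; reported
#' relations always carry `lag_tau >= 0`. Applying the mapping twice
#' returns the original triple.
#'
#' @param source,target hormone names.
#' @param lag signed lag in sampling intervals.
#' @return `list(source, target, lag_tau)` with `lag_tau >= 0`.
#' @export
orient_candidate <- function(source, target, lag) {
  if (lag < 0) list(source = target, target = source,
                    lag_tau = as.integer(-lag))
  else list(source = source, target = target, lag_tau = as.integer(lag))
}

#' Infer the dynamic (lagged) hormone network
#'
#' For every hormone pair the per-subject cross-correlation functions
#' over lags `-L .. L` are averaged into a cohort CCF whose dual optima
#' (most positive and most negative value) define candidate relations
#' with their delays. Candidates are re-expressed with non-negative lags
#' (an optimum of `(a, b)` at a negative lag becomes `(b, a)` at the
#' positive lag; lag-0 candidates are listed under both orders but
#' tested once). Each candidate is tested with a one-sided cohort t-test
#' at its optimum; because the optimum is the best of the searched lags,
#' the p-value is by default Sidak-corrected for the size of the search
#' window (see [analysis_config()]) before the whole candidate family is
#' FDR-corrected at `alpha_dynamic` - itself deliberately stricter than
#' the static network's level. Surviving
#' relations are then validated for robustness (leave-two-out
#' resampling, [leave_two_out_robustness()]) and, when lagged, for
#' directionality ([test_directionality()]).
#'
#' @param secretion long cohort table of secretion values (one occasion,
#'   or select one with `occasion`).
#' @param config an [analysis_config()].
#' @param occasion occasion label to restrict to.
#' @return An object of class `dynamic_network` with `table` (all
#'   candidates, one row per presentation order), `edges` (FDR-significant
#'   rows with robustness and directionality attached), `config`,
#'   `occasion`, and the per-pair subject CCF matrices in `ccfs`.
#' @seealso [network_edges()] for the validated relation list,
#'   [test_treatment_effect()] for before/after comparison.
#' @export
infer_dynamic_network <- function(secretion, config = analysis_config(),
                                  occasion = NULL) {
  config <- as_analysis_config(config)
  cs <- cohort_series_list(secretion, occasion)
  if (length(cs$subjects) < 3L) stop("need at least three subjects",
                                     call. = FALSE)
  L <- config$max_lag_tau
  pairs <- utils::combn(cs$hormones, 2L)
  ccfs <- list()
  cands <- list()
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    M <- subject_ccf_matrix(cs, a, b, L)
    key <- paste(a, b, sep = "|")
    ccfs[[key]] <- M
    cohort <- mean_ccf(M, config)
    opt <- find_optima(cohort, config)
    # lags actually searched for the optima (defined, within window)
    J <- sum(abs(cohort$lags) <= L & !is.na(cohort$values))
    for (sgn in c("+", "-")) {
      o <- if (sgn == "+") opt$positive else opt$negative
      if (is.null(o)) next
      oc <- orient_candidate(a, b, o$lag)
      r_subj <- M[, match(o$lag, cohort$lags)]
      p <- test_relation(r_subj, direction = sgn, config)
      # the candidate's p-value refers to the best of J searched lags;
      # a Sidak correction restores null calibration before the FDR step
      p_rel <- if (config$optimum_correction == "sidak")
        1 - (1 - as.numeric(p))^J else as.numeric(p)
      cands[[length(cands) + 1L]] <- list(
        pair_key = key, a = a, b = b, orig_lag = as.integer(o$lag),
        source = oc$source, target = oc$target, lag_tau = oc$lag_tau,
        sign = sgn, mean_assoc = o$value, t_stat = attr(p, "t_stat"),
        p_optimum = as.numeric(p), p_relation = p_rel)
    }
  }
  n_cand <- length(cands)
  if (n_cand == 0L) {
    empty <- empty_edge_table()
    return(structure(list(table = empty, edges = empty, config = config,
                          occasion = cs$occasion, hormones = cs$hormones,
                          subjects = cs$subjects, ccfs = ccfs),
                     class = "dynamic_network"))
  }
  p_all <- vapply(cands, `[[`, numeric(1), "p_relation")
  fdr <- bh_fdr(p_all, config$alpha_dynamic)
  rows <- vector("list", 0L)
  for (k in seq_len(n_cand)) {
    cd <- cands[[k]]
    cd$q_relation <- fdr$q_values[k]
    cd$significant <- fdr$reject[k]
    cd$robust <- NA
    cd$modal_lag <- NA_integer_
    cd$modal_fraction <- NA_real_
    cd$p_directionality <- NA_real_
    cd$directed <- NA
    if (cd$significant) {
      M <- ccfs[[cd$pair_key]]
      rb <- leave_two_out_robustness(M, sign = cd$sign, config)
      cd$robust <- rb$robust
      # report the modal lag in the candidate's own orientation
      cd$modal_lag <- if (is.na(rb$modal_lag)) NA_integer_
        else if (cd$orig_lag < 0) -rb$modal_lag else rb$modal_lag
      cd$modal_fraction <- rb$modal_fraction
      cd$p_directionality <- test_directionality(M, cd$orig_lag,
                                                 sign = cd$sign, config)
      cd$directed <- if (cd$lag_tau == 0L) FALSE
        else !is.na(cd$p_directionality) &&
          cd$p_directionality <= config$directionality_alpha
    }
    cd$test_id <- k
    rows[[length(rows) + 1L]] <- candidate_row(cd, cd$source, cd$target)
    if (cd$lag_tau == 0L)  # presentation-only duplicate, same test
      rows[[length(rows) + 1L]] <- candidate_row(cd, cd$target, cd$source)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, edges = tab[tab$significant, , drop = FALSE],
                 config = config, occasion = cs$occasion,
                 hormones = cs$hormones, subjects = cs$subjects,
                 ccfs = ccfs),
            class = "dynamic_network")
}

candidate_row <- function(cd, source, target) {
  data.frame(source = source, target = target, lag_tau = cd$lag_tau,
             sign = cd$sign, mean_assoc = cd$mean_assoc,
             t_stat = cd$t_stat, p_optimum = cd$p_optimum,
             p_relation = cd$p_relation,
             q_relation = cd$q_relation, significant = cd$significant,
             robust = cd$robust, modal_lag = cd$modal_lag,
             modal_fraction = cd$modal_fraction,
             p_directionality = cd$p_directionality,
             directed = cd$directed, q_treatment = NA_real_,
             treatment_flag = NA_character_, test_id = cd$test_id,
             stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(source = character(0), target = character(0),
             lag_tau = integer(0), sign = character(0),
             mean_assoc = numeric(0), t_stat = numeric(0),
             p_optimum = numeric(0), p_relation = numeric(0),
             q_relation = numeric(0),
             significant = logical(0), robust = logical(0),
             modal_lag = integer(0), modal_fraction = numeric(0),
             p_directionality = numeric(0), directed = logical(0),
             q_treatment = numeric(0), treatment_flag = character(0),
             test_id = integer(0), stringsAsFactors = FALSE)
}

subject_ccf_matrix <- function(cs, a, b, L) {
  lags <- seq.int(-L, L)
  M <- t(vapply(cs$series, function(mat) {
    x <- mat[a, ]
    y <- mat[b, ]
    if (anyNA(x) || anyNA(y)) return(rep(NA_real_, length(lags)))
    vapply(lags, function(k) ccf_at_lag(x, y, k), numeric(1))
  }, numeric(length(lags))))
  colnames(M) <- lags
  rownames(M) <- cs$subjects
  M
}

#' Validated edges of a dynamic network
#'
#' The relations that enter the reported network: FDR-significant at
#' their optimum and, by default, robust under leave-two-out resampling.
#' Directionality only decides whether an edge is drawn with an arrow,
#' not whether it is included.
#'
#' @param net a `dynamic_network`.
#' @param require_robust drop edges that failed the robustness check.
#' @param collapse_lag0 keep only one presentation order for lag-0
#'   relations.
#' @return The edge table subset.
#' @export
network_edges <- function(net, require_robust = TRUE,
                          collapse_lag0 = FALSE) {
  ed <- net$edges
  if (require_robust) ed <- ed[!is.na(ed$robust) & ed$robust, , drop = FALSE]
  if (collapse_lag0) ed <- ed[!duplicated(ed$test_id), , drop = FALSE]
  ed
}

#' @export
print.dynamic_network <- function(x, ...) {
  n_tests <- length(unique(x$table$test_id))
  cat(sprintf("<dynamic network> occasion \"%s\": %d candidate optima, %d significant (FDR %.2g), %d robust\n",
              x$occasion, n_tests,
              length(unique(x$edges$test_id)),
              x$config$alpha_dynamic,
              length(unique(network_edges(x)$test_id))))
  ed <- network_edges(x, require_robust = FALSE)
  if (nrow(ed) > 0L)
    print(ed[, c("source", "target", "lag_tau", "sign", "mean_assoc",
                 "q_relation", "p_directionality", "robust", "directed")],
          row.names = FALSE, digits = 4)
  invisible(x)
}

#' Assign treatment-effect flags from q-values
#'
#' @param q numeric vector of FDR-adjusted q-values.
#' @param config an [analysis_config()].
#' @return Character vector: `"significant"` (`q <= alpha_treatment`),
#'   `"tendency"` (q inside the open tendency band), else `"none"`.
#' @export
treatment_flags <- function(q, config = analysis_config()) {
  config <- as_analysis_config(config)
  band <- config$tendency_band
  ifelse(is.na(q), NA_character_,
         ifelse(q <= config$alpha_treatment, "significant",
                ifelse(q > band[1] & q < band[2], "tendency", "none")))
}

#' Test for a treatment effect on reference relations
#'
#' Compares the intensity of each reference relation between two
#' occasions at its pre-selected reference delay (the optimum found in
#' the reference occasion). For every edge the per-subject association
#' at that delay is computed in both occasions and the paired
#' differences (on the Fisher z scale) are tested with a two-sided
#' t-test - two-sided because an intensity change in either direction is
#' of interest, and no optimum search takes place here. The edge family
#' is FDR-corrected at `alpha_treatment`; q-values in the tendency band
#' are flagged as a tendency. A shifted optimum in the new situation
#' also surfaces here, as intensity at the now non-optimal reference
#' delay diminishes.
#'
#' @param before,after long secretion tables for the two occasions.
#' @param edges reference edge table (rows of a `dynamic_network` table,
#'   carrying the reference-occasion optimum in `lag_tau`/`sign`).
#' @param config an [analysis_config()].
#' @return `edges` with `q_treatment` and `treatment_flag` filled in,
#'   plus columns `delta_assoc` (mean paired z difference, back on the
#'   correlation scale) and `p_treatment`.
#' @export
test_treatment_effect <- function(before, after, edges,
                                  config = analysis_config()) {
  config <- as_analysis_config(config)
  if (nrow(edges) == 0L) return(edges)
  cs_b <- cohort_series_list(before)
  cs_a <- cohort_series_list(after)
  common <- intersect(cs_b$subjects, cs_a$subjects)
  if (length(setdiff(union(cs_b$subjects, cs_a$subjects), common)) > 0L)
    warning("subjects present in only one occasion were dropped",
            call. = FALSE)
  if (length(common) < 3L)
    stop("insufficient data: fewer than 3 subjects in both occasions",
         call. = FALSE)
  keep_b <- cs_b$series[common]
  keep_a <- cs_a$series[common]
  uniq <- !duplicated(edges$test_id)
  p_vals <- rep(NA_real_, nrow(edges))
  delta <- rep(NA_real_, nrow(edges))
  for (i in which(uniq)) {
    src <- edges$source[i]
    tgt <- edges$target[i]
    lag <- edges$lag_tau[i]
    r_b <- vapply(keep_b, function(mat) pair_r(mat, src, tgt, lag),
                  numeric(1))
    r_a <- vapply(keep_a, function(mat) pair_r(mat, src, tgt, lag),
                  numeric(1))
    ok <- !is.na(r_b) & !is.na(r_a)
    if (sum(ok) < 3L)
      stop("insufficient data: fewer than 3 complete subject pairs",
           call. = FALSE)
    d <- fisher_z_quiet(r_a[ok]) - fisher_z_quiet(r_b[ok])
    tt <- cohort_t_test(d, sided = "two")
    p_vals[i] <- tt$p_value
    delta[i] <- inverse_fisher_z(tt$mean)
  }
  # lag-0 duplicates share their test: propagate, count once in the family
  for (i in which(!uniq)) {
    j <- match(edges$test_id[i], edges$test_id)
    p_vals[i] <- p_vals[j]
    delta[i] <- delta[j]
  }
  fdr <- bh_fdr(p_vals[uniq], config$alpha_treatment)
  q_uniq <- fdr$q_values
  q_all <- q_uniq[match(edges$test_id, edges$test_id[uniq])]
  edges$p_treatment <- p_vals
  edges$q_treatment <- q_all
  edges$delta_assoc <- delta
  edges$treatment_flag <- treatment_flags(q_all, config)
  edges
}

pair_r <- function(mat, source, target, lag) {
  if (!all(c(source, target) %in% rownames(mat))) return(NA_real_)
  x <- mat[source, ]
  y <- mat[target, ]
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  ccf_at_lag(x, y, lag)
}
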