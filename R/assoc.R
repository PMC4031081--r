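#' Lagged Pearson cross-correlation
#'
#' Computes the Pearson correlation of `(x[t], y[t + k])` over the
#' truncated overlap for every lag `k` in `-max_lag .. +max_lag`. A
#' positive lag means `y` follows `x`. No padding and no wrap-around are
#' used: the record is a finite 24-hour window, so the overlap at lag `k`
#' simply has `n - |k|` points. Lags whose overlap has zero variance in
#' either series are undefined (`NA`).
#'
#' @param x,y numeric vectors or [hormone_series][secretion_series()] on
#'   a common grid.
#' @param max_lag largest lag in sampling intervals; must satisfy
#'   `max_lag < length(x) - 3`.
#' @param tau_minutes sampling interval carried along as metadata.
#' @return A list of class `ccf_fn` with fields `lags` (integer vector
#'   `-max_lag:max_lag`), `values`, and `tau_minutes`.
#' @export
cross_correlation <- function(x, y, max_lag = 24L, tau_minutes = 10) {
  if (inherits(x, "hormone_series") && inherits(y, "hormone_series"))
    check_same_grid(x, y)
  xv <- as_series_values(x)
  yv <- as_series_values(y)
  n <- length(xv)
  if (length(yv) != n) stop("x and y lengths differ", call. = FALSE)
  if (max_lag >= n - 3L)
    stop("max_lag must be smaller than the series length minus 3",
         call. = FALSE)
  lags <- seq.int(-max_lag, max_lag)
  values <- vapply(lags, function(k) ccf_at_lag(xv, yv, k), numeric(1))
  structure(list(lags = lags, values = values, tau_minutes = tau_minutes),
            class = "ccf_fn")
}

# correlation of (x[t], y[t+k]) on the truncated overlap; NA when either
# slice is constant
ccf_at_lag <- function(x, y, k) {
  n <- length(x)
  if (k >= 0) {
    xs <- x[seq_len(n - k)]
    ys <- y[seq_len(n - k) + k]
  } else {
    xs <- x[seq_len(n + k) - k]
    ys <- y[seq_len(n + k)]
  }
  if (var(xs) == 0 || var(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

#' @export
print.ccf_fn <- function(x, ...) {
  def <- !is.na(x$values)
  cat(sprintf("<cross-correlation> lags %d..%d (tau = %g min), %d defined\n",
              min(x$lags), max(x$lags), x$tau_minutes, sum(def)))
  if (any(def)) {
    i <- which.max(abs(x$values))
    cat(sprintf("  largest |r| = %.3f at lag %d\n", x$values[i], x$lags[i]))
  }
  invisible(x)
}

#' Partial correlation given all remaining hormones
#'
#' The partial correlation of a pair, conditioning on every other
#' measured hormone, is read off the inverse of the correlation matrix:
#' `pcor_ij = -P_ij / sqrt(P_ii * P_jj)` with `P = R^-1`. It equals the
#' correlation of the residuals after regressing both members of the
#' pair on all remaining variables, and suppresses indirect links
#' mediated by a measured third hormone. Near-singular correlation
#' matrices are ridged (`1e-8 * trace / m` added to the diagonal) with a
#' warning.
#'
#' @param data numeric matrix, rows = time points, columns = hormones
#'   (named); more rows than columns required.
#' @param pair length-2 vector of column names or indices.
#' @return `partial_correlation()`: the partial correlation of `pair`
#'   given all other columns. `partial_correlation_matrix()`: the full
#'   symmetric matrix of such values.
#' @export
partial_correlation <- function(data, pair) {
  m <- partial_correlation_matrix(data)
  m[pair[1], pair[2]]
}

#' @rdname partial_correlation
#' @export
partial_correlation_matrix <- function(data) {
  data <- as.matrix(data)
  m <- ncol(data)
  if (m < 2L) stop("need at least two hormones", call. = FALSE)
  if (nrow(data) <= m)
    stop("need more time points than hormones", call. = FALSE)
  R <- cor(data)
  P <- tryCatch(solve(R), error = function(e) {
    warning("near-singular correlation matrix; ridge regularization applied",
            call. = FALSE)
    solve(R + diag(1e-8 * sum(diag(R)) / m, m))
  })
  denom <- sqrt(diag(P))
  pc <- -P / tcrossprod(denom)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R)
  pc
}

#' Fisher z transform and its inverse
#'
#' `fisher_z(r) = atanh(r)` stabilizes the variance of correlation
#' coefficients before averaging and t-testing; `inverse_fisher_z()` maps
#' back with `tanh`. Correlations with `|r| >= 1` are clipped to
#' `1 - 1e-7` in magnitude with a warning, as their transform is
#' unbounded.
#'
#' @param r correlation value(s).
#' @param z transformed value(s).
#' @return Transformed (or back-transformed) numeric vector; `NA`s pass
#'   through.
#' @export
fisher_z <- function(r) {
  clip <- !is.na(r) & abs(r) >= 1
  if (any(clip)) {
    warning("|r| >= 1 clipped before Fisher transform", call. = FALSE)
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

# internal: clip without the warning, for bulk cohort averaging where
# |r| = 1 can arise legitimately from self-pairs in degenerate fixtures
fisher_z_quiet <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(r)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control: `q_i = min_{j >= i} m * p_(j) / j` on the sorted
#' p-values, mapped back to input order (delegated to
#' [stats::p.adjust()]). Hypotheses with `q <= alpha` are rejected; the
#' rejections always form a prefix of the sorted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A list with `q_values` and logical `reject`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(q_values = numeric(0), reject = logical(0)))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= alpha)
}

#' One-sample cohort t-test
#'
#' Tests whether per-subject statistics (typically Fisher-transformed
#' correlations) share a common nonzero mean across the cohort. One-sided
#' versions are used at cross-correlation optima, whose sign is known by
#' construction.
#'
#' @param values per-subject statistics (>= 3 finite values required).
#' @param null_mean mean under the null hypothesis.
#' @param sided `"two"` or `"one"`.
#' @param direction for one-sided tests: `"+"` tests mean > `null_mean`,
#'   `"-"` tests mean < `null_mean`.
#' @return A list with `statistic` (t), `df`, `p_value`, `n`, `mean`, and
#'   `flag` (`"ok"` or `"zero_variance"`).
#' @export
cohort_t_test <- function(values, null_mean = 0, sided = c("two", "one"),
                          direction = c("+", "-")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("insufficient data: fewer than 3 finite values",
                   call. = FALSE)
  mu <- mean(values)
  s <- sd(values)
  df <- n - 1L
  if (s == 0) {
    if (mu == null_mean) {
      p <- if (sided == "two") 1 else 0.5
      return(list(statistic = 0, df = df, p_value = p, n = n, mean = mu,
                  flag = "zero_variance"))
    }
    agrees <- (sided == "two") ||
      (direction == "+" && mu > null_mean) ||
      (direction == "-" && mu < null_mean)
    return(list(statistic = sign(mu - null_mean) * Inf, df = df,
                p_value = if (agrees) 0 else 1, n = n, mean = mu,
                flag = "zero_variance"))
  }
  t_stat <- (mu - null_mean) / (s / sqrt(n))
  p <- switch(sided,
              two = 2 * pt(-abs(t_stat), df),
              one = if (direction == "+") pt(t_stat, df, lower.tail = FALSE)
                    else pt(t_stat, df))
  list(statistic = t_stat, df = df, p_value = p, n = n, mean = mu,
       flag = "ok")
}
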