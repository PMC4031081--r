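#' Hormone time-series containers
#'
#' A `hormone_series` is one subject x hormone x occasion profile on a
#' uniform sampling grid. Two kinds exist: `"concentration"` (assay units,
#' what is measured in blood) and `"secretion"` (mass released per grid
#' step, what deconvolution estimates and the simulator generates).
#'
#' @param values numeric vector of non-negative values, one per grid point.
#' @param delta grid spacing in minutes (default 10).
#' @param times sampling times in minutes; defaults to
#'   `0, delta, ..., (length(values)-1)*delta`.
#' @param subject_id,hormone,occasion identity labels.
#' @param elim [elimination_model()] associated with a secretion series
#'   (the clearance model used to generate or to fit it), or `NULL`.
#' @param diagnostics optional list of fit diagnostics (see [deconvolve()]).
#'
#' @return An object of class `hormone_series` (a list with the fields
#'   above plus `kind`).
#' @seealso [secretion_series()], [elimination_model()]
#' @export
concentration_series <- function(values, delta = 10, times = NULL,
                                 subject_id = "s1", hormone = "h",
                                 occasion = "before") {
  new_series(values, delta, times, subject_id, hormone, occasion,
             kind = "concentration")
}

#' @rdname concentration_series
#' @export
secretion_series <- function(values, delta = 10, times = NULL,
                             subject_id = "s1", hormone = "h",
                             occasion = "before", elim = NULL,
                             diagnostics = NULL) {
  s <- new_series(values, delta, times, subject_id, hormone, occasion,
                  kind = "secretion")
  s$elim <- elim
  s$diagnostics <- diagnostics
  s
}

new_series <- function(values, delta, times, subject_id, hormone, occasion,
                       kind) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("series values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("series values must be non-negative", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar", call. = FALSE)
  if (is.null(times))
    times <- seq(0, by = delta, length.out = length(values))
  times <- as.numeric(times)
  if (length(times) != length(values))
    stop("times and values lengths differ", call. = FALSE)
  if (length(times) > 1L) {
    d <- diff(times)
    if (any(d <= 0) || max(abs(d - delta)) > 1e-8)
      stop("times must be a strictly increasing uniform grid with spacing delta",
           call. = FALSE)
  }
  structure(list(subject_id = subject_id, hormone = hormone,
                 occasion = occasion, times = times, values = values,
                 delta = delta, kind = kind),
            class = "hormone_series")
}

#' @export
print.hormone_series <- function(x, ...) {
  cat(sprintf("<%s series> %s / %s / %s: %d samples, delta = %g min\n",
              x$kind, x$subject_id, x$hormone, x$occasion,
              length(x$values), x$delta))
  cat(sprintf("  range [%.4g, %.4g], %d nonzero bins\n",
              min(x$values), max(x$values), sum(x$values > 0)))
  invisible(x)
}

#' @export
length.hormone_series <- function(x) length(x$values)

# shared grid check used by coupling and correlation code
check_same_grid <- function(x, y) {
  if (length(x$values) != length(y$values) ||
      abs(x$delta - y$delta) > 1e-8)
    stop("series are not on the same sampling grid", call. = FALSE)
  invisible(TRUE)
}

as_series_values <- function(x) {
  if (inherits(x, "hormone_series")) x$values else as.numeric(x)
}
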