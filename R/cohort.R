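# Internal helpers turning long cohort tables (subject_id, hormone,
# occasion, time_min, value) into per-subject value matrices.

required_cohort_columns <- c("subject_id", "hormone", "occasion",
                             "time_min", "value")

check_cohort_columns <- function(df) {
  missing <- setdiff(required_cohort_columns, names(df))
  if (length(missing) > 0L)
    stop(sprintf("cohort table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# Restrict to one occasion and reshape into a list of per-subject
# hormone-by-time matrices. Network inference is defined within one
# occasion; pooling occasions silently would mix two different regulatory
# states, so more than one remaining occasion is an error.
cohort_series_list <- function(df, occasion = NULL) {
  check_cohort_columns(df)
  if (!is.null(occasion)) df <- df[df$occasion %in% occasion, , drop = FALSE]
  occ <- unique(df$occasion)
  if (length(occ) == 0L) stop("no rows for the requested occasion",
                              call. = FALSE)
  if (length(occ) > 1L)
    stop(sprintf(paste0("cohort contains %d occasions (%s); network ",
                        "inference requires exactly one - pass `occasion`"),
                 length(occ), paste(occ, collapse = ", ")), call. = FALSE)
  subjects <- sort(unique(df$subject_id))
  hormones <- sort(unique(df$hormone))
  times <- sort(unique(df$time_min))
  n_t <- length(times)
  series <- lapply(subjects, function(s) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    mat <- matrix(NA_real_, nrow = length(hormones), ncol = n_t,
                  dimnames = list(hormones, NULL))
    for (h in intersect(hormones, unique(sub$hormone))) {
      rows <- sub[sub$hormone == h, , drop = FALSE]
      rows <- rows[order(rows$time_min), , drop = FALSE]
      if (nrow(rows) != n_t) next  # incomplete grid: leave NA, caller drops
      mat[h, ] <- rows$value
    }
    mat
  })
  names(series) <- subjects
  list(subjects = subjects, hormones = hormones, times = times,
       series = series, occasion = occ)
}

# per-subject r for an ordered pair at one signed lag
pair_values_at_lag <- function(cs, source, target, lag) {
  vapply(cs$series, function(mat) {
    x <- mat[source, ]
    y <- mat[target, ]
    if (anyNA(x) || anyNA(y)) return(NA_real_)
    ccf_at_lag(x, y, lag)
  }, numeric(1))
}
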