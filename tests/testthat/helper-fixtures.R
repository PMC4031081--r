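# Shared fixture builders. Everything is generated in code; sizes are kept
# small so single tests stay fast, while acceptance tests use the full
# study design.

quick_design <- function(n_subjects = 6L, n_samples = 145L,
                         occasions = "before") {
  study_design(n_samples = n_samples, delta = 10, n_subjects = n_subjects,
               occasions = occasions)
}

# a secretion series with pulses at fixed bins (deterministic fixture)
fixed_train <- function(bins, masses = NULL, n = 145, delta = 10, ...) {
  v <- numeric(n)
  if (is.null(masses)) masses <- rep(1, length(bins))
  v[bins] <- masses
  secretion_series(v, delta = delta, ...)
}

# independent-pair cohort: per-subject matrices of independent trains
null_cohort <- function(n_subjects, hormones, seed, design = quick_design()) {
  truth <- ground_truth_network(hormones = hormones)
  design$n_subjects <- as.integer(n_subjects)
  simulate_cohort(truth, design, seed = seed)$secretions
}

# naive two-pass Pearson on the explicitly sliced overlap (oracle for
# cross_correlation; independent of cor())
pearson_oracle <- function(x, y, k) {
  n <- length(x)
  if (k >= 0) {
    xs <- x[1:(n - k)]
    ys <- y[(1 + k):n]
  } else {
    xs <- x[(1 - k):n]
    ys <- y[1:(n + k)]
  }
  mx <- sum(xs) / length(xs)
  my <- sum(ys) / length(ys)
  sxy <- sum((xs - mx) * (ys - my))
  sxx <- sum((xs - mx)^2)
  syy <- sum((ys - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# direct evaluation of the BH step-up formula (oracle for bh_fdr)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
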