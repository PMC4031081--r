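#' Exponential elimination model
#'
#' Clearance of a hormone from the circulation is modelled as first-order
#' (exponential) decay: over one grid step of `delta` minutes a fraction
#' `2^(-delta/half_life)` of the circulating amount remains.
#'
#' @param half_life elimination half-life in minutes (> 0).
#' @param basal_rate constant (non-pulsatile) secretion mass added per
#'   grid step (>= 0).
#' @param initial_concentration concentration already circulating at the
#'   first sample (>= 0).
#' @return A list of class `elimination_model`.
#' @export
elimination_model <- function(half_life, basal_rate = 0,
                              initial_concentration = 0) {
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("half_life must be a positive duration in minutes", call. = FALSE)
  if (basal_rate < 0 || initial_concentration < 0)
    stop("basal_rate and initial_concentration must be non-negative",
         call. = FALSE)
  structure(list(half_life = half_life, basal_rate = basal_rate,
                 initial_concentration = initial_concentration),
            class = "elimination_model")
}

decay_fraction <- function(elim, delta) 2^(-delta / elim$half_life)

#' Directed coupling between two hormones
#'
#' Ground-truth specification of one lagged regulatory relation used by the
#' simulator: each secretion pulse of `source` either triggers (sign `"+"`)
#' or suppresses (sign `"-"`) secretion of `target` a fixed number of
#' sampling intervals later, with a given probability (`strength`).
#'
#' @param source,target hormone names (must differ).
#' @param delay lag in sampling intervals (integer >= 0).
#' @param sign `"+"` for stimulation, `"-"` for suppression.
#' @param strength per-pulse coupling probability in `[0, 1]`.
#' @return A list of class `coupling`.
#' @export
coupling <- function(source, target, delay, sign = c("+", "-"),
                     strength = 1) {
  sign <- match.arg(sign)
  if (identical(source, target))
    stop("coupling source and target must differ", call. = FALSE)
  if (delay < 0 || delay != round(delay))
    stop("delay must be a non-negative integer (in tau units)", call. = FALSE)
  if (strength < 0 || strength > 1)
    stop("strength must lie in [0, 1]", call. = FALSE)
  structure(list(source = source, target = target, delay = as.integer(delay),
                 sign = sign, strength = strength),
            class = "coupling")
}

#' Ground-truth network for the simulator
#'
#' Describes a cohort-generating model: the hormones, their pulsing
#' statistics, clearance half-lives, and the couplings between them. This
#' object is returned alongside simulated data and serves as the recovery
#' oracle for the inference machinery.
#'
#' Per-hormone parameters (`pulse_rate`, `mass_mean`, `mass_cv`,
#' `half_life`) may be scalars (recycled) or vectors named by hormone.
#'
#' @param hormones character vector of unique hormone names.
#' @param couplings list of [coupling()] objects.
#' @param pulse_rate expected number of secretion pulses per 24 h.
#' @param mass_mean,mass_cv mean and coefficient of variation of the
#'   log-normal pulse mass distribution.
#' @param half_life elimination half-life in minutes.
#' @param basal_rate basal secretion mass per grid step.
#' @return A list of class `ground_truth_network`.
#' @export
ground_truth_network <- function(hormones, couplings = list(),
                                 pulse_rate = 16, mass_mean = 1,
                                 mass_cv = 0.3, half_life = 60,
                                 basal_rate = 0) {
  if (anyDuplicated(hormones))
    stop("hormone names must be unique", call. = FALSE)
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(hormones)), hormones)
    if (!all(hormones %in% names(x)))
      stop(sprintf("%s must be a scalar or named for every hormone", what),
           call. = FALSE)
    x[hormones]
  }
  for (cp in couplings) {
    if (!inherits(cp, "coupling"))
      stop("couplings must be a list of coupling() objects", call. = FALSE)
    if (!cp$source %in% hormones || !cp$target %in% hormones)
      stop(sprintf("coupling endpoint '%s' or '%s' not among hormones",
                   cp$source, cp$target), call. = FALSE)
  }
  structure(list(hormones = hormones, couplings = couplings,
                 pulse_rate = expand(pulse_rate, "pulse_rate"),
                 mass_mean = expand(mass_mean, "mass_mean"),
                 mass_cv = expand(mass_cv, "mass_cv"),
                 half_life = expand(half_life, "half_life"),
                 basal_rate = expand(basal_rate, "basal_rate")),
            class = "ground_truth_network")
}

#' Study sampling design
#'
#' The default design is the 24-hour dense-sampling protocol this package
#' targets: 145 samples on a 10-minute grid (t = 0, 10, ..., 1440 min,
#' endpoints inclusive), 18 subjects, two occasions ("before" and "after"
#' an intervention).
#'
#' @param n_samples number of samples per series (>= 2).
#' @param delta sampling interval in minutes.
#' @param n_subjects cohort size.
#' @param occasions ordered character vector of occasion labels.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_samples = 145L, delta = 10, n_subjects = 18L,
                         occasions = c("before", "after")) {
  stopifnot(n_samples >= 2, delta > 0, length(occasions) >= 1)
  structure(list(n_samples = as.integer(n_samples), delta = delta,
                 n_subjects = as.integer(n_subjects),
                 occasions = as.character(occasions)),
            class = "study_design")
}

#' Generate a pulsatile secretion train
#'
#' Draws the number of pulses from a Poisson law with mean
#' `pulse_rate * duration / 24 h`, places them uniformly on the grid
#' subject to a minimal inter-pulse gap (a short refractory period), and
#' assigns each pulse a log-normal mass with the requested mean and CV.
#' A constant basal mass per step may be added on top.
#'
#' @param design a [study_design()].
#' @param pulse_rate expected pulses per 24 h (>= 0).
#' @param mass_mean,mass_cv pulse mass distribution (mean > 0 when
#'   `pulse_rate > 0`; CV >= 0).
#' @param basal_rate constant secretion mass per grid step.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param min_gap minimal distance between two pulse bins, in bins.
#' @param subject_id,hormone,occasion labels for the returned series.
#' @return A secretion [hormone_series][secretion_series()].
#' @export
generate_secretion_train <- function(design, pulse_rate, mass_mean = 1,
                                     mass_cv = 0.3, basal_rate = 0,
                                     seed = 1L, min_gap = 2L,
                                     subject_id = "s1", hormone = "h",
                                     occasion = "before") {
  if (pulse_rate < 0) stop("pulse_rate must be >= 0", call. = FALSE)
  if (mass_cv < 0) stop("mass_cv must be >= 0", call. = FALSE)
  if (pulse_rate > 0 && mass_mean <= 0)
    stop("mass_mean must be > 0 when pulse_rate > 0", call. = FALSE)
  n <- design$n_samples
  duration_min <- (n - 1L) * design$delta
  lambda <- pulse_rate * duration_min / 1440
  masses <- numeric(n)
  withr::with_seed(as.integer(seed), {
    n_pulses <- rpois(1L, lambda)
    bins <- place_pulses(n, n_pulses, min_gap)
    if (length(bins) > 0) {
      sdlog <- sqrt(log(1 + mass_cv^2))
      meanlog <- log(mass_mean) - sdlog^2 / 2
      masses[bins] <- rlnorm(length(bins), meanlog, sdlog)
    }
  })
  secretion_series(masses + basal_rate, delta = design$delta,
                   subject_id = subject_id, hormone = hormone,
                   occasion = occasion)
}

# uniform placement with a refractory gap: candidates within `min_gap`
# bins of an accepted pulse are removed from the pool
place_pulses <- function(n, n_pulses, min_gap) {
  allowed <- seq_len(n)
  bins <- integer(0)
  for (i in seq_len(n_pulses)) {
    if (length(allowed) == 0L) break
    b <- allowed[sample.int(length(allowed), 1L)]
    bins <- c(bins, b)
    allowed <- allowed[abs(allowed - b) >= min_gap]
  }
  sort(bins)
}

#' Impose a lagged coupling on a secretion train
#'
#' Realizes one [coupling()] between two secretion trains. For a positive
#' coupling each driver pulse independently (probability `strength`)
#' triggers an added pulse in the target exactly `delay` bins later,
#' carrying the driver pulse's mass (truncated at the end of the record).
#' For a negative coupling, background pulses of the target falling in a
#' suppression window centred `delay` bins after a driver pulse are
#' removed with probability `strength` - secretion cannot go negative, so
#' inhibition is realized as pulse deletion.
#'
#' @param driver secretion series of the source hormone.
#' @param spec a [coupling()].
#' @param background uncoupled secretion series of the target hormone,
#'   on the same grid as `driver`.
#' @param seed integer seed.
#' @param suppression_width width of the suppression window in bins
#'   (centred on the delayed bin; only used for negative couplings).
#' @return The coupled secretion series for the target hormone.
#' @export
couple_secretion <- function(driver, spec, background, seed = 1L,
                             suppression_width = 3L) {
  check_same_grid(driver, background)
  n <- length(background$values)
  if (spec$delay >= n)
    stop("coupling delay exceeds the series length", call. = FALSE)
  drv <- driver$values
  out <- background$values
  pulses <- which(drv > 0)
  withr::with_seed(as.integer(seed), {
    if (spec$sign == "+") {
      for (j in pulses) {
        if (runif(1L) <= spec$strength) {
          t <- j + spec$delay
          if (t <= n) out[t] <- out[t] + drv[j]
        }
      }
    } else {
      half <- (suppression_width - 1L) %/% 2L
      windows <- rep(FALSE, n)
      for (j in pulses) {
        lo <- max(1L, j + spec$delay - half)
        hi <- min(n, j + spec$delay + half)
        if (lo <= hi) windows[lo:hi] <- TRUE
      }
      for (t in which(background$values > 0)) {
        if (windows[t] && runif(1L) <= spec$strength) out[t] <- 0
      }
    }
  })
  secretion_series(out, delta = background$delta,
                   subject_id = background$subject_id,
                   hormone = background$hormone,
                   occasion = background$occasion)
}

#' Convolve secretion with exponential clearance
#'
#' Forward model mapping a secretion train to a concentration profile.
#' With per-step decay fraction `d = 2^(-delta/half_life)`, the noiseless
#' value at bin `t` is
#' `C0 * d^t + sum_{j <= t} (mass_j + basal) * d^(t-j)`.
#' Optional multiplicative assay noise scales each value by `1 + e`,
#' `e ~ Normal(0, noise_cv)`; values are floored at a small positive
#' detection limit.
#'
#' @param s a secretion [hormone_series][secretion_series()].
#' @param elim an [elimination_model()].
#' @param noise_cv assay coefficient of variation (>= 0; 0 = noiseless).
#' @param seed integer seed (used only when `noise_cv > 0`).
#' @param detection_limit floor applied to the final values.
#' @return A concentration [hormone_series][concentration_series()].
#' @export
secretion_to_concentration <- function(s, elim, noise_cv = 0, seed = 1L,
                                       detection_limit = 1e-6) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  d <- decay_fraction(elim, s$delta)
  x <- s$values + elim$basal_rate
  conc <- as.numeric(stats::filter(x, d, method = "recursive"))
  t_idx <- seq_along(conc) - 1L
  conc <- conc + elim$initial_concentration * d^t_idx
  if (noise_cv > 0) {
    withr::with_seed(as.integer(seed), {
      conc <- conc * (1 + rnorm(length(conc), 0, noise_cv))
    })
  }
  conc <- pmax(conc, detection_limit)
  cs <- concentration_series(conc, delta = s$delta,
                             subject_id = s$subject_id, hormone = s$hormone,
                             occasion = s$occasion)
  cs$elim <- elim
  cs
}

#' Simulate a before/after cohort of coupled pulsatile hormones
#'
#' Generates one concentration series per (subject, hormone, occasion)
#' under a [ground_truth_network()]. For the `"after"` occasion the
#' couplings may be replaced wholesale by `altered` (emulating an
#' intervention that rewires or weakens regulation); subjects keep their
#' own random sub-streams, derived deterministically from the master
#' seed, so any single series is reproducible.
#'
#' Couplings are applied in list order, each reading the current state of
#' its driver, so chains (a -> b -> c) propagate.
#'
#' @param truth a [ground_truth_network()].
#' @param design a [study_design()].
#' @param altered `NULL` (couplings unchanged after treatment) or a list
#'   of [coupling()] objects replacing the originals in occasion
#'   `"after"` (the second occasion of the design).
#' @param noise_cv multiplicative assay noise CV applied to
#'   concentrations.
#' @param seed master integer seed.
#' @param suppression_width see [couple_secretion()].
#' @return A list with elements `concentrations` and `secretions` (long
#'   data frames with columns `subject_id, hormone, occasion, time_min,
#'   value`), and `truth` (couplings per occasion plus the generating
#'   parameters).
#' @export
simulate_cohort <- function(truth, design = study_design(), altered = NULL,
                            noise_cv = 0.05, seed = 1L,
                            suppression_width = 3L) {
  occ <- design$occasions
  couplings_by_occ <- stats::setNames(rep(list(truth$couplings), length(occ)),
                                      occ)
  if (!is.null(altered)) {
    for (cp in altered) {
      if (!inherits(cp, "coupling"))
        stop("altered must be a list of coupling() objects", call. = FALSE)
      if (!cp$source %in% truth$hormones || !cp$target %in% truth$hormones)
        stop(sprintf("altered coupling references unknown hormone '%s'",
                     setdiff(c(cp$source, cp$target), truth$hormones)[1]),
             call. = FALSE)
    }
    if (length(occ) < 2L)
      stop("altered couplings require a design with at least two occasions",
           call. = FALSE)
    for (o in occ[-1]) couplings_by_occ[[o]] <- altered
  }
  rows_conc <- vector("list", 0L)
  rows_secr <- vector("list", 0L)
  idx <- 0L
  for (si in seq_len(design$n_subjects)) {
    sid <- sprintf("s%02d", si)
    for (o in occ) {
      trains <- list()
      for (h in truth$hormones) {
        idx <- idx + 1L
        trains[[h]] <- generate_secretion_train(
          design, pulse_rate = truth$pulse_rate[[h]],
          mass_mean = truth$mass_mean[[h]], mass_cv = truth$mass_cv[[h]],
          basal_rate = truth$basal_rate[[h]],
          seed = derive_seed(seed, idx),
          subject_id = sid, hormone = h, occasion = o)
      }
      for (cp in couplings_by_occ[[o]]) {
        idx <- idx + 1L
        trains[[cp$target]] <- couple_secretion(
          trains[[cp$source]], cp, trains[[cp$target]],
          seed = derive_seed(seed, idx),
          suppression_width = suppression_width)
      }
      for (h in truth$hormones) {
        idx <- idx + 1L
        elim <- elimination_model(truth$half_life[[h]])
        cs <- secretion_to_concentration(trains[[h]], elim,
                                         noise_cv = noise_cv,
                                         seed = derive_seed(seed, idx))
        rows_conc[[length(rows_conc) + 1L]] <- series_to_rows(cs)
        rows_secr[[length(rows_secr) + 1L]] <- series_to_rows(trains[[h]])
      }
    }
  }
  list(concentrations = do.call(rbind, rows_conc),
       secretions = do.call(rbind, rows_secr),
       truth = list(couplings = couplings_by_occ,
                    network = truth, design = design,
                    noise_cv = noise_cv, seed = seed))
}

series_to_rows <- function(s) {
  data.frame(subject_id = s$subject_id, hormone = s$hormone,
             occasion = s$occasion, time_min = s$times, value = s$values,
             stringsAsFactors = FALSE)
}
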