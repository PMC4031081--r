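# hormonet

Detecting lagged regulatory relations between hormones from densely
sampled 24-hour cohort time series.

Hormones are secreted in bursts and cleared exponentially, and they
regulate one another with delays of minutes to hours. Given
concentration profiles sampled every 10 minutes for 24 hours in a
cohort of subjects (the design used in clinical pulsatility studies),
`hormonet` reconstructs each hormone's secretion profile, quantifies
lagged associations between hormones, and summarizes them as a
validated network - before and after an intervention. It is intended
for endocrinologists and systems-biology analysts working with dense
hormone sampling, and ships a ground-truth simulator of coupled
pulsatile hormones so that every inferential step can be verified
end to end.

## Method at a glance

* **Deconvolution.** Concentration is modelled as
  `C_t = sum_{j<=t} m_j d^(t-j)` with per-step decay
  `d = 2^(-Δ/t_half)` and episodic non-negative secretion masses `m_j`.
  The inverse problem is solved by weighted non-negative least squares
  with an L1 mass penalty (coordinate descent, compiled), followed by
  thresholding and an unpenalized refit; residual whiteness is checked
  with a Ljung-Box test.
* **Association.** Lagged Pearson cross-correlation `r(k)` of secretion
  series over the truncated overlap, lags `k = -24..24` in units of
  τ = 10 min (a four-hour window).
* **Dynamic network.** The extremes of the cohort-average CCF define
  candidate relations and their delays. Candidates are tested one-sided
  at the optimum (Fisher-z, search-corrected), FDR-controlled at 0.01,
  validated by leave-two-out robustness over all C(n,2) subject pairs,
  and marked directed when the association at the optimal lag credibly
  exceeds the lag-0 association. `a -> b` at lag k means b follows a by
  k sampling intervals; negative relations are dashed by convention.
* **Static network.** Conventional lag-0 correlation and
  partial-correlation networks (two-sided tests, FDR 0.05) as a
  reference.
* **Treatment effect.** Paired t-tests of per-subject association at
  the pre-selected reference delay, before vs after treatment, FDR
  0.05, with a "tendency" band at 0.05 < q < 0.10.

## Worked example

Simulate a 18-subject cohort of four hormones where ACTH drives
cortisol (CRT) at one lag positively and TSH instantaneously, and where
the intervention abolishes the ACTH-TSH relation; then infer the
network and test the treatment effect:

```r
library(hormonet)

truth <- ground_truth_network(
  hormones  = c("ACTH", "CRT", "TSH", "PRL"),
  couplings = list(coupling("ACTH", "CRT", delay = 1, sign = "+", strength = 0.9),
                   coupling("ACTH", "TSH", delay = 0, sign = "+", strength = 0.8)),
  half_life = c(ACTH = 20, CRT = 66, TSH = 50, PRL = 45))

sim <- simulate_cohort(truth, study_design(n_subjects = 18),
                       altered = list(coupling("ACTH", "CRT", 1, "+", 0.9)),
                       seed = 42)

before <- sim$secretions[sim$secretions$occasion == "before", ]
after  <- sim$secretions[sim$secretions$occasion == "after", ]

net <- infer_dynamic_network(before)
net
#> <dynamic network> occasion "before": 12 candidate optima, 4 significant (FDR 0.01), 4 robust
#>  source target lag_tau sign mean_assoc q_relation p_directionality robust directed
#>    ACTH    CRT       1    +    0.61793  2.938e-12        4.767e-15   TRUE     TRUE
#>    ACTH    TSH       0    +    0.58556  9.539e-10               NA   TRUE    FALSE
#>     TSH   ACTH       0    +    0.58556  9.539e-10               NA   TRUE    FALSE
#>     TSH   ACTH       1    -   -0.09429  2.803e-03        1.000e+00   TRUE    FALSE
#>     TSH    CRT       1    +    0.35360  7.851e-08        2.979e-09   TRUE     TRUE
```

The planted ACTH→CRT relation is recovered at its true lag with an
arrow (the delayed association beats the instantaneous one,
p ≈ 5e-15); the lag-0 ACTH-TSH relation appears under both orders with
`NA` directionality, as lag-0 relations have no direction. The
TSH→CRT edge is the indirect path through ACTH - the dynamic network
deliberately does not partialize (see the vignette), so mediated
relations can appear.

```r
edges <- test_treatment_effect(before, after, network_edges(net))
edges[, c("source", "target", "lag_tau", "sign", "q_treatment", "treatment_flag")]
#>  source target lag_tau sign q_treatment treatment_flag
#>    ACTH    CRT       1    +    6.94e-01           none
#>    ACTH    TSH       0    +    2.44e-11    significant
#>     TSH   ACTH       0    +    2.44e-11    significant
#>     TSH   ACTH       1    -    5.01e-03    significant
#>     TSH    CRT       1    +    1.32e-08    significant
```

The abolished ACTH-TSH relation (and everything mediated by it) is
flagged as a significant treatment effect; the untouched ACTH→CRT
relation is not. Deconvolution of a single measured profile works the
same way on real data:

```r
secr <- deconvolve(concentration_series(values), 
                   deconvolution_settings(half_life = 66))
secr$diagnostics$ljung_box$p_value   # residual whiteness check
```

A thin command-line interface over the same functions is installed at
`system.file("cli", "hormonet.R", package = "hormonet")` with
subcommands `simulate | deconvolve | static-net | dynamic-net |
treatment | export` (CSV/TSV in, edge tables and GraphML out, exit
code 2 on validation errors).

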