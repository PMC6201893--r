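# qreveal

Validation statistics for patient-reported outcome measures (PROMs): does a
questionnaire actually reveal a patient's disease status as measured by a
continuous objective endpoint?

Standard correlation coefficients (Pearson, ICC, Spearman) are a poor fit
for this question — the PRO is ordinal, the clinical endpoint is continuous,
repeated visits are correlated, and the coefficient itself has no clinical
reading. `qreveal` instead estimates the **revealing-truth probability**: for
subject *i* and PROM scale *z*, assume a subject-specific latent threshold
*a_iz* on the objective endpoint *X* (the minimum objective state that
triggers a PRO of at least *z*), and define

    Q_iz = Pr(PRO_i >= z | X_i >= a_iz) = Pr(PRO_i < z | X_i < a_iz)

— the probability that the dichotomized PRO agrees with the side of the
latent threshold on which the objective outcome fell. `Q = 0.5` is a coin
flip (no association); `Q = 0.9` means the PROM reveals the truth 90% of the
time. The statistic applies to correlated repeated measures and needs no
distributional assumption on the latent threshold.

## Estimation

From a subject's `t` repeated pairs `(x_k, g_k)`, the estimator scans a
pre-specified grid of candidate thresholds `a_1 < ... < a_m` (chosen from
clinical knowledge of the plausible range of X, never from the data). At
each grid point the visits form a 2×2 table against the dichotomized PRO,
with agreement accuracy `R_j = (TP + TN)_j / t`. Then

* **max rule** — `Q-hat = max_j R_j`, consistent for Q > 0.5; the latent
  threshold estimate `a-hat` is the median of the grid points tied at the
  maximum;
* **median rule** — `Q-hat = median_j R_j`, the right estimator at the
  no-association null Q = 0.5 where the max rule is badly inflated;
* exact binomial (Clopper–Pearson) confidence interval and variance
  `q(1-q)/t`, since TP + TN is Binomial(t, Q) at the true threshold.

Population inference (`aggregate_q`) tests whether the mean of the subject
level estimates clears a minimum acceptable probability δ; responsiveness
(`threshold_change`) tests whether stricter dichotomizations shift the
latent thresholds upward, by the median shift and a one-sided exact
Wilcoxon signed-rank test. A Monte-Carlo module (`sim_config`, `run_study`,
`convergence_table`) reproduces the estimator's operating characteristics
under correlated multivariate-normal outcomes.

## Worked example

Nine visits from one subject, scanned over a 9-point grid:

```r
library(qreveal)
s <- paired_series("toy", x = c(5, 7, 9, 11, 12, 13, 14, 15, 16),
                   g = c(0, 0, 0, 1, 1, 1, 1, 1, 1), scale_label = "PRO >= 5")
grid <- threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
estimate_q(threshold_scan(s, grid))
#> Revealing-truth probability estimate (max rule) for subject 'toy' at PRO >= 5
#>   Q-hat = 1.0000  (9/9 agreements; 95% exact CI 0.6637-1.0000)
#>   a-hat = 10.5  (median of 2 tied grid points: 10, 11)
```

The PRO agreed with the objective outcome at all 9 visits at the best
threshold; the accuracy maximum is tied at grid points 10 and 11, so the
latent threshold is estimated at their median 10.5. Flipping the second
visit's PRO to positive drops the estimate to `Q-hat = 0.89` (8/9) with
`a-hat = 10` (ties at 6, 10, 11).

A population analysis on simulated data with known truth (Q = 0.9,
a = 1.2, 60 subjects, 40 visits):

```r
cfg <- sim_config(rho = 0.8, a_true = 1.2, q_true = 0.9, t = 40,
                  n_reps = 10, seed = 2026)
f <- tempfile(fileext = ".csv")
write_fixture(cfg, n_subjects = 60, f)
res <- run_pipeline(study_config(f, threshold_grid_range(-2, 5, 0.1),
                                 delta = 0.8))
res$population
#>   cutoff n_subjects n_filtered    mean_q    ci_low   ci_high level delta passes
#> 1      g         60          0 0.8941667 0.8814507 0.9068826  0.95   0.8   TRUE
```

The mean estimate 0.894 recovers the generating Q = 0.9 (max-rule small-
sample bias is mild at t = 40), and its lower 95% bound 0.881 clears the
chosen δ = 0.8, so this PROM would be judged able to reveal disease status.

A thin command-line wrapper over these functions is installed at
`inst/cli/qreveal.R` with subcommands `estimate`, `aggregate`,
`responsiveness` and `simulate`.

## Further reading

The methods vignette (`vignettes/revealing-truth-probability.Rmd`) documents
the model and its assumptions, the tie-breaking and rounding conventions,
what the simulation does and does not emulate, and known limitations.
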