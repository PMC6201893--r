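---
title: "The revealing-truth probability: model, estimation and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The revealing-truth probability: model, estimation and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qreveal)
```

## The problem

Before a patient-reported outcome measure (PROM) can support effectiveness
claims for a drug or device, it must be shown to track the disease status it
is meant to reflect. The usual correlation coefficients (Pearson, ICC,
Spearman) are awkward here: the PRO is ordinal while the clinical endpoint is
continuous, repeated visits from the same subject are correlated, and a
correlation of, say, 0.6 carries no direct clinical meaning.

`qreveal` implements a conditional-association statistic with a direct
interpretation. For subject $i$ and PROM scale $z$, assume a subject-specific
*latent threshold* $a_{iz}$ on the objective endpoint $X$: the minimum
objective disease state that triggers a PRO of at least $z$. The
*revealing-truth probability* $Q_{iz}$ is the probability that the
dichotomized PRO agrees with the side of $a_{iz}$ on which the subject's
objective outcome actually fell:

$$
Q_{iz} \;=\; \Pr(\mathrm{PRO}_i \ge z \mid X_i \ge a_{iz})
       \;=\; \Pr(\mathrm{PRO}_i < z \mid X_i < a_{iz}).
$$

The two conditional probabilities are assumed equal — the response is one of
two Bernoulli variables with the same parameter but opposite meaning,
depending on which side of the threshold $x$ falls. $Q = 0.5$ means the
subject might as well flip a coin (no association); the closer $Q$ is to 1,
the better the PROM reveals the disease status. Unequal probabilities on the
two sides would require knowing their ratio and the marginal distributions of
$X$ at every visit, which is impractical; the equal-probability model is the
scope of this package.

## Estimation by threshold scan

Data for one subject are $t$ repeated pairs $(x_k, g_k)$, $k = 1,\dots,t$,
where $g_k \in \{0, 1\}$ is the dichotomized PRO. A *pre-specified* grid
$a_1 < \dots < a_m$ of candidate thresholds spans the clinically plausible
range of $X$ (for hemoglobin, say 5–20 g/dL); it is fixed from clinical
knowledge, never fitted to the data — `threshold_grid_range()` generates it
by integer index so that step arithmetic cannot drift. At each grid point the
visits are cross-classified into a 2×2 table (outcome $\ge a_j$ vs. $< a_j$
against PRO positive vs. negative; ties $x = a_j$ count as $\ge a_j$), giving
the agreement accuracy

$$
R_j = \frac{(TP + TN)_j}{t}.
$$

$E(TP+TN)$ equals $tQ$ exactly at $a_j = a_{iz}$, and when $Q > 0.5$ it is
maximal there; so the **max rule** $\hat{Q} = \max_j R_j$ is consistent for
$Q$, and the latent threshold is estimated by the median of the grid points
tied at the maximum (mean of the two middle points for an even tie count).
Tie detection compares the integer counts $TP+TN$ directly, so no floating
tolerance is involved. Under the no-association null $Q = 0.5$ *every* $R_j$
is unbiased and the maximum is badly inflated in small samples; the
**median rule** $\hat{Q} = \mathrm{median}_j R_j$ is the appropriate
estimator there. Under the median rule no threshold is identified (there is
nothing to find); `estimate_q()` still reports the median of the grid points
whose accuracy is nearest the median, flagged `a_identified = FALSE`.

Because $TP+TN$ is Binomial$(t, Q)$ at the true threshold, the variance
estimate is $\hat{Q}(1-\hat{Q})/t$ and the interval is the exact binomial
(Clopper–Pearson) interval on the selected successes — appropriate because
$t$ is small in practice (often $\le 6$ visits). Under the median rule the
implied successes $\hat{Q}t$ need not be an integer; they are rounded half
*up* (`floor(q*t + 0.5)`, avoiding R's round-half-to-even) before the
interval is formed, an explicit approximation since the binomial argument is
exact only at the true threshold.

```{r toy}
s <- paired_series("toy", x = c(5, 7, 9, 11, 12, 13, 14, 15, 16),
                   g = c(0, 0, 0, 1, 1, 1, 1, 1, 1))
grid <- threshold_grid(c(5, 6, 8, 10, 11, 12, 13.5, 15, 16))
estimate_q(threshold_scan(s, grid))
```

## Multi-subject inference

A trial yields one $\hat{Q}_{iz}$ per subject. `aggregate_q()` summarises
them by their mean with a t-interval on $n-1$ degrees of freedom — the
simplest interval consistent with "the mean with its CI", treating the
subject-level estimates as the independent replicates; the level is a
parameter (default 0.95) and the interval is deliberately not clipped to
$[0,1]$ so that its width is honest. The PROM is judged able to reveal
disease status when the lower bound exceeds a minimum acceptable probability
$\delta$ chosen in advance ($\delta = 0.5$ is the bare no-association bar; a
regulator may demand more). The comparison is the one-sided lower-bound test
by default.

Subjects whose PRO never reaches the dichotomized value, or whose objective
outcomes are all identical, carry no information about the threshold
location; they are flagged ineligible and excluded from population summaries
by default (`filter_eligible`), never rejected at estimation time.

**Responsiveness.** Dichotomizing at a stricter scale point ($z' \to z$,
$z > z'$) should raise the latent threshold: "very much improved" demands
more objective improvement than "much improved". `threshold_change()` forms
the per-subject differences $\hat{a}_{iz} - \hat{a}_{iz'}$ and, because
their distribution is typically highly skewed, reports the median and a
one-sided Wilcoxon signed-rank test of a positive shift — a significant
result means the *majority* of subjects moved up. The signed-rank test is
implemented in the package: the null distribution of the positive-rank sum
is computed exactly (by convolution over sign assignments of the midranks,
valid under ties) whenever at most 20 nonzero differences remain, and by the
tie-corrected normal approximation (variance $\sum r_i^2/4$, no continuity
correction) beyond that. Zero differences are dropped by the usual Wilcoxon
convention; Pratt's zero-handling is available behind the `zeros` argument.
Subjects missing a threshold estimate at either cutoff are excluded with a
logged count; subjects absent from one arm altogether are an error, since
that indicates a pairing bug rather than missing data.

## What the simulation emulates

`sim_config()`/`run_study()` generate one subject's visits as correlated
multivariate normal outcomes: means cycle the block $(0, 0.5, 1, 1.5, 2)$
and variances the block $(1, 1.3, 1.6, 1.9, 2.2)$ up to length $t$
(truncating mid-block when $t$ is not a multiple of 5), and every
off-diagonal covariance is $\rho\,\sigma_l\sigma_s$ for a single $\rho$ — an
exchangeable-correlation structure on heterogeneous variances, checked for
positive definiteness at construction (it fails for sufficiently negative
$\rho$, e.g. $\rho \le -1/(t-1)$ with equal variances). Given $x_k$, the
response is Bernoulli: positive with probability $q$ above the true
threshold, negative with probability $q$ below it. The default grid is
$-2$ to $5$ in steps of $0.1$ ($m = 71$), about two standard deviations
beyond the extreme means, and the default thresholds/probabilities follow
the standard study lattice ($\rho \in \{0.3, 0.5, 0.8\}$,
$a \in \{-0.3, 0.4, 1.2\}$, $Q \in \{0.5,\dots,0.9\}$,
$t \in \{5, 10, 20, 40\}$, 10,000 replicates).

This emulates a repeated-measures trial with visit-specific drift and
spread and a *constant* revealing probability. It does not emulate
non-normal objective outcomes, learning or fatigue effects on the PRO,
missing visits, or between-subject heterogeneity in $Q$ — so passing
simulation checks demonstrate the estimator's behaviour under the stated
model, not robustness to violations of it.

Reproducibility: a configuration's seed initialises R's stream once and all
replicates are drawn in a single vectorized block, so identical seed and
configuration give bit-identical results (tested). We chose this over
per-replicate RNG streams because the estimator is embarrassingly
vectorizable and a single stream keeps the fast path and the reproducibility
contract identical.

Two operating characteristics are worth knowing. The max rule is biased
*upward* in small samples (selection bias of a maximum): at $t = 5$ the mean
estimate under the null $Q = 0.5$ is about 0.77, decaying toward 0.61 by
$t = 40$; the bias also depresses the CI's coverage in the $Q = 0.5$ column.
For $Q \ge 0.6$ the Clopper–Pearson interval is conservative (coverage at or
above the nominal 95%). The median rule at $Q = 0.5$ is nearly unbiased
(mean estimates 0.50–0.52 across the lattice). `convergence_table()` and
`plot_convergence()` reproduce the convergence-in-$t$ picture.

## Numerical and design choices

* Ties $x = a_j$ are positive, fixed by the 2×2 convention above.
* Tied maxima: median of the tied grid points, mean of the two middle
  points when even — forced by the tie convention of the toy example
  (ties at 10 and 11 give 10.5).
* The population t-interval, the half-up rounding under the median rule,
  the dropped zeros in the signed-rank test and the unclipped t-interval
  are the package's choices where the methodology leaves the detail open;
  each is surfaced as an argument where a user could defensibly want the
  alternative.
* Degenerate series (all-identical $x$, or constant $g$) are estimable with
  a warning, and the eligibility filter — PRO contains the dichotomized
  value and at least two distinct objective outcomes — is applied only at
  the population stage, on by default.
* Visit order is taken from the `visit` column, not file order; the
  statistics are order-invariant but reports should be stable. Duplicate
  (subject, visit) rows are an error.

The package's test suite exercises the estimator against brute-force
enumeration (random series up to $t = 8$ over grids up to $m = 12$), the
signed-rank exact branch against full sign-pattern enumeration, and the
interval against numeric inversion of the binomial tails. Monte-Carlo checks
in the routine suite run 800–1,200 replicates per cell with tolerances set
from their own Monte-Carlo standard errors; `scripts/acceptance.R` runs the
full 10,000-replicate study.

## Limitations

The method needs repeated paired measurements per subject and weakens
quickly for very small $t$ (the max-rule bias above); it assumes a
unidimensional PROM, equal revealing probabilities on both sides of the
threshold, and a non-negative association direction (transform $X$ first if
the association is negative). The latent threshold is only located up to the
grid resolution, and under the null there is no threshold to locate at all.
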