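---
title: "Intracluster correlation, design effects and sample-size inflation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intracluster correlation, design effects and sample-size inflation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustericc)
```

## The problem

In single-stage cluster sampling — the design of most multicenter health
studies, where hospitals are the primary sampling units and every eligible
patient of a participating hospital is enrolled — subjects within a
cluster resemble each other more than subjects drawn at random from the
population. The intracluster correlation coefficient
$$\rho \;=\; \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2}$$
quantifies that resemblance: the share of total outcome variance that
lies *between* clusters. $\rho = 0$ means clustering is ignorable;
$\rho = 1$ means each cluster is internally homogeneous, so a cluster
contributes no more information than a single subject. Because clustering
inflates the variance of estimated means and proportions, every analysis
and every sample-size calculation for a clustered design needs $\rho$ —
and the best source of plausible values is the catalogue of ICCs
published by earlier studies in the same field. `clustericc` implements
the estimation side (one-way ANOVA ICC for unbalanced clusters, binary or
continuous outcomes), the design side (design effects and sample-size
inflation), and bundles the 261-variable ICC catalogue published by the
Brazilian Multicenter Study on Preterm Birth (EMIP), a 20-hospital,
5,296-birth obstetric study (`load_emip_fixture()`).

## The estimator

For clusters $i = 1,\dots,a$ of sizes $n_i$ ($N = \sum_i n_i$), the
one-way ANOVA decomposition gives mean squares $MSB$ (between, $a-1$ df)
and $MSW$ (within, $N-a$ df), and the adjusted average cluster size
$$n_0 = \frac{N - \sum_i n_i^2/N}{a-1},$$
which equals the common size for balanced designs. Two classical ways of
writing the ANOVA ICC are exported, because both circulate in the
survey-sampling literature:

* **Kish's roh** (`icc_kish()`):
  $\rho = (s_a^2 - s_b^2/b)/\hat{s}^2$ with
  $\hat{s}^2 = s_a^2 + \frac{b-1}{b} s_b^2$. We evaluate it with the
  ANOVA mappings $s_a^2 = MSB/n_0$ (variance among cluster means on the
  element scale), $s_b^2 = MSW$, $b = n_0$.
* **The F computing formula** (`icc_from_F()`), the form used by survey
  software such as Stata's `loneway`:
  $\rho = \dfrac{(F-1)/n_0}{1 + (F-1)/n_0}$ with $F = MSB/MSW$, reading
  the reciprocal mean cluster size as $1/n_0$.

With these mappings both reduce algebraically to the textbook moment
estimator $(MSB - MSW)/(MSB + (n_0-1)MSW)$ — for *all* designs, not only
balanced ones. Rather than assuming the reconciliation, the test suite
verifies the three forms agree to $10^{-12}$ on a thousand random
datasets. The same ANOVA estimator is applied to 0/1 outcomes, where it
consistently estimates the pairwise within-cluster correlation — the
quantity the beta-binomial generator below fixes by construction.

Raw estimates can be negative (cluster means varying less than chance
predicts); they are truncated to 0 for reporting, matching the
`"<0.001"` floor used by the printed catalogues, and the raw value is
retained in `rho_raw` for diagnostics. When $MSW = 0$ the ICC is 1 by
definition and $F$ is reported as `Inf`.

## Confidence intervals

Two large-sample intervals are available from
`icc_confidence_interval()`:

* `"fpivot"` (default) pivots the variance-ratio statistic:
  $\left[\frac{F/F_u - 1}{F/F_u + n_0 - 1},\,
         \frac{F/F_l - 1}{F/F_l + n_0 - 1}\right]$,
  $F_u = F_{1-\alpha/2}(a-1, N-a)$, $F_l = F_{\alpha/2}(a-1, N-a)$
  (Searle-type; exact for balanced Gaussian data, approximate through
  $n_0$ otherwise).
* `"wald"`: $\hat\rho \pm z_{1-\alpha/2}\,\widehat{se}$, with Smith's
  (1956) asymptotic variance of the ANOVA ICC for unbalanced designs
  (the form reproduced in Donner's 1986 review); this asymptotic
  standard error is stored in the `se` field whichever interval is
  requested.

The default was a genuinely open choice, settled by measurement: in
Monte-Carlo experiments at the design scale of a 20-hospital study
(2,000 replicates per condition, $m = 265$, $\rho \in
\{0.01, 0.05, 0.1, 0.3\}$, Gaussian and beta-binomial outcomes) the Wald
form covered 89–92% at nominal 95% — with only $a - 1 = 19$ df behind
the between-cluster mean square, the normal approximation is slightly
too confident — while the F-pivot covered 93–96% in every condition.
Both bounds are truncated to $[0,1]$; a truncated lower bound of exactly
0 is rendered `"<0.001"`, the convention of the printed tables. Normal
quantiles are used in the Wald form with no small-sample $t$ correction,
consistent with its asymptotic derivation.

## Design effects and sample size

`deff_ratio()` computes the design effect as a variance ratio,
$$Deff = \frac{var_{actual}(r)}{var_{SRS}(r)},$$
with $var_{actual} = s_a^2/a$ — the with-replacement single-stage PSU
approximation, using the *unweighted* variance of cluster means (the
size-weighted linearized-totals estimator is available via
`weighted = TRUE`; the two coincide for balanced designs) — and
$var_{SRS} = s^2/N$ with the unbiased $N-1$ element-variance
denominator. No finite-population correction is applied: hospitals are
treated as sampled with replacement from a conceptual superpopulation of
centers. Unlike the planning approximation
$$Deff \approx 1 + (m-1)\rho, \qquad m = N/a,$$
(`deff_approx()`), the exact ratio can fall below 1 under negative
estimated intracluster correlation — the bundled catalogue contains such
rows (Deff 0.6–0.9) — which is why both are reported.

For planning, `srs_sample_size_proportion()` implements the closed form
$n = \lceil z_{1-\alpha/2}^2\, p(1-p)/d^2 \rceil$ and
`inflate_sample_size()` multiplies it by $1+(m-1)\rho$, with ceilings
throughout (a conservative design convention). The normal quantile is
computed exactly (`qnorm`), not via the two-digit 1.96: at $p = 6.5\%$,
$d = 0.25\%$, $\alpha = 0.05$ this gives $n = 37{,}355$ — the kind of
figure a protocol rounds to "about 37,000 deliveries".

## The synthetic multicenter generator

No subject-level data accompany published ICC catalogues, so the
estimators are validated by parameter recovery on synthetic data whose
true $\rho$ is known exactly:

* **Continuous** (`simulate_continuous()`): Gaussian random intercepts,
  $y_{ij} = \mu + u_j + e_{ij}$, $u_j \sim N(0, \rho\sigma^2)$,
  $e_{ij} \sim N(0, (1-\rho)\sigma^2)$; the population ICC is $\rho$ by
  construction.
* **Binary** (`simulate_binary()`): beta-binomial,
  $p_j \sim \mathrm{Beta}(\alpha,\beta)$ with mean $\pi$ and
  $\alpha+\beta = (1-\rho)/\rho$, subjects $\mathrm{Bernoulli}(p_j)$.
  This parameterization was chosen over logistic-normal random
  intercepts because its pairwise within-cluster correlation equals
  $\rho$ in closed form ($1/(\alpha+\beta+1)$), making recovery tests
  exact in expectation rather than approximate. $\rho = 0$ degenerates
  to independent Bernoulli draws; $\rho = 1$ is rejected (the
  parameterization degenerates).

`simulate_emip_like_study()` assembles a whole study: 20 clusters with
sizes drawn uniformly in $265 \pm 50\%$ (total $\approx 5{,}300$
subjects — exact per-center enrolment figures are not published, so
unbalance is emulated, not matched), about 30 variables spanning
prevalences 0.01–0.9 and true ICCs 0.005–0.95 (including a
betamethasone-like clinical-management variable at $\pi = 0.85$,
$\rho = 0.95$), eight continuous variables (birth-weight-like mean
2,321 g, gestational-age-like mean 34.5 wk, ...), and per-variable
missing-completely-at-random rates cycling over 0–60% so each variable
has its own analysable $N$, as in real multicenter tables. Missingness
is MCAR because no informative mechanism is documented for such tables.
Every generator is a pure function of its spec and seed.

What the generator deliberately does **not** emulate: regional
stratification of centers, informative missingness, within-subject
correlation across variables (each variable is drawn independently on
the shared design), and case–control subsampling. Passing recovery
tests therefore demonstrate estimator correctness under the stated
models, not robustness to those real-data features.

## Validation by simulation: what is run, at what size

The test suite and the acceptance script validate, end to end:

* exact agreement of the ANOVA sums with a brute-force double-loop
  oracle on small datasets, and the 9-point toy dataset
  ($MSB = 27$, $MSW = 1$, $F = 27$, $\rho = 26/29$);
* three-formula equivalence to $10^{-12}$ on 1,000 random balanced
  datasets;
* parameter recovery at the multicenter design scale — $a = 20$,
  $m = 265$, $\rho \in \{0.01, 0.05, 0.1, 0.3\}$, Gaussian and
  beta-binomial, 500 replicates per condition: mean estimate within
  $\pm 0.02$ of truth and 95% CI coverage within [90%, 98%];
* the exact Deff ratio averaging within 10% of $1+(m-1)\rho$ on
  balanced simulations ($a = 20$, $m = 100$);
* rare-outcome instability: at equal $\rho$ and design, the estimator's
  replicate standard deviation at $\pi = 0.01$ clearly exceeds that at
  $\pi = 0.3$ — the practical reason published ICCs for rare outcomes
  deserve caution.

These problem sizes (500 replicates, 20×265 designs) keep the whole
suite under a minute while leaving Monte-Carlo error well below the
tolerances being asserted.

## Numerical and convention choices

* $n_0$ uses the standard unbalanced one-way ANOVA adjusted cluster
  size; for balanced data it is the common size exactly.
* Censored catalogue entries (ICC printed `"<0.001"`) are stored as
  numeric 0 with a `censored` flag; since every aggregate reported by
  `summarize_icc()` is a median or a strict-threshold proportion, their
  sub-0.001 true values cannot change any reported statistic.
* Medians of an even number of values are the midpoint of the two
  central values (`stats::median`), matching hand-verification of the
  printed per-table medians; threshold proportions use strict `<` and
  are rounded half-up to one decimal.
* Mean cluster size $n_a$ is the variable's non-missing $N$ divided by
  the number of clusters contributing at least one observation,
  displayed rounded to the nearest integer.
* Degenerate inputs raise classed conditions
  (`clustericc_degenerate_error`) rather than propagating `NaN`:
  all-identical values, all-singleton clusters, or fewer than two
  clusters after missing-data removal. Batch estimation
  (`estimate_all()`) converts them into explicit `failure` rows, never
  silent drops.

## Limitations

Only the one-way ANOVA (moment) estimator is provided — no REML/mixed
models, no Bayesian intervals, and no ordinal outcomes beyond indicator
coding; these are deliberate non-goals. The F-pivot interval is exact
only for balanced Gaussian data; for heavily unbalanced or strongly
non-Gaussian data its coverage is approximate (validated here at the
multicenter design scale only). The bundled catalogue is a transcription
of printed, rounded values: it supports aggregate reproduction and
regression testing, not re-estimation of the underlying per-variable
ICCs, which would require the original subject-level records.
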