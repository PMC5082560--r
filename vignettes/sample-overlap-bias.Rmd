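---
title: "Weak-instrument bias from sample overlap: models, formulas, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-instrument bias from sample overlap: models, formulas, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mroverlap)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables (IVs) to estimate the causal effect of a risk factor $X$ on an
outcome $Y$ from observational data. Summarized-data MR combines, for each
variant, the variant–risk factor association $\hat\beta_{Xk}$ and the
variant–outcome association $\hat\beta_{Yk}$, usually taken from two
different consortia. When the two consortia share no participants
("two-sample" MR), weak-instrument bias acts *towards the null*; when they
are the same sample ("one-sample"), it acts *towards the confounded
observational association* and inflates false-positive rates. Real
consortia overlap partially, and this package quantifies what happens in
between.

The key empirical fact the package is built around: with a continuous
outcome, the expected bias of the IV estimate is **linear in the overlap
proportion**. Under the causal null,

$$\text{bias} \;=\; \hat\beta_{OLS} \times \omega \times \frac{1}{E(F)},$$

where $\hat\beta_{OLS}$ is the observational (confounded) slope, $\omega$
is the overlap proportion, and $E(F)$ is the *F parameter* — the
expectation of the first-stage F statistic, related to the concentration
parameter $\mu$ by $E(F) = \mu/K + 1$ for $K$ instruments. The relative
bias of a fully overlapping analysis is $1/E(F)$: an F parameter of 10
means 10% relative bias, so 50% overlap means 5% and 30% overlap means 3%.

Overlap is defined with respect to the **larger** dataset: only shared
participants correlate the two sets of association estimates, and extra
participants on either side dilute that correlation. If all 1,000
participants of a small exposure study are inside a 10,000-participant
outcome study, the overlap is 10%, not 100%.

## From bias to Type 1 error

A biased but approximately normal estimator with standard error
$\sigma$ rejects a two-sided test of size $\alpha$ with probability

$$2 - \Phi\!\left(z_{1-\alpha/2} - \tfrac{\text{bias}}{\sigma}\right)
    - \Phi\!\left(z_{1-\alpha/2} + \tfrac{\text{bias}}{\sigma}\right),$$

implemented in `type1_error()`. The printed constant 1.96 is generalized
to the exact $z_{1-\alpha/2}$, so the function is usable at any test size
and reproduces 1.96 at $\alpha = 0.05$. The expression is already
symmetric in the sign of the bias, which settles the behaviour for
negative bias without further convention.

The IV-estimate variance is approximated by

$$\widehat{\mathrm{var}} \;\simeq\; \frac{\mathrm{var}(R_Y)}{N\,
\mathrm{var}(X)\, \rho^2}
\qquad\text{(continuous)},\qquad
\frac{1}{N\, \mathrm{var}(X)\, \rho^2\, P(Y{=}1)P(Y{=}0)}
\qquad\text{(binary)},$$

where $R_Y$ is the outcome residual after removing the causal effect
(equal to $Y$ under the null), $N$ the outcome-sample size and $\rho^2$
the proportion of risk-factor variance explained by the IVs (estimated by
the first-stage $R^2$). `overlap_bias()` composes these pieces; the F
statistic and $R^2$ are interconvertible through
$F = \frac{N-K-1}{K}\frac{R^2}{1-R^2}$ (`f_from_r2()` / `r2_from_f()`).
When a caller supplies both an F value and an $R^2$, they are checked
against this relation at 1% relative tolerance and a disagreement is an
error — silently preferring one input would hide mistakes in units or
sample size.

**Units.** All formulas work in raw units when `var_x` / `var_ry` are
given; the defaults of 1 correspond to standard-deviation units. This is
the one place users most often go wrong, so it is an explicit argument
rather than an implicit convention.

**Accuracy at very weak instruments.** The composed pipeline reproduces
the simulated one-sample rejection rates closely for F parameters above
about 6, and its agreement with our own simulation study is within half a
percentage point for mean F of 14 and above. Below that, the normal
approximation (and the first-order variance) understate the inflation —
at mean F near 4 the pipeline predicts a rejection rate several points
below the empirical one. The calculator is a screening tool: if it
already signals inflation, the truth is at least as bad.

## Instrument strength: the F statistic is not the F parameter

The bias formulas need the F *parameter*, but any one dataset only shows
an F *statistic*, which is highly variable (equally sized substudies of
one dataset can show F statistics ranging from 3 to 23). Two mitigations
are implemented:

1. `project_f()` takes the $R^2$ (sample-size independent) from an
   external dataset and computes the F statistic implied at the sample
   size under analysis.
2. `f_param_ci_lower()` inverts the noncentral-F distribution to give a
   one-sided lower confidence limit for the F parameter: it solves for the
   noncentrality $\lambda_L$ at which the observed F sits at the chosen
   quantile of $F(K, N{-}K{-}1, \lambda_L)$ (monotone root-finding with
   `uniroot` on `pf`, bracket expansion, tolerance $10^{-8}$ on the
   quantile equation), then converts $\lambda_L$ to the F-parameter scale.
   Only the lower tail is of interest: a *stronger* instrument set than
   observed is not a bias concern.

**Conversion choice.** Two conversions from noncentrality to an
F-parameter scale are defensible: the exact noncentral-F mean
$\frac{df_2}{df_2-2}\cdot\frac{\lambda+df_1}{df_1}$, and the mode-type
approximation $\frac{\lambda + df_1 - 2}{df_1}$. For large $df_1$ they
are indistinguishable, but at $df_1 = 5$ they differ by several percent.
The package uses the second, which reproduces the published worked
examples for consortium-scale scores (lower limits 93.7, 14.0 and 2.3)
across $df_1$ from 5 to 97; the mean-based conversion matches only the
large-$df_1$ case. When even $\lambda = 0$ would place the observed F
below the target quantile, the limit is truncated at 1 — the approximate
expectation of a central F — and flagged, since negative noncentrality is
undefined.

## Estimators

- `mr_tsls()` implements split-sample two-stage least squares: first-stage
  coefficients from sample 1, fitted risk-factor values in sample 2 from
  sample-2 genotypes, second-stage regression of the sample-2 outcome on
  those fitted values (logistic for binary outcomes). Risk-factor
  measurements in sample 2 are never used, so overlap is expressed purely
  through shared individuals. Two standard-error conventions are offered:
  the default `"second_stage"` SE comes from the second-stage regression
  alone, the only residual information a genuine split-sample or
  summarized-data analysis has; `"textbook"` is the conventional
  one-sample 2SLS SE with structural residuals from the observed risk
  factor, the convention standard IV software reports. The two agree for
  strong instruments but diverge at weak ones, where the second-stage
  residuals overstate the error variance; the Monte Carlo harness uses the
  textbook convention for fully overlapping (one-sample) analyses and the
  second-stage convention otherwise, which is what each setting's
  practitioner would compute.
- `mr_ivw()` is the summarized-data workhorse: a fixed-effect
  meta-analysis of per-variant ratio estimates with first-order weights
  $\hat\beta_{Xk}^2/\mathrm{se}(\hat\beta_{Yk})^2$ — the exposure-side
  uncertainty is ignored, consistent with standard practice and validated
  by the mean-level agreement with 2SLS to 3 decimal places in our
  simulations (exact equality holds when instrument columns are exactly
  uncorrelated and the weights share a common residual variance).
- `mr_allele_score()` is the equally weighted allele-score analysis from
  summarized data, $\sum_k \hat\beta_{Yk} / \sum_k \hat\beta_{Xk}$, with a
  fixed-weight delta-method SE. Because its weights do not depend on the
  exposure associations estimated in the data under analysis, it is the
  overlap-robust fallback. Equal weights are sign-sensitive, so variants
  are re-oriented to a non-negative exposure association before summing.
- `per_variant_associations()` produces the summarized data a consortium
  would release, with the option to restrict exposure-side regressions to
  controls. Monomorphic variants are dropped with a warning (recorded in
  the `"excluded"` attribute) rather than failing the analysis.

## The data-generating models

The continuous-outcome generator (`simulate_continuous()`) draws, per
individual, $K = 20$ independent variants $g_{ik} \sim
\mathrm{Binomial}(2, 0.3)$, a standard-normal confounder $u_i$ and noise,
and sets $x_i = \alpha \sum_k g_{ik} + u_i + \varepsilon_{Xi}$,
$y_i = \beta_X x_i + \beta_U u_i + \varepsilon_{Yi}$. The defaults — 20
variants of MAF 0.3 with a common per-allele effect, 20,000 individuals of
whom 10,000 contribute to each association — are the package's reference
conditions; the per-allele effect $\alpha \in \{0.04, 0.06, 0.08\}$ spans
mean F statistics from about 4 to 14 at $N = 10{,}000$, the weak-to-decent
range where overlap matters. Closed-form moments used as oracles in the
tests: $\mathrm{var}(x) = 2 + 2K\alpha^2\,\mathrm{maf}(1-\mathrm{maf})$,
$\mathrm{cov}(x,y) = \beta_X \mathrm{var}(x) + \beta_U$,
$\mathrm{var}(y) = \beta_X^2\mathrm{var}(x) + 2\beta_X\beta_U + \beta_U^2
+ 1$.

Overlap is deterministic, not resampled: the exposure sample is always
individuals 1–10,000 and the outcome sample slides — 10,001–20,000 at 0%
overlap, 9,001–19,000 at 10%, down to 1–10,000 at 100%
(`overlap_slices()`; indices are 1-based inclusive in R, translating the
sampling plan verbatim).

The binary generator (`simulate_binary_cc()`) replaces the outcome line
with $\mathrm{logit}\,\pi_i = -3 + \beta_X x_i + \beta_U u_i$, simulates a
population of 100,000 and keeps the first 5,000 cases and first 5,000
controls in generation order ("first" meaning generation order, not a
random subsample). The intercept $-3$ gives a population prevalence near
4.7% under the null, so the case quota is comfortably met; a shortfall is
an error reporting achieved counts, not a silent truncation.

What these generators deliberately do *not* model: linkage disequilibrium
between variants, MAF or effect-size variation across variants, pleiotropy
or invalid instruments, measurement error in the risk factor, or
population structure. Tests passing under these conditions show that the
estimators and calculators behave as the theory predicts in the idealized
regime the theory addresses; they do not certify behaviour under invalid
instruments (out of scope here).

## The Monte Carlo harness

Replication is seed-laddered: each grid cell derives a seed from the base
seed plus its parameter values, and replicate $r$ uses cell seed $+ r$, so
any single replicate or subgrid is reproducible in isolation
(`run_continuous_cell()`, `run_overlap_grid()`, `run_null_validation()`,
`run_binary_validation()`). Summaries report the Monte Carlo standard
error `mc_se` $= \mathrm{sd}/\sqrt{n}$ and stochastic tests use
$3\,$`mc_se` tolerances rather than fixed constants.

Problem sizes are a package choice balancing resolution against desk-scale
runtimes: the shipped tests use 1,000–2,500 replicates for continuous
cells (`mc_se` about 0.001–0.006; the larger counts where the quantity
under test is a small ratio or a rejection rate near 1/3), 500–1,000 for
binary cells, and 2,000 simulated F statistics for the confidence-limit
coverage check, all at the reference sample sizes above. The full 198-cell overlap grid at 10,000 replicates is
available through `run_overlap_grid()` but is not exercised by default.

`balance_point()` locates the overlap at which the attenuation-towards-null
and pull-towards-confounding cancel for a non-null causal effect, by a
least-squares line of mean estimate on overlap (more stable than
piecewise interpolation at modest replication); no crossing inside
$[0,1]$ returns `NA` with a message. The balance point depends on the
strength of confounding and on the causal effect itself, so it is
descriptive, not a design target.

## Known limitations

- The analytic Type 1 error is an underestimate for F parameters below
  about 6 (see above); inference methods that do not assume normality of
  the IV estimate (Fieller, Anderson–Rubin) are the remedy at that
  extreme, and are out of scope.
- The binary-outcome estimand is a population-averaged log odds ratio;
  non-collapsibility means estimators are compared under the null, where
  all are consistent.
- The F-parameter confidence limit is anchored to the published worked
  examples; alternative noncentrality-to-mean conversions differ at small
  $df_1$ and there is no universally agreed convention.
- Winner's-curse effects of discovering variants in an overlapping sample
  are a distinct (and additive) problem not modelled here.
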