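---
title: "Estimating selection on composite traits with reduced-rank regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection on composite traits with reduced-rank regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsel)
```

## The problem

Phenotypic selection on a small set of well-defined traits is routinely
measured by regressing relative fitness (individual fitness divided by the
population mean) on the traits: the partial slopes are selection gradients.
Floral scent breaks this recipe. A scent blend is a high-dimensional,
strongly collinear set of volatile emission rates, often with more
compounds than can be stably entered into a multiple regression at typical
field sample sizes, and with no a-priori reason to think pollinators
attend to any single compound rather than a combination.

`rrsel` treats the blend as a *composite trait*: a learned linear
combination of the volatiles, estimated jointly with the selection
gradient acting on it. For individual $i$ with relative fitness $w_i$,
standard traits $x_{ik}$ (morphology, phenology), and standardized
volatiles $z_{il}$,

$$
w_i \;=\; \alpha \;+\; \sum_{k} x_{ik}\,\beta_k
\;+\; \sum_{k \le r}\Big(\sum_{l} v_{kl}\, z_{il}\Big)\,\beta^{a}_{k}
\;+\; \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),
$$

where $r$ is the model rank (1 by default: a single "scent selection
axis"), the weights $v_{kl}$ define the axis, and $\beta^a_k$ is the
selection gradient on it. With the axis reported at unit norm, the
gradient on axis $k$ projects back onto the original compounds as
$\beta^*_l = \sum_k v_{kl}\,\beta^a_k$, giving per-compound selection
estimates despite the dimension reduction. With $r$ equal to the number
of volatiles the model spans the full multiple regression, which is the
package's main internal consistency check.

Gaussian error on relative fitness is an approximation — fitness proxies
such as fruit counts are nonnegative and often overdispersed — but it is
the assumption under which regression slopes are interpretable as
selection gradients, and it is what the package implements. No random
effects are included.

## Sampler and priors

All full conditionals are conjugate, so fitting uses a Gibbs sampler
(implemented in C++): given the weights the model is linear in the
intercept and all slopes (joint normal update); given the slopes it is
linear in each axis's weight vector (normal update per axis); the
residual variance is inverse-gamma. Priors are independent
$N(0, \tau_\beta^2)$ on the intercept and slopes over standardized
covariates, $N(0, \tau_v^2)$ on the raw weights, and
inverse-gamma$(0.01, 0.01)$ on $\sigma^2$, with $\tau_\beta = \tau_v = 1$
by default. On the standardized covariate scale and with relative fitness
as the response (SD typically 0.2–0.5), a unit prior SD is weak at the
sample sizes of field selection studies (tens to low hundreds of
individuals) while keeping wide, collinear volatile blocks numerically
stable; in the multiple-regression baseline it acts as mild ridge
regularization. Defaults are 2 chains of 1000 warmup plus 1000 retained
draws; a warning is raised when any split-R-hat exceeds 1.1.

## Identification of the bilinear term

The axis term $(\mathbf{v}, \beta^a)$ is identified only up to sign and
scale: $(c\mathbf{v}, \beta^a/c)$ and $(-\mathbf{v}, -\beta^a)$ give the
same likelihood. Three post-processing steps make posterior summaries
meaningful, none of which changes predictions:

1. **Scale**: each draw's weight vector is rescaled to unit norm, the
   axis slope absorbing the magnitude.
2. **Sign (draws)**: draws are flipped to have nonnegative dot product
   with the element-wise median weight vector, iterating the median until
   stable (at most 25 passes; ties at exactly zero count as aligned).
   Summaries of weights, axis slope, and credible intervals use these
   aligned draws.
3. **Sign (support)**: the *posterior support* statistic is computed
   from draws that are **not** per-draw aligned. Within a chain, the
   sampler wanders between the two sign modes when the data carry little
   directional information and locks into one mode when they do; that
   switching *is* the evidence, and per-draw alignment would erase it
   (pushing null supports toward 1). What is arbitrary is which mode a
   chain starts in, so whole chains (never individual draws) are
   oriented to the median aligned direction before computing support.
   Under no selection the support then sits near 0.5; under strong
   selection it approaches 1.

Support itself is sign-consistency: $\max(P(\beta > 0), P(\beta < 0))$,
with exact zeros split equally. For a continuous posterior the naive
$P(|\beta| > 0)$ would always be 1; sign-consistency reproduces the
intended 0.5-at-null behaviour.

Ranks above 1 are supported (and used internally for the full-rank
check), but individual axes of a rank-$r$ fit are rotationally
non-identified; only quantities invariant to rotation, such as
back-projected compound gradients and predictions, should be interpreted.

## Reporting scales

Raw gradients depend on measurement units, so the package reports, per
draw and then summarized:

* $\beta_\sigma = \beta \times SD(\mathrm{trait})$ — variance-scaled,
  the change in relative fitness per SD of trait; the scale on which
  selection strength is compared across traits and studies.
* $\beta_\mu = \beta \times \overline{\mathrm{trait}}$ — mean-scaled,
  the change in relative fitness per proportional change in trait;
  meaningful only for ratio-scale traits, so it is reported for standard
  traits and (after back-projection) for volatile emission rates, but
  *not* for the scent axis, which has no natural zero.

For the axis, $\beta_\sigma$ uses the realized SD of that draw's axis
scores (with the $n-1$ denominator); whether an analytic SD would be
preferable is moot for reporting since the two agree closely, and the
realized-score version is exact for the sample at hand. The posterior SD
of each quantity serves as its standard error; intervals are equal-tailed
95% quantile intervals, which always contain the posterior median (the
mean can escape only under extreme skew).

## Model evaluation

Explanatory $r^2$ is the squared Pearson correlation between
posterior-mean in-sample predictions and observed relative fitness — the
same definition as the cross-validated version, so the two are
comparable. Predictive $r^2$ uses $k$-fold cross-validation (5 folds by
default): the *entire* fit, including weight estimation and the
covariate standardization constants, is redone on each training set, so
no information leaks from held-out rows; held-out predictions are pooled
before correlating. Relative fitness itself is defined on the full
dataset (it is the response, not part of the model). Folds are simple
unstratified random partitions, assigned after sorting rows by
individual id so the result is invariant to row order; the fold seed is
a required argument. Method agreement $r_\beta$ is the Pearson
correlation between per-compound mean-scaled gradients from the
reduced-rank fit (via back-projection) and from the multiple-regression
baseline.

In-sample, the multiple-regression model always explains at least as
much variance as the rank-1 model (it nests it); out-of-sample the
ordering often reverses, which is the argument for the dimension
reduction.

## Variation of selection across datasets

For a compound measured in $D$ datasets with posterior-mean mean-scaled
gradients $\hat\beta_d$ and posterior variances $SE^2_d$, the
among-dataset variance corrected for sampling error is the moment
estimator

$$
\sigma^2_{\beta,c} \;=\; \mathrm{Var}(\hat\beta_d) \;-\;
\overline{SE^2_d},
$$

with the $n-1$ sample variance. The estimate can be negative (datasets
agree more than their uncertainty predicts); the variance column reports
it honestly, while the SD column truncates at zero before the square
root, since a reported dispersion must be real. Mean-scaled gradients
are the meta-analyzed quantity: their dispersion reads in units of the
strength of selection on fitness itself. Compounds are matched across
datasets by column name; a compound present in fewer than two datasets
is skipped with a log message, and one present in a subset is analyzed
over that subset — the least wasteful rule when volatile panels differ
between studies.

## The synthetic-data generator

Every statistical claim the test suite makes is evaluated on data from
`simulate_dataset()`, so what it does (and does not) emulate bounds what
the tests show.

* **Volatiles**: $\log$-scale factor model, $\exp(\mu + \Lambda f + e)$
  with 3 latent factors, loadings $N(0, 0.6^2)$ and noise SD 0.5 —
  right-skewed, all-positive emission rates whose correlation comes from
  a few shared axes, mimicking biosynthetically linked compound
  families.
* **Standard traits**: multivariate normal, exchangeable correlation
  0.3, mean 10 and SD 2 (arbitrary ratio-scale units so that
  mean-scaling is exercised).
* **Fitness**: $w = 1 + \beta^a s + \sum_k \beta_k x^{(std)}_k +
  \varepsilon$ with the true composite score $s$ standardized, so the
  generating gradients are variance-scaled by construction; residual SD
  0.3. Defaults emulate a typical single study: $n = 80$, 3 standard
  traits, 22 volatiles, axis gradient 0.15 (about the across-study
  average strength of selection on scent blends), standard-trait
  gradients 0.1.
* **Collections**: `simulate_study_collection()` shares the true axis
  across datasets and draws each dataset's gradient from
  $N(\beta^a_{base}, \tau^2)$, the generative counterpart of
  $\sigma^2_{\beta,c}$.

Gaussian fitness is the default because it is the analysis model's own
error structure; a Poisson fruit-count mode exists as a robustness
check, not as the primary condition. Because Gaussian noise around a
mean of 1 can dip below zero, simulated datasets may contain (rare,
slightly) negative fitness values; the file loader accepts these only
when the schema says so explicitly, and otherwise enforces the
nonnegativity that real fruit counts and mass proxies obey. The
generator does **not** emulate measurement-batch effects, censored or
zero-inflated emissions, phenological covariance between scent and
flowering time, or pollinator behaviour; passing tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to those features of real field data.

The loader is deliberately agnostic about volatile pre-processing
(log-transformation, standardization by total emission): conventions
differ between labs, and the right transformation is a measurement
question the analysis cannot settle. Values are used on the scale
provided. Missing data are handled by listwise deletion — the norm in
selection analysis — never by imputation; zero-variance volatile columns
are dropped with a warning, and every drop is recorded in a cleaning
log.

## Numerical choices and degenerate inputs

* Conditional draws use Cholesky factorization of the precision matrix;
  a non-positive-definite conditional (impossible for valid inputs)
  aborts with an error rather than a silent repair, as does any
  non-finite sampler state, which is reported with its iteration number.
* All randomness flows through R's RNG; one `set.seed()` per fit drives
  both chains sequentially, so identical seeds give bit-identical draws,
  summaries and output files.
* Effective sample sizes use the combined-chain autocorrelation series
  with Geyer-style paired-sum truncation (lags capped at 500);
  split-half R-hat uses two halves per chain. A parameter with zero
  variance across draws reports `NA` R-hat rather than dividing by
  zero.
* Zero-variance predictions in $r^2$ computations return 0 with a
  warning instead of `NaN`.
* An axis slope drawn exactly at 0 makes that axis's weight conditional
  revert to its prior — the correct limit, not a special case.

## Problem sizes used by the checks

The statistical acceptance checks in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R` use: 20 datasets ($n = 200$, 6 volatiles) for
the full-rank equivalence, compared with a conservative
3-Monte-Carlo-SE bound appropriate for a 120-way maximum and under weak
priors (prior SD 10), where the identity holds exactly; 200 replicate
studies ($n = 200$, 8 volatiles, gradient 0.3, 500 warmup + 500 draws)
for interval coverage and axis recovery; 100 null replicates for support
calibration; 500 direct-simulation replicates for the
$\sigma^2_{\beta,c}$ estimator, which isolates the moment estimator from
MCMC noise; these sizes give stable results while keeping a full run in
tens of seconds on one CPU.

## Known limitations

* Linear (directional) selection only; quadratic and correlational
  gradients are out of scope.
* Gaussian likelihood on relative fitness; no GLM fitness models, random
  effects, or spatial/phylogenetic structure.
* Rank > 1 fits lack rotational identifiability of individual axes.
* The support statistic depends on the sampler visiting both sign modes
  under weak signal; with very long warmup and extremely strong priors a
  chain could in principle lock spuriously, which the R-hat warning
  would flag.
* Published point estimates from other implementations of the same model
  are expected to agree only approximately, since prior choices and
  covariate scaling conventions differ between packages.
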