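---
title: "Methylation clocks and EWAS: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation clocks and EWAS: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammclock)
```

# The model

An epigenetic clock is a sparse linear model on methylation beta values.
For sample $i$ with probe vector $x_i \in [0,1]^p$ and transformed age
$y_i = F(a_i)$, the clock solves the elastic-net problem

$$\hat b_0, \hat b \;=\; \arg\min \;
\frac{1}{2n}\sum_i (y_i - b_0 - x_i^\top b)^2
+ \lambda\Big(\alpha\lVert b\rVert_1 + \tfrac{1-\alpha}{2}\lVert b\rVert_2^2\Big),$$

with the mixing parameter fixed at $\alpha = 0.5$ — the midpoint between
ridge and lasso, which keeps the model sparse while letting groups of
correlated CpGs share weight. $\alpha$ is deliberately not tuned: tuning
it on the same cross-validation used to assess accuracy would make the
accuracy optimistic. The penalty $\lambda$ is chosen by internal 10-fold
cross-validation *within each training set* (`cv_select_lambda()`), at the
minimum of the out-of-fold mean squared error ("lambda.min"); this is the
prediction-oriented choice, and a 1-SE-style alternative can be emulated
from the returned CV curve. An estimated age is the inverse transform of
the linear predictor, so accuracy is always reported in years.

## Age transforms

Three transforms of the dependent variable are supported, all strictly
increasing and exactly invertible:

* **identity** — used for single- and dual-species elephant blood clocks,
  where one species' age range does not need rescaling;
* **log-linear** — $F(a) = \log\frac{a+1}{m+1}$ for $a \le m$ and
  $\frac{a-m}{m+1}$ above, with $m$ the species' *adult age*. The two
  branches meet with equal slope $\tfrac{1}{m+1}$ at $m$, so $F$ is
  continuous and once-differentiable. It expands the juvenile age range,
  where methylation changes fastest, making young-animal errors
  comparable across species in a multi-species clock;
* **relative** — $a/\mathrm{maxLifespan}$, a dimensionless age in $[0,1]$
  that gives multi-species clocks a biologically comparable scale.

Adult ages and maximum lifespans are per-species configuration entries
with no shipped "truth": the defaults used in examples (adult age 15 for
elephants, 20 for humans; maximum lifespans 85 and 122) are conventional
values, and the maximum lifespan serves purely as a mathematical parameter
of the prediction model. Which transform a given clock uses is itself
configuration: identity for the pure elephant clocks, log-linear for the
multi-species chronological clock, relative for the relative-age clock.

## The solver

The coordinate-descent core (`enet_fit()`, in C++) follows the
conventions of the reference implementation of the field: loss scaled by
$1/(2n)$ so $\lambda$ is comparable across sample sizes, predictors
standardized with the population ($1/n$) standard deviation, the
intercept unpenalized, soft-threshold updates
$b_j \leftarrow S(\rho_j, \lambda\alpha) / (v_j + \lambda(1-\alpha))$,
warm starts down a log-uniform 100-point penalty path from
$\lambda_{\max} = \max_j |x_j^\top y|/(n\alpha)$, and a final full sweep
that verifies the KKT conditions so the returned solution optimizes the
stated objective and not a screened approximation. Convergence is
declared when the largest absolute coefficient change in a sweep falls
below `tol` ($10^{-7}$ for every fit whose coefficients are returned).

Two throughput choices matter at cross-validation scale and are the
package's own trade-offs:

* *CV fold fits* use a looser tolerance ($10^{-4}$) and deviance-based
  path early-termination (stop when the deviance ratio improves by less
  than $10^{-5}$ relative per step, or exceeds 0.999): these fits only
  rank penalties, and the ranking is insensitive to the last decimals of
  the coefficients. Where a fold's path stops early, its last solution is
  carried forward — by the stopping rule those fits would differ
  negligibly.
* The full-data refit is truncated at the selected penalty, since
  coefficients below it are never used.

One caveat worth knowing when comparing against glmnet: glmnet internally
standardizes the response, which implicitly rescales its *ridge* penalty
by $\mathrm{sd}(y)$. For $\alpha < 1$ and $\mathrm{sd}(y) \ne 1$ glmnet's
solution therefore does not minimize the objective above exactly —
`mammclock`'s does (the suite verifies this against an independent
box-constrained L-BFGS optimizer on the nonnegative-split reformulation).
The two agree to $10^{-6}$ when $y$ has unit population variance.

## Cross-validation schemes

`loocv()` omits one sample at a time; the held-out sample never enters
standardization, penalty selection, or the coefficients (it needs
$n \ge 11$ so the internal 10-fold selection fits inside every training
split). `lofo10()` is 10-fold with species-stratified folds: within each
species, fold sizes differ by at most one from exact proportionality, and
which folds receive the remainders is randomized under the seed. With 83
Asian and 57 African samples every fold holds 8–9 Asians and 5–6
Africans. Reported metrics are the Pearson R between chronological age
and DNAm age and the *median* absolute error in years (robust to the few
very old animals).

Epigenetic age acceleration defaults to the raw difference
DNAm age − age, matching the verbal definition used with these clocks;
the residual from regressing DNAm age on age is also provided since the
human literature favors it (it is mean-zero and age-uncorrelated by
construction).

# EWAS

Age EWAS is a marginal Pearson correlation screen per probe:
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided $p$ from the $t_{n-2}$
distribution — identical to the univariate-regression p-value — and a
signed normal-scale statistic $z = \mathrm{sign}(r)\,\Phi^{-1}(1-p/2)$.
Cohorts are combined by Stouffer's method,
$z_\mathrm{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with
$w_i = \sqrt{n_i}$ (the standard sample-size weighting; equal weights are
a switch). Top CpGs are selected at $p < 10^{-5}$ — more stringent than
5% FDR, less than Bonferroni, appropriate because neighbouring CpGs are
strongly correlated — then ranked by $|z|$ within each direction and
capped at 500 per direction, with lexicographic probe-id tie-breaks so
the selection is deterministic and order-free.

The sex screen fits `beta ~ sex + age` per probe by ordinary least
squares on the beta scale (df $n-3$) and reports the sex coefficient;
the interaction screen adds `sex:age` (df $n-4$). OLS on bounded beta
values is a pragmatic convention (an M-value analysis would be the
variance-stabilized alternative); calibration under the null is verified
by simulation rather than assumed. Cross-species concordance labels a
probe *shared* when both cohorts pass the threshold with agreeing signs
and *divergent* when they pass with opposite signs; the threshold is the
same $10^{-5}$ in both cohorts and configurable, and probes absent from
either cohort are excluded and counted.

# The synthetic generator

`simulate_methylation()` emulates the data the pipeline targets. For
sample $i$, probe $j$:

$$\mathrm{logit}(\mu_{ij}) = \beta_{0j} + s_j\, g_j(a_i)
 + \delta^{sex}_j \mathbb{1}[F]
 + \delta^{sp}_j \mathbb{1}[\text{non-reference species}]
 + \varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with betas the inverse logit clipped to $[0.001, 0.999]$. $g_j$ is either
$a/a_{\max}$ or $\log(a+1)/\log(a_{\max}+1)$ (half of age probes each),
so some probes change fastest early in life, as observed on real arrays.
Age-probe signs follow the annotation: probes in CpG islands or promoters
gain methylation with age with probability `cgi_hyper_bias` (default
0.8), others lose it — reproducing the observed directionality (global
hypomethylation with age, promoter/island hypermethylation). Sex probes
sit on one scaffold (`"X_like"`), mirroring the X-chromosomal clustering
of sex-differential CpGs. Background baselines are drawn bimodally (most
CpGs are nearly un- or fully methylated); effect probes get moderate
baselines so their effects are not saturated by the clipping.

The `clocklike` preset encodes the study conditions used throughout the
tests: 83 + 57 animals of two species with female fraction 0.8, age
ranges 2.36–73.6 and 1.20–48.5 years, 2,000 probes with 200 age probes,
half-normal age-slope magnitudes with scale 1.5 logit units per unit
transformed age, and residual logit noise 0.4 — strong, clock-grade
signal. Ages are uniform within range by default; a `zoo_skew` option
weights mid-life to mimic managed-population age pyramids. The `null`
preset (60 samples, 500 probes, all effects zero) drives calibration and
leakage checks.

What the generator does **not** emulate: probe-level SNP confounding,
batch and chip effects, between-probe correlation beyond shared age
dependence, heteroskedastic measurement error near the beta boundaries,
and real minor-allele methylation distributions. Passing recovery tests
on this generator therefore demonstrates the *correctness of the
machinery* (no leakage, calibrated tests, faithful optimization), not
that real elephant data will yield a given R.

# Numerical choices and degenerate inputs

* Ties in penalty selection resolve to the larger (sparser) $\lambda$.
* Zero-variance predictors are excluded from the penalized set with
  coefficient 0; a zero-variance response yields an intercept-only model
  with a warning rather than an error.
* $\lambda_{\max}$ is nudged up by $10^{-9}$ relatively so the head of
  the path is exactly the null model despite floating-point rounding.
* Inverse transforms clamp negative ages to 0 with a warning.
* Probes missing from a prediction matrix are an error unless imputation
  by stored training means is explicitly enabled; betas outside $[0,1]$
  are rejected at read time, never coerced.
* Clock JSON uses 17 significant digits, so doubles round-trip
  bit-faithfully.
* All fold assignments, forests and simulations derive from explicit
  seeds; package functions restore the caller's RNG state.

Problem sizes in the shipped tests are chosen to keep the full suite
inside a normal desk run: the full-scale study conditions (140 × 2,000
LOOCV, 10,000-probe calibrations, $10^5$-permutation oracle) run once in
the acceptance suite, while per-module tests use down-scaled versions of
the same presets.

# Known limitations

* **LOOCV under a true null is ill-behaved.** When the data carry no age
  signal, the selected model is empty or nearly so, and each left-out
  prediction is (approximately) the training mean $(S - y_i)/(n-1)$ —
  which correlates with the held-out value at exactly $-1$ by
  construction. With a handful of spurious coefficients the artifact
  dilutes, but at $n = 60$ the null LOOCV R is typically strongly
  negative and occasionally strongly positive: across 20 null replicates
  we observed R from $-1.0$ to $+0.66$ with median near $-0.4$ (the same
  behaviour reproduces with cv.glmnet). A LOOCV R near zero should
  therefore *not* be expected under the null; large positive R on real
  data remains meaningful because the artifact's sign is negative and its
  magnitude collapses as soon as predictions acquire real variance. The
  acceptance suite records this property honestly rather than asserting
  a bound the estimator cannot meet.
* OLS on beta values inherits boundary heteroskedasticity; M-values or
  beta regression would be principled alternatives for the sex screens.
* The concordance rule (both cohorts at $p < 10^{-5}$) is conservative;
  borderline probes land in `not_significant` rather than being
  half-classified.
* The elastic-net CpG *set* is not stable under resampling (correlated
  probes trade places); only predictions are. Published clock CpG lists
  should be treated as one representative solution, not a unique
  biomarker panel.
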