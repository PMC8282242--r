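# mammclock

Build and validate DNA-methylation age estimators ("epigenetic clocks")
and run epigenome-wide association studies (EWAS) on mammalian methylation
array data — the workflow used to derive blood epigenetic clocks for Asian
and African elephants and to compare their methylation aging with humans.

Field measurements of elephant age (tooth wear, morphometrics, dung bolus
size) are subjective and often wildly wrong, which matters for demographic
models underlying conservation. Methylation fractions (beta values) at
conserved CpGs change predictably with age, so a sparse penalized
regression on a few dozen CpGs can estimate age to within a few years from
a blood sample.

## What the package implements

* **Elastic-net clock training** — gaussian elastic net (mixing
  `alpha = 0.5`) fit by a bespoke cyclic coordinate-descent solver with a
  glmnet-style penalty path; the penalty is selected by internal 10-fold
  cross-validation. For observations $(x_i, y_i)$ the solver minimizes

  $$\frac{1}{2n}\sum_i (y_i - b_0 - x_i^\top b)^2
    + \lambda\Big(\alpha\lVert b\rVert_1
    + \tfrac{1-\alpha}{2}\lVert b\rVert_2^2\Big).$$

* **Age transforms** — the dependent variable is chronological age
  (single- and dual-species clocks), log-linear transformed age
  ($\log\frac{a+1}{m+1}$ below the adult age $m$, linear with matched
  slope above), or relative age $a/\mathrm{maxLifespan}$, all exactly
  invertible so predictions are reported in years.

* **Cross-validation** — leave-one-sample-out (LOOCV) and
  species-stratified 10-fold (LOFO10, fold sizes within one sample of
  exact species proportionality); metrics are the Pearson correlation R
  between DNAm age and chronological age and the median absolute error in
  years. Epigenetic age acceleration (difference or residual) and its
  cross-clock correlations are provided.

* **EWAS** — per-probe marginal Pearson correlation tests
  ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, signed $z$), Stouffer meta-analysis
  across cohorts with $\sqrt{n}$ weights, top-CpG selection
  ($p < 10^{-5}$, up to 500 per direction by $|z|$), cross-species
  shared/divergent concordance labels, genomic-context summaries
  (TSS-distance bins, CpG-island status), and age-adjusted sex and
  sex-by-age interaction screens.

* **Integrity classifiers** — random-forest predictors of species and sex
  with out-of-bag error, used to catch plate-map mix-ups.

* **Synthetic data** — a generator for mammalian-array-like datasets with
  known ground truth (age/sex/species effects on the logit scale), so the
  entire pipeline is testable without access to restricted animal data.

## Worked example

```r
library(mammclock)

# two-species elephant-like dataset: 83 + 57 animals, 2,000 probes of
# which 200 carry a true age signal
d <- simulate_methylation(sim_preset("clocklike", seed = 1))

# leave-one-sample-out cross-validation of the dual-species clock
cv <- loocv(d$beta, d$samples, age_transform("identity"), seed = 1)
cv
#> Clock cross-validation: n = 140, R = 0.968, MAE = 3.25 years

# train on the full data and inspect the clock
clock <- train_clock(d$beta, d$samples, age_transform("identity"), seed = 1)
clock
#> Epigenetic clock: 145 CpGs, alpha = 0.5, lambda = 1.132
#>   transform: identity | trained on 140 samples (african_elephant, asian_elephant)

ages <- predict_age(clock, d$beta, d$samples)

# per-species age EWAS and meta-analysis
asian <- d$samples$species == "asian_elephant"
rows_as <- correlation_screen(d$beta[, asian], d$samples$age_years[asian])
rows_af <- correlation_screen(d$beta[, !asian], d$samples$age_years[!asian])
meta <- ewas_meta(list(asian = rows_as, african = rows_af))
top <- select_top(data.frame(probe_id = meta$probe_id,
                             p = meta$p_meta, z = meta$z_meta))
```

The cross-validated R of about 0.97 and median error of about 3 years say
that on data with this signal strength the clock orders animals almost
perfectly by age and is typically within one reproductive season of the
truth — accuracy in the range needed for demographic work.

The whole workflow (confidence filter, classifiers, CV, training, EWAS,
meta-analysis, concordance, context summary) also runs as one call:

```r
cfg <- run_config(beta = d$beta, samples = d$samples,
                  annotation = d$annotation, out_dir = "run1",
                  cv_scheme = "lofo10", seed = 1)
bundle <- run_full_pipeline(cfg)
```

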