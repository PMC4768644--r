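# stochtrans

Partitioning stochastic population dynamics into asymptotic and
transient components.

## The problem

Structured plant populations live in variable environments. Their
dynamics are classically summarized by the asymptotic growth rate of a
projection matrix — the dominant eigenvalue λ_max of the annual matrix
**A** in the model **x**(t+1) = **A**(t) **x**(t). But whenever the
current stage structure **x**(t) deviates from the stable stage
structure **w** (the dominant right eigenvector of **A**(t)), the
realized one-step growth differs from λ_max: the population *booms*
(transient amplification) or *busts* (transient attenuation). Per time
step the observed growth factorizes as

    λ_obs(t) = ‖A(t)x(t)‖₁ / ‖x(t)‖₁ = λ_max(t) · reactivity(t)

with `reactivity(t) = ‖ (A(t)/λ_max(t)) · x(t)/‖x(t)‖₁ ‖₁`, which is
additive on the log scale:

    log λ_obs(t) = log λ_max(t) + log reactivity(t)

Because the two components can act in opposite directions, the net
decomposition hides antagonism — strong-but-opposing forces look like
weak ones. The *absolute dynamic*

    log λ_abs(t) = |log λ_max(t)| + |log reactivity(t)|

separates these cases, and `|log reactivity| / log λ_abs` is the share
of the absolute dynamic contributed by transients.

`stochtrans` implements this decomposition end to end for comparative
analyses across many populations:

* eigen-analysis and ergodicity diagnostics for projection matrices
  (`dominant_eigenvalue`, `stable_structure`, `is_ergodic`);
* the stochastic simulation protocol — equal starting stage abundances,
  i.i.d. uniform matrix draws, a 500-step burn-in, and one measured
  step per replicate (`simulate_population`);
* per-population variance partitioning: the squared Pearson
  correlations of log λ_obs with each component, and the mean transient
  share of the absolute dynamic (`variance_explained`,
  `transient_proportion`, `summarize_population`);
* a generator of synthetic plant-demography databases with controlled
  statistical structure (`generate_database`), plus a long-format CSV
  exchange for external matrix collections (`read_matrix_csv`);
* hierarchical comparative models: logit-transformed proportion
  responses regressed on growth form and matrix dimension with a
  species random intercept, an intercept-only "boom tendency" test,
  and reactivity–growth association tests (`fit_contribution_model`,
  `boom_test`, `association_test`);
* a one-call pipeline with a reproducible report bundle
  (`run_pipeline`), also exposed as a command-line script in
  `inst/scripts/stochtrans-pipeline.R`.

## Worked example

A two-stage matrix with λ_max = √2 projected from a structure
concentrated in the first stage shows exact antagonism: asymptotic
growth and transient attenuation cancel in net growth but add in the
absolute dynamic.

```r
library(stochtrans)
A <- matrix(c(0, 1, 2, 0), 2, 2)
decompose_step(A, c(1, 0))
#> <step_decomposition>
#>   log lambda_obs : +0.00000  (net growth)
#>   log lambda_max : +0.34657  (asymptotic)
#>   log reactivity : -0.34657  (transient)
#>   log lambda_abs :  0.69315  (absolute dynamic)
```

A small comparative study on a synthetic database:

```r
db   <- generate_database(generator_config(n_species = 20, seed = 2024))
kept <- apply_inclusion_filters(db)$populations
sim  <- simulate_database(kept, n_replicates = 1000, burn_in = 500,
                          seed = 2024)
summ <- sim$summaries
round(colMeans(summ[, c("r2_asym", "r2_trans", "prop_abs_trans",
                        "mean_log_reactivity")]), 3)
#>             r2_asym            r2_trans      prop_abs_trans mean_log_reactivity
#>               0.731               0.446               0.342               0.002
```

On average across these 46 populations, variation in λ_max explains 73%
of the variance in net stochastic growth and reactivity 45% (the shares
need not sum to 1 — the components covary), and transients contribute
34% of the absolute dynamic. The boom test asks whether mean
log-reactivity is centred on zero across populations:

```r
boom_test(summ)
#>     parameter estimate  lower95  upper95 p_value important
#> 1 (Intercept) 0.002101 0.000529 0.003674 0.01193      TRUE
```

The interval excludes zero: these populations boom slightly more than
they bust. The contribution model for the transient share of absolute
dynamics fits one intercept per growth form plus a shared
matrix-dimension slope:

```r
fit_contribution_model(summ, "prop_abs_trans")
#>                         parameter estimate   lower95 upper95   p_value important
#> 1 growth_formherbaceous_perennial  -1.4108 -2.183625 -0.6379 0.0006761      TRUE
#> ...
#> 6                matrix_dimension   0.1446  0.003175  0.2860 0.0453129      TRUE
```

The positive `matrix_dimension` slope (logit scale) says populations
modelled with more life stages have more of their absolute dynamics
contributed by transients.

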