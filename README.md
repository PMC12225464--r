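# patroldetect

Conditional Bayesian modelling of violation occurrence and detectability in
enforcement-patrol records.

## The problem

Enforcement agencies log every patrol action — region, targeted actor,
species, regulation, patrol time, group size — together with a binary
outcome: was a violation detected? That outcome confounds two processes:
whether a violation was **present**, and whether the patrol **detected** it
given presence. An empty-handed patrol may mean compliance or may mean a
missed offence, and the two call for opposite management responses.

`patroldetect` separates them with a conditional hierarchical model, in the
spirit of occupancy models with imperfect detection. For patrol `i`:

```
y_i ~ Bernoulli(P_i),   P_i = p_i * s_i,   s_i ~ Bernoulli(v_i)

logit(p_i) = mu_p + b1*T_i + b2*N_i + b3[region] + b4[actor] + b5[year]
logit(v_i) = mu_v + b6[violation type] + b7[species]
```

`v_i` is the probability a violation is present, `s_i` its latent
indicator, and `p_i` the conditional detection probability
("detectability"). `T` (patrol minutes) and `N` (enforcer count) are
min–max scaled to [0, 1]; categorical factors use treatment coding against
a reference level. All coefficients carry uniform priors on [-2.2, 2.2]
(about 10%–90% on the probability scale). The latent `s_i` is marginalised
analytically — `P(y=1) = v*p` — and the posterior is explored with an
adaptive Metropolis sampler written in C++.

The package covers the full pipeline: validated CSV I/O and category
handling, a synthetic-data generator that executes the two-stage Bernoulli
process from known ground truth, multi-chain MCMC with split-chain Rhat and
effective-sample-size diagnostics, WAIC model comparison across predictor
assignments, posterior-predictive classification with an F1-optimal
threshold sweep, and posterior reporting (per-category log-odds ratios with
effort shares, annual detectability series, headline probabilities), with
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## A worked example

Simulate records from known ground truth, fit, and evaluate:

```r
library(patroldetect)

cfg <- paper_like_config(n_records = 5000, seed = 1,
                         n_regions = 4, n_actors = 4,
                         n_species = 6, n_violations = 3)
records <- simulate_records(cfg)
mean(records$outcome)
#> [1] 0.102

fit <- sample_posterior(records, seed = 2)   # 3 chains x (600 + 2400)
compute_rhat(fit)
#> <convergence_report: max Rhat = 1.0144, PASS (threshold 1.10)>

head(tidy(fit))
#> # A tibble: 6 x 7
#>   term                   estimate std.error conf.low conf.high  rhat   ess
#>   <chr>                     <dbl>     <dbl>    <dbl>     <dbl> <dbl> <dbl>
#> 1 mu_p                    -1.59       0.245   -2.07     -1.10   1.00  242.
#> 2 b1_time                  1.72       0.319    0.985     2.18   1.00  479.
#> 3 b2_enforcers            -1.23       0.366   -1.94     -0.465  1.00  441.
#> 4 b3_region[Tarapaca]      0.197      0.189   -0.173     0.559  1.01  482.
#> 5 b3_region[Antofagasta]  -0.0356     0.197   -0.425     0.362  1.00  489.
#> 6 b3_region[Atacama]       1.10       0.188    0.745     1.48   1.01  459.
```

The ground truth here has a time slope of +1.79 and a group-size slope of
-1.52; both posterior intervals cover them, and every Rhat is below 1.1.

Detections are rare (~10% of patrols above), so the F1-optimal
classification threshold sits well below the conventional 0.5:

```r
preds <- posterior_predict(fit, records, thin = 4)
sweep <- threshold_sweep(preds$.pred, records$outcome)
best_threshold(sweep)
#> [1] 0.21

confusion_and_scores(classify(preds$.pred, best_threshold(sweep)),
                     records$outcome)
#> Model prediction (rows) vs dataset outcome (columns):
#>               outcome
#> prediction     Not detected Detected
#>   Not detected         3969      196
#>   Detected              521      314
#> precision = 0.3760  recall = 0.6157  specificity = 0.8840  F1 = 0.4669

headline_summary(fit, records, thin = 4)
#> # A tibble: 3 x 3
#>   quantity       mean    sd
#>   <chr>         <dbl> <dbl>
#> 1 detectability 0.286 0.232
#> 2 violation     0.359 0.294
#> 3 overall       0.102 0.137
```

`headline_summary()` reports the across-record means of detectability `p`,
violation probability `v`, and their product — the overall chance a patrol
records a violation, which matches the empirical detection rate.
`summarize_categories(fit, records, "actor")` and
`annual_detectability(fit, records)` give the per-category log-odds-ratio
tables and the annual detectability series; each has an `autoplot()`
method. `fit_model_ladder()` compares predictor assignments by WAIC, from
the null model up to the full structure.

See `vignettes/conditional-detectability.Rmd` for the model's assumptions,
the generator's design, and the package's numerical conventions.

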