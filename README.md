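# swipr

Similarity-weighted informative priors for Bayesian multiple regression.

## The problem

Informative priors let a focal study borrow strength from previously
conducted studies — but previous studies differ in their samples, their
predictors, and their results. Borrowing from a heterogeneous body of
background knowledge as if it were a set of direct replications biases the
focal estimates; refusing to borrow wastes real knowledge. swipr quantifies
*how similar* K previous studies are to the focal study and uses that
similarity as the weight of the informative prior.

The similarity measure for coefficient *p* is

ω_p = B̄ · L / (1 + exp[ s·(τ²_p + δτ²_p − ω₀) ]),   L = 1, ω₀ = 0.24, s = 10

where

* **B̄** is the average generalizability index: per previous study, a
  logistic sampling-propensity model separates the two samples, and B_k is
  the Bhattacharyya overlap ∫√(f_f f_k) of the two propensity-score
  densities (1 = identical samples, 0 = disjoint);
* **τ²_p** is the between-study heterogeneity of the coefficient's Fisher-z
  partial-correlation effect size from a hierarchical Bayesian
  random-effects meta-analysis;
* **δτ²_p** = max(0, τ² − τ²_res) is the extra heterogeneity explained by
  study-level moderators under the matching mixed-effects model.

The weighted prior enters the regression y ~ N(β₀ + Xβ, σ²) as
β_p ~ N(μ_p, SE²_p)^{ω_p}, implemented exactly as N(μ_p, SE²_p / ω_p):
ω = 1 uses the meta-analytic prior at full strength, ω → 0 flattens it
away. Comparator arms are included: the pooled non-informative analysis,
the normalized power prior (NPP, conjugate normal-inverse-gamma with a
uniform random borrowing weight), and the robust meta-analytic predictive
prior (MAP).

## Worked example

```r
library(swipr)

params <- sim_params()                      # focal beta (0.5, 0.25, -0.5), meta means (0.4, 0, 0.3)
cond   <- sim_grid(levels_k = 5, levels_dn = -100,
                   levels_dmu = 0.5, levels_tau2 = 0.05)[1, ]
focal  <- simulate_focal(params, seed = 1)
db     <- simulate_database(cond, params, seed = 2)

bb <- generalizability_index(focal, db)
glance(bb)
#>   b_bar     k min_b max_b
#> 1 0.901     5 0.886 0.914

hs <- heterogeneity_summaries(db, mcmc = mcmc_config(seed = 3))
w  <- similarity_weights(hs, bb)
w
#>   predictor   tau2 delta_tau2 b_bar omega
#> 1         1 0.0252          0 0.901 0.807
#> 2         2 0.0821          0 0.901 0.747
#> 3         3 0.0232          0 0.901 0.808

fit <- fit_swip(focal, swip_prior(hs, w), mcmc = mcmc_config(seed = 4))
tidy(fit)
#>   term        estimate std.error  median  rhat   ess
#> 1 (Intercept)  -0.0856    0.0831 -0.0861  1.00 4364.
#> 2 x1            0.484     0.0686  0.485   1.00 4017.
#> 3 x2            0.205     0.0738  0.205   1.00 4325.
#> 4 x3           -0.195     0.0648 -0.195   1.00 2709.
#> 5 sigma         1.17      0.0637  1.16    1.00 1749.
```

The samples overlap strongly (B̄ = 0.90) and the effect sizes are only
mildly heterogeneous, so ω ≈ 0.75–0.81 and the prior borrows substantially:
x3's focal-study value is −0.5 but its meta-analytic mean is +0.3, and the
posterior mean −0.195 is pulled far toward the background knowledge —
exactly the similarity-driven shrinkage the weight is designed to produce.
Had the previous samples been shifted (Δ_μ = 3) or the effects scattered
(τ² = 0.5), ω would collapse toward 0 and the fit would stay at the
focal-only estimates. `fit_pooled()`, `fit_npp()` and `fit_map()` run the
comparators on the same data; `run_condition()` / `run_study()` orchestrate
the full simulation design (210 conditions; 21,000 datasets at 100
replications) and `behavior_models()` summarizes how ω tracks
heterogeneity, sample shift and shrinkage.

See `vignettes/swip-methods.Rmd` for the models, hyperpriors, numerical
choices, and the generator's assumptions.

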