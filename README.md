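# mgwrdim

Multiscale geographically weighted regression (MGWR) and a three-dimension
classification of geographic disparity, for county-scale ecological analysis
of spatially varying associations between area characteristics and a health
outcome rate (e.g. opioid use disorder diagnoses per 1,000 beneficiaries).

A global regression assumes every association is the same everywhere. MGWR
relaxes that twice over: associations may vary across space, and each
covariate may operate at its own spatial scale. The package provides the
full modeling chain:

* **Composite indices** — first-principal-component deprivation/isolation
  indices with semantic sign anchoring, and mean-of-z indices
  (`pca_index()`, `mean_index()`).
* **Global baseline** — OLS on standardized variables with VIF diagnostics
  and hat-trace AICc (`fit_ols()`, `vif()`, `model_aicc()`).
* **GWR engine** — adaptive bisquare kernel, local weighted least squares
  `(X'WᵢX)⁻¹X'Wᵢy`, hat matrix, AICc-minimizing golden-section bandwidth
  search (`fit_gwr()`, `select_bandwidth()`).
* **MGWR** — back-fitting of the additive model `y = Σⱼ fⱼ + ε` with a
  per-variable bandwidth, per-variable effective parameters ENPⱼ, corrected
  local inference, and a Monte Carlo permutation test for spatial
  non-stationarity (`fit_mgwr()`, `monte_carlo_test()`).
* **Dimensions of disparity** — per covariate: *level of influence*
  (population-weighted share of units with a significant local estimate;
  > 50% ⇒ primary influencer), *scalability* (bandwidth > 0.75 n ⇒ global,
  < 0.25 n ⇒ local, else regional), and *specificity* (the covariate with
  the strongest absolute local association in each unit)
  (`dimension_report()`).
* **Synthetic generator** — datasets with known constant / gradient / bump
  coefficient surfaces so every stage is testable without restricted claims
  data (`simulate_dataset()`, `synthetic_preset()`).

## Worked example

```r
library(mgwrdim)

sim <- simulate_dataset(synthetic_preset())   # n = 400, 6 covariates
ols <- fit_ols(sim$data)
fit <- fit_mgwr(sim$data)
mc  <- monte_carlo_test(sim$data, fit, n_perm = 99, seed = 1)
mgwr_table(fit, mc)
```

```
     variable   mean    sd    min median    max bandwidth    enp mc_p_value
1 (Intercept)  0.011 0.004  0.002  0.012  0.016       400  1.696       0.95
2   const_pos  0.555 0.006  0.544  0.555  0.565       400  1.549       0.88
3   const_neg -0.436 0.008 -0.451 -0.436 -0.424       400  1.557       0.77
4      grad_x -0.071 0.272 -0.481 -0.071  0.398        69 13.966       0.01
5      grad_y  0.022 0.334 -0.432 -0.028  0.605       102  9.100       0.01
6    bump_pos  0.256 0.373 -0.173  0.110  1.348        29 33.299       0.01
7    bump_neg -0.139 0.252 -1.055 -0.060  0.202        34 29.875       0.03
```

The two constant-surface covariates are fitted at the maximal bandwidth
(400 = n) with near-zero spread across units and null Monte Carlo p-values
— stationary, global associations. The gradient and bump covariates select
much smaller bandwidths, show wide local-estimate ranges, and the
permutation test rejects stationarity (p ≤ 0.03). Model comparison on the
same run: `ols$aicc` = 933.97 (adj. R² 0.409) vs `fit$aicc` = 410.14 — the
multiscale model fits this heterogeneous data far better.

```r
dimension_report(fit, sim$data)
```

```
     variable bandwidth scalability_class influence_share influence_class dominance_count dominance_share
1 (Intercept)       400            global              NA            <NA>              NA              NA
2   const_pos       400            global           100.0         primary             266            66.5
3   const_neg       400            global           100.0         primary               0             0.0
4      grad_x        69             local            73.7         primary               0             0.0
5      grad_y       102          regional            84.8         primary              20             5.0
6    bump_pos        29             local            28.9       secondary              80            20.0
7    bump_neg        34             local            12.7       secondary              34             8.5
```

`const_pos` is significant everywhere (influence 100%, primary) and, having
the largest absolute coefficient in 266 of 400 units, dominates specificity;
the bump covariates influence only the minority of the population living
inside their pockets (secondary) and classify as local-scale. Dominance
counts always sum to n.

An end-to-end run (descriptives → OLS → MGWR → Monte Carlo → dimensions,
all artifacts as CSV plus a MANIFEST) is

```r
run_pipeline(pipeline_config(preset = synthetic_preset(), seed = 1), "out_dir")
```

and a thin CLI wrapper lives at `inst/scripts/mgwr_pipeline.R`.

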