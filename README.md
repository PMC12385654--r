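# berrystore

Storage-quality modelling and multi-objective optimization of storage
conditions for fresh wolfberry (*Lycium barbarum* L.).

Fresh wolfberry deteriorates quickly after harvest: thin skin, high sugar and
water content, and vigorous respiration. How hard the fruit stays, how much
soluble sugar (SSC), titratable acid (TA) and vitamin C (Vc) it retains all
depend jointly on **storage temperature** (−4 to 24 °C), **storage time**
(0 to 28 d) and the **initial maturity at harvest** (20 to 90 %).
`berrystore` implements, end to end, the analysis pipeline used to study and
optimize that dependence:

1. **Optimized Latin hypercube design** — an individual-based multi-objective
   evolutionary algorithm (LHS-MOEA) that evolves permutation-encoded Latin
   hypercubes towards two space-filling objectives, the maximin pairwise
   distance and the centered L2 discrepancy. The sample-size rule
   *n* = 2(*N* + 1)(*N* + 2) gives the 40-run design for *N* = 3 factors.
2. **Surrogate quality models** over normalized factors
   *x* = (*x*ᵢ − *x*ᵢ,min)/(*x*ᵢ,max − *x*ᵢ,min):
   a Gaussian **RBF network** *y*ⱼ = Σᵢ *w*ᵢⱼ exp(−‖*x* − *c*ᵢ‖²/2σ²) with one
   center per training point and analytic (ridge-regularized) output weights,
   an **Elman recurrent network** *x*(k) = f[W₁ *x*c(k) + W₂ *u*(k)],
   *x*c(k) = *x*(k − 1), *y*(k) = g[W₃ *x*(k)] trained by truncated dynamic
   backpropagation, and a full **quadratic response surface** (10-term basis,
   OLS). The surfaces published for this system ship as `eq15_surfaces()`.
3. **Sensitivity decomposition** — main-effect curves (mean response as one
   factor sweeps its range, averaged over a low-discrepancy background of the
   others) and signed Pareto term contributions
   |*b*ₜ| / Σ|*b*| × 100 of each polynomial term.
4. **SMPSO storage optimization** — speed-constrained multi-objective particle
   swarm (constriction factor χ(φ), velocity clamp, crowding-bounded Pareto
   archive, polynomial mutation) maximizing all four predicted quality
   responses over the condition box, with fixed-storage-time scenario queries
   and automatic knee-point selection.
5. **Data** — the packaged 40-run experiment (`load_table2()`), plus synthetic
   generators: quadratic-surface data with Gaussian noise
   (`generate_from_rsm()`) and stage-wise kinetic profiles anchored at the
   observed peaks (SSC/Vc at 8 °C; hardness/Vc at day 4; SSC/TA at day 8;
   `generate_kinetic_profiles()`).

Quality metrics follow the study's definitions: RMSE, centered R², MAPE and
range-normalized NRMSE (`fit_metrics()`), plus the maturity-index
calibrations and the titration formula for TA.

## Worked example

```r
library(berrystore)

# the packaged 40-run storage experiment
t2 <- load_table2()

# quadratic response surface fitted to it
fit <- fit_quadratic_rsm(t2)
glance(fit)
#>   response r.squared  nobs
#> 1 hardness     0.666    40
#> 2 ssc          0.341    40
#> 3 ta           0.436    40
#> 4 vc           0.185    40
```

The training R² values show that the printed responses scatter strongly
around any smooth surface — an honest feature of this dataset that the
methods vignette discusses in detail.

```r
# which terms drive hardness, and in which direction?
tc <- term_contributions(eq15_surfaces())
head(dplyr::arrange(dplyr::filter(tc, response == "hardness"),
                    dplyr::desc(percent)), 3)
#>   response term  percent  sign
#> 1 hardness x1       37.2    -1
#> 2 hardness x1^2     18.1     1
#> 3 hardness x2^2     12.5    -1
```

Storage temperature (`x1`) dominates hardness and acts negatively — warmer
storage means softer fruit.

```r
# optimal conditions when the fruit must be stored for 10 days
scenario_query(eq15_surfaces(), time_days = 10,
               config = smpso_config(12, 50, seed = 1))
#>   temperature time maturity hardness   ssc    ta    vc ideal_distance
#> 1      -0.908   10       20    2261. 14.55 1.572 16.89          0.883
```

The swarm freezes time at 10 d, maximizes all four predicted qualities over
temperature and maturity, and returns the knee of the Pareto archive in raw
units (here on the published polynomial surfaces; pass trained `rbf_train()`
/ `elman_train()` models for the network-based pairing).

```r
# an optimized 40-point design is markedly more uniform than random LHS
uniformity_report(optimize_design(40, 3, moea_config(seed = 1)))
#> Design uniformity report
#>   min pairwise distance  : 0.15685
#>   centered L2 discrepancy: 0.04008
#>   Latin bins occupied once: yes
```

`run_pipeline(pipeline_config(...))` chains all stages (data → split →
surrogates → metrics → sensitivity → SMPSO → scenarios) under one master
seed and `write_report()` serializes the result as a CSV/JSON bundle.

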