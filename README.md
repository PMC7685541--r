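# powerforest

Stable random-forest feature selection and simulation-based power analysis
for biomarker discovery in tabular omics data (metabolomics, lipidomics,
transcriptomics, or any samples-by-features matrix with a continuous or
two-class outcome).

Single fits of a random forest give unstable importance rankings, so a
variable that tops the list once may vanish on the next bootstrap.
`powerforest` addresses this with two modules:

* **Module 1 — stability selection.** Four selection algorithms built on
  unscaled permutation importance — Boruta shadow-variable testing,
  outcome-permutation significance testing (raw and Benjamini–Hochberg
  corrected), and recursive feature elimination — run inside a nested
  cross-validation loop: four outer rotations (75:25 train/test, every
  sample held out exactly once), hyperparameters tuned on an inner tuning
  slice, and 100 independently seeded selection iterations per rotation.
  Variables selected in > 5/100 iterations form the *low-stringency* (LS)
  stable set; ≥ 90/100 the *high-stringency* (HS) set. Validation forests
  restricted to each stable set are scored on the held-out folds.

* **Module 2 — power analysis.** A multivariate log-normal model fitted to
  the candidate biomarkers preserves their correlation structure; synthetic
  cohorts drawn from it support Monte-Carlo power estimation per variable.
  Effect sizes are estimated automatically (Pearson *r* against a continuous
  outcome, Cohen's *d* = |μ₁ − μ₂| / s_pooled between two classes), highly
  correlated variables are grouped (single linkage at |r| ≥ 0.8) and
  represented by their largest-effect member, and power(n) over a
  sample-size grid yields a sample-size recommendation for each candidate
  biomarker group. Power for a target with effect *r* at size *n* is the
  fraction of replicates in which the target or one of its correlated
  partners is significant (simple regression, or one-way ANOVA for two
  groups, at α = 0.05).

A built-in simulation module generates benchmark data with six correlated
predictor groups `V_i^(j) = x_i + (0.01 + 0.5(j−1)/9)·N(0, 0.3)` and the
nonlinear outcome
`y = 0.25·e^{4x₁} + 4/(1+e^{−20(x₂−0.5)}) + 3x₃ + N(0, 0.2)`,
so selection quality can be scored against known ground truth (V1–V30
informative, V31–V60 correlated decoys, the rest noise).

## Worked example

```r
library(powerforest)

## simulate a small benchmark: 200 samples, 300 predictors,
## six correlated groups of ten
sim <- simulate_uniform(sim_config(n_obs = 200, p_total = 300, seed = 1))

## nested-CV stability selection with Boruta and RFE (reduced iteration
## count for the example)
plan <- nested_cv_plan(n_iterations = 20, ls_threshold = 1, hs_threshold = 18,
                       seed = 1)
rep <- run_stability(sim, methods = c("boruta", "rfe"), plan = plan,
                     task = "regression", n_trees = 100)
rep
#> <stability_report> regression - 300 variables, 20 iterations x 4 rotations
#>   boruta         LS:  29 vars  HS:  20 vars  (HS TP/FP: 20/0)
#>   rfe            LS:  30 vars  HS:  18 vars  (HS TP/FP: 18/0)

## power analysis of the six correlated groups plus one noise variable
X <- sim$X[, c(paste0("V", 1:60), "V300")]
pow <- power_analysis(X, sim$y, mode = "regression",
                      n_grid = c(10, 25, 60, 140, 225, 500),
                      reps = 200, seed = 1)
pow
#> <power_report> regression mode, 7 representative variable(s), 200 Monte-Carlo reps
#>   V1         effect 0.800 (large): n >= 10 for power 0.8
#>   V19        effect 0.428 (small): n >= 60 for power 0.8
#>   V25        effect 0.261 (small): n >= 140 for power 0.8
#>   V40        effect -0.054 (negligible): power 0.8 not reached on grid
#>   V47        effect 0.109 (negligible): n >= 500 for power 0.8
#>   V55        effect -0.088 (negligible): power 0.8 not reached on grid
#>   V300       effect 0.054 (negligible): power 0.8 not reached on grid
```

Reading the output: at high stringency Boruta recovers exactly the twenty
clearly informative variables (groups 1 and 2) with no false positives, and
RFE recovers eighteen of them; the liberal low-stringency sets add the
weaker group-3 variables. The power module detects the seven correlated
groups (six simulated plus the noise singleton), estimates each
representative's effect size against the outcome, and reports the smallest
simulated cohort size reaching 80% power — about 10 samples for the strong
group-1 representative (r ≈ 0.80), about 60 for the group-2 representative
(r ≈ 0.43), about 140 for the group-3 representative (r ≈ 0.26), and no
attainable n on this grid for the decoy groups whose effects are
indistinguishable from zero.

The same pipeline is available from the shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "powerforest.R", package = "powerforest"))')" \
  simulate --out sim.csv --n-obs 200 --p-total 300 --seed 1
# ... select / stability / power subcommands; see the header of the script
```

Every run writes a JSON provenance record with the resolved configuration
and seed; identical configurations produce byte-identical outputs.

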