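# teamjudge

Combining the judgments of humans and machines on forced-choice tasks —
and measuring whether the team beats its best member.

A human expert panel and a set of machine classifiers (image networks
reporting class probabilities, language models choosing the
lower-perplexity candidate) each judge the same items and report a
confidence. When confidence is *calibrated* (higher confidence, higher
accuracy) and the members are *diverse* (they err on different items), a
combined team can surpass every individual — including the case where
the humans are the weakest members. `teamjudge` provides:

- **A confidence-weighted logistic combination model** for any number of
  teammates and classes. Each member contributes a signed-confidence
  predictor: magnitude = that trial's confidence (rating *r*, class score
  *π*, or absolute perplexity difference |Δq|), sign = the choice. Binary
  tasks use `p = 1 / (1 + exp(−(β_I + Σ_k β_k x_k)))`; multiclass tasks
  use the conditional-logit extension with shared member weights. A
  no-confidence variant (all magnitudes set to 1) is the
  wisdom-of-the-crowds foil, and a per-member squashing transform
  `f(x) = 1 + (x−1)/(1+α|x−1|)` with grid-selected α protects against
  miscalibrated members.
- **A two-member Bayesian combination model**: correlated bivariate-normal
  latent scores per item and class (means `b + (a−b)·1[z=j]`, member
  scales σ, correlation ρ), a temperature-softmax choice likelihood and
  an ordered-logistic confidence likelihood with breakpoints *c* and
  sharpness δ. Posterior inference by adaptive Metropolis with the human
  latents integrated out by Gauss–Hermite quadrature; label prediction by
  Bayes' rule over posterior draws.
- **The evaluation protocol**: leave-one-item-out cross-validation that
  holds out *all* observations of an item, enumeration of all 2^K − 1
  team subsets, shuffle controls (accuracy must fall to 1/L), Welch and
  paired t comparisons, binomial standard errors.
- **Diagnostics** for the two complementarity conditions:
  equal-count-bin calibration curves with their slopes, and pairwise
  Spearman correlations of per-item difficulty profiles.
- **A synthetic panel generator** with controllable accuracy, confidence
  calibration, and inter-agent diversity (a shared item-difficulty
  factor with per-agent loadings), so the whole pipeline runs without any
  external dataset.

## Worked example

A benchmark-shaped synthetic panel: 100 binary items, three
perplexity-based language-model judges (target accuracies
0.70/0.72/0.75, difficulty loading 0.8) and one pooled human expert
population (target accuracy 0.65, loading 0.3, 2–9 observations per
item).

```r
library(teamjudge)

panel <- make_brainbench_like(seed = 1)
panel
#> Judgment panel: 100 items, 2 classes, 870 records
#>   llm_small      machine_perplexity 100 records
#>   llm_mid        machine_perplexity 100 records
#>   llm_large      machine_perplexity 100 records
#>   human          human_continuous   570 records

loocv(panel, "human")
#> Team [human] (logistic): accuracy 0.6246 +/- 0.0203 SEM over 570 evaluations
loocv(panel, "llm_large")
#> Team [llm_large] (logistic): accuracy 0.7800 +/- 0.0414 SEM over 100 evaluations

loocv(panel, team_spec(c("human", "llm_mid", "llm_large")))
#> Team [human + llm_mid + llm_large] (logistic): accuracy 0.8105 +/- 0.0164 SEM over 570 evaluations
```

The weakest member still helps: the human–machine team (0.81) beats the
best machine alone (0.78). Dropping confidence (`use_confidence = FALSE`,
a weighted vote) gives 0.7842 on the same panel — trial-by-trial
confidence is doing real work. The fitted weights show each member's
contribution per unit of signed confidence:

```r
coef(logit_combiner(panel, c("human", "llm_mid", "llm_large")))
#> (intercept)       human     llm_mid   llm_large
#>      -0.016       0.578       1.048       0.981
```

Both complementarity conditions are visible in the diagnostics:

```r
calibration_curve(panel, "human", n_bins = 5)$slope   # 0.104 (> 0: calibrated)
diversity_matrix(panel)
#>           llm_small llm_mid llm_large human
#> llm_small     1.000   0.349     0.323 0.191
#> llm_mid       0.349   1.000     0.356 0.039
#> llm_large     0.323   0.356     1.000 0.165
#> human         0.191   0.039     0.165 1.000
```

Machines correlate with each other more than with the human — the human
brings diversity. The Bayesian pair model is available through
`fit_bayesian(panel, team_spec(c("human", "llm_large"), combiner =
"bayesian"))` followed by `predict()`; see the vignette in
`vignettes/combining-judgments.Rmd` for the model's assumptions,
identifiability discussion, and every tunable default.

A thin CLI wraps the same functions:

```sh
exec/teamjudge simulate --out panel_dir --seed 1
exec/teamjudge evaluate --panel panel_dir --out results/run --teams all
exec/teamjudge diagnose --panel panel_dir --out results/diag.json
```

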