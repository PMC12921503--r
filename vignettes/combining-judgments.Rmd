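---
title: "Combining human and machine judgments: models, protocol, and synthetic panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining human and machine judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamjudge)
```

## The problem

A team of judges -- human raters and machine classifiers -- each answer the
same forced-choice questions and report how confident they are. Two
conditions make a combined team better than its best member: *calibration*
(higher confidence goes with higher accuracy for each member) and
*diversity* (members err on different items). `teamjudge` implements two
combination models that exploit both, an item-grouped cross-validation
protocol for evaluating every team subset, diagnostics for the two
conditions, and a synthetic panel generator so that the whole pipeline can
be exercised and stress-tested without access to proprietary judgment
datasets.

## The confidence-weighted logistic combination model

Each team member $k$ contributes one predictor per trial: the *signed
confidence* $x_{i,j,k}$, whose magnitude is the member's confidence on
trial $i$ and whose sign says whether class $j$ was their choice. For a
human with rating $r_i$, $x_{i,j,H} = r_i$ if class $j$ was chosen and
$-r_i$ otherwise. For a probabilistic classifier with class scores
$\pi_{i,j}$, $x_{i,j,M} = \pm\pi_{i,j}$, each class keeping its own score
magnitude. A language model judging two candidate texts chooses the one
with lower perplexity, and its confidence is the absolute perplexity
difference $|\Delta q_i|$; its scores are $\mathrm{Softmax}(-q)$.

For binary tasks the model is a logistic regression on the class-0 signed
confidences,

$$p_x = \frac{1}{1 + e^{-\beta^\top x}}, \qquad
  \beta^\top x = \beta_I + \sum_k \beta_k x_{i,0,k},$$

where $p_x$ is the predicted probability of the (arbitrarily assigned)
first option. The fitted weight $\beta_k$ absorbs both the member's
accuracy and the scale of their confidence, which is why confidences are
ingested raw, with no normalization. Optional extensions add an
interaction column $x_H x_M$ or polynomial columns $x_k^2, \dots$

For more than two classes the package uses the minimal faithful
generalization, a conditional logit: evidence
$\mathrm{ev}_j = \sum_k \beta_k x_{i,j,k}$ with member weights shared
across classes and a softmax over $j$. A shared intercept cancels in the
softmax and is therefore omitted; per-class intercepts are available
(`per_class_intercept = TRUE`) but off by default, since nothing in the
binary form suggests class-specific offsets and the synthetic truth is
exchangeable across classes.

**Fitting.** The ridge-penalized log-likelihood is maximized by damped
Newton iterations (binary) or BFGS with the analytic gradient
(multiclass), always from zero -- fits are deterministic. The default
ridge of $10^{-4}$ on member and extra weights (never the intercept)
keeps weights finite on separable leave-one-out folds; complete
separation at ridge 0 is flagged as non-convergence, never silent.
Convergence is declared at a relative log-likelihood change of $10^{-8}$
(at most 500 iterations). Exact probability ties at prediction time break
to the lowest class index and are counted.

**The no-confidence foil.** With `use_confidence = FALSE` every magnitude
is replaced by 1 and only signs remain: a weighted vote, the
wisdom-of-the-crowds baseline. Comparing it with the standard model
isolates the contribution of trial-by-trial confidence.

**Calibration squashing.** The per-member transform
$f(x) = 1 + (x-1)/(1 + \alpha |x-1|)$ interpolates between the identity
($\alpha = 0$) and a constant 1 ($\alpha \to \infty$). A member who is
accurate but whose confidence is noise should be driven toward the
sign-only regime; `fit_alpha()` selects each member's $\alpha$ on a grid
by inner leave-one-out accuracy on the training split only, resolving
ties toward the smaller $\alpha$. The default grid `c(0, 1, 16)` spans
identity, mild squashing, and the near-vote regime; a coarse grid is
deliberate, because inner-LOOCV accuracy resolves only differences of
order $1/M$ and a fine grid just picks noise.

## The two-member Bayesian combination model

For a human--machine pair on a binary task, latent probability scores per
item $i$ and class $j$ are correlated bivariate normals

$$\begin{pmatrix}\pi_H\\ \pi_M\end{pmatrix} \sim
  \mathcal N\!\left(\begin{pmatrix}\mu_H\\ \mu_M\end{pmatrix},
  \begin{pmatrix}\sigma_H^2 & \sigma_H\sigma_M\rho\\
                 \sigma_H\sigma_M\rho & \sigma_M^2\end{pmatrix}\right),
  \qquad \mu_k = b_k + (a_k - b_k)\,\mathbb 1[z_i = j],$$

so correctness raises the latent mean from $b_k$ to $a_k$, and $\rho$
captures how much the two members' evidence co-varies (low $\rho$ =
diversity). The machine's latents are matched directly to its empirical
scores. The human's are latent: the observed choice is
$y_H \sim \mathrm{Categorical}(\mathrm{Softmax}(\pi_H/\tau))$ with a small
fixed temperature, and the observed ordinal rating follows an ordered
logit on the chosen-class latent,
$r_H \sim \mathrm{OrderedLogistic}(\pi_{H,y}, c, \delta)$ with increasing
breakpoints $c$ and sharpness $\delta$ in the cumulative
parameterization $P(r \le k) = \mathrm{logistic}((c_k - \pi_{H,y})/\delta)$
($\delta$ as an inverse-sharpness divisor; logit and probit links are
practically interchangeable here). Continuous confidences (sliders,
$|\Delta q|$) are first discretized into $R$ empirical-quantile bins
computed on training data only -- $R = 3$ by default, mirroring common
low/medium/high scales.

**Choices the model form leaves open, and what this package does.**

* *Priors*: $a, b \sim \mathcal N(0.5, 1)$;
  $\sigma, \delta \sim \mathrm{HalfNormal}(1)$; $\rho \sim U(-1, 1)$;
  breakpoints via an ordered transform of $\mathcal N(0, 2)$ increments.
  Weakly informative and scale-matched to probability-score data.
* *Temperature*: $\tau = 0.05$, fixed and exposed in the configuration. It
  makes the choice nearly deterministic in the latent scores while keeping
  the likelihood smooth.
* *Inference*: the human latents are integrated out *exactly* (to
  quadrature accuracy) by Gauss--Hermite quadrature on the conditional
  normal given the machine scores -- an 8-node-per-dimension product grid
  over the two class latents by default. Posterior sampling then runs an
  adaptive random-walk Metropolis sampler on the 10 remaining parameters
  (2 chains, 2500 warmup + 1500 kept draws by default), with split-$\hat R$
  and acceptance-rate diagnostics recorded; any $\hat R > 1.05$ flags the
  fit as non-converged while still returning it.
* *Prediction*: for each candidate label the observation likelihood is
  computed per posterior draw (same quadrature), averaged over an evenly
  thinned subset of draws, and normalized by Bayes' rule under a uniform
  label prior. Quadrature replaces Monte-Carlo marginalization of the
  latent scores: the integral is two-dimensional, so deterministic
  quadrature is both cheaper and free of simulation error.
* *Scope*: the implementation covers the published two-member, binary
  form. The latent integral grows exponentially in the number of classes
  and the model does not extend naturally past two members; multiclass
  and larger teams are the logistic combiner's job.

**Identifiability.** The likelihood is invariant to a common shift of
$(a_H, b_H, c)$ -- choices depend on latent differences, ratings on
latents relative to breakpoints -- and, in the small-$\tau$ limit, nearly
invariant to a common rescaling of the human-side gap, $\sigma_H$,
breakpoint offsets and $\delta$. Only the priors pin these directions, so
marginal posteriors of $a_H$ and $b_H$ are intentionally wide and their
$\hat R$ values converge slowly; the sampler parameterizes the human
location as its own coordinate (with breakpoints as ordered offsets from
$b_H$) precisely so the flat direction is explored rather than hidden.
Functions of identified combinations ($a_M$, $b_M$, $\rho$, the gap) are
where the information is.

## Evaluation protocol

With $M$ observations across $N$ items ($M > N$ when human populations
contribute several observations per item), `loocv()` removes *all*
observations of one item, trains the team's combiner on the remaining
$N-1$ items, predicts all held-out observations, and pools the $M$
predictions; accuracy is reported with its binomial standard error
$\sqrt{p(1-p)/M}$. Single-member teams skip training and score the
member's own recorded choices. An assertion inside every fold verifies
the held-out item contributed no training rows. A pooled human population
is treated as one teammate: each human observation on an item pairs with
the machine records for that item, and evaluation counts observations.
Teams without the pooled human are evaluated once per item; in the
generator, human observation counts are independent of item difficulty,
so the two denominators estimate the same quantity.

`enumerate_teams()` builds all $2^K - 1$ subsets; `shuffle_control()`
permutes predicted labels (seeded) as a leakage check -- accuracy must
fall to $1/L$; `compare_accuracies()` applies Welch's $t$ (or a paired
$t$) to lists of team accuracies, one value per team, mirroring the
degrees-of-freedom patterns of group-level comparisons rather than
observation-level mixed models.

Diagnostics follow the two complementarity conditions.
`calibration_curve()` sorts an agent's observations into equal-*count*
confidence bins (robust to the strong skew of machine scores toward high
values; any remainder goes to the lowest bins, deterministically) and
reports the least-squares slope of bin accuracy on bin index -- the slope
on bin mean confidence is also emitted, since either convention is
defensible. `item_difficulty()` orients every agent type so larger means
easier: perplexity gap $q_{\text{incorrect}} - q_{\text{correct}}$ for
perplexity agents, score at the true label for score agents, mean per-item
correctness for humans. `diversity_matrix()` is the pairwise Spearman
correlation of those profiles over shared items (mid-ranked ties; pairs
sharing fewer than 3 items are missing).

## The synthetic panel generator

`simulate_panel()` draws one shared difficulty factor
$d_i \sim \mathcal N(0,1)$ per item. Agent $k$'s latent evidence on an
observation is $e = s_k - (\lambda_k d_i + \sqrt{1-\lambda_k^2}\,\varepsilon)$
with idiosyncratic noise $\varepsilon \sim \mathcal N(0,1)$; the judgment
is correct with probability $\mathrm{logistic}(e)$, wrong answers are
uniform over the remaining labels, and the skill $s_k$ is set by
root-finding so the expected accuracy equals the target. Reported
confidence mixes signal and noise,
$\mathrm{conf} = \gamma_k |e| + (1-\gamma_k)|\eta|$, so
`calibration_quality` $\gamma_k = 1$ gives fully informative confidence
and $\gamma_k = 0$ pure noise. Formatting then follows the agent type:
within-agent quantile ratings $0..R-1$ for discrete humans, raw values for
continuous humans, a perplexity pair with $|\Delta q| = \mathrm{conf}$ and
the lower perplexity at the chosen label, or a softmax score vector whose
maximum increases with confidence.

`make_brainbench_like()` instantiates the study conditions used
throughout the tests: 100 binary items; three perplexity judges with
target accuracies 0.70/0.72/0.75 and loading 0.8 (machines err together);
one pooled continuous-confidence human with target accuracy 0.65, loading
0.3, and 2--9 observations per item. These are the regimes in which both
complementarity conditions hold while the human is the weakest member --
the interesting case. `degrade_confidence()` permutes one agent's
confidences (choices untouched), destroying calibration while preserving
accuracy and the confidence marginal; it is the foil used to exercise the
$\alpha$-selection mechanism.

**What the generator does not emulate.** Real item difficulty need not be
one-dimensional; a single shared factor reproduces the block structure of
difficulty correlations but not richer error patterns. Wrong answers
carry no confusion structure. Machine score vectors are a one-parameter
softmax of confidence, not the output of any particular classifier, and
perplexity magnitudes are calibrated only in rank, not in their joint
distribution across models. Passing tests on these panels therefore show
that the estimators and the protocol behave as designed under the stated
conditions -- not that any particular real-world team will achieve
complementarity.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to keep the full suite
comfortable on a laptop while leaving the statistical conclusions stable:
20 panels of at most 30 observations for the fitter-vs-oracle comparison
($10^{-3}$ agreement); 20 replicates of 200 items for Bayesian parameter
recovery (90% intervals, 80% coverage threshold); 10 generator seeds for
the complementarity, ablation, squashing-selection and diagnostics
patterns; 800 items for the 16-class shuffle control. The
`scripts/acceptance.R` entry point recomputes all of these from scratch
for any seed.

## Known limitations

* The Bayesian combiner is binary and two-member by design; its
  random-walk sampler trades efficiency for having no compiled-sampler
  dependency, and flags (rather than hides) slow mixing along
  prior-identified directions.
* `fit_alpha()` optimizes each member's $\alpha$ sequentially, not
  jointly; with many miscalibrated members the selections can interact.
* Interaction and polynomial feature columns are defined for binary
  panels only.
* Perplexity ties (and score ties) break deterministically to the lowest
  class index, and are flagged; with continuous perplexities ties have
  measure zero, but discretized inputs can make the tie rule visible.
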