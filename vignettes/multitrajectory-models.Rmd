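---
title: "Multi-trajectory mixture models with distal outcomes and multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trajectory mixture models with distal outcomes and multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The model

trajmix fits group-based multi-trajectory models: finite mixtures for
longitudinal data in which each latent group $j = 1, \dots, J$ is defined by
simultaneous polynomial age trajectories on $K$ phenotypes. For subject $i$,
phenotype $k$, assessment age $t$, the latent score is

$$y^{*}_{ikt} = \beta_{jk0} + \beta_{jk1} c_t + \beta_{jk2} c_t^2 +
  \varepsilon_{ikt}, \qquad \varepsilon_{ikt} \sim N(0, \sigma_k^2),$$

with $c_t = \text{age}_t - 11$ the centered age. Group membership is
multinomial with probabilities $\pi_j = \mathrm{softmax}(\theta)_j$, the
first logit fixed at zero.

Because the observed phenotypes are bounded questionnaire sum scores
(e.g. an ADHD scale scored 7–35, where a sizeable fraction of children sit
exactly at the minimum), the observed score is modelled as the latent
normal censored at the scale bounds $[S_{\min}, S_{\max}]$:

* interior scores contribute the normal density,
* scores at $S_{\min}$ contribute the lower-tail mass
  $\Phi\!\big((S_{\min}-\mu)/\sigma\big)$,
* scores at $S_{\max}$ the upper-tail mass.

This tobit-type emission is the standard treatment of floor and ceiling
effects in the group-based trajectory tradition for psychometric scales.
Setting the bounds to $\pm\infty$ recovers the plain normal exactly
(`censored_normal_loglik()` is tested to agree with `dnorm()` to 1e-12 in
that limit), so the censoring is an option, not an obligation.

A subject's marginal log-likelihood sums over groups with log-sum-exp
stabilisation; observations missing at a wave simply drop out of the inner
sum, so subjects are retained under arbitrary intermittent missingness (a
subject with *no* observations at all is rejected with a distinct error
class).

### Distal outcomes, one step

Group-specific means of outcomes measured after the trajectory window
(here: age-20 outcomes after ages 7–15) are estimated *jointly* with the
mixture: the outcome likelihood $N(z_{io};\, \mu_{jo}, \tau_o^2)$
multiplies the trajectory likelihood inside the same mixture sum. This
one-step formulation propagates classification uncertainty into the
outcome means, unlike classify-then-analyze. The joint fit is warm-started
at the trajectory-only solution ("start values provided"), and
`trajectory_stability_check()` verifies, after optimal label matching,
that adding the outcomes did not move the model-predicted trajectories
(default pass threshold: 1 score unit, on the reasoning that a shift
smaller than a single item response cannot change the interpretation of a
group).

Standard errors come from the inverse observed information of the full
parameter vector. The information matrix is computed as the negative
Jacobian, by central differences, of the *analytic* score of the observed
-data log-likelihood; differentiating an exact gradient once is far better
conditioned than differencing the log-likelihood twice. If the information
matrix is not positive definite, SEs are flagged unavailable rather than
silently pseudo-inverted.

## Estimation

Fitting is by EM:

* **E-step** — posterior responsibilities from the current parameters,
  computed on the log scale.
* **M-step** — membership logits update in closed form
  ($\pi_j = \bar r_{\cdot j}$); the censored-normal polynomial regressions
  (all groups of one phenotype, with the shared $\sigma_k$) are maximised
  by BFGS with analytic tobit gradients, warm-started at the current
  parameters. A bounded number of BFGS iterations per M-step makes this a
  generalized EM; ascent from a warm start preserves the monotonicity
  guarantee, which the tests assert on every fitted trace (tolerance
  1e-8). Outcome means and variances have closed-form updates.

**Starts.** Mixtures have local optima; `fit_multitrajectory()` tries
`n_starts` random responsibility draws, one quantile-stratified start
(subjects ranked by mean standardized score, cut into $J$ strata) and one
k-means start on per-subject standardized wave scores, runs each for
`short_iter` EM iterations, and continues the best to convergence. The
k-means start almost always dominates on well-separated data; the random
starts guard against its failure modes. Groups collapsing below one
expected subject trigger a restart from a fresh random draw (counted and
warned).

**Convergence and tie-breaks.** Convergence is declared when the
log-likelihood change drops below `tol` (default 1e-6; the simulation
studies below use looser values, see *Problem sizes*). Modal assignment
ties break toward the lowest group index. The BIC convention is
$-2\log L + k\log n$, minimised; the equivalent maximisation form orders
models identically.

**Numerical guards.** $\sigma$ is optimised on the log scale and clamped
to $[10^{-6}, 10^{6}]$ during line searches; a pathological line-search
end point is discarded in favour of the warm start; boundary-mass
gradients use log-scale inverse Mills ratios to avoid overflow in the
tails. The emission kernel is compiled (Rcpp) because one full-scale fit
evaluates it roughly $10^7$ times.

### Model selection

`select_model()` fits a range of $J$, reports log-likelihood, BIC and the
smallest group share, and picks the minimum-BIC candidate — but flags any
candidate containing a group below a configurable share (default 5%),
since a "better" BIC bought with a vanishing group is rarely a model one
can use for group comparisons downstream. Information criteria inform the
choice; they do not finish it.

## Missing data

Wave missingness is handled by chained-equation multiple imputation
(`chained_impute()`), operating on the wave-level composite scores and the
outcome scores laid out one column per variable:

* continuous variables: **predictive mean matching** — Bayesian-draw
  linear regression on all other variables, each missing cell receiving
  the observed value of one of its `k_donors = 5` nearest predicted-mean
  donors, uniformly at random. Imputed values therefore always lie in the
  observed support (asserted on every run), which keeps bounded scores in
  bounds for free;
* factor variables: polytomous (multinomial-logit) regression with a
  categorical draw.

Perfect collinearity falls back to a small ridge penalty with a warning.
The default is $M = 3$ imputations with 10 sweeps; the per-iteration means
of imputed values are kept as a convergence trace. Imputation at the
questionnaire-item level is out of scope here: the model consumes
composites, and a composite-level chained system keeps the conditional
models at desk scale.

After fitting the model once per completed dataset (all imputations share
the first imputation's fit as start values), group labels are aligned
across imputations by `align_group_labels()`: an exact search over label
permutations minimising the summed squared distance between
model-predicted trajectory curves, with the per-group maximum curve
discrepancy reported as the quantitative "same groups in every
imputation" audit.

Aligned parameters are pooled by **Rubin's rules**
(`pool_rubin()`): $\bar Q = \tfrac1M\sum Q_m$,
$T = \bar U + (1 + 1/M) B$, with $B$ the between-imputation variance.
Group proportions are pooled on the probability scale (the reporting
scale), not as logits. Confidence intervals use the normal quantile
($z_{0.975} = 1.959964$): on the worked example shipped with the package
this choice reproduces most printed 95% bounds digit for digit, and every
cell to within 0.02 — the worst case attainable when the mean, the SE and
the bound are each independently rounded to two decimals before printing
($0.005\,(1 + 1.96) + 0.005 \approx 0.02$). A small-$M$ $t$ quantile
cannot produce these bounds: with $M = 3$ the Rubin degrees of freedom are
at most 2 and the 97.5% quantile is at least $t_{2,0.975} = 4.30$, more
than twice the printed half-widths allow. Group differences are screened by
**CI non-overlap** (`compare_groups_ci()`): shared endpoints count as
overlap, no multiple-comparison correction is applied, and the screen is
deliberately conservative relative to a formal test of the difference —
the null-calibration test verifies a per-pair false-positive rate well
below 0.05.

## The synthetic cohort generator

No individual-level data from the motivating study design are publicly
available, so the package carries a generator
(`simulate_cohort()`) reproducing the *statistical structure* the analysis
assumes, with known ground truth:

* 1620 subjects, assessed at ages 7, 8, 9, 10, 11, 12, 13 and 15 (note
  the final two-year gap — the model runs on actual age, not wave index,
  so unequal spacing is handled naturally);
* three bounded phenotypes: ADHD 7–35, internalising 7–35,
  externalising 17–85;
* six latent groups with proportions 32.5%, 27.9%, 10.6%, 13.5%, 12% and
  3.4% (renormalised to sum to one), whose default trajectory
  coefficients are **synthetic package defaults** shaped to the canonical
  qualitative patterns — flat-low; mildly elevated then declining;
  internalising-only high; low start then escalating on all domains; high
  start then declining; persistently high ADHD/internalising with rapidly
  remitting externalising. They are not estimates of any fitted model;
* missing-at-random wave deletion: observations are deleted with
  probability $\mathrm{logit}^{-1}(\alpha_{kt} + \gamma\,
  y_{ik,t-1})$, with $\alpha_{kt}$ calibrated by root-finding so marginal
  rates match per-phenotype-per-wave targets derived from the reference
  design's observed counts (up to 41% at the worst wave). Deletion
  probabilities are computed before any deletion at the current wave and
  depend only on still-observed earlier data, so the mechanism is MAR by
  construction — a property the tests audit by perturbing current-wave
  values and checking the deletion pattern is unchanged. Monotone dropout
  is available behind a flag; intermittent is the default because the
  reference per-wave counts are not monotone;
* twelve age-20 distal outcomes drawn normal around group-specific means
  (defaults taken from the worked-example pooled table, residual SDs from
  the reference descriptives), each observed for a configurable fraction
  of subjects. Real outcomes of this kind are strongly skewed (counts of
  rare behaviours); the generator's default mirrors the analysis model's
  normality assumption, and a matched-moment lognormal option exists for
  robustness experiments.

What passing simulations show, and what they do not: recovery and
calibration on this generator demonstrate the estimator and pipeline are
correct *under the model's own assumptions* (normal-within-group,
censoring at known bounds, MAR). They cannot certify behaviour under
misspecification — skewed outcomes, item-level missingness, or
informative dropout.

## Design choices where the design was open

* **Emission**: a plain-normal emission is available by setting infinite
  bounds, but censoring is the default — the reference descriptives sit
  exactly at the scale floors, which a plain normal cannot produce.
* **Residual variances**: $\sigma_k$ is shared across groups within a
  phenotype, the standard identification choice in this model family;
  group-specific *outcome* variances are available via
  `fit_joint(group_var = TRUE)`. Group-specific trajectory variances are
  not implemented: with censored scales and groups of a few dozen
  subjects they are weakly identified, and the shared-variance model is
  the one the downstream pooling assumes.
* **Polynomial order**: quadratic for every group and phenotype by
  default ("linear and quadratic growth"), configurable per fit.
* **Time metric**: actual age in years, centered at 11 for conditioning.
* **Outcome missingness** is treated as ignorable given group; only
  observed outcomes enter the likelihood.
* **Imputation count**: $M = 3$ by default, matching the reference
  procedure (each imputation's groups must be inspected, which caps how
  many are practical); all of $M$, sweeps and donors are configurable.

## Problem sizes used by the test and acceptance studies

The simulation studies fix their own sizes as part of the study design:
six-group recovery uses the full reference design ($n = 1620$, 20
replicates, k-means + stratified starts, EM tolerance $10^{-2}$ on the
log-likelihood — at that point the proportion estimates move by under
$10^{-3}$ per iteration); model selection uses single-phenotype cohorts
($n = 600$ for three groups, $n = 300$ for one); end-to-end calibration
uses the scaled three-group design ($n = 400$, four outcomes, $M = 3$, 20
replicates). The acceptance script re-runs the same computations at
reduced replicate counts and prints each quantity with the size it used.

## A short example

```{r example, eval = FALSE}
cfg <- small_cohort_config(400)
run <- run_pipeline(cfg, seed = 1, M = 3)
run$pooled          # outcome x group pooled means, SEs, 95% CIs
run$significance    # CI-overlap screen, pairwise
autoplot(run$joint_fits[[1]])        # trajectory figure
autoplot(run$pooled)                 # pooled means figure
```

A caveat the recovery studies surface deliberately: at the default
degree of group overlap (realistic for symptom scales, where
mirror-image "escalating" and "remitting" groups coincide mid-childhood),
individual simulated cohorts can admit six-group solutions whose
log-likelihoods differ by only a few units but whose partitions differ
appreciably from the generating one — the likelihood surface, not the
optimiser, is the limit. Recovery is therefore summarised as averages
over replicates, which is also how such models should be read in
practice.

## Known limitations

* No within-group random effects (growth *mixture* models are out of
  scope), no covariates on group membership, no count/zero-inflated
  emissions.
* The CI-overlap screen is conservative; non-overlap is sufficient but
  not necessary for a significant difference.
* PMM with few donors can understate imputation uncertainty at extreme
  quantiles; the trace should be inspected when missingness is heavy.
* Exact label alignment is $O(J!)$ and intended for $J \le 8$.
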