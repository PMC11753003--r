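---
title: "Covariate-constrained randomization and analysis of time-to-event cluster-randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-constrained randomization and analysis of time-to-event cluster-randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(crtperm)
```

## The problem

Cluster-randomized trials (CRTs) randomize groups — census tracts, schools,
clinics — rather than individuals, and often enroll few clusters per arm
(8–25 is typical). With so few units, an unlucky randomization can leave
prognostic cluster-level covariates badly imbalanced between arms, and the
usual asymptotic analyses can be anti-conservative. Covariate-constrained
randomization addresses the first problem at design time: enumerate or
sample candidate allocations, score each for covariate imbalance, and draw
the trial's allocation only from the best-balanced fraction. The second
problem — valid analysis with correlated outcomes and few clusters — is
addressed here for censored time-to-event outcomes by three analyses: a
cluster-robust Cox model, a Gaussian random-intercept Cox model, and a
permutation test on deviance residuals whose reference distribution is the
randomization space actually used.

## Data-generating model

Subject $j$ of cluster $i$ has an exponential event time with hazard

$$\lambda_{ij} = \lambda_0\, \gamma_i\, e^{\mathbf{x}_i'\boldsymbol\beta + T_i \log\delta},$$

where $T_i$ is the cluster's treatment indicator, $\mathbf{x}_i$ holds four
binary cluster-level covariates (independent Bernoulli(0.3) draws),
$\delta$ is the treatment hazard ratio, and $\gamma_i$ is a mean-one gamma
frailty, $\gamma_i \sim \mathrm{Gamma}(\text{shape} = 1/\sigma^2,
\text{scale} = \sigma^2)$, so $\mathrm{Var}(\gamma_i) = \sigma^2$ and
$\sigma^2 = 0$ means no frailty. All subjects still event-free at
$\tau = 2$ years are administratively censored. The baseline hazard is not
a free parameter: it is solved from a stated cumulative incidence over the
study period, $\lambda_0 = -\log(1 - \pi)/\tau$ with $\pi = 0.25$ by
default (`solve_baseline_hazard()`).

Two regimes create intraclass correlation: *prognostic* covariates
($\beta > 0$, $\sigma^2 = 0$), where the balanceable covariates drive the
correlation, and *non-prognostic* covariates ($\beta = 0$, $\sigma^2 > 0$),
where the correlation is frailty-driven and balancing buys nothing.
Combining both is rejected by `check_pairing()`: frailty on top of
prognostic covariates stacks two correlation sources and makes the
comparison between the regimes uninterpretable.

### A note on ICC calibration

`empirical_icc()` measures the outcome-scale intraclass correlation
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ on the *latent* (pre-censoring)
times, using $(n-1)$-denominator variances for both components; censoring
distorts variance-based measures, which is why latent times are retained in
every simulated dataset. Under gamma frailty this measure comes out close
to $\sigma^2$ itself. A latent-scale (log-hazard) ICC,
$\psi'(1/\sigma^2) / (\psi'(1/\sigma^2) + \pi^2/6)$ with $\psi'$ the
trigamma function, gives systematically
smaller values for the same $\sigma^2$. The two conventions disagree by
roughly a factor of two in the range used here, so the package treats the
frailty variance $\sigma^2$ as the authoritative generator input and makes
no promise about any particular ICC label attached to it. Scenario
configuration is always in terms of $\sigma^2$.

## Constrained randomization

For $g$ clusters per arm, candidate allocations put exactly $g$ of the $2g$
clusters in arm A. `allocation_space()` enumerates the full space when
$\binom{2g}{g} \le 10^6$ (so $g = 8$, with 12,870 allocations, is exact) and
otherwise samples 20,000 allocations uniformly with replacement and removes
duplicates. Mirror pairs (arm swaps) are kept as distinct members: the
permutation null distribution must be symmetric under arm relabeling.

Each allocation is scored by the inverse-variance imbalance metric

$$B = \sum_{k} \omega_k (\bar{x}_{Ak} - \bar{x}_{Bk})^2, \qquad
  \omega_k = 1/\mathrm{Var}(x_k),$$

with the variance taken across all $2g$ clusters ($2g - 1$ denominator).
`constrain(space, q)` retains allocations with $B$ at or below the
empirical $q$-th percentile, implemented as the $\lceil Mq \rceil$-th
smallest score with an inclusive comparison. Ties at the cutoff are all
retained — with binary covariates the score distribution is heavily tied,
so the retained fraction can be noticeably larger than $q$; inclusiveness
guarantees a nonempty, order-independent constrained set. `q = 1` retains
everything and reproduces simple randomization, which keeps the whole
pipeline uniform across comparisons.

An alternative, ratio-based rule (`ratio_balance_filter()`) retains
allocations whose per-covariate arm-mean ratios fall strictly inside
$(1/1.1, 1.1)$, optionally also requiring per-category cluster counts of a
categorical covariate to balance within $\pm 1$. This is the rule used by
vector-control field trials that motivated the toolkit; the two constraint
strategies are alternatives, not composable stages.

`check_validity()` computes, for every cluster pair, the proportion of
retained allocations placing the pair in the same arm, flagging pairs
outside $(0.25, 0.75)$ — a constrained design should not hard-wire any two
clusters together or apart. `select_allocation()` draws uniformly from the
retained set and labels the treatment arm by a fair coin, so each cluster's
marginal treatment probability is exactly one half.

## Analysis methods

**Cluster-robust Cox** (`fit_cox()` + `wald_reject()`): the Breslow-ties
partial likelihood with treatment and the first $S \in \{0,\dots,4\}$
covariates, with the Huber sandwich variance aggregated at cluster level.
The Wald test rejects when the 95% CI for the hazard ratio excludes 1.

**Mixed-effects Cox** (`fit_mixed_cox()` + `mixed_wald_reject()`): adds a
Gaussian random intercept $b_i \sim N(0,\theta)$ on the log-hazard scale.
For fixed $\theta$ the penalized Breslow partial likelihood (penalty
$b'b/2\theta$) is maximized by Newton iteration with step-halving;
$\theta$ maximizes the Laplace approximation to the marginal likelihood,

$$\ell(\theta) = \mathrm{PL}(\hat\beta, \hat b)
  - \frac{\hat b'\hat b}{2\theta} - \frac{m}{2}\log\theta
  - \frac{1}{2}\log\det H_{bb},$$

searched on a seven-point log grid over $[10^{-4}, 10]$ and refined by
golden-section/parabolic search on the log scale; boundary solutions are
reported as $\hat\theta = 0$ and collapse exactly to `fit_cox()`. Because
every model term is cluster-level, the score and information reduce to
cluster-indexed sums, which is what makes a full Newton step cheap enough
for Monte-Carlo use. The treatment standard error comes from the penalized
information. Note the intentional mismatch in the simulation study: data
carry *gamma* frailties but are analyzed with a *Gaussian* random effect —
a robustness feature of the study design, not a bug.

**Permutation test** (`permutation_test()`): the trial data are fit once
with the *null-model* Cox fit (covariates only, no treatment term). Each
subject's Cox–Snell residual $r_{Cj} = e^{\mathbf{x}_j'\hat\beta}
\hat H_0(y_j)$ uses the Breslow baseline cumulative hazard with a
right-continuous step convention, and is transformed to the deviance
residual

$$r_{Dj} = \mathrm{sign}(\delta_j - r_{Cj})
  \sqrt{-2\left[\delta_j - r_{Cj} + \delta_j \log r_{Cj}\right]},$$

which symmetrizes the skewed Cox–Snell scale and accommodates censoring
($\delta_j$ the event indicator; a censored subject with $r_C = 0$ maps to
0 by continuity). The statistic is the scaled arm difference of
cluster-mean residuals, $S = g^{-1}\sum_i (2T_i - 1)\bar r_i$. Its null
distribution is produced by recomputing $S$ for every allocation in the
space the trial was actually randomized from — the constrained subset for a
constrained design, the full deduplicated space for simple randomization.
Mismatching these spaces invalidates the test, so `permutation_pvalue()`
errors if the observed allocation is not a member of the referenced space.
Because the null fit ignores treatment, residuals are computed once per
dataset and held fixed across permutations.

Conventions adopted where the field leaves them open: the test is
two-sided via $|S^\ast| \ge |S_{\mathrm{obs}}|$ (the natural choice given
the mirror symmetry of the space), the observed allocation is included in
numerator and denominator (so $p > 0$ always), rejection is at
$p \le 0.05$, and the comparison uses a $10^{-12}$ slack so ties in
$|S^\ast|$ are never lost to floating-point rounding.

## Monte-Carlo engine

A `crt_scenario()` bundles a design, a constraint percentile, analysis
methods, adjustment levels, and `n_sim`. Each replicate draws covariates
and frailties, builds and scores the allocation space *from that
replicate's covariate matrix*, constrains, selects the allocation,
simulates outcomes, and runs every requested analysis. One master seed
spawns five per-replicate sub-seeds (covariates, frailties, space sampling,
selection, outcomes), so results are independent of execution order, and
scenarios differing only in `q` or analysis settings see identical data at
each replicate index — the paired comparison the study design calls for.

Two policies deserve emphasis:

* **Non-converged fits** (monotone likelihoods at $g = 8$ are possible;
  coefficients are capped at $|\beta| = 15$ and flagged) are excluded from
  that cell's denominator and counted in `n_flagged`. Counting them as
  either rejections or acceptances would bias rates invisibly.
* **Degenerate covariates**: with $2g = 16$ clusters and Bernoulli(0.3)
  draws, a covariate is constant across all clusters in roughly 1.3% of
  replicates. Its arm-mean difference is then identically zero and its
  inverse-variance weight undefined, so the engine drops it from both the
  imbalance score and the adjustment models for that replicate.
  `imbalance_score()` itself still errors on zero-variance input, naming
  the covariate.

Rejection rates are reported with the binomial Monte-Carlo standard error
$\sqrt{\hat p(1 - \hat p)/n}$.

## What the generator does and does not emulate

The generator reproduces the structure of a two-arm parallel CRT with
cluster-level binary covariates, exchangeable subjects, a shared frailty,
and administrative censoring only. Real trials depart from this in ways
that matter: individual-level covariates, household-within-cluster nesting,
staggered entry, loss to follow-up (random or informative censoring), and
non-exponential or non-proportional hazards are all outside the model.
Passing tests therefore demonstrate correctness of the methods under the
stated model, and the robustness comparisons among the three tests, but not
performance under those richer departures.

## Problem sizes and tolerances

The test suite and the acceptance script run the study at desk scale:
500 replicates for type-I-error cells and 300 for power cells (the full
1,000 of a publication-scale run is available through `n_sim`), with
anchors compared at three pooled Monte-Carlo standard errors. Numerical
tolerances elsewhere follow the estimation accuracy involved: $10^{-3}$
against a $10^{-4}$-step grid-search oracle, $10^{-8}$–$10^{-12}$ for
algebraic identities (martingale sums, mirror symmetry, antisymmetry).
Newton iterations stop at gradient max-norm $10^{-6}$ or relative
log-likelihood change $10^{-9}$, capped at 50 iterations.

## Known limitations

* The mixed-effects fitter requires cluster-level fixed effects; it
  exploits that structure for speed and will not accept subject-level
  covariates.
* Breslow tie handling is used throughout (ties are measure-zero under the
  continuous generator; fits of heavily tied real data will differ slightly
  from an Efron-ties analysis).
* The imbalance score supports inverse-variance weights only; user-chosen
  weights are an extension point, not a feature.
* Power and type-I estimates inherit Monte-Carlo error; at desk scale the
  3-MCSE bands are wide (about ±2–4 percentage points near 5% rejection,
  ±6 near 90% power at 300 replicates).
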