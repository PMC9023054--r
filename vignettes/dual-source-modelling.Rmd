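---
title: "Modelling learning from primary and secondary information sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling learning from primary and secondary information sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwdual)
```

## The task being modelled

`rwdual` analyses two-source probabilistic learning tasks. On each of 120
trials an agent chooses between two options. Two information streams carry
reward information:

* the **primary source** is directly indicated by the trial feedback
  (outcome `r(t) = 1` when the primary-congruent option is rewarded);
* the **secondary source** is an advice cue whose accuracy must be
  *inferred* from the same feedback: the advice was correct exactly when it
  endorsed the rewarded option.

Both sources follow independent pseudo-randomised probability schedules
composed of **stable** phases (reward probability constant for more than 30
trials) and **volatile** phases (probability reversing between `q` and
`1 - q` every 10--20 trials). Which stream is social and which is
individual is a between-group label (`individual-primary` vs
`social-primary`) that does not change the computational structure, so a
single model serves both groups.

## The dual-source Rescorla--Wagner model

Two value traces run in parallel from a common starting value
$V_0 = 0.5$. The primary trace tracks the probability that the
primary-congruent option is rewarded; the secondary trace tracks the
probability that the advice is correct. Each is updated by the delta rule

$$V_{i+1} = V_i + \alpha\,(r_i - V_i),$$

with the learning rate $\alpha$ selected per trial by the source's phase
label, giving four rates:
$\alpha_{ps}, \alpha_{pv}, \alpha_{ss}, \alpha_{sv}$
(primary/secondary $\times$ stable/volatile). Before each choice the
secondary belief is converted to a primary-congruent probability through
the advice weighting

$$V^{aw}_{i} = \lvert \text{advice}_i - V^{sec}_i \rvert,$$

where advice is coded 0 when it endorses the primary-congruent option,
and mixed with the primary trace by the weight $\zeta \in (0, 1)$:

$$V^{comb}_i = \zeta\, V^{aw}_i + (1 - \zeta)\, V^{prim}_i.$$

The unit-square sigmoid maps the combined belief to a choice probability,

$$P(y_i = 1) = \frac{(V^{comb}_i)^{\beta}}
 {(V^{comb}_i)^{\beta} + (1 - V^{comb}_i)^{\beta}},$$

with $\beta > 0$ the inverse decision temperature ($\beta = 1$ is the
identity map; larger $\beta$ makes choices more deterministic). The six
free parameters are therefore the four learning rates, $\zeta$ and
$\beta$; $V_0$ is fixed at 0.5 and never fitted, because the response
model's free parameters are deliberately limited to $\alpha$, $\beta$ and
$\zeta$.

Trials with a missing choice still update the traces (the feedback was
shown) but contribute nothing to the likelihood. The combined value is
clipped to $[10^{-6}, 1 - 10^{-6}]$ before exponentiation, the returned
choice probability to $[10^{-12}, 1 - 10^{-12}]$, and each trial's log
loss is floored at $\log 10^{-12}$ symmetrically in the two choice
branches, so that relabelling the two options leaves the likelihood
invariant up to floating-point noise.

## The model family

Reduced variants tie parameters: learning rates can be shared across
sources, shared across phases, or both, and $\zeta$ can be fixed at 0.5
(indifference between sources). The `model_space()` family is the full
$2 \times 2 \times 2$ factorial — eight models, of which exactly one (all
splits on, $\zeta$ free) is the full model. The factorial composition is
configuration, not code: any list of `model_variant()` objects can replace
it in `fit_model_space()`.

## The Bayesian optimal learner

The benchmark learner tracks a Bernoulli reward probability $p_t$ that
drifts over time, together with its log-volatility $v_t$ and a
volatility-trend parameter $k$, by filtering on a fixed
$(p, v, k)$ grid with a uniform prior. Per trial, $v$ drifts as a
zero-mean Gaussian with standard deviation $e^{k}$, then $p$ diffuses with
a beta kernel of concentration $c = e^{-v}$, shape parameters
$1 + p\,c$ and $1 + (1-p)\,c$. This parameterisation peaks at the current
$p$ and keeps both shapes $\ge 1$ at every volatility level, so the kernel
never develops boundary spikes. The outcome then multiplies the grid by
the Bernoulli likelihood and the posterior is renormalised. The
prediction $\hat p_t$ is the posterior mean *before* trial $t$'s outcome,
so $\hat p_1 = 0.5$.

### Numerical scheme

Both transition kernels are discretised as moment-matched tridiagonal
drift-diffusion operators applied as matrix powers: each one-trial kernel
is split into $m$ sub-steps whose per-step mass shifts stay below 0.45 of
a cell, with reflecting boundaries. This finite-volume construction is
consistent across grid resolutions even when the one-trial kernel is much
narrower than a cell (where naive midpoint-density transition matrices
freeze and never converge) or much wider (where a single three-point
stencil would be invalid). Under the default resolution
(`n_p = 50, n_v = 34, n_k = 30`), doubling every grid dimension changes
the predictions of a 120-trial session by less than $10^{-3}$, which the
test suite asserts.

### Choice of grid ranges

The task never reveals its generative volatility, so the grid ranges are
package choices. They were calibrated against a target-independent
criterion: the learner's mean out-of-sample predictive log score on
outcome sequences sampled from the package's own schedules, under the
constraint that the grid-refinement property above holds. The selected
range, $v \in [-9, -0.5]$ with $k \in [\log 0.05, \log 1.5]$, spans
effectively static behaviour (per-trial step s.d. $\approx 0.003$) to
strong drift (s.d. $\approx 0.23$), matching the regime of stable phases
and 10--20-trial reversals. A wider range predicted these schedules
slightly worse and converged more slowly in the volatility dimension.

### Per-source prediction series

For the primary source the learner filters `r(t)` directly; for the
secondary source it filters the inferred advice-correctness sequence and
converts the accuracy estimate to the primary-congruent scale through the
same advice weighting as the response model,
$\lvert \text{advice}_t - \hat p_t \rvert$.

## Fitting

Parameters are estimated by maximum a posteriori in unconstrained space:
logit for learning rates and $\zeta$, log for $\beta$, with independent
Gaussian priors (defaults: rates centred on 0.3, $\zeta$ on 0.5, $\beta$
on 4, unit variance in transformed space). The priors are weakly
informative regularisers of the kind customary for this model class; they
are fully configurable through `prior_config()`. Optimisation is
multi-start BFGS (Nelder--Mead fallback per start): the prior mean plus
`n_starts` prior draws, best optimum kept, ties broken by first
occurrence, deterministic given the seed.

Approximate log model evidence is the Laplace approximation at the MAP,
with the Hessian of the negative log joint obtained by central finite
differences (step $10^{-4}$). If the Hessian is not positive definite the
function falls back to $-\mathrm{BIC}/2$ with a warning. A model with all
parameters fixed has evidence equal to its log-likelihood.

Random-effects model selection (`bms()`) uses the variational Dirichlet
scheme: starting from a uniform Dirichlet(1) prior over model
frequencies, subject-wise model responsibilities and Dirichlet counts are
iterated until the parameters change by less than $10^{-6}$ (cap 10,000
iterations). Exceedance probabilities are estimated from 100,000 seeded
Dirichlet draws, which puts their Monte-Carlo error well below 0.01.

## Optimal-learner analyses

**Regression weights.** How strongly a session's choices follow each
source is measured by two *separate* single-predictor binomial logistic
regressions of the choices on the standardised prediction series of the
two optimal learners; the slope coefficients are the reported weights.
Standardisation is within-session. Constant predictors or perfect
separation yield a capped coefficient ($\pm 10$) and a flag rather than
an error, since deterministic simulated agents make separation routine.

**Optimal learning rates.** The learning rates an optimal learner
effectively exhibits are obtained by simulation: sample a schedule and
trial realisation, filter both sources with the Bayesian learner, combine
the two prediction series with the response model ($\zeta = 0.5$, an even
mix, and $\beta = 10$, near-deterministic responding), sample binary
choices, and refit the full dual-source RW model; the four fitted rates
are averaged over datasets (default 100). Fitting to sampled choices is
the default because it keeps the refit pipeline identical to the one used
for behavioural data; fitting to thresholded probability trajectories is
available (`choices_mode = "probabilities"`) and gives similar averages.
`alpha_diff()` then subtracts these optimal rates from fitted
(untransformed) rates slot by slot.

Under the package's reconstructed schedules the averaged optimal rates
are close for stable and volatile phases (the volatile ones slightly
lower): a learner that has just traversed a long stable phase is
rationally slow at the first reversals, and its measured per-trial update
rate is approximately 0.10 in both phases. Reconstructions with more
volatile-dominant schedules would raise the volatile-phase averages.

## Synthetic cohorts

`generate_cohort()` produces a complete two-group crossover study: each
subject is simulated in both a placebo and a drug session (order
counterbalanced by subject index), on one of four counterbalanced
schedule variants (`schedule_variants()`: phase order crossed between the
two sources), with the same schedule reused across a subject's two
sessions but fresh outcome draws.

Per-subject parameters are sampled in transformed space: one offset per
parameter per subject, shared across sessions, added to the
drug-condition means — so the programmed drug effect is a within-subject
shift, and every draw automatically respects the parameter bounds. The
default condition means encode the effect the analysis pipeline is meant
to detect: the drug lowers the primary-source learning rates
(stable 0.290 to 0.218, volatile 0.184 to 0.169) and leaves the
secondary-source rates essentially unchanged (0.151/0.187 vs
0.202/0.200). Between-subject SDs are per-slot pooled values on the
natural scale, converted to the logit scale by the delta method at the
slot's grand mean. Population values of $\zeta$ (0.3, SD 0.15) and
$\beta$ (4, 30% log-scale spread, no drug effect on either) are package
choices, as no group statistics are available to anchor them.

What the generator deliberately does *not* emulate: attentional lapses,
response biases (side or colour preferences), missed responses, learning
or fatigue across sessions, exclusion rules, demographics, and any
questionnaire-derived structure. Passing end-to-end tests therefore shows
that the pipeline recovers what this generative family encodes — model
identity, parameter values, and the programmed drug-by-source pattern —
not that real participants satisfy the model's assumptions.

## Numerical choices and degenerate inputs

* Value clip $10^{-6}$ before the sigmoid; choice-probability clamp
  $10^{-12}$; per-trial log-loss floor $\log 10^{-12}$.
* Finite-difference Hessian step $10^{-4}$ in transformed space.
* BMS convergence $10^{-6}$, 100,000 exceedance draws.
* Volatile-block reversal intervals are drawn uniformly from the feasible
  subset of the 10--20 range that leaves a remainder of zero or at least
  ten trials, so no truncated short run can appear at a block end.
* Schedules reject stable blocks of 30 trials or fewer and block lists
  whose lengths do not sum to the session length; fitting requires at
  least 30 non-missing choices; `bms()` requires finite evidences, at
  least two models and two subjects.

## Problem sizes used by the checks

The package's own verification uses 120-trial sessions throughout;
parameter recovery is asserted at 50 agents with 1000-trial sessions
(correlations above 0.8 per learning rate) and contrasted against
120-trial sessions, where recovery is noticeably noisier; the optimal
learning rates are averaged over 100 datasets; the end-to-end cohort
check uses the default 31-subject, two-session design. These sizes are
the package's chosen verification conditions.

## Known limitations

* The schedule reconstruction is parameterised, not a copy of any
  specific experiment's trial lists; quantities that depend on fine
  schedule details (notably volatile-phase optimal learning rates)
  vary with the reconstruction.
* The Laplace evidence is a local approximation; strongly multimodal
  posteriors (short sessions, extreme $\beta$) may be poorly summarised,
  which the multi-start optimiser mitigates but cannot eliminate.
* The Bayesian learner's grid filter scales as
  $O(n_p^2 n_v n_k + n_v^2 n_p n_k)$ per trial; very long sequences are
  feasible but not fast.
* $V_0$ is fixed; tasks where initial biases matter would need it freed,
  which the parameterisation supports internally but the fitting layer
  deliberately does not expose.
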