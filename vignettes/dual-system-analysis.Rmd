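---
title: "Dual-system analysis of instrumental control: models, simulators and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system analysis of instrumental control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcontrol)
```

## The scientific problem

Two experimental traditions claim to measure the same dichotomy of
instrumental control. Outcome-devaluation paradigms contrast
*goal-directed* behavior — choices that track the current value of their
consequences — with *habitual* behavior that persists after an outcome
has lost its value. Sequential decision-making tasks contrast
*model-based* control — prospective planning through a learned
representation of the task's transition structure — with *model-free*
control driven purely by reward prediction errors. If the two
operationalizations tap one underlying trait, individual measures from
the two tasks should correlate: that is the construct-validity question
this package makes computationally explicit. It provides generative
models of both tasks, the hybrid reinforcement-learning model and its
hierarchical fitting machinery, the behavioral statistics, and a
synthetic-cohort generator with a controllable latent trait so the whole
analysis chain can be exercised, calibrated and power-analyzed end to
end.

## The two-step task and the hybrid learner

Each trial has two stages. A first-stage choice between two options
leads to one of two second-stage states — *commonly* (probability 0.7)
to one of them, *rarely* (0.3) to the other — where a second choice is
rewarded or not. Reward probabilities of the four second-stage options
drift as independent Gaussian random walks with reflecting boundaries at
0.25 and 0.75, so subjects must keep learning throughout a 201-trial
session.

The hybrid learner maintains model-free values by SARSA(&lambda;).
With stage index $i$, chosen option $a_{i,t}$ and prediction error
$\delta_{i,t} = r_{i,t} + Q_{MF}(s_{i+1,t}, a_{i+1,t}) -
Q_{MF}(s_{i,t}, a_{i,t})$ (no reward at stage 1; no third stage), the
chosen values update as

$$Q_{MF}(s_i, a_i) \leftarrow Q_{MF}(s_i, a_i) + \alpha_i \delta_{i,t},$$

with an additional *stage-skipping* update of the first-stage value by
$\alpha_1 \lambda \delta_{2,t}$. Model-based first-stage values multiply
the best second-stage value by the true transition probabilities,

$$Q_{MB}(s_A, a) = P(s_B \mid s_A, a)\max_{a'}Q_{MF}(s_B, a') +
P(s_C \mid s_A, a)\max_{a'}Q_{MF}(s_C, a'),$$

and the two systems mix at the first stage,
$Q = \omega Q_{MB} + (1 - \omega) Q_{MF}$. Choices follow a softmax with
stage-specific inverse temperatures $\beta_1, \beta_2$ and a
perseveration bonus $\rho$ for repeating the previous first-stage
choice. The seven parameters are $(\beta_1, \beta_2, \alpha_1, \alpha_2,
\lambda, \omega, \rho)$; $\omega \in [0,1]$ is the quantity of primary
interest, with $\omega = 0$ purely model-free and $\omega = 1$ purely
model-based.

Three conventions are deliberate and worth stating because the printed
equations do not fix them:

* **Update order within a trial.** $\delta_1$ is computed from the
  *pre-update* second-stage value, matching the SARSA convention of
  backing up the value that informed the choice.
* **On-policy bootstrap.** The stage-1 error bootstraps on
  $Q_{MF}(s_2, a_2)$ of the *taken* second-stage action (SARSA), not the
  maximum (Q-learning); the model family is explicitly on-policy.
* **Transition probabilities are fixed**, not learned — the instructed
  70/30 structure enters as known constants, which has been shown to
  outperform incremental transition learning in this task.

Perseveration applies at the first stage only and is zero on trial 1.
The softmax is stabilized by max-subtraction and per-trial probabilities
are floored at $10^{-300}$ before taking logs, so even extreme inverse
temperatures yield finite log-likelihoods. The forward pass is
implemented in C++ (identically in a likelihood-only and a
per-trial-diagnostics variant); an independent step-wise R oracle in the
test suite pins both down to $10^{-10}$ over all 64 three-trial outcome
configurations.

## The devaluation paradigm and the dual-controller agent

Training interleaves three stimulus pairs (50 trials each): two food
conditions, in which the high-probability stimulus delivers a food
(chocolate or tomato) with $p = 0.5$ and fruit tea with $p = 0.25$ while
the low-probability stimulus delivers only tea with $p = 0.25$, and a
neutral condition delivering water with $p = 0.75$ versus $p = 0.25$.
One food is then devalued by feeding to satiety, and choice is probed in
extinction (150 trials, foods withheld, tea at $p = 0.3$ for either food
stimulus). A goal-directed chooser abandons the devalued stimulus
immediately; a habitual one keeps choosing it.

No model is fitted to this task; a *dual-controller agent* serves as the
generative stand-in for a subject. It mixes a goal-directed value $G$
(expected current utility under the true training contingencies) with a
habit value $H$ (running average of delivered utility, rate
`alpha_h`) as $wG + (1-w)H$ and chooses by softmax (`beta_d`).
Devaluation changes only the utility entering $G$; $H$ is untouched.
Choices of this agent, not its internals, are the analysis input.

Three generative choices deserve explanation:

* **Post-satiety utility is mildly negative** (`u_deval = -0.25`, versus
  food = 1, tea = water = 0.5, none = 0). With a devalued utility of
  exactly zero the devalued condition's two stimuli would have
  *identical* goal-directed values (0.5·0 + 0.25·0.5 = 0.25·0.5), so even
  a fully goal-directed agent could only fall to indifference — a choice
  drop of at most ~0.49. Sated subjects typically rate the devalued food
  unpleasant, and a mildly aversive utility reproduces the decisive
  behavioral abandonment that the paradigm is designed to show.
* **$G$ uses the true contingencies** rather than learned estimates:
  after 50 training trials per condition the stimulus–outcome
  probabilities are well learned, and a learned-$G$ variant would add a
  nuisance parameter without changing the qualitative signatures.
* **Values are frozen during extinction.** The analysis windows are the
  last 10 training and first 10 extinction trials per condition; over 10
  trials relearning from tea-only feedback is negligible, and freezing
  makes the extinction phase a clean read-out of stored habit strength.
  (Whether the neutral condition keeps delivering water in extinction is
  not determined by the paradigm description; it does here, as in
  training.)

Subjects (real or synthetic) failing 75% correct training choices in any
condition are excluded, the comparison being inclusive at exactly 75%.

## Behavioral statistics

**Stay probabilities.** For every trial after the first, the stay
indicator (first-stage choice repeats the previous one) is binned by the
previous trial's reward and transition. Model-free control predicts a
main effect of reward only; model-based control predicts a
reward-by-transition interaction, because a rare transition inverts what
a second-stage reward implies about the first-stage choice. Group tests
reduce the 2×2 within-subject ANOVA to paired contrasts — per subject,
main effect $= \frac{RC + RR}{2} - \frac{UC + UR}{2}$ and interaction
$= (RC - RR) - (UC - UR)$ — tested against zero with one-sample t tests;
$F = t^2$ with df $(1, n-1)$ is the exact ANOVA equivalence (checked in
the tests against an independently computed `aov()` with error strata).

**Interaction scores.** The per-subject model-based score is
$(RC - RR) - (UC - UR)$ on stay probabilities. The devaluation score is
the condition-specific drop in high-probability choices,
$(\text{devalued}_{pre} - \text{devalued}_{post}) -
(\text{valued}_{pre} - \text{valued}_{post})$ in 10-trial windows. This
orientation is chosen so that *higher = more goal-directed* is literally
true: a goal-directed subject drops the devalued stimulus (large first
difference) while retaining the valued one (small second difference).
The opposite, valued-minus-devalued orientation is available behind
`literal_formula = TRUE`; under it a goal-directed subject scores
*negative*, so the two readings cannot both satisfy the "higher is more
goal-directed" interpretation, and the package treats the orientation as
an explicit analysis switch rather than silently picking one.

**Correlation.** The construct-validity test is a one-tailed Spearman
correlation (directed hypothesis: positive association), with average
ranks for ties. For $n \le 9$ the p-value is exact by full enumeration
of all $n!$ rank permutations ($9! = 362{,}880$); for larger $n$ a t
approximation with $n - 2$ df is used. Its type-I calibration at the
study's sample size ($n = 13$) is verified by simulation in the test
suite.

## Hierarchical empirical-Bayes fitting

Parameters are fitted on an unconstrained scale — logit for $\alpha_1,
\alpha_2, \lambda, \omega$, log for $\beta_1, \beta_2$, identity for
$\rho$ — under a Gaussian group prior. Per subject, the maximum a
posteriori estimate maximizes the penalized log-likelihood by BFGS from
10 restarts drawn from the current prior (the surface is multimodal;
restarts plus a warm start at the previous optimum make the E-step
reliable). Posterior uncertainty is approximated by the inverse
*diagonal* Hessian (central finite differences) at the optimum — the
diagonal Laplace choice trades exactness for robustness with 7
parameters; non-positive curvature falls back to the prior variance.
The M-step moment-matches including that uncertainty:
$\mu \leftarrow \overline{y}$, $\sigma^2 \leftarrow \overline{y^2 +
v} - \mu^2$, floored at $10^{-4}$ to prevent collapse on small or
homogeneous cohorts. Convergence is declared when the summed penalized
objective improves by less than $10^{-3}$; `em_fit(max_iter = 1)`
reproduces the alternative set-once-prior reading of the procedure. The
starting prior is broad (mean 0, variance 5 per coordinate, i.e.
centered on $\alpha = \lambda = \omega = 0.5$, $\beta = 1$, $\rho = 0$).

In the recovery simulations shipped in the tests (50 agents, 201 trials,
$\omega \sim U(0.2, 0.7)$, other parameters at the observed group
medians, 30 EM iterations) the fitted $\omega$ correlates with the
generative $\omega$ at $r \approx 0.7$ and the group mean is recovered
within $\pm 0.1$. Thirty iterations is the fitted-cohort default used
throughout the package's own analyses: the objective's late-stage gains
are tiny and purely prior-tightening, and the estimates are stable well
before formal $10^{-3}$ convergence.

## The synthetic cohort and its calibration

`cohort_config()` couples the two tasks through a latent trait
$g \sim N(0,1)$: $\operatorname{logit}(\omega) = \mu_\omega + k g +
\varepsilon$ and $\operatorname{logit}(w) = \mu_w + k g + \varepsilon'$.
Only $\omega$ and $w$ load on $g$ — $\lambda$, the learning rates,
temperatures and perseveration are independent across tasks — so the
generator embodies the specificity hypothesis that goal-directedness,
not model-free learning, is the shared trait; the analysis indeed finds
no devaluation–main-effect correlation at any coupling.

Group centers for the hybrid parameters are the empirically observed
medians for this task family ($\beta_1 = 6.55$, $\beta_2 = 2.42$,
$\alpha_1 = 0.56$, $\alpha_2 = 0.58$, $\lambda = 0.70$, $\omega = 0.43$,
$\rho = 0.20$), with spreads derived from the reported interquartile
ranges (IQR/1.349 on the unconstrained scale). The dual-controller
population uses $w$ centered at 0.5 (logit SD 1), $\beta_d$ log-normal
around 8, $\alpha_h$ logit-normal around 0.15 — chosen once so that
training performance and attrition look like a real cohort: at these
defaults roughly 1–2 of 18 synthetic subjects fail the 75% criterion,
the scale of exclusion seen in practice.

The default coupling is $k = 3$. Calibration of the generator showed the
expected cross-task Spearman correlation *saturates* near 0.5 (study-scale
cohorts: $k=1 \to 0.28$, $k=2 \to 0.34$, $k=3 \to 0.48$, $k=5 \to 0.52$):
trial-sampling noise in a 10-trial-window devaluation score and a
201-trial stay-table score bounds the attainable correlation well below
the latent trait correlation, however strong the coupling. $k = 3$ sits
at the knee of that curve. A single observed correlation near 0.7 in a
cohort of ~13 is entirely compatible with this regime — the
between-cohort SD of the estimate at that size is about 0.2 — which is
itself a useful caution about small-sample correlation estimates.

What the generator does *not* emulate: reaction times, satiety dynamics
and pleasantness ratings, within-session drift of any parameter, and any
arbitration process by which real subjects might shift control between
systems. Passing tests therefore certify the analysis chain and the
qualitative behavioral signatures, not the biological fidelity of the
dual-controller stand-in.

## Numerical and degenerate-input conventions

* Reward-walk reflection folds the excursion once per step (increments
  are far smaller than the bound width at the default
  `sd_innovation = 0.025`, chosen so walks drift slowly relative to a
  201-trial session); a loop guard handles pathological step sizes.
  Initial values are uniform within the bounds.
* Actions, second-stage states and stimuli are 0-indexed; trial indices
  are 1-based.
* Boundary parameter values ($\alpha, \lambda, \omega \in \{0, 1\}$) are
  clipped into the open interval with a warning before the logit
  transform; $\exp$ is capped at $e^{50}$ on the way back.
* Stay-table cells that were never visited are `NA` (missing), never 0;
  subjects with missing cells are dropped from group contrasts
  (complete-case) and raise an error in per-subject scores.
* Constant inputs to the Spearman test raise an error rather than
  returning `NA`.
* All simulators accept a `seed` and are bit-reproducible given it;
  cohort generation derives every stream from the single config seed.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the package's own study
conditions: 201-trial two-step sessions; 150 + 150-trial devaluation
sessions with 10-trial analysis windows; 200 agents per pure-strategy
cohort; 50 subjects for recovery with 30 EM iterations; cohorts of 200
subjects (20 replicates under the null, 6 under coupling) for the
pipeline calibration; 10,000 draws for all law-of-large-numbers checks.

## Known limitations

* The diagonal Laplace approximation ignores posterior correlations
  between parameters (notably $\beta_1$–$\rho$ and
  $\alpha_1$–$\lambda$); group variances are accordingly approximate.
* EM convergence to $10^{-3}$ is slow on large cohorts because the
  moment-matched prior keeps tightening; estimates stabilize long
  before, and `converged = FALSE` with a monotone trajectory is the
  expected outcome at moderate iteration caps.
* The dual-controller agent has perfect outcome knowledge in $G$; it is
  a stand-in with the correct qualitative signatures, not a claim about
  subjects' true generative process.
* With 201 trials the model-based score and $\omega_{MAP}$ are noisy
  individual measures; cross-task correlations in small cohorts have
  sampling SDs of ~0.2 and should be interpreted accordingly.
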