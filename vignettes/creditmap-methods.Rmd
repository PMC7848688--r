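---
title: "Models and methods in creditmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in creditmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

creditmap simulates and analyses a full-feedback dual-outcome bandit task in
which four bandits ("persons") each lead deterministically to a unique pair
out of four probabilistic outcomes ("vegetables"), every vegetable being
shared by exactly two persons. This note documents the generative model, the
hybrid learning agent, the estimation and model-comparison machinery, the
model-agnostic regression signatures, and the normative simulations — along
with the numerical and design choices behind them and what the synthetic
benchmarks do and do not establish.

## The task generative process

A session has 7 blocks of 56 trials (`task_config()`). Per block, each
vegetable's sale probability follows an independent Gaussian-increment random
walk (SD 0.03 per trial) with reflecting boundaries at 0.2 and 0.8,
initialized at a uniformly random permutation of (0.2, 0.4, 0.6, 0.8). A
fresh walk is drawn every block. Reflection is implemented as mirror
fold-back, iterated until the value is inside the bounds — clipping would
pile probability mass at the boundaries, whereas folding preserves the
reflected-diffusion stationary distribution (uniform on the interval).

Offers always pair two persons who share exactly one vegetable. Up to
relabeling, the person-vegetable bipartite graph is forced to a 4-cycle, so 4
of the 6 person pairs are valid offers and the vegetables of a valid offer
partition into one *Common*, two *distinctive* and one *Absent* outcome. In
the balanced design each valid pair appears on 14 trials per block in
shuffled order. Display sides are assigned uniformly at random each trial
(the side-choice regression needs a side indicator, and no counterbalancing
scheme is assumed). All four outcomes are Bernoulli-sampled and revealed
every trial (full feedback); a trial's earnings count only the chosen
person's two vegetables.

The *importance-autocorrelated* variant (`pair_persistence` > 0) replaces the
shuffled schedule by a symmetric two-state Markov chain over the two
importance classes of offer pairs (the two classes are the two distinctive
vegetable pairs of the 4-cycle), with stay probability `pair_persistence`;
the pair within the class is uniform. The lag-1 autocorrelation of the class
indicator is `2 * pair_persistence - 1`. This is a reconstruction of the
variant from its stated property (positively autocorrelated outcome
importance); the original construction is not public.

There is no response deadline and there are no missed trials in simulation.

## The hybrid agent

Choice arises from model-free (MF), model-based (MB) and perseveration
contributions. On feedback, outcomes are classified by their role on that
trial — Common, Exclusive (chosen person only), Counterfactual (unchosen
only), Absent — and rewards are coded +1 (sold) / -1 (unsold). The chosen
person's cached value updates as

    Q_MF(chosen) <- (1 - f_mf) Q_MF(chosen) + sum_type c^MF_type r_type,

with the other persons' values decaying by `(1 - f_mf)`; each vegetable's MB
value updates as `Q_MB <- (1 - f_mb) Q_MB + c^MB_type r_type`; perseveration
values decay by `(1 - f_p)` and the chosen person gains `pr`. At choice, the
MB value of a person is the sum of its two vegetables' values, the net value
is `Q_MB + Q_MF + PERS`, and the choice probability is the logistic of the
net-value difference. All value stores reset to zero at block boundaries.

Two deliberate conventions: there is **no inverse-temperature parameter**
(the choice rule has none; the CA weights carry the scale, so fitted weights
are effective learning-rate-times-temperature quantities and are bounded to
[-3, 3], which covers the empirically reported ranges with margin), and
**reward coding is fixed at ±1** in the updates while the regression analyses
code rewards as ±0.5 — these are two different conventions for two different
analyses, both kept fixed.

The five nested submodels are linear constraints on the 12 parameters:
`pure_mb` (MFCA weights 0), `pure_mf` (MBCA weights 0), `no_cm_mf` (all four
MFCA weights equal), `no_unrelated_mfca` (Counterfactual and Absent MFCA
weights 0), `egalitarian_mb` (all four MBCA weights equal). A forgetting rate
whose value cannot move the likelihood under the constraint (e.g. `f_mf`
when all MFCA weights are zero) is dropped from the free-parameter count, so
BIC penalizes only parameters that matter: k = 12, 7, 7, 9, 10, 9
respectively.

## Likelihood, fitting, and the dual computation route

The session log-likelihood sums log choice probabilities over trials with
block resets. It is computed twice, by design: a compiled recursion with an
analytic 12-parameter gradient (the production path, `session_loglik()`),
and a deliberately naive R replay of the update equations built from
`choice_probability()` and `update_after_feedback()`
(`session_loglik_replay()`). The two agree to better than 1e-10 across
random sessions and parameters; the tests enforce this.

`fit_mle()` maximizes the likelihood by multi-start projected L-BFGS
(compiled, memory 6, Armijo backtracking along the projected arc, steepest-
descent fallback) with box bounds: weights and `pr` in [-3, 3] on the
natural scale, forgetting rates on a logit scale in [-10, 10] so bounds are
never attained exactly. Starts are the chance point (all weights zero — this
start guarantees the fitted log-likelihood is at least `n log 0.5`) plus
Latin-hypercube draws; the hypercube is drawn once at a fixed size and
subset, so enlarging the number of starts only adds starts and the best
log-likelihood is monotone in their number. Ties between starts break to the
lowest index. The compiled optimizer reproduces `optim`'s L-BFGS-B optima on
shared starts (tested) at roughly twenty times the speed, which is what makes
the bootstrap machinery below tractable.

Parameter recovery at the study's scale (42 subjects, 392 trials, 10 starts,
heterogeneous generating parameters drawn around the empirical pattern —
weights Gaussian with SD 0.3, forgetting uniform on [0.05, 0.6]) yields
generating-vs-recovered correlations of roughly 0.8–0.95 for all eight CA
weights; forgetting rates are more weakly identified (about 0.4–0.8).

## Bootstrap GLRT

A submodel is tested against the full model by a parametric bootstrap of the
generalized likelihood ratio. The statistic is `2 (LL_full - LL_sub)`, made
non-negative by construction: the full-model fit always includes the
embedded submodel optimum among its starts and is floored at the submodel
likelihood. The null distribution simulates each subject's session from that
subject's *fitted* submodel parameters and refits both models; the group
statistic is the sum over subjects, and p-values use the add-one rule
`(1 + #(null >= obs)) / (1 + n_boot)`.

One detail is essential for calibration: the observed data and every
bootstrap replicate are fitted by **exactly the same procedure** — one
shared start set (chance point plus a fixed Latin-hypercube draw) for the
submodel, and the embedded optimum plus the same shared set for the full
model. An earlier asymmetric variant (bootstrap refits seeded at the
generating parameters, observed fits not) over-rejected (about 13% at
nominal 5%) because the bootstrap side was better optimized; with the
symmetric procedure the empirical size is 5% to within Monte-Carlo error.
The calibration study in the acceptance tests runs 200 replicate
experiments of 3-subject single-block cohorts at `n_boot = 200`; the power
study runs 25 replicates of 10-subject single-block cohorts against the
pure-MB null. These problem sizes are the package's desk-scale defaults and
are configurable upward.

## Random-effects model selection and averaging

Per-subject log model evidence is approximated by -BIC/2
(`log_evidence_bic()`); this is stated prominently because the evidence
approximation shifts prevalence estimates. The population distribution over
models is treated as random effects: a Dirichlet prior (alpha0 = 1 per
model) updated by the standard variational iteration against the evidence
matrix. Exceedance probabilities are Monte-Carlo frequencies of the argmax
over 1e5 posterior Dirichlet draws, with an exact 1/K shortcut in the fully
symmetric case (so that equal evidence yields expected probabilities and
protected exceedance probabilities of exactly 1/K). The Bayes omnibus risk
compares the variational free energy against the equal-frequency null, and
`pxp = xp (1 - bor) + bor / K` holds exactly for every output. A K = 2
grid-integration oracle cross-checks the variational posterior in the tests,
including the single-subject case where one large evidence gap cannot
establish population prevalence (bor stays near 1/2). Bayesian model
averaging weights each subject's embedded parameter vectors by that
subject's posterior model responsibilities from the same variational fit.

## Model-agnostic signatures

Two regressions probe credit assignment without the model. The
choice-repetition model uses only within-block transitions whose second
trial re-offers the previously chosen person, classifying outcomes as
Common / Unique / Other / Absent relative to the new offer and regressing
repetition on their ±0.5 reward codes and the ±0.5 importance code of the
Unique and Other vegetables. The side-choice model uses all within-block
transitions and regresses right-side choice on the previous rewards of the
two distinctive vegetables and their importance. Estimation is **two-stage**
by default — per-subject maximum-likelihood logistic fits (coefficients
capped at ±10 under separation, flagged) followed by across-subject
t-tests on coefficients and contrasts — rather than the trial-level
random-coefficient mixed model used in the original analysis. At the
synthetic cohort sizes involved the two agree on direction and
approximately on power, and the two-stage route is robust and fast; the
mixed-effects analysis of fitted CA parameters (`ca_param_effects()`) does
use `lmer` with a subject random intercept.

A signature "holds" when its group estimate has the predicted sign with
one-sided p < 0.05. Synthetic cohorts reproduce the core dissociation
pattern: the full model at the empirical pattern shows the repetition
signatures and the side-choice interactions; `pure_mb` loses the Common
main effect; `no_cm_mf` loses the Common-Absent contrast; `egalitarian_mb`
loses the negative Other-by-importance interaction; `pure_mf` loses the
side-choice reward-by-importance interactions.

Two genuine caveats surfaced by these simulations, both consequences of the
task's structure rather than implementation artifacts, and both left
visible in the test suite rather than tuned away.

*Memory-autocorrelation confound.* A pure-MF agent with slow forgetting
(f_mf around 0.1) produces small but systematic positive Unique-Common and
Absent-Other contrasts (about a third of the full model's), without any MB
system. Rewards of the Common vegetable also accrue, on earlier trials, to
the cached value of the *alternative* offered person (both offered persons
grow it), which attenuates the Common coefficient relative to Unique;
symmetrically, Other-vegetable rewards accrue to the alternative person and
push its coefficient below Absent. Because the walks drift slowly, trial-n
reward codes proxy for that accumulated history. The effect disappears when
MF forgetting is fast (f_mf around 0.6). These contrasts are therefore
clean MB signatures only when MF memory is short relative to the walk
drift.

*Pair-repetition selection confound.* For repeat-eligible transitions the
importance code is structurally equivalent to exact offer-pair repetition
(the two pairs of an importance class are disjoint, so a repeated person
plus an unchanged class forces the same pair). Conditioning on the trial-n
choice of a repeated pair is a selection on the persons' value difference,
which correlates with recent rewards; this pushes *both*
outcome-by-importance interactions in the positive direction. In
egalitarian-MBCA cohorts (where the true modulation is zero) the
Unique-by-importance interaction is therefore partially mimicked (roughly
half of cohorts reach one-sided significance), while the negative
Other-by-importance interaction is robustly absent — indeed the confound
biases it the wrong way, which also attenuates the full model's negative
Other-by-importance effect at the moderate empirical modulation (0.28 vs
0.15), making it the least reliably detected of the six signatures at 42
subjects.

## The ideal Bayesian observer

The benchmark observer runs, per vegetable, an exact discretized Bayes
filter: a grid of 121 equally spaced points on [0.2, 0.8] (the estimate
moves by well under 0.005 when the grid is halved or doubled), a transition
kernel integrating the reflected-Gaussian step density over grid cells
(single reflection images suffice at SD 0.03; columns renormalized), a
Bernoulli likelihood update for each of the four outcomes every trial, and a
reset to the uniform prior on [0.2, 0.8] at block starts. The uniform prior
is a deliberate choice: the observer knows the walk process and the resets
but is not given the discrete initialization atoms, matching the closed-form
check that one sold observation from the uniform prior moves the posterior
mean to E[p^2]/E[p] = 0.56. The observer chooses the person with the higher
posterior-mean value sum; accuracy is scored against the generating
probabilities with true ties excluded (ties have probability ~0 except at
initialization) and observer ties broken at random. Over 200 default
sessions this yields an accuracy of about 0.82–0.83.

## Normative earnings simulations

`standardized_earnings()` scores an agent per session as
`(agent - random) / (oracle - random)`, where per trial the oracle takes the
better offered person's expected value and the random baseline their mean.
Two variance-reduction choices keep the grids cheap without changing
expectations: earnings integrate the *expected* reward of the (sampled)
choice rather than coin flips, and the agent's per-trial earnings integrate
over its own choice probability (the sampled choice still drives learning).
Consequences: the oracle scores exactly 1, a coin-flip policy exactly 0, and
the all-zero agent exactly 0, per session.

The sweep families map a 7 x 7 grid to full-model parameters: `mf_ratio`
(related MFCA weight x unrelated/related ratio from +1 down to -1),
`mf_split` and `mb_split` (total CA x split proportion), `mb_split_autocorr`
(the MB split on the autocorrelated task at persistence 0.9), and
`hybrid_split` (total CA x MF proportion, where the MF arm uses the
map-guided pattern — related positive, unrelated negative, equal magnitude —
so MB dominance is demonstrated against the *best* MF regime, and the MB arm
is egalitarian). Axis ranges cover the empirically reported parameter ranges
with margin. Nuisance parameters are fixed once: forgetting 0.2 for active
systems, perseveration off. Defaults are 2,000 simulated sessions per cell
(configurable; SE per cell about 0.005), and each column's maximum is
flagged when it is not at least two pooled SEs above the central-row cell,
in which case the central row is reported co-optimal. At these settings the
sweeps reproduce the expected optima: ratio -1 for guided MFCA, the equal
split for MBCA in the balanced task, an important-favoring split under
autocorrelation at moderate total CA (at large totals the softmax saturates
and the split matters little), and the pure-MB corner of the hybrid sweep.

## What the synthetic benchmarks do not show

The generator reproduces the task's structure, schedules and feedback, and
the agents that play it — not human behaviour. Passing tests establish
internal consistency (the estimators recover what the generator planted, the
tests are calibrated on their own nulls) and the normative claims about this
task's structure; they do not reproduce the original study's empirical
effect sizes, prevalence estimates or exceedance probabilities, which
require the deposited behavioural data and the original evidence
approximation. The optional loader path (`read_session()` on suitably
mapped CSVs) exists for such re-analysis but nothing here depends on it.

## Reproducibility

All randomness flows through R's RNG; sessions regenerate byte-identically
under a fixed seed, and the pipeline stages (`run_simulate()` through
`run_sweep()`) derive per-stage seeds from one master seed and are
idempotent. `scripts/acceptance.R` recomputes the task-difficulty and
ideal-observer anchors from scratch with a caller-supplied seed.
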