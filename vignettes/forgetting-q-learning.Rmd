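---
title: "Modelling reward seeking under punishment risk with forgetting Q-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward seeking under punishment risk with forgetting Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(forgetq)
```

## The behavioral problem

In a two-tone lever-pull task, a head-fixed mouse hears one of two tones and
then chooses to pull a lever or to withhold the pull. Pulling can produce a
water reward, but in a *positive punishment* variant it also risks an
air-puff to the eye, and in a *negative punishment* variant the expected
reward may be omitted. The two task structures bundled as presets are:

* **air-puff task** (`taskPreset("air_puff")`): tone A on 20% of trials;
  every pull is rewarded; a pull triggers an air-puff with probability 0.9
  after tone A and 0.1 after tone B;
* **omission task** (`taskPreset("omission")`): tone A on 40% of trials; a
  pull is rewarded with probability 0.1 after tone A and 0.9 after tone B;
  no air-puff is ever delivered.

A trial without a pull yields neither water nor air-puff. Tone A is the
high-risk cue in both tasks, and trained animals come to pull rarely after
tone A and frequently after tone B.

This package provides the full modelling pipeline for such data: trial-log
handling and preprocessing, a family of Q-learning models, maximum-likelihood
fitting with AIC/BIC comparison, generative simulation scored by RMSE, and a
single-parameter perturbation analysis that attributes an acute behavioral
change (for example after pharmacological inactivation of a cortical region)
to one model parameter.

## The model family

Each tone $x \in \{A, B\}$ carries its own pair of action values,
$Q_{x,\mathrm{pull}}$ and $Q_{x,\mathrm{non}}$. On a pull with reward
indicator $r$ and punishment indicator $p$:

$$Q_{x,\mathrm{pull}} \leftarrow Q_{x,\mathrm{pull}} +
  \alpha_l\,(\kappa_r r - \kappa_p p - Q_{x,\mathrm{pull}}), \qquad
  Q_{x,\mathrm{non}} \leftarrow (1-\alpha_f)\,Q_{x,\mathrm{non}},$$

and on a non-pull:

$$Q_{x,\mathrm{pull}} \leftarrow (1-\alpha_f)\,Q_{x,\mathrm{pull}}, \qquad
  Q_{x,\mathrm{non}} \leftarrow Q_{x,\mathrm{non}} +
  \alpha_l\,(\psi - Q_{x,\mathrm{non}}).$$

The other tone's pair is never touched; the two tones form independent
learning sequences. The pull probability is the temperature-free sigmoid of
the value difference,
$P_{x,\mathrm{pull}} = 1/(1+e^{-(Q_{x,\mathrm{pull}} - Q_{x,\mathrm{non}})})$.

The five parameters, their meaning, units (all dimensionless) and bounds:

| parameter  | meaning                                        | bounds    |
|------------|------------------------------------------------|-----------|
| `alpha_l`  | learning rate of the chosen action's value     | (0, 1)    |
| `alpha_f`  | forgetting (decay) rate of the unchosen value  | (0, 1)    |
| `kappa_r`  | subjective reward value of water               | [0, 20]   |
| `kappa_p`  | subjective aversion to the punishing event     | [0, 20]   |
| `psi`      | covert reward for withholding the pull         | [0, 20]   |

`kappa_r` and `alpha_l` appear in every variant; toggling `kappa_p`, `psi`
and `alpha_f` on or off gives exactly seven variants (`simple`,
`punishment`, `saving`, `forgetting`, `P-F`, `S-F`, `P-S-F`), a disabled
parameter being fixed at zero. The punishment indicator is task-dependent:
in the air-puff task it is the physical air-puff; in the omission task it is
a pull that goes unrewarded (`derivePunishmentIndicator()`). This makes the
omission task's "punishment" the exact complement of its reward on pull
trials — one reason the punishment weight is statistically fragile there
(see *Identifiability* below).

The upper bound of 20 on the outcome weights matches the ceiling of the
perturbation grid search, so fitting and perturbation explore the same
parameter space.

## Fitting and model comparison

`fitModel()` minimizes the negative log-likelihood
$-\sum_t \log z(t)$, with $z(t)$ the pull probability on pulled trials and
its complement otherwise, accumulating in log space and clamping each
per-trial probability to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-12}$, so the objective stays finite at the parameter
bounds. Initial Q-values for fitting are zero — the value-neutral start and
the fixed point of every disabled-parameter variant.

Optimization is bounded L-BFGS-B from uniform-random starting points within
the bounds, with the exact gradient of the likelihood carried analytically
through the update recursions (verified against finite differences in the
test suite). Each restart runs at a coarse convergence tolerance and the
best optimum is then polished at full precision; the contract is the usual
multi-restart one — a local optimum from every start, best kept. The default
restart count is 5,000, following the original procedure; the likelihood
surfaces of this family are low-dimensional and well behaved, and the test
suite uses 100 restarts (the scaled-down figure it also states), which in
practice reaches the same optimum as larger counts.

`informationCriteria()` computes $\mathrm{AIC} = -2\log L_{max} + 2K$ and
$\mathrm{BIC} = -2\log L_{max} + K\log T_n$; `compareModels()` fits all
seven variants, z-scores both criteria across them (the form used to
display per-subject scores), and reports the argmin of the raw scores, ties
resolving to the earlier model in the canonical order.

## Generative simulation and the two RMSE readings

`simulateChoices()` replays the subject's tone order; per replicate each
trial's action is drawn from the model's current pull probability, and
outcomes follow the coupling rule: simulated pull on an actually-pulled
trial replays the recorded outcome; simulated pull on an actually-withheld
trial draws from the task probabilities; simulated non-pull yields nothing.
Per-trial means across replicates and per-replicate RMSEs against the
actual binary choices are returned; the default replicate count is 1,000.

The summary RMSE supports two readings of "error between actual and
simulated choice". The default (`pred_mode = "binary"`) scores each
replicate's 0/1 choices and averages the RMSEs — the literal procedure. The
alternative (`pred_mode = "mean"`) scores the replicate-averaged choice
probability against the binary choices. The distinction matters more than
it looks: the binary score's per-trial expectation is
$a + (1-2a)P_{\mathrm{sim}}$, which is minimized by pushing
$P_{\mathrm{sim}}$ to 0 or 1 — an *improper* scoring rule that rewards
overconfidence. Consequently, a grid scan of a single parameter under the
binary score can sit away from the generative value even on self-generated
data, drifting toward values that sharpen the choice probabilities. The
probability score is proper and its argmin tracks the generative parameter;
the package's self-recovery test uses it, while attribution analyses keep
the default, since all candidate parameters share the bias and only their
relative RMSEs matter.

`binAverageChoices()` provides the subject-averaged display summary: 10
(tone A) and 40 (tone B) bins in the air-puff task, 20 and 30 in the
omission task, matching the tone presentation ratios; when the trial count
is not a multiple of the bin count the leading bins take one extra trial.

## Perturbation attribution

`identifyInjectionParameter()` asks which single parameter change best
explains a post-injection session. Each free parameter is scanned over a
fixed grid (rates 0 to 1 in steps of 0.01; outcome weights 0 to 20 in steps
of 0.1) with the others held at their training-fit values; each candidate
is scored by generative-simulation RMSE against the post-injection log, and
the parameter whose re-optimization achieves the smallest RMSE is reported
as the injection-related parameter, with `delta_rmse` = baseline −
optimized (improvement, non-negative on the canonical grids, which always
contain the unchanged value).

Two numerical choices are worth stating. First, the same random-number
stream is reused for every grid value and every parameter (the simulation
consumes exactly three uniforms per replicate-trial regardless of branch),
so grid differences reflect the parameter change rather than Monte-Carlo
noise. Second, ties resolve to the candidate closest to the original value
within a scan, and across parameters to the canonical order (`alpha_l`,
`alpha_f`, `kappa_r`, `kappa_p`, `psi`).

Initial values for the post-injection simulation follow one of two
conventions: `carryover` starts from the last Q-values of the training fit;
`steady_state` (air-puff task only) derives them from the candidate
parameter set itself, as the fixed point of the expected-value updates
($Q_{x,\mathrm{pull}} = \kappa_r R_x - \kappa_p P_x$,
$Q_{x,\mathrm{non}} = \psi$, with $R_x, P_x$ the task's outcome
probabilities), on the premise that an injection delivered before the
session means the equilibrated values already reflect the changed
parameter.

## Synthetic ground truth and what the tests show

`generateAgentLog()` simulates agents governed by the model equations
inside the task environments, emitting the behavioral log together with the
latent value and probability trajectories; `generateInactivationPair()`
produces matched baseline/perturbed sessions sharing tone schedules and
random draws, the synthetic stand-in for vehicle-control versus inactivation
sessions. Early pulls are never generated (the modelling excludes them
anyway), and no response-time, kinematic, satiety or attention dynamics are
emulated — passing tests demonstrate the estimation machinery on data that
obey the model exactly, not that real mice do.

### Identifiability and the reference regimes

`referenceAgent()` fixes one documented ground-truth regime per variant,
used by the recovery tests. Two structural facts drove their design. In the
omission task the punishment indicator equals $1-r$ on pull trials, so
`kappa_p` shifts both tones' pull values by the same constant and is nearly
collinear with `psi`; punishment-carrying variants are therefore probed in
the air-puff task, whose asymmetric puff probabilities (0.9 vs 0.1)
separate the punishment weight from the other offsets. Conversely, in the
air-puff task rewards are certain, so after the values equilibrate nothing
fluctuates unless a punishment term is present; variants without `kappa_p`
are probed in the omission task, where stochastic rewards keep the values
informative about the learning rate throughout the session. Within those
placements the magnitudes follow the qualitative regime of trained animals
(reward value of a few units, punishment weight large enough to suppress
high-risk pulling, saving term around one unit), sized so that each free
parameter retains useful maximum-likelihood precision at the
five-thousand-trial scale the recovery tests use. Even so, several
parameters sit near the information bound at that scale: the estimators are
unbiased, but standard errors of a few hundredths (rates) to a few tenths
(outcome weights) are intrinsic to the design, not removable by more
restarts.

### Problem sizes

The test suite runs recovery at 5,000 trials with 100 restarts and 20
generation seeds per model; model-selection recovery at 4,000 trials;
attribution recovery with 1,500 training trials, 250-trial post sessions,
200 simulation replicates and 20 seeds per perturbed parameter; and the
environment calibration checks at $10^5$ draws. These are the package's
documented study conditions for synthetic validation; the user-facing
defaults (5,000 restarts, 1,000 replicates) remain the original procedure's.

## Worked example

A compact end-to-end run on synthetic data:

```{r example, eval = FALSE}
ag <- referenceAgent("P-S-F")
sc <- scenarioConfig(taskPreset(ag$task), n_sessions = 1,
                     trials_per_session = 2000, seed = 42)
run <- generateAgentLog(sc, agentSpec("P-S-F", ag$params))
leverPullRate(run$log, "A"); leverPullRate(run$log, "B")

cmp <- compareModels(run$log, n_restarts = 100, seed = 1,
                     models = c("S-F", "P-S-F"))
cmp$best_by_aic

sim <- simulateChoices(run$log, taskPreset(ag$task),
                       cmp$fits[[cmp$best_by_aic]]$params,
                       n_reps = 200, seed = 2)
sim$rmse
```

The pipeline version of the same flow, driven by a YAML config and writing
JSON artifacts plus a run manifest, is `runPipeline()`; see
`system.file("extdata", "demo_config.yaml", package = "forgetq")`.

## Known limitations

* The choice rule has no inverse-temperature parameter (by construction),
  so choice stochasticity is controlled entirely by the value magnitudes;
  regimes with very large values produce near-deterministic choices and
  flat likelihood directions.
* Binary-choice RMSE is improper (see above); single-parameter argmin
  values under the default mode should be read as "best explaining", not
  as unbiased estimates of the underlying change.
* Parameter recovery precision at realistic session counts is bounded by
  the Fisher information of the design; the saving term and punishment
  weight trade off structurally in the air-puff task (a large `psi`
  suppresses exactly the high-risk pulls that identify `kappa_p`).
* The synthetic generators emulate the task contingencies only; none of
  the physiological or motivational structure of real sessions is modelled.
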