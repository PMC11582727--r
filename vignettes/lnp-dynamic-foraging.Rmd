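---
title: "Dynamic foraging and the linear-nonlinear-probabilistic choice model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic foraging and the linear-nonlinear-probabilistic choice model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragefit)
```

## The task

`foragefit` simulates and analyses a two-option dynamic-foraging experiment.
On every trial a participant (here: a synthetic agent) chooses between two
stimulus options drawn from the sets S1 = {low-pitch tone, green
checkerboard, auditory} and S2 = {high-pitch tone, red checkerboard, visual},
depending on the block's modality condition (`AudAud`, `VisVis`, `AudVis`).
Rewards are scheduled by independent per-trial Bernoulli arrivals — a
discrete-time rendering of a Poisson process, trials being the task's natural
time unit — whose per-option rates split an overall rate of 1/3 in the
block's programmed ratio (1:3, 1:1 or 3:1). Two classical schedule
constraints shape behaviour:

* **Baiting** — an assigned reward stays on its option until that option is
  next chosen, which punishes pure exploitation: the unchosen option
  accumulates certainty of reward.
* **Change-over delay (COD)** — a reward earned on the trial on which the
  choice just switched is withheld and delivered only if the same option is
  chosen again, which punishes indiscriminate alternation.

A session holds 9 value-task blocks (each reward ratio crossed once with each
modality condition, in random order) followed by 3 control-task blocks (one
per modality); the default experiment is two sessions of 72-trial blocks. In
the control task there is no reward schedule: yellow feedback instructs a
switch and blue a keep (a per-trial Bernoulli(1/3) instructed-switch flag,
earned by whichever option is chosen), and the agent follows instructions
with a set compliance (default 95%).

One schedule decision deserves emphasis, because it changes a headline
number. As in concurrent variable-interval schedules, the reward clock of an
option is *suspended while its bait slot is occupied* (by a bait or by a
pending COD reward): a clock tick on an occupied slot assigns nothing. Under
the alternative accounting, in which such ticks count as assigned-and-lost
rewards, the fraction of assigned rewards an agent can collect plateaus
around 60–62% for any sensitivity between 0.1 and 1.5 — no agent, however
tuned, can approach the mid-90s harvest the task is known for. With the
suspended clock the only losses are baits left on the schedule at block end,
and harvest lands in the mid-90s. `assign_rewards()` still draws the raw
clock (24 ticks per 72-trial block on average, which is what an agent-free
measurement of the schedule sees); `step_value_trial()` reports which ticks
were realized as assignments, and `harvest_rate()` divides delivered by
realized-assigned.

## The model

The linear-nonlinear-probabilistic (LNP) model splits choice into a learning
and a decision stage.

**Learning.** The delivered-reward history of option *i* is the binary vector
r_i(t−k), 1 when option *i* was chosen and rewarded k trials ago. Subjective
value is a causal linear filter over the last n trials,

v_i(t) = Σ_{k=1..n} w_k · r_i(t−k),

with n = half the span over which the reward ratio is constant (36 for
72-trial blocks). With weights normalized to sum to 1, v_i lives on a 0–1
reward-fraction scale and the differential value dv = v1 − v2 in [−1, 1].

**Decision.** The probability of choosing S1 is the cumulative normal
Φ(dv; μ, σ): μ is a bias in dv units and σ the sensitivity (explore–exploit)
parameter — σ → 0 is deterministic exploitation of the value comparison,
large σ is random exploration.

**Fitting.** Because assignment is symmetric over options, learning is
estimated on the composite series r = r1 − r2 and c = c1 − c2. The filter
weights solve the Wiener–Hopf equations α = C_rr⁻¹ C_rc, with C_rr the n-lag
auto-covariance matrix of r and C_rc the lagged cross-covariance with c;
covariances are computed on mean-centred series with 1/T normalization, and
lags never cross block boundaries (missing history counts 0). This is
numerically identical to ordinary least squares of c on the lagged-r design
with an intercept — a property the test suite checks against `lm()` to 1e-8.
The weight profile is summarized by fitting A·exp(−k/τ); τ is the learning
time scale in trials. The decision stage is fitted by splitting trials into
20 equal-count bins of dv and least-squares fitting Φ(dv; μ, σ) to the bin
proportions (a trial-level maximum-likelihood probit is available via
`method = "probit"` and agrees within simulation error).

The generative agent uses the same model with the exponential filter
directly: weights ∝ exp(−k/τ), normalized, over delivered rewards only — on
a COD trial the withheld feedback enters the history as 0, because the
history is defined by delivered feedback.

## Choices the data forced

Several places where the procedure is genuinely underdetermined were decided
as follows; each was measured, not assumed.

**Subjective values use the fitted exponential filter.** The raw Wiener–Hopf
solution with n = 36 lags estimated from ~300 within-condition trials is
noisy, and its normalization divides by the (noisy) weight sum: in a minority
of fits the sum is near zero or negative, which flips or explodes the
relative weights and, downstream, the value series. `fit_lnp()` therefore
computes values with the normalized exponential weights at the fitted τ (the
model's parametric filter); `weights = "raw"` restores the literal Eq.-4
behaviour. For the same reason `fit_exponential_decay()` fits the raw
weights — τ is invariant to overall scale, so the result is identical to
fitting the normalized weights whenever their sum is positive, and
well-defined when it is not.

**The control task's reinforcement signal is compliance.** The control task
pays no rewards; its performance currency is following the instructions.
When the LNP machinery is fitted to control-task behaviour (for the
absDV-by-feedback analysis), the reward-analog is "chosen and instruction
correctly followed". Treating the yellow switch-instruction itself as a
reward-analog instead makes the fitted absDV cells unstable and
systematically unequal — the most recent "reward" then always sits one lag
behind a yellow, inflating |dv| after yellow feedback — which would
manufacture a feedback effect in a task designed to have none.

**Transfer to the control task uses delivered rewards.** When value-task
parameters are tested on control-task choices (the leave-one-out transfer),
subjective values are computed from actual delivered rewards. The control
task delivers none, so dv is identically zero and prediction is at chance —
which is precisely the dissociation the transfer analysis is meant to show.

**Post-switch exclusion and what it does to estimates.** Trials on which the
choice just changed are excluded from all fitting and scoring: the COD makes
them unrewardable and hence not fully free. This exclusion conditions the
analysed sample on *staying*, i.e. on the outcome variable. Two measured
consequences:

* Refitted parameters are conditional estimates. Simulating at
  (τ, μ, σ) = (1.22, 0.07, 0.81) and refitting recovers ≈ (1.5, 0.04, 0.26):
  τ is biased long, σ steep. The estimators themselves are unbiased — on
  choices sampled from Φ(dv; μ, σ) over a frozen dv stream with no exclusion,
  μ and σ are recovered within simulation error, and τ within sampling error
  of its grid-search oracle — the bias is induced entirely by the exclusion
  (including switch trials as regression targets restores τ ≈ 1.3; toggling
  the COD has no effect). A cohort-level "refit recovers the generative
  parameters" check therefore fails by construction under the published
  procedure, and the acceptance suite reports that honestly rather than
  redefining the procedure.
* Valid-trial prediction accuracy is not bounded by the unconditional
  ceiling. For a deterministic predictor of an LNP generator, accuracy over
  *all* responded trials equals E[max(p, 1−p)] (verified against that oracle
  within Monte-Carlo error); over valid trials only, accuracy sits above it,
  because the scored trials are exactly the stays. `leave_one_out_accuracy()`
  exposes both via its `score` argument and defaults to the published
  valid-trial scoring.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `trials_per_block` | 72 | trials | even; divisible by 8 in `AudVis` blocks for exact counterbalancing |
| `overall_reward_rate` | 1/3 | per trial | total Bernoulli tick rate over both options |
| `reward_ratios` | 1:3, 1:1, 3:1 | — | per-block S1:S2 split of the overall rate |
| `control_switch_rate` | 1/3 | per trial | instructed-switch probability |
| `bait_cap` | 1 | rewards | bait slots per option; the clock suspends at the cap |
| `cod_enabled` | TRUE | — | change-over delay in the value task |
| `tau` | 1.22 | trials | agent filter time scale (group mean) |
| `mu` | 0.07 | dv units | agent choice bias (group mean) |
| `sigma` | 0.81 | dv units | agent sensitivity (group mean) |
| `compliance` | 0.95 | probability | control-task instruction following |
| `n` (filter length) | 36 | trials | half the constant-ratio span |
| `n_bins` | 20 | — | equal-count dv bins for the choice fit |
| `tr_seconds` | 1.5 | s | fMRI sampling interval |

Numerical choices: the exponential and cumulative-normal fits use bounded
multi-start Levenberg–Marquardt (τ ∈ (0, n], σ ≥ 1e-3, starts spanning two
orders of magnitude); near-singular C_rr (condition number > 1e8) is solved
with a small ridge and flagged; choice probabilities are clipped to
[1e-6, 1−1e-6] in the generator to avoid absorbing states; σ = 0
degenerates to the deterministic rule with ties broken toward repeating;
equal-count binning breaks dv ties deterministically by block and trial; a
zero-variance reward history is an error ("degenerate reward history").

## The fMRI regressors

`build_event_table()` lays out the published univariate design: per task ×
condition one unmodulated stick regressor at stimulus onset (trial identity)
and two parametric sticks carrying the per-option subjective values — named
`lpSV`/`hpSV` (auditory), `gSV`/`rSV` (visual), `aSV`/`vSV` (audio-visual) —
or, in the control task, 0/1 compliance weights; plus unmodulated response
and feedback regressors collapsed across tasks and a block-start instruction
regressor. `convolve_hrf()` mean-centres each parametric modulator, places
sticks on a fine grid (TR/16), convolves with the canonical double-gamma HRF
(response gamma shape 6, undershoot shape 16, ratio 6, 32 s support — the
community defaults) and samples at the scan grid. `serial_orthogonalize()`
residualizes each condition's second modulator against the first (sequential
projection; earlier regressors unchanged), and `build_design_matrix()`
assembles the full 35-column scheme: 18 task regressors, response, feedback,
and 15 nuisance columns (instruction, six zero motion placeholders, 7 run
indicators for the 8 runs, constant). The two compliance modulators of a
control condition are identical by construction, so the second is zeroed by
orthogonalization with a warning — the expected behaviour for that design.
Motion placeholders are named zero columns: real head motion is out of scope.

## What the simulation does and does not emulate

The generator reproduces the task's structure exactly (block grid, exact
side/pairing counterbalancing, baiting, COD, instructed switches, trial
timing with uniform fixation jitter on 1.8 ± 0.45 s — the distribution is a
choice; only the mean and spread are given) and the LNP choice process at
the published group-mean parameters. It does not emulate: missed responses
(agents always respond; the schema records `choice = none` and downstream
code skips such trials), reaction-time structure (RTs are uniform fillers for
event timing), perseveration or choice-kernel effects beyond the LNP (real
matching behaviour is stickier than the fitted LNP — the simulated switch
rate is ~43%, at the top of the plausible band, versus ~27% in humans), any
modality bias (off by default; a per-condition μ can reproduce one), and
session-level nonstationarity. Passing tests therefore validate the
machinery and the internal consistency of the published pipeline on data
that obey the LNP exactly; they do not certify the LNP as the true model of
human foraging.

Problem sizes used by the tests and the acceptance script — a 20-agent
cohort of the full two-session experiment (34,560 trials), 10,000 schedule
draws for the assignment checks — were chosen so Monte-Carlo error is well
inside every stated tolerance.

## Known limitations

* The Wiener–Hopf filter at n = 36 from ~300 within-condition targets is
  noisy; per-modality τ estimates scatter (s.d. ≈ 0.4 across conditions) and
  are stabilized by the raw-weight exponential fit, not by regularizing the
  filter itself.
* Group-mean refits are conditional-on-stay estimates (see above); comparing
  them directly to generative parameters conflates the estimator with the
  exclusion rule.
* The control-task reinforcement signal (compliance) is a modelling choice
  the task description underdetermines; alternatives are selectable
  (`signal` argument) and measurably worse behaved.
* `bait_cap > 1` is supported but untested against any published benchmark;
  the suspended-clock accounting applies at the cap.
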