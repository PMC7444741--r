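---
title: "Modelling a rule-cued cross-modal attention task as active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a rule-cued cross-modal attention task as active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeinf)
```

## The task and the model

A mouse hears one of two auditory cues (blue or brown noise). The cue sets an
attentional rule: after a delay, visual and auditory target stimuli appear
simultaneously, and the animal must report the target carried by the *cued*
modality, ignoring the other. A correct report earns milk. Solving the task
requires (i) inferring the rule from the cue, (ii) holding it across a delay
in which no informative stimulus is present, (iii) using it to gate the two
sensory streams, and (iv) converting the gated evidence into a choice.

`activeinf` treats this as exact Bayesian decision making in a discrete-state
partially observed Markov decision process with three hidden factors — rule
(attend-vision / attend-audition), target (blue / green) and choice
(no-choice / blue / green) — and four outcome modalities (cue, vision,
audition, feedback), each with a "null" level for phases in which the
modality is silent. The agent's generative model is the usual categorical
quadruple:

* **A** (likelihood): one stochastic array per modality and trial phase,
  mapping the joint hidden state to outcome probabilities. The phase
  dependence is stored as one array per time step; this is equivalent to
  conditioning a single array on a deterministic clock factor, with a
  smaller state space and identical marginals.
* **B** (transitions): identity matrices for rule and target — the precise
  recurrent dynamics that carry beliefs across the delay — and an
  action-dependent matrix for choice (stay / pick-blue / pick-green, picked
  levels absorbing).
* **C** (log-preferences): zero everywhere except feedback at the final
  step: `+c` for correct, `-c` for incorrect. Published descriptions of the
  task leave the magnitude open; the package default is `c = 3` nats, large
  enough that the correct-choice policy dominates the softmax, and exposed
  (`build_task_model(preference = ...)`) for sensitivity analyses.
* **D** (initial priors): uniform over rule and target; choice starts at
  "no-choice" with certainty.

Attention is purely structural here: at the stimulus phase the attended
modality's likelihood is an identity map from the target (mutual information
ln 2) and the unattended modality is uniform (mutual information 0). Nothing
else implements "gain control"; the gating emerges from inference, because
the sensory message to the target population is the contraction of the
log-likelihood with the current rule beliefs.

The policy space defaults to the three terminal-choice sequences
(stay, stay, *u*): the task permits one response, after the stimuli. A
`full-tree` mode (all 27 sequences) exists to study premature responding.

## Inference: variational message passing

Per policy, beliefs are a mean-field product over factors and represented
times. Each population holds a potential `v` (depolarization), its softmax
`s` (firing rate / expectation), and updates via the prediction error

```
eps = w * (forward + backward) + sensory - v,     v <- v + kappa * eps
```

with the forward message the expected log-transition from the previous
represented time (the log initial prior at the first), the backward message
its transpose from the next, and the sensory message the observed-outcome
contraction of the floored log-likelihood with the other factors' beliefs.

Numerical conventions, all configurable through `engine_settings()`:

* `n_iter = 16` iterations per observation epoch, `kappa = 0.25`. The
  sources this scheme derives from do not print their constants; these
  values converge well before the epoch ends while leaving a visible,
  plottable transient.
* Updates are **parallel** (Jacobi): every unit computes its error from the
  same snapshot of activity before any potential moves. Sequenced sweeps
  reach the same fixed points but propagate the entire represented-time
  chain in a single iteration, which hides the staggered onsets across
  represented times (the "place coding for time") that the simulated
  electrophysiology is meant to display.
* `message_form = "expected-log"` (default) uses `E_s[ln B]` messages: the
  exact mean-field form, under which the free energy is a true bound on
  surprise and descends within epochs. The `"marginal"` form (`ln(B s)`) is
  provided as the variant used by marginal message-passing schemes; under it
  the free energy evaluated at the prior with no observations is exactly
  zero, but the bound and descent properties fail by a Jensen gap, which is
  why it is not the default.
* Every log of a probability is floored as `log(p + exp(-16))`, so
  impossible outcomes carry a -16-nat penalty rather than `-Inf`.
* Beliefs warm-start across epochs, so the iteration traces concatenate
  into one continuous 64-bin within-trial time series.
* Policies are scored by `softmax(-gamma * (F + G))` with `gamma = 1`; a
  `prior-only` flag scores by `-G` alone. Expected free energy `G` is risk
  (divergence of predicted outcomes from log-preferences) plus ambiguity
  (expected outcome entropy given states); the task affords no epistemic
  foraging, so no novelty term is included. Actions take the posterior
  marginal over the current step's action, ties resolving to the lowest
  index.

### What the tests can and cannot certify about the engine

On deterministic models the converged beliefs equal exhaustive-enumeration
smoothing to 1e-6. On random stochastic chains the mean-field fixed point is
an I-projection, not the vector of exact smoothed marginals: across seeded
2-level, 3-step chains the median divergence is ~0.002 nats, but a minority
of draws (roughly one in ten, typically with near-degenerate parameters)
exceeds KL 0.05, and no variant of this message-passing family avoids that.
The test suite therefore certifies exactness for deterministic models and
the median-level agreement for stochastic ones, and the known worst-case
behavior is stated here rather than hidden.

## The environment

The generative process mirrors the agent's likelihood evaluated at the true
states: the cue names the rule, the delay is silent, the attended modality
shows the target, feedback rewards a match (and punishes no-choice). The
unattended distractor has two modes:

* `"independent"` (default): drawn uniformly from the two stimulus levels,
  exactly matching the model's uniform unattended likelihood, so trials are
  congruent (distractor equals target) half the time.
* `"incongruent"`: the distractor always contradicts the target — the
  conflict condition of the divided-attention task this models, and the
  condition under which the rule is indispensable.

The distinction matters for lesion experiments. A rule-blind agent still
answers congruent trials correctly, because both modalities then point at
the target; analytically its error rate under the independent mode is 25%
(half the trials congruent and correct, half incongruent and at chance),
which the simulations reproduce. The claim that a complete failure of delay
maintenance produces errors on *half* of trials presupposes conflict on
every trial, so chance-level performance is asserted under the incongruent
mode, and under the default mode the congruency-resolved accuracies (1.0 and
~0.5) are asserted instead. A congruency flag is recorded per trial.

One master seed drives everything; conditions, distractor draws and
synthetic-neural-data noise use sub-streams derived with `derive_seed()`, so
every module is independently reproducible.

## Simulated electrophysiology

A unit is a (factor, level, represented-time) population. Its firing rate is
the policy-averaged expectation `sum_pi posterior(pi) s_pi`, with the policy
posterior evaluated at the same iteration bin; the matching policy-averaged
depolarization summed over a population, first-differenced, is read out as
the local field potential (zero wherever beliefs are static — in practice
the delay-period LFP is under 5% of the cue-epoch deflection). Rasters
render rates as density by default, matching the figure style the package
reproduces; a seeded point-process mode draws binary events instead. The
expected physiology holds per trial: rule units concentrate in epoch 1 and
persist (delay-period activity carried by the identity transitions), target
units at epoch 3, choice units by epochs 3–4; units representing the first
time step stay concentrated to the trial end (postdiction).

## Lesions

Lesions are convex mixtures of the targeted arrays toward uniform, giving a
graded severity axis whose endpoints are the published manipulations:
lateral prefrontal damage flattens the rule transitions (delay-period rule
beliefs collapse to exactly 0.5; stimuli cannot be gated; choices fall to
chance under conflict), and medial damage flattens the feedback likelihood
at every step (only the final step matters functionally; rule and target
inference survive, but expected free energy becomes identical across
policies — spread below 1e-9 — so the policy posterior stays maximally
uncertain). Two alternatives discussed alongside them are included:
cue-likelihood flattening (rule and cue rendered conditionally independent)
and preference flattening. All lesioned models remain valid stochastic
models at every severity.

## Canonical variates analysis

To illustrate predictive validity, the package regenerates the
multivariate-analysis demonstration: a three-column design matrix of
population time-courses from one intact trial, data synthesized as
`design %*% M + E` with standard-normal mixing onto `k = 10` simulated
neurons (the source does not state a width; 10 exceeds the design rank
comfortably), and CVA with sequential Bartlett chi-square tests on Wilks'
lambda at `alpha = 0.05` (the source does not name its procedure; a
row-permutation test is available as an assumption-free alternative).

Two constructions needed care:

* **Noise scale.** The stated signal-to-noise ratio of 8 is applied to the
  *centered* mixtures: CVA centers both matrices, so noise scaled to the raw
  mixtures (whose means dominate their rms, firing rates living in [0, 1])
  would make the nominal SNR an effective ~1.6 on the analyzed variation
  and lose the third variate.
* **Choice column.** Rule and target columns average the inferred-level
  belief across each factor's represented-time units, all of which carry
  the inference. Choice units for pre-decision times represent "no choice"
  and carry no decision signal, so averaging them merely rescales the
  decision-time unit and leaves the column collinear (r = 0.93) with the
  target time-course; the default therefore reads the choice population at
  the represented present — the enacted decision, which rises one epoch
  after the target — and the represented-average variant remains available
  (`choice_signal = "represented-average"`).

With these defaults the modal outcome over 100 mixing/noise seeds is three
significant variates (100/100 in the packaged configuration), the count is
non-decreasing along an SNR ladder (0.5, 2, 8, 32), and on design-independent
noise at least one variate is "significant" in well under 10% of seeds.

## Problem sizes and limitations

All packaged simulations are small by design: a trial is 3 policies x 4
epochs x 16 iterations over a 2 x 2 x 3 state space (about 0.2 s), sessions
are 50–200 trials, the oracle battery enumerates 2-level 3-step chains, and
the CVA study uses 100 syntheses of a 64 x 10 data matrix.

What passing tests show is internal: Bayes-optimality of the intact agent
*under its own generative process*, the double dissociation of the synthetic
lesions, and recoverability of the three population time-courses from
noisy linear mixtures. They do not show that real mice implement this
scheme: the generator emulates a noiseless, over-trained task with fixed
delay length, no inter-trial learning (the arrays are given, not learned),
no reaction times, and stimuli exactly as the model expects them. Known
limitations: mean-field marginals deviate from exact smoothing on a minority
of adversarial models (quantified above); the electrophysiology is a
rate-level idealization with no biophysics; and Bartlett's test treats
iteration bins as independent rows, which is anticonservative for
autocorrelated time-courses — acceptable for a demonstration, and the
permutation option exists where calibration matters.
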