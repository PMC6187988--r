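---
title: "Arbitration of model-based and model-free avoidance learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitration of model-based and model-free avoidance learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the task, the
dual-controller model and its assumptions, the choices we made where the
design was genuinely open, and what the simulation-based validation does
and does not establish.

## The task

A two-step avoidance task: from a single initial state, a LEFT/RIGHT
choice leads stochastically to one of four intermediate states, where a
second choice leads to one of four outcome states, shown as coloured coins
(red, yellow, blue, grey) carrying 0, 1, 2 or 4 electric shocks. The
0-shock coin is red and the 4-shock coin grey. Two manipulations create
the model-based/model-free dissociation:

* **Goal condition.** In *flexible* blocks every coin keeps its face
  value, so a fixed stimulus–response habit suffices. In *specific* blocks
  a goal colour (red, yellow or blue — never grey) is displayed and
  resampled every trial; only the matching coin keeps its value, all
  others deliver the 4-shock default. Exploiting this requires planning
  over an internal model of the transitions, i.e. outcome devaluation.
* **Transition uncertainty.** Each (state, action) has two configured
  successors, visited with probability 0.9/0.1 in *low*-uncertainty blocks
  and 0.5/0.5 in *high*. Blocks run 3–5 trials (low) or 5–7 (high).

A full experiment comprises a 100-trial training session (flexible goal,
0.5/0.5 transitions, no shocks delivered) followed by two sessions that
together hold 12 blocks of each of the four condition cells — 48 blocks —
randomly interleaved within session (6 per cell per session, the only
allocation consistent with the printed totals).

### Successor layout

The mapping of "likely" successors per (state, action) is a design choice
constrained by the behavioural structure the task must produce: in the
flexible condition the optimal first-stage action should be the same under
both uncertainty levels, while the optimal second-stage action at the
likely intermediate state should flip. The default layout pairs the best
and worst coins (0 and 4 shocks) on one action and the middle coins (1 and
2) on the other at the critical states: under low uncertainty the 0.9
chance of the 0-shock coin wins; under high uncertainty the 0/4 gamble
averages 2 shocks and the 1/2 pair (1.5 shocks) becomes optimal. With the
default layout the first-stage optimum in the flexible condition is
`R` at both uncertainty levels and the second-stage optimum at the likely
intermediate state is `R` (low) versus `L` (high); every goal colour is
reachable with high probability from at least one intermediate state, so
specific-goal planning is always meaningful. This is checked in the test
suite via exhaustive expectimax enumeration.

A consequence worth noting: "success" is a trial delivering 0 shocks (a
configurable alternative, shocks < 4, is deliberately not the default),
and the *shock-minimising* ideal agent does not maximise success — under
flexible/high it prefers the certain 1–2 pair and its success probability
is 0, below the random baseline. The enumerated baselines expose this.

## The two learners

Outcomes enter with negative sign (n shocks = value −n), so both systems
maximise value and avoidance is maximisation of negative pain.

**Model-free SARSA.** `Q_MF` over the five choice states is updated by the
outcome prediction error `OPE = r + Q_MF(s', a') − Q_MF(s, a)`, scaled by
the shared learning rate `alpha`. The first-stage update uses `r = 0` and
bootstraps from the second-stage action actually chosen (on-policy); the
outcome-stage update uses `r = −shocks` and no successor term. Because no
outcome occurs before the terminal transition, `Q_MF` is confined to
[−4, 0] and no prediction error can exceed 4 in magnitude — a bound used
below. The model-free system never reads the goal: holding the experienced
states, actions and outcomes fixed, permuting the goal sequence leaves
`Q_MF` unchanged (a property test), which is the computational content of
"habits cannot see ahead".

**Model-based FORWARD learner.** The transition model `T(s, a, s')` over
the two configured successors of each pair is updated by the state
prediction error `SPE = 1 − T(s, a, s_observed)` with increment
`alpha · SPE`; the unobserved successor is rescaled multiplicatively so the
row stays stochastic (the standard estimator-family choice, and the one
that keeps every entry in [0, 1]). Values are recomputed by exact backward
induction over the two-level tree. On every trial the terminal values are
first set by the goal rule (devaluation), then planning runs; this ordering
— devalue before the first choice — reflects that the goal box is visible
from trial onset.

Initialisation is least-informative: `Q_MF = 0`, `T` uniform (0.5),
terminal values at the flexible map. Simulated subjects then run the
100-trial training session before the experimental sessions, so initial
experimental values are experience-shaped rather than hand-set. During
training no shocks are delivered; learning is driven by the displayed coin
magnitudes (the reading we adopt of how subjects could learn the
contingencies without stimulation). Values persist across blocks and
conditions — the sessions are continuous, with no resets.

## Reliabilities and arbitration

The model-free reliability is driven by an estimator of the absolute OPE,
`Omega <- Omega + eta · (|OPE| − Omega)`; if the estimator predicts zero
OPE, reliability is maximal: `chi_MF = max(0, 1 − Omega/Omega_max)`. We
set `Omega_max = 4`, the maximum attainable |OPE| given that outcomes
occur only at the terminal transition (see the bound above); a larger
normaliser compresses `chi_MF` towards 1 and renders the arbitration
insensitive to the devaluation-driven errors that should drive control
towards the planner. It remains configurable.

The model-based reliability counts a transition as perfectly predicted
when its SPE falls below the threshold `omega`; `chi_MB` is the
exponentially weighted rate of such zero-SPE transitions. The indicator
average shares the learning rate `eta` with the Omega estimator so that no
unfitted free parameter is added beyond the six the model names.

Control is allocated by a two-state dynamical system on (p_MF, p_MB),
p_MF + p_MB = 1, with logistic transition rates modulated by the
reliabilities:

```
tau_MF->MB = A_MF->MB · sigma(B (chi_MB − chi_MF))
tau_MB->MF = bias_MF · A_MB->MF · sigma(B (chi_MF − chi_MB))
p_MB <- p_MB + tau_MF->MB (1 − p_MB) − tau_MB->MF p_MB   (clipped to [0, 1])
```

The functional form is a design choice: the model fits two *amplitudes*,
so we fix a shared logistic steepness `B = 10` on the reliability
difference and let the amplitudes be free. An alternative form — each rate
a logistic of the *other* system's reliability alone — would also satisfy
the verbal description; we prefer the difference form because it makes the
equilibrium weight a monotone function of `chi_MB − chi_MF` (a property
test checks this monotonicity). The fixed bias towards habit at equal
reliabilities is implemented as the multiplier `bias_MF = 1.5` on the
MB-to-MF rate, the simplest mechanism with the required effect.
Reliabilities update after every prediction error (two OPEs and two SPEs
per trial); the weight updates once per trial, after the outcome. Choices
are softmax with inverse temperature `beta` on the convex combination
`Q = p_MB Q_MB + (1 − p_MB) Q_MF`.

## Parameters

| parameter | role | default | why |
|---|---|---|---|
| `alpha` | shared value/transition learning rate (per update) | 0.5 | fast enough to re-adapt within 3–7-trial blocks |
| `eta` | reliability learning rate (per update) | 0.5 | reliability must track block-level changes; the pain context favours dynamic reliability |
| `omega` | zero-SPE threshold (probability) | 0.45 | counts a transition as predicted iff its SPE beats the 0.5 chance level |
| `A_MF->MB`, `A_MB->MF` | transition-rate amplitudes (per trial) | 0.5, 0.3 | weight can move substantially within a block |
| `beta` | softmax inverse temperature (1/value) | 3 | decisive but stochastic choice at value differences ~1 shock |
| `B` | logistic steepness (fixed) | 10 | a reliability difference of 0.1 is already decisive |
| `bias_MF` | MB-to-MF rate multiplier (fixed) | 1.5 | habit bias at equal reliability |
| `Omega_max` | `chi_MF` normaliser (fixed) | 4 | maximum attainable \|OPE\| |
| `p_mb0`, `zspe0` | starting weight / zero-SPE rate | 0.5 | uninformative midpoints |

The free-parameter defaults are the generator's study conditions. They
were chosen, once, so that the arbitration expresses the dynamics the
model is meant to capture — weight on the planner rising under specific
goals and low uncertainty, falling under flexible goals — which is the
premise of the regime analysis; with a compressed `chi_MF` (e.g.
`Omega_max = 8`) or sluggish reliabilities the weight never leaves the
habitual regime and the arbitration is vacuous. The suite verifies the
separation directionally and via the likelihood-ratio analysis; we did not
revisit the defaults thereafter.

## Simulation and likelihood

One compiled engine (Rcpp) executes the within-trial sequence —
devaluation and planning, softmax first choice, transition, SPE update and
replanning, second choice, SARSA updates, outcome under the goal rule,
reliability updates, weight update — in two modes: free-running
(simulation) and teacher-forced along observed choices and outcomes
(likelihood replay). Sharing the code path is itself an invariant: the
suite simulates with a fixed seed and replays the resulting log, requiring
identical latent traces, and cross-checks both against an independent
replay built from the exported R step functions. Replay recomputes the
outcome value deterministically from (outcome state, condition, goal), so
a log's shock column cannot contradict its goal column.

The likelihood sums `−log P(a)` over both stages of every included trial,
flooring each choice probability at 1e-12. Penalising trials (no response
within the deadline; simulated via an optional per-trial miss probability
as computer-random choices flagged excluded) contribute nothing.
Training-session choices are excluded from the likelihood by default —
the replay still runs through training so the model's values are
experience-shaped at the first experimental trial — with a flag to include
them.

Fitting uses Nelder–Mead from multiple uniform random starts inside the
bounds (learning rates and amplitudes [0.01, 1], threshold [0.01, 0.99],
`beta` [0.01, 20]), searching in a scaled-logit transformed space so the
simplex is unconstrained; function tolerance 1e-6, at most 2000
evaluations per restart; restart k starts from a deterministic child seed
of the master seed, so enlarging the restart count only appends start
points. The bounds and transform are declared as this package's choices,
not inferred from any original implementation. Per-subject fitting is the
default (group statistics are computed from per-subject fits, which is
what between-group parameter tests require); pooled fitting is available
by passing a list of trial logs. The MF-only and MB-only variants pin the
weight and fit only `alpha` and `beta` — the remaining parameters do not
enter their likelihoods.

Ties in the ideal policy's expectimax are broken by fixed action order
(`L` before `R`). Degenerate inputs are rejected at construction:
probability vectors must sum to 1 and equal {0.9, 0.1} or {0.5, 0.5},
shock magnitudes must be exactly {0, 1, 2, 4} with red = 0 and grey = 4,
and trial logs whose transitions the environment cannot produce are
refused at replay.

## What the synthetic data do and do not establish

The generator emulates the design of the study — the state tree, the
transition schedule, goal devaluation, block structure, training session
and penalising trials. It does not emulate reaction times, fatigue or
habituation of pain ratings, sequential dependencies beyond the model
(e.g. perseveration), or individual lapses in attention. Passing tests
therefore establish that the pipeline is *self-consistent*: the model
implements the stated equations, the fitting machinery can retrieve
generating parameters at the study's scale (15 subjects, 48 blocks), and
the regime analysis recovers the controller that actually generated the
choices. They do not establish that human avoidance behaves this way; the
analyses of real behavioural summaries (group t statistics on human data)
are outside what synthetic cohorts can reproduce, and the reward-vs-pain
comparison is reproduced structurally on two synthetic cohorts differing
in `eta` rather than on the original datasets.

## Problem sizes used by the validation suite

The suite runs the structural checks instantly; the stochastic ones use
10,000 transition draws (3 binomial standard errors), 1,000 random
instances for the backward-induction/expectimax equivalence (tolerance
1e-10), 20 simulated subjects for the regime likelihood-ratio analysis
(each with 5-restart fits of the two 2-parameter pinned variants), and a
15-subject, 20-restart recovery study for the 6-parameter model. These
sizes were chosen as the smallest at which the corresponding quantities
are stable across seeds.

## Known limitations

* `chi_MB` is an exponentially weighted indicator rate; a Bayesian
  posterior over zero-SPE counts is a defensible alternative reading of
  the same verbal description and would change the reliability dynamics
  quantitatively.
* The logit arguments of the transition rates are fixed by our design
  choice (reliability difference, shared steepness); the amplitudes absorb
  some, but not all, of the difference to other forms.
* Inter-state and inter-trial intervals are scheduling metadata only; no
  computation depends on them, and reaction times are not modelled.
* The likelihood treats the environment's transition layout as known to
  the analyst; fitting data from a different successor layout requires
  constructing the matching environment first.
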