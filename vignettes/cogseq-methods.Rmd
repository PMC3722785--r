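---
title: "Models and methods: simulating strategic cognitive sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating strategic cognitive sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogseq)
```

`cogseq` packages four desk-scale neural-circuit simulations of how
prefrontal cortex (PFC), basal ganglia (BG), the midbrain dopamine system
and the hippocampus cooperate to select, sequence and plan cognitive
actions. All four models run on fully synthetic inputs generated inside the
package, under a single master seed, and return tidy per-trial records.
This vignette explains each model, its assumptions, the parameters that
matter, and the design decisions taken where the architecture left choices
open.

## The rate-coded substrate

All models share a minimal substrate (`layer_spec()`, `projection_spec()`,
`network_spec()`, `settle()`): layers of units with activations in $[0,1]$,
weighted projections, and synchronous settling. Each cycle computes net
input (scaled weighted sums over incoming projections, divided by the
number of projections so wiring density does not inflate drive), subtracts
a hard k-winners-take-all (kWTA) inhibition threshold placed midway between
the k-th and (k+1)-th largest net inputs, and pushes each unit a fraction
of the way toward a logistic target:

$$a_i \leftarrow a_i + \lambda\,\big(\sigma(g\,(\eta_i - \theta_k)) - a_i\big),
\qquad \sigma(x) = \frac{1}{1+e^{-x}}.$$

Defaults: step rate $\lambda = 0.3$, gain $g = 5$, tolerance $0.005$ on the
maximum per-unit change, 100-cycle budget. A deliberately smooth step rate
keeps the *phases* of settling observable — the subgoal-discovery model
depends on being able to inspect early, middle and late snapshots. The
logistic unit is a stand-in for more biophysically detailed rate functions;
any saturating monotone sigmoid with $\sigma(0)=\tfrac12$ preserves the
behaviours the models rely on. Inhibition is the hard midpoint-threshold
kWTA variant; ties resolve toward the lowest unit index so tests are
deterministic.

Three local learning rules operate on weights clipped to $[0,1]$:

* **Hebbian (CPCA-style)** `hebbian_update()`:
  $\Delta w_{ij} = \epsilon\, y_i (x_j - w_{ij})$, which converges each
  active row onto the presynaptic pattern (default $\epsilon = 0.04$).
* **Contrastive error-driven** `error_driven_update()`:
  $\Delta w_{ij} = \epsilon\,(y_i^+ x_j^+ - y_i^- x_j^-)$ between a free
  ("minus") and a clamped ("plus") phase — error-driven learning without
  backpropagated gradients.
* **Three-factor dopamine-modulated** `three_factor_update()` /
  `learn_from_da()`: $\Delta w_{ij} = \epsilon\, s\, \delta\, y_i x_j$ with
  pathway sign $s$ (+1 Go, −1 NoGo) and dopamine $\delta$ (default
  $\epsilon = 0.1$), masked by the eligibility trace of the most recent
  gating event.

## Dopamine: a tabular delta-rule critic

`critic()` holds values $V(c) \in [0,1]$ per discrete context key and emits
$\delta = r - V(c)$ at outcomes (burst if positive, dip if negative),
followed by $V(c) \leftarrow V(c) + \alpha (r - V(c))$, $\alpha = 0.1$.
The biological critic this abstracts separates primary-value and
learned-value subsystems; here only its functional signature is kept:
better-than-expected bursts, worse-than-expected dips. The running value is
an exponentially weighted average with effective window $\approx 2/\alpha$,
so its instantaneous value fluctuates by design; properties about
convergence are stated for time-averages.

`effort_discounted_da()` implements the dopaminergic cost-of-delay signal
used by the strategy model: positive bursts shrink by $\kappa$ per unit of
accumulated effort ($\delta' = \max(0, \delta - \kappa E)$), dips pass
through. The weighting $\kappa = 0.05$ is the package default; the
phenomenon it models is stated only as "a small weighting term", so the
value is a package choice, exposed in every relevant function.

## Gating: Go/NoGo stripes

A `stripe()` is a gatable working-memory slot. Go and NoGo units project
from the current features; the update gate fires when
$w_{go}\!\cdot\!f - w_{nogo}\!\cdot\!f + \mathcal N(0,\sigma^2) > \theta$
(defaults $\theta = 0$, $\sigma = 0.1$). When the gate holds, content is
robustly maintained — bit-identical over arbitrarily many trials. A
`forced_nogo` flag vetoes gating unconditionally (used to forbid mid-task
strategy switches). Output gating releases the maintained pattern to drive
responses. Dopamine credit: the gated stripe learns at full rate with the
burst/dip sign; stripes that were passed over learn at a quarter rate with
reversed sign, so a rejected option can regain credit when the chosen
course fails — without this, an early unlucky streak can permanently bury
the best option. Credit is episode-level: an outcome's dopamine reaches
every gating decision of the episode (the tasks here have at most three
decisions before an outcome).

## Model 1: model-free learning of action sequences (`run_roomnav_experiment()`)

The environment (`room_graph()`) is a forward-only three-level lattice of
"rooms": Room 0, then Rooms 1–2, then terminal Rooms 3–5 with Bernoulli
rewards. Transitions are deterministic (LEFT/RIGHT); only terminal rooms
pay. The agent (`nav_agent()`) carries one maintenance slot whose matrix
has one Go/NoGo circuit per action over the room features; the winning
circuit loads its action, the output gate releases it, and at the terminal
the critic's dopamine is applied to every decision of the episode.

The experiment protocol is fixed by the study conditions: 10 independently
seeded agents, 75 trials per epoch, stop at an average epoch reward of 85%
or after 25 epochs. **Default terminal reward probabilities are 0.9 / 0.3 /
0.1** — a package choice, since the original task's percentages are not
printed. The best room's probability must exceed the 0.85 criterion for
the protocol to be coherent: with a best room at 0.8, even the optimal
policy clears an 85% epoch average only by sampling luck (probability
$\approx 0.11$ per 75-trial epoch), which contradicts the reported typical
four-epoch success. With 0.9, the optimal policy's epoch average clears
the criterion in expectation and the experiment measures learning speed,
not luck. All probabilities are config-overridable.

## Model 2: reward/effort strategy selection (`run_pbdm()`)

Four task strategies (localist ids 0–3) differ in reward probability and
delay (effort). The inner task is deliberately *not* simulated: a strategy
is an (effort, reward-probability) pair, exactly the feedback parameters
the circuit experiences. Each episode runs CHOICE (gate a strategy into
DLPFC), PERF × delay (forced NoGo; effort accrues), DONE (Bernoulli
reward; dopamine; learning). Task context is a random 20-bit cue (25%
density) that switches every 10 episodes among 20 pretraining tasks.

Value stripes (`value_stripes()`): four OFC stripes hold running-average
reward probability (updated only at DONE), four ACC stripes hold
running-average effort (accrued over PERF trials), both with rate 0.1, and
both encoded as 7-unit Gaussian bumps (`encode_scalar()`) — the coarse
distributed code that projects to the gating matrix, with an analytic
decoder standing in for the scalar read-out layer.

Two design decisions shape the dynamics and are worth stating explicitly:

* **Critic context.** The critic uses a single shared context key, making
  $V$ the running value of the agent's own policy — an actor-critic
  baseline. Choices are thus always evaluated *relative to the incumbent*:
  inferior strategies keep being punished relative to better ones, which
  produces the observed exploration-then-exploitation and lets a batch
  occasionally stabilize on the second-best strategy (sampling luck) but
  never on clearly worse ones. A per-strategy context was tried and
  rejected: prediction errors then vanish per strategy and nothing sustains
  discrimination between them.
* **Feature normalization.** The concatenated (cue, OFC code, ACC code)
  feature vector is L2-normalized before the gating nets are computed. With
  raw features (squared norm ≈ 8) a single rewarded choice moves the
  Go−NoGo margin by roughly thirteen times the exploration noise s.d.,
  so the first lucky sample locks in permanently; normalization puts
  learning steps and the $\sigma = 0.1$ exploration noise on a common
  scale.

A batch's *stabilized preference* is its modal choice over the final 20%
of its 500 episodes. Under the balanced regime (rewards .4/.6/.6/.8
against delays 1–4) the package's dynamics concentrate most batches on the
highest net-value strategy with a minority on low-effort options; the
mixture is real but weaker than the (figure-only) proportions of the
original report, and the "at least three distinct preferences in 16
batches" operationalization is met only at some seeds.

## Model 3: instructed learning (`run_stages()`)

Ten-unit localist Condition, Action and Premotor layers. Three stages:

1. **Pretraining**: the action-to-premotor identity table is trained with
   the contrastive rule to a 10/10 winner criterion; a BG execution gate
   learns to open on output trials. These weights are then frozen.
2. **Instruction**: each (condition, action) rule is bound by the model
   hippocampus (`episode_store()`): the concatenated localist pair is
   projected through a fixed random matrix into a 200-unit layer, the 10
   most-driven units form a sparse conjunctive code, and a full-rate
   Hebbian binding attaches the action pattern to it — one shot suffices;
   the default four repetitions model a short practice period, not a
   necessity. The condition part of the conjunction is weighted 6× the
   action part because the condition is the retrieval cue at test: with
   that weighting the cue code's overlap with its stored episode stays
   above the 0.5 abstain threshold with margin (worst observed 0.6 over
   2000 recalls at default sizes), while the code still depends on the
   bound action. Re-instructing a condition overwrites its binding
   (newest instruction wins).
3. **Performance**: conditions only — no Action-layer input. Recall
   pattern-completes the stored episode; the retrieved action drives the
   frozen premotor pathway through the opened execution gate. If recall
   abstains, the premotor competition resolves on noise alone (chance
   performance), which is what the zero-instruction control measures.

Learning loci are strictly separated: after pretraining only the episode
store changes, which is what makes instruction fast, proactive and
error-free rather than a slow rewiring of the whole pathway.

## Model 4: bridging-state discovery (`find_bridge()`)

A dual-area settling network, trained **only on adjacent** state-action-
state triads, finds the intermediate state between a clamped current state
and a goal two steps away. The semantic area (StateNodes, ActionNodes;
loose kWTA, k = 3) learns Hebbian co-occurrence associations; the relation
engine (BeforeState, ActionBetween, AfterState; tight kWTA, k = 1) learns
the role relations with the contrastive rule. The goal enters the semantic
area at full strength and the AfterState layer only as a weak hint (scale
0.15). ActionBetween starts with loose competition (k = 3) and tightens
linearly to a single winner over 25 cycles, so the early phase — all
actions available in the current state co-active — is observable before
the winner emerges; convergence is not allowed to pre-empt the ramp.

Three numerical choices matter and were fixed against the module's own
breadth-first-search oracle on random DAGs:

* **Grouped role training.** Each relation mapping is trained with one
  minus phase per source pattern against the multi-hot set of its valid
  fillers. Per-triad updates instead make a state's several valid actions
  compete each other's weights down to nothing.
* **Count-proportional semantics.** Semantic weights start at zero and
  train briefly (5 epochs at rate 0.04). At the Hebbian equilibrium each
  link normalizes toward 1/degree, and the bridge's defining advantage —
  association with *both* query states — cancels exactly against a
  single-link neighbour; in the brief-training regime link strength stays
  proportional to co-occurrence and two links beat one.
* **In-degree normalization.** After training, rows of the action→after
  projection are capped to the smallest edge-bearing row sum. Without
  this, a state with many incoming transitions feeds itself through the
  after ↔ action loop in proportion to its in-degree and hub states beat
  the true midpoint.

Residual disagreements with the graph oracle (≈5–10% of queries on random
DAGs) are direction-blind semantic confounds: a state adjacent to both
query states but with the second edge pointing the wrong way is
semantically indistinguishable from a true midpoint, and resolving it
would need a second relation step, which this one-step constraint
satisfaction deliberately does not perform. Queries with no two-step path
simply fail to converge on a confident winner, which the result flags.

## What the synthetic generators do and do not emulate

All inputs are generated: room lattices, Bernoulli terminal rewards,
random task-cue bit patterns, random rule sets, random transition DAGs.
They reproduce the *structure* of the modelled tasks — probabilistic
payoffs, context cues uncorrelated with value, localist conditions and
actions, adjacency-only experience — at the stated sizes. They do not
emulate perceptual noise, graded similarity between contexts, non-
stationary reward schedules, or timing within trials; passing tests
therefore demonstrate the circuit-level learning and decision phenomena at
desk scale, not robustness of these mechanisms to real sensory data.

## Problem sizes and determinism

Default experiment sizes (10 agents × ≤25 epochs × 75 trials; 10–16
batches × 500 episodes; 100 rule-set replications; 50 random DAGs) were
chosen so that every experiment and the whole test suite run comfortably
on a single CPU while keeping the binomial error of the reported counts
below the tolerances being tested. Every source of randomness flows
through R's generator from one master seed (`derive_seeds()` splits it
into per-agent/per-batch streams), so identical configs reproduce results
bit-for-bit.

## Known limitations

* The substrate is functional, not biophysical: no spiking, conductances,
  or detailed inhibitory interneuron dynamics.
* Gating stripes compete only through learning, not lateral inhibition,
  and eligibility is episode-level; tasks with long decision-outcome gaps
  would need a decaying trace.
* The strategy model's effort weighting $\kappa$ trades off against reward
  differences; the balanced-regime preference proportions are sensitive to
  it (and were reported as highly stochastic to begin with).
* One-step bridging only: multi-subgoal planning is out of scope, and the
  semantic area cannot distinguish edge direction (see above).
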