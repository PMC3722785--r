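# cogseq

Neural-circuit simulations of **strategic cognitive sequencing**: how the
prefrontal cortex (PFC), basal ganglia (BG), midbrain dopamine system and
hippocampus cooperate to choose, order and plan cognitive actions. The
package is for computational cognitive neuroscientists who want compact,
fully seeded, desk-scale re-implementations of four circuit models on a
common rate-coded substrate, with tidy per-trial output.

The four models:

1. **Model-free sequence learning** (`run_roomnav_experiment()`) — an
   actor-critic circuit in which BG Go/NoGo units gate actions into gated
   PFC working-memory slots and a dopamine reward-prediction error
   $\delta = r - V$ trains every gating decision of an episode. The task is
   a forward-only "rooms" lattice with probabilistic terminal rewards; the
   agent must learn a two-step LEFT/RIGHT sequence from stochastic terminal
   feedback alone.
2. **Reward/effort strategy selection** (`run_pbdm()`) — orbitofrontal
   stripes hold running-average reward probability, anterior-cingulate
   stripes hold running-average effort, both as coarse-coded bumps; the
   DLPFC gating matrix learns from (optionally effort-discounted,
   $\delta' = \max(0, \delta - \kappa E)$) dopamine to select among four
   task strategies that trade reward probability against delay.
3. **Instructed learning** (`run_stages()`) — a fast hippocampal associator
   binds ten if-then rules (condition → action) as sparse conjunctive codes
   in one shot; at test, the condition alone pattern-completes to the
   instructed action, which a pretrained, frozen action→premotor pathway
   executes through a BG gate — without errors and without retraining.
4. **Bridging-state discovery** (`find_bridge()`) — a dual-area attractor
   network (loose-competition semantic area, tight-competition relation
   engine) trained only on adjacent state-action-state triads settles, from
   a clamped current state and goal, onto the intermediate subgoal state
   and the action toward it: one-step planning by constraint satisfaction.

The substrate underneath (`settle()`, `kwta_threshold()`,
`hebbian_update()`, `error_driven_update()`, `three_factor_update()`) is a
minimal rate-coded network engine: activations in [0, 1], k-winners-take-all
inhibition, bidirectional settling, and three local learning rules.

## Worked example

```r
library(cogseq)

res <- run_roomnav_experiment(seed = 42)
res
#> <cogseq_roomnav_result> 10/10 agents reached 85% criterion; mean epochs among successes: 1.5
glance(res)
#> # A tibble: 1 × 4
#>   n_agents n_success mean_epochs criterion
#>      <int>     <int>       <dbl>     <dbl>
#> 1       10        10         1.5      0.85
```

Ten independently seeded agents each get 75 trials per epoch; an agent
"succeeds" when its average epoch reward reaches 0.85 (the best terminal
room pays with probability 0.9, so the optimal two-step policy clears this
in expectation). Here all ten agents succeeded, after 1.5 epochs on
average. `tidy(res)` returns the per-epoch learning curves and
`autoplot(res)` plots them.

```r
set.seed(42)
run_stages(random_rule_set(10))
#> <cogseq_instructed_result> 10 rules; Performance-stage errors: 0
```

Ten never-seen if-then rules, four instruction presentations each, then a
test on conditions alone: zero errors — instruction assembles pre-trained
elements instead of retraining them.

```r
set.seed(42)
bn <- train_triads(bridging_network(default_state_graph()))
find_bridge(bn, 0, 2)
#> <cogseq_bridge_result> S0 -> goal S2: bridge S1 via action a0 (25 cycles)
```

The network was trained only on adjacent transitions of a 3-state chain
(plus two distractor branches from S0), yet settles on the intermediate
state S1 and the correct first action. `settling_phases()` shows the
diagnostic trajectory: early in settling all three actions available in S0
are co-active in the relation engine's action layer, before competition
singles out the correct one.

Everything is also reachable from a thin command-line wrapper:

```sh
Rscript inst/cli/cogseq.R roomnav --agents 10 --seed 1 --out out/
Rscript inst/cli/cogseq.R pbdm --regime reward_only --batches 10 --seed 1
Rscript inst/cli/cogseq.R bridge --from 0 --to 2 --trace trace.csv
```

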