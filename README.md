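# cognisys

Deterministic cognizers-system worlds, observer-dependent probability and
entropy, and inverse-causality realization.

`cognisys` is for people who want to *compute with* the idea that observation
and physical interaction are the same kind of thing.  Every entity in a world
— coin, table, molecule, measuring device, person — is a **cognizer**: a
finite-state agent whose next state is a function of its own state and the
current states of all the others, updated simultaneously each tick,

    u_{t+1} = F(u_t) = (f_{C1}(u_t), ..., f_{Cn}(u_t)).

The world is strictly deterministic and symbolic, so every quantity the
package reports is a relative frequency counted from an actual orbit:

* `p_meta(traj, A, X)` — the model-builder's state-count ratio `#A / #X`;
* `p_overall(stream, A)` — how often an observer's cognition `A` occurs,
  pooled over everything it does;
* `p_cog(stream, A, B)` — how often `A` follows a particular earlier
  cognition `B` (the degree of certainty under that observation or action);
* `h_overall()` / `h_cog()` — Shannon entropies (bits) of those
  distributions, and `info_amount()` for signed entropy differences;
* `total_probability()` — the decomposition `sum_i P(A|B_i) P(B_i) = P(A)`,
  which holds here as an exact integer-arithmetic identity, not to tolerance.

Observers differ only in coupling and resolution: external observers are
one-way coupled (attaching one provably never perturbs the observed
subsystem), internal observers are ordinary members, and
`induced_partition()` computes what any observer can and cannot discriminate
about an object.  A second, internalist module inverts the picture:
`realize()` takes nothing but a percept symbol sequence and, by enforcing the
unique-successor principle (ICM at the percept level, ICW at the whole level),
derives the foreign symbols — an internal model of external reality —
that make the sequence causal.

Two canonical worlds ship with the package: a repeated coin toss with a
perfectly discriminating observer attachable alongside a coarse human one
(`coin_toss_world()`), and a Maxwell's-demon lattice gas in which the demon
is nothing but the hole's motion rule (`maxwell_world()`).  Pseudo-randomness
lives *inside* these worlds as a hidden Lehmer-permutation cognizer; the seed
only picks the initial state.

## Worked example

Twenty thousand ticks of the fair-coin world (10,000 tosses as one continuous
trajectory), watched by both observers:

```r
library(cognisys)

cw <- coin_toss_world(bias = 0.5, seed = 42)
w  <- attach_external_observer(cw$world, demon_observer(0.5))
w  <- attach_external_observer(w, human_observer())
u0 <- world_state(w, c(cw$u0, demon = "idle", human = "idle"))
traj <- evolve(w, u0, 20000)

pats <- coin_patterns()
p_overall(events(traj, "coin"), pats$heads, population = pats$outcome)
#> <prob_estimate external_overall> 5039/10000 = 0.5039

demon <- events(traj, "demon")
p_cog(demon, event_pattern(to = "obsH"), event_pattern(to = "predH"))
#> <prob_estimate external_cog> 5039/5039 = 1
h_cog(demon, event_pattern(to = "predH"),
      list(event_pattern(to = "obsH"), event_pattern(to = "obsT")))
#> <entropy_report external_cog> H = 0 bits over 2 outcomes
#>   p = (1, 0)

human <- events(traj, "human")
h_cog(human, event_pattern(from = c("sawH", "sawT"), to = "idle"),
      list(event_pattern(to = "sawH"), event_pattern(to = "sawT")))
#> <entropy_report external_cog> H = 0.999957 bits over 2 outcomes
#>   p = (0.5039, 0.4961)
```

Read: heads came up 5,039 times in 10,000 trials (`P_overall ≈ 1/2` — an
objective property of the world that no observer can change); every one of the
demon's 5,039 heads-predictions was followed by heads, so its conditional
uncertainty is 0 bits; the human's conditioning cognition tells it nothing,
leaving essentially a full bit.  The two are reconciled exactly by the law of
total probability:

```r
total_probability(demon, event_pattern(to = "obsH"),
                  list(event_pattern(to = "predH"),
                       event_pattern(to = "predT"),
                       event_pattern(to = c("idle", "obsH", "obsT"))))
#> <total_probability> over 19999 conditioning slots (offset 1 )
#>   B_1: P(A|B)=1/1  P(B)=5039/19999  term=5039/19999
#>   B_2: P(A|B)=0/1  P(B)=4961/19999  term=0/1
#>   B_3: P(A|B)=0/1  P(B)=9999/19999  term=0/1
#>   sum = 5039/19999   P_overall(A) = 5039/19999   exact match: TRUE
```

And the internalist direction — deriving reality from a percept stream:

```r
realize(c("m0", "m1", "m2", "m0", "m1", "m3"))
#> <ic_realization>
#>   sequence: (m0|e2*) (m1|e0*) m2 (m0|e3*) (m1|e1*) m3
#>   E0* (ICM): {e0*, e1*}
#>   E1* (ICW): {e0*, e1*, e2*, e3*}
```

The two `m1` percepts had different successors, so ICM posits two external
states `e0*`, `e1*` behind them; that in turn splits the `m0` percepts at the
whole level, so ICW posits `e2*`, `e3*` — a device-mediated, it-from-bit
constitution of two more.

See `vignettes/cognizers-system.Rmd` for the model, the four
probability/entropy types, the algorithmic conventions, and the scenarios'
design.

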