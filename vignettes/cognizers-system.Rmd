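---
title: "Cognizers systems: observer-dependent probability, entropy, and realization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognizers systems: observer-dependent probability, entropy, and realization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognisys)
```

## The model

A *cognizers system* is a finite deterministic multi-agent dynamical system in
which every entity — a coin, a table, a molecule, a measuring device, a person
watching an experiment — is the same kind of object: a **cognizer** with a
finite state set and a motion rule.  At every global, synchronous tick each
cognizer's next state is a function of its own current state and the current
states of all the others:

$$f_C : \mathbf{C} \times \mathbf{E} \to \mathbf{C}, \qquad
  u_{t+1} = F(u_t) = (f_{C_1}(u_t), \dots, f_{C_n}(u_t)),$$

so the joint state $u_t$ evolves on the product space
$\mathbf{U} = \mathbf{C}_1 \times \cdots \times \mathbf{C}_n$ along the orbit
$u_0, F(u_0), F^2(u_0), \dots$.  The world is deterministic by construction;
there is no stochastic kernel anywhere in the core, and all state labels are
symbolic, so trajectories are bit-identical across runs and platforms.

A **cognition** is one tick's state change $c_i \to c_j$ of one cognizer,
*including* the non-change $c_i \to c_i$.  The same construct carries both
readings of "information": for an observing cognizer it is the occurrence of
an event (it observed something and changed state accordingly); for a physical
cognizer it is simply motion.  This unification is what lets one probability
calculus serve epistemic and ontic questions at once.

Three standpoints are distinguished:

* the **meta-observer** — the model builder outside the world, who sees joint
  states directly (`p_meta()` counts states);
* an **external observer** — a cognizer one-way coupled to an observed
  subsystem: its rule reads the subsystem, but no subsystem rule reads it
  (`attach_external_observer()` enforces this by construction, so the observed
  trajectory is provably unperturbed);
* an **internal observer** — an ordinary member of the system, mutually
  coupled with its environment (the coin-tosser; the demon controlling the
  hole it sits in).

What an observer can resolve is its **discriminability**: for each observer
state, `induced_partition()` groups object states by the successor state they
induce in the observer.  All-singleton blocks are the Laplace's-demon limit;
a single block is total blindness.

## Time and coarse views

Time is a dimensionless global tick; simultaneity means no rule ever sees
another cognizer's next state.  Where a measurement naturally spans two ticks
(sensor deflection and return, `run_sensor_memory()`), the intermediate states
are ordinary ticks of the core; coarser, object-synchronized views are
produced afterwards by collapsing the stream, never by changing the dynamics.
That keeps a single source of truth for what happened.

## The four probabilities

Every probability here is a relative frequency — a ratio of event counts from
an actual run — never a degree of belief.  Degrees of belief are deliberately
not represented: within this framework they are states of a cognizer, not
probabilities.

For an event stream (one cognizer's chain of cognitions over a trajectory):

* `p_overall(stream, A)` — the fraction of events matching $A$ in a reference
  population, irrespective of what was observed before.  The reference
  population is explicit: for repeated trials embedded in one continuous
  trajectory you restrict it to the outcome slots of the cycle.
* `p_cog(stream, A, B)` — the fraction of occurrences of the conditioning
  cognition $B$ that are followed (by default immediately; `offset` for longer
  cycles) by $A$.  A condition that never occurs raises an explicit
  "undefined conditional" error rather than returning 0 or `NaN`.

Both are exact count ratios, and the law of total probability

$$\sum_i P(A \mid B_i)\,P(B_i) = P(A)$$

is implemented (`total_probability()`) as an *integer-arithmetic identity*:
with $a_i$ joint counts, $b_i$ condition counts and $N$ eligible slots, each
term is $\tfrac{a_i}{b_i}\tfrac{b_i}{N} = \tfrac{a_i}{N}$, so the sum equals
the directly counted $P(A)$ with zero error.  One alignment choice makes this
exact rather than approximate: $P(A)$ in the decomposition counts only target
slots that *have* a conditioning slot (a stream's first transition has none).
Conditions must partition those slots; overlaps and gaps are validation
errors, not silent renormalizations.

Counts stay below $2^{53}$ for any run this package can produce, so exact
integer arithmetic in doubles suffices; fractions are reported unreduced so
sample sizes stay visible.

A deterministic world revisits states whenever its orbit enters a cycle, so
the occurrence count of a state set generally exceeds the number of distinct
states in it.  `p_meta()` therefore reports both counts and an `all_distinct`
flag instead of assuming they coincide.

## Entropies and amounts of information

`shannon_entropy()` is $H = \sum_i p_i \log_2 p_i^{-1}$ in bits with
$0\log(1/0) := 0$.  Crossing the two probability types with the two observer
attachments gives four entropies; the package computes the two shapes
(`h_cog()`, `h_overall()`) and tags the standpoint.  The useful facts, all of
which are tested properties rather than assumptions:

* $0 \le H \le \log_2 k$, with $H = 0$ iff some $p_i = 1$; $H$ is symmetric
  under permuting the distribution (an 80:20 and a 20:80 world are equally
  uncertain — entropy measures distinction, not meaning).
* A perfectly discriminating conditioning cognition forces every defined
  `p_cog` into $\{0,1\}$ and hence `h_cog` to 0 bits.
* `h_overall` of outcome events does not move when the observer is refined,
  as long as outcomes stay distinguishable: switching from a human to a demon
  yields zero overall information about a fair coin.
* The condition-averaged conditional entropy `expected_h_cog()` is monotone
  non-increasing under refinement of the condition partition.

`info_amount()` is the signed difference $H_{\mathrm{ref}} - H_{\mathrm{new}}$
of two like-typed reports: information is relative, and a coarser second
cognition legitimately yields a negative amount.

Entropies are computed from the exact count ratios and converted to floating
point once; equality tests in the suite use an absolute tolerance of 1e-12.

## Inverse causality: ICM and ICW

The realization module inverts the viewpoint: nothing is assumed to exist
except a temporal sequence of percept symbols.  The **unique-successor
principle** — every element of the sequence has exactly one successor — is
causal determinism stated at the sequence level; its contrapositive (if
$F(a) \ne F(b)$ then $a \ne b$) becomes an algorithm:

* **ICM** (`icm()`): where a symbol has two or more distinct successors, its
  occurrences are annotated with *foreign* symbols $e_k^*$ so that annotated
  elements have unique successors.  The foreign symbols are the subject's
  internal model of an undetectable external difference — level-0 reality.
* **ICW** (`icw()`): the same operation repeated on whole elements
  (base + annotations), layer by layer, until the whole-level sequence is
  causal.  Each pass pushes distinctions one step towards the start of the
  sequence, which bounds the number of passes by the sequence length.
  The completed symbol set is level-1 reality, the device-mediated,
  it-from-bit constitution of the world.

`realize()` composes the two and is idempotent.  Two conventions had to be
fixed where the worked example underdetermines them:

* *Grouping*: occurrences of a violating element that share a successor share
  one foreign symbol; occurrences with different successors get distinct
  symbols.  This is the minimal realization consistent with the canonical
  example (two occurrences, two successors, two symbols); whether
  same-successor occurrences should ever be split is genuinely open, and we
  chose not to split.
* *Naming*: $e_k^*$ numbered in order of introduction, ICM first, then ICW
  passes, left to right within a pass.
* *Boundaries*: the final element has no successor and never violates; the
  first element has no predecessor, so backward propagation stops there.

The bridge back to the externalist model: run `certainty_world()` (a cyclic
hidden environment driving an observer that cannot resolve it) and realize
the observer's own percept stream — the derived annotations recover exactly
the hidden distinctions that mattered for successors, i.e. realization acts
as a measurement of the environment the observer could not see.

## The canonical scenarios and what they emulate

Both scenario generators obey one discipline: **pseudo-randomness lives
inside the deterministic world**.  A hidden register cognizer steps through a
fixed Lehmer permutation $x \mapsto 16807\,x \bmod (2^{31}-1)$; the external
`seed` only selects the initial microstate $u_0$.  Repeated trials are one
continuous trajectory, not independent re-initializations, so "the initial
states are distributed randomly" is an emergent property of the orbit, not an
assumption.

**Coin toss** (`coin_toss_world()`): a two-tick trial cycle (toss, outcome);
the coin thresholds the hidden register by `bias`.  The attachable
`demon_observer()` reads the register itself and predicts each outcome before
it happens — its conditionals are all 0 or 1, yet the overall frequency of
heads stays near `bias` even for it.  The `human_observer()` sees only the
coin's face: same overall entropy, one full bit of conditional uncertainty.
Default study conditions used in the tests: bias 1/2, 10,000 trials, 20
initial microstates, agreement with 1/2 judged at three binomial standard
errors.

**Maxwell's demon** (`maxwell_world()`): non-interacting particles bouncing
on a 1-D lattice, a wall with a hole at the midpoint, the hole itself a
cognizer.  The demon *is* the hole's motion rule — discriminate approaching
particles, select open/closed — it never touches the particle rules, which is
the point: a change in one component's cognitive properties produces a
macroscopic pattern (occupancy concentrates in one chamber), read off as a
drop in overall chamber-occupancy entropy.  Because strictly periodic
non-interacting particles phase-lock (the safe-to-open window then almost
never recurs), the same hidden-register device also delivers weak thermal
agitation: each particle reads its own residue of the register and reverses
velocity with relative frequency about 1/61.  Defaults: 20 particles, 16
cells, 5,000 ticks, 10 seeds, with the demon-on entropy required only to be
strictly below demon-off — the magnitude is a property of this toy's
geometry, not a quantity the framework fixes.

What the generators do *not* emulate: real coins (no physics of flight),
real gases (no collisions, 1-D, no thermodynamic calibration of the demon's
cost), and any back-action of weak measurement — only the two poles, exact
zero coupling (external) and full coupling (internal), are modelled, because
the framework itself leaves the intermediate regime open.  Passing tests
therefore show the internal consistency of the counting calculus on worlds
with these idealizations, not agreement with laboratory data.

## Problem sizes and numerical choices

The test suite runs every estimator at the scales above (the largest single
run is 20,001 ticks of the five-cognizer coin world and 5,001 ticks of the
22-cognizer gas).  Property-style checks use 200 random small worlds for the
total-probability identity and 20 for partition-refinement monotonicity, all
under fixed seeds.  Exhaustive validation of rule totality and closure is
performed for joint spaces up to $10^6$ states; the hidden-register worlds
are validated structurally instead (the permutation is total by number
theory).

## Known limitations

* Rules are R closures evaluated per cognizer per tick; worlds of a few dozen
  cognizers over tens of thousands of ticks are comfortable, but this is not
  a vectorized simulator for thousands of agents.
* `induced_partition()` pins non-object cognizers at a context and can verify
  context-independence only by enumeration on small worlds.
* Only the two coupling poles (external/internal) are represented; "very
  weak" observation back-action has no intermediate model here.
* The evolutionary reading of the internal entropies (fitness trade-offs of
  discriminability) is outside the package's scope: nothing here optimizes
  anything.
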