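---
title: "Executable domain models: statecharts, token flows and the EAE case study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Executable domain models: statecharts, token flows and the EAE case study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainsim)
```

## The three-level model

domainsim executes biological *domain models* structured at three levels:

* **System** — a research context linking the observed phenomena that
  motivate the model (e.g. paralysis of EAE-induced mice, and their
  spontaneous recovery) to the emergent behaviours expected to produce
  them and the cellular components involved. Links carry a polarity:
  autoimmune drive, regulatory counter-action, or neutral. A phenomenon
  may be declared *out of scope*: it is recorded but never linked, and
  the assembler and consistency checker both enforce that nothing claims
  to produce it.
* **Perspectives** — activity networks decomposing one expected
  behaviour into cellular interactions. These networks are typically
  cyclic and may lack end nodes (population-level processes have no
  single completion point); they must have start nodes so execution can
  begin. Three extended relationship kinds express population phenomena
  that plain activity edges cannot: *propagating* (spawning without
  source termination), *interrupting* (partial-to-full blocking of a
  transition) and *contributory* (weighted influence on a decision).
* **Single entity** — one statechart per entity type, with orthogonal
  regions, composite states, and transition guards mixing logical
  predicates with probabilistic `δ(p)` and timed `λ(t)` atoms.

## Execution semantics and their numerical choices

### Time

Time is discrete and unitless: one step is one synchronous update of
every live component. `λ` durations are integer step counts and `δ`
probabilities are per-evaluation Bernoulli draws. Discrete steps keep
every oracle analytic (geometric first-firing times, Poisson spawn
totals) and make the statechart and token-flow engines composable in one
simulation loop.

### Statecharts

Guards are evaluated against a start-of-step snapshot, so a firing in
one region can never change guard outcomes in a sibling region within
the same step; cross-region influence always takes effect on the next
step. At most one transition fires per region per step, with enabled
transitions tie-broken uniformly at random — conflict priorities would
be an extra assumption, and a uniform, seedable choice is the least
committal. Both operands of every connective are evaluated (no
short-circuiting): a guard mentioning `δ(p)` twice draws twice, and RNG
consumption depends only on guard structure, which keeps trajectories
reproducible. Dwell counters reset on state entry (including re-entry),
so `λ(t)` measures time in the *source* state. Partial orthogonality —
e.g. a maturation step that is only possible in some locations — is
expressed by guards naming another region's active states as
predicates; the interpreter automatically values every state label of
the machine's own regions.

Isolated states (no incident transitions) record standing capabilities,
such as a matured dendritic cell remaining MHC-II capable; they live in
their own region and simply stay active. States may also record
influence rather than internal state (the cytokine "influence
machines"): they execute like any other state but are instantiated as
fields, not agents, in simulation.

### Token flows

`step_flow()` also uses a start-of-step snapshot. A token is eligible
to leave once its age reaches the edge's dwell (default one step).
Several outgoing sequential edges duplicate the token (implicit fork,
matching the concurrent reading of cellular events); decisions route a
single token along one branch sampled from weights (baseline 1 per
branch, plus additive shifts from active contributory sources, floored
at zero and renormalized); joins hold arriving tokens per branch and
emit one token once every branch has delivered. Interrupters compose
multiplicatively — an edge under interrupters of degrees
\(d_1, d_2\) fires with probability \(\prod_i (1 - d_i)\) — treating
independent partial blockades as order-free. Propagation spawns
`Poisson(rate)` tokens per source token per step: spawning "any number
of times" with a single rate parameter and an analytic mean. A
degree-0 interrupter draws no random number, so it is bit-identical to
its absence, not just statistically indistinguishable.

### Simulation

Cells are agents; molecules are per-compartment scalar fields (a
deliberate abstraction: individual molecule agents would dominate the
agent count without adding behaviour, and the influence-machine
semantics are recovered as field-derived presence predicates with a
threshold, default 0.5, and per-molecule geometric decay). Interaction
pairing assumes cells are well mixed within a compartment: each
eligible actor samples one uniformly random eligible co-located partner
per rule per step; no contact model is imposed because none is given by
the biology as modelled. Killing asserts a `killed` predicate and the
victim's own statechart decides how to die, keeping death semantics in
the single-entity level. Proliferation spawns exactly one daughter per
division emission. Migration is owned by the simulation loop: the
statechart location region is frozen during stepping and rewritten
after each move, so the location region's transitions exist for static
cross-reference analysis (rules R2/R3) while the migration-rule table,
with its per-type movement probabilities, governs actual movement.
Agent iteration order is shuffled every step as a safeguard against
order artifacts, although the snapshot semantics already remove the
main source of them.

## Consistency checking

`check_model()` runs seven rules that make the manual cross-referencing
between diagrams executable; `list_rules()` documents them. The most
interesting is R3, binding feasibility: a transition guarded by a
declared binding predicate (e.g. the CD8Treg priming step requiring
TCR:Qa-1:CDR1/2 engagement with a dendritic cell) is flagged if it is
satisfiable in a compartment its binding partner can never reach.
Binding predicates are declared structurally
(`{partner_entity, partner_state}`) so the rule is decidable without
parsing natural-language predicate names, and satisfiability is
assessed by static reachability over location regions — conservative,
and faithful to an argument made by inspecting diagrams rather than by
simulation. Molecules are treated as confined to their secretion
compartment; cross-compartment diffusion would need an explicit
transport model that the domain model does not assert. Violations are
data (warnings) by default and errors under `strict = TRUE`, because a
domain model may deliberately abstract.

## The EAE fixture and its defaults

`build_eae_model()` encodes murine EAE: five compartments
(Circulation, CLN, Spleen, SLO, CNS), seven cell types, two cytokine
fields. The autoimmune arm: dendritic cells mature under antigen
stimulus, prime CD4Th1 cells in lymphoid organs; activated Th1 cells
traffic to the CNS, secrete type-1 cytokines, stimulate CNS-resident
macrophages, which kill neurons. The regulatory arm: primed CD4Treg
cells license dendritic cells, licensed DCs engage naive CD8Tregs
(possible only where DCs can be — not in circulation), CD8Tregs mature
to effectors, which are barred from re-entering lymphoid organs and
kill CD4Th1 cells in blood and CNS.

The source domain description publishes no rates, so **every numeric
parameter is this package's own** (and so marked in
`provenance_table()`). They were chosen once, by order-of-magnitude
reasoning — maturation and priming on a ~5–10 step timescale,
migration probabilities of 0.05–0.25 per step, a T-cell lifespan (150
steps) exceeding the default 120-step run so that death in a default
run is regulatory killing rather than old age, and a division
probability (0.02/step) giving slow clonal expansion — verified to
produce the qualitative onset-then-recovery pattern, then frozen.
Default initial populations (120 agents across compartments) and the
120-step horizon keep a full run in seconds while leaving a clear gap
between autoimmune expansion (peak near step 20–40) and the
regulatory crash.

What the fixture's passing tests do and do not show: they demonstrate
that the mechanisms *as modelled* suffice for the emergent pattern —
CD4Th1 populations peak and then collapse to under half their peak
when CD8Treg killing is enabled, and persist at or near their peak when
it is knocked out. They do not calibrate to in-vivo kinetics, do not
model space within compartments, and say nothing about the out-of-scope
phenomenon (protection against re-induction), which is declared but
never linked or simulated.

## Degenerate inputs and tie-breaks

* Empty guard text is the always-true guard; `λ(0)` behaves as
  always-true; `δ(0)`/`δ(1)` are degenerate Bernoulli draws.
* A decision whose effective weights are all zero routes nothing; the
  token waits.
* Self-migration (`from == to`) is always allowed: remaining in place
  is not a migration.
* Dead agents are retained for bookkeeping but never step, emit,
  interact or migrate; the accounting identity
  `initial + births = alive + deaths` holds per type at every step.
* Identifier matching is case-sensitive and exact everywhere — the
  price of making cross-diagram joins unambiguous.

## Problem sizes used in the checks

The packaged checks run at desk scale: 10,000-trial guard statistics,
1,000 randomized statechart runs, 10,000–20,000-step token flows, and
10 + 10 simulation runs of 120 steps starting from 120 agents (growing
to a few hundred under knockout). These sizes give three-standard-error
margins on every stochastic oracle while keeping the full suite
comfortably interactive.

## Known limitations

* UML event queues, deferred events, history pseudostates and
  do-activities are out of scope; so are expansion regions, which the
  domain-modelling approach this package executes explicitly rejects
  for compounding concurrency (the propagating relationship covers that
  role).
* Continuous quantities (expression levels, secretion rates) appear
  only as categorical states plus parameters.
* Guards may combine `δ` and `λ` in one transition via conjunction;
  this is a grammar-level generalization beyond the diagrams the
  fixture reproduces, documented rather than forbidden.
* Perspective execution and agent simulation are parallel views of the
  same biology; they share the parameter table but are not coupled at
  run time.

## A worked example

```{r example, eval = FALSE}
model <- build_eae_model()
check_model(model)                      # 7/7 rules pass

run <- run_sim(model, eae_sim_config(seed = 3))
glance(run)
autoplot(run)

ko <- apply_knockout(eae_sim_config(seed = 3),
                     "CD8Treg_kills_CD4Th1", model)
run_ko <- run_sim(model, ko)            # no recovery without the killing
```
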