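---
title: "Recovering implicit transpositions from DCJ scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering implicit transpositions from DCJ scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjtrans)
```

## The problem

Genome rearrangement studies summarize the evolution between two species as
a sequence of operations on gene orders. The double-cut-and-join (DCJ)
operation — cut up to two adjacencies, rejoin the four ends — covers
reversals, translocations, fusions and fissions in one uniform move, and
admits a closed-form distance. Transpositions (segment relocations) do not
fit this mold: a transposition is a 3-break, and in a DCJ-only scenario it
appears as a *pair of weakly dependent DCJs*, possibly far apart in the
scenario. Any DCJ-based reconstruction therefore understates transposition
activity. This package makes the hidden transpositions explicit: it
recovers them constructively from a given scenario, and — more usefully —
bounds their rate *uniformly over all scenarios of a class* using nothing
but the two genomes.

## Representation

A genome is a set of chromosomes over signed genes, each gene used exactly
once. Gene `g` contributes extremities `g:t` (tail) and `g:h` (head);
reading `+g` traverses tail→head. The breakpoint graph of `P` (black) and
`Q` (red) places both adjacency sets on the shared extremities. Two
conventions matter downstream:

* **Per-end telomere vertices.** Every chromosome end gets its own degree-1
  vertex (printed `*`). Components of the graph are then literally
  alternating cycles and paths — no capping tricks — and path ends identify
  the genome (PP-, QQ- or mixed-end paths) directly.
* **Persistent edge identities.** Every edge carries an integer id, minted
  once and never reused across a transformation. Dependence between steps
  is detected through ids, not endpoint coordinates, which is exactly what
  makes dependency-graph arcs correspond one-to-one to created-then-removed
  edges in proper scenarios.

Component counts give the classical distance `d = n − c − p_even/2` and two
package statistics: `s = n + p_odd + p_even/2 − c2 − p2` and
`E = n − 2c − p − p_even/2 + c2 + p2`, linked by `E = 2d − s`.

## Scenario construction

`sort_scenario()` repeatedly applies one distance-reducing move per step
until every component is trivial, using four structural move types only:
trivial-cycle extraction on a red edge of a non-trivial cycle or even path,
fusion of a PP-path's two telomeric ends, and fission next to a red
telomere of a QQ-path. Consequences that the tests verify: the scenario
length always equals the closed-form distance; fusions number exactly
`p_odd_P` and fissions exactly `p_odd_Q`; every prefix reduces the distance
by exactly one; and the result always passes the proper-scenario check.

Tunable choices: `policy = "deterministic"` processes the lexicographically
smallest eligible move (stable regression baseline); `policy = "random"`
draws uniformly among all eligible moves under a seed, which is what the
property suites sample. Randomization matters because the theorems quantify
over *all* shortest scenarios, so tests should not keep seeing one
canonical witness.

`check_proper()` validates the three conditions defining proper scenarios.
Two operational decisions were genuinely open:

* **(P1) with telomeres.** "Never recreate a removed adjacency" is tested
  with a wildcard telomere: removing the telomeric adjacency at extremity
  `x` and later re-telomerizing `x` counts as recreation. This is the
  stricter reading; it is also the one under which our generated scenarios
  and all shortest scenarios pass.
* **(P2) operationalized as strong dependence.** The defining phrase — no
  two DCJs replaceable by a single equivalent DCJ — is checked as: no step
  removes *both* edges created by one earlier step. Proper scenarios
  provably contain no strongly dependent pairs, and no broader effective
  test is known to us; the condition beyond strong dependence is left
  unformalized rather than guessed.

## Dependency graphs and recovery

`build_dependency_graph()` draws an arc (α, β) whenever β removes an edge α
created (weight 2 = strong, impossible in proper scenarios). The scenario
order is a topological order, so acyclicity is structural. An arc is a
*shortcut* (`is_shortcut()`) when an alternative directed path joins its
endpoints; such a pair can never be made adjacent by (T1) swaps of
independent neighbors — the package checks this equivalence exhaustively
against direct enumeration of topological orders on all small labeled DAGs.

Recovery proceeds exactly along the constructive proofs:

1. choose a shortcut-free matching in DG(*t*) — `dit_lower_bound()` builds
   one by `layered_forest()` + `greedy_matching()` (degree bound 3) in
   proper mode, or greedy matching on the whole forest-shaped DG (degree
   bound 4) in shortest mode;
2. `reorder_with_adjacency()` contracts each matched arc, topologically
   orders the contracted DAG (smallest original index first, for
   determinism) and expands — every matched pair lands adjacent; the
   realizing sequence of (T1) swaps is attached as an audit trail;
3. `recover_transpositions()` merges each adjacent pair into one 3-break
   (three edges replaced by three edges on the same endpoints — verified by
   replay) giving a mixed scenario of length |*t*| − DIT and rate
   `DIT/(|t| − DIT)`.

The proper-mode pipeline always routes through the layered forest, even
when DG(*t*) already is one, to keep the ⌈e/6⌉ guarantee's proof path (and
its tests) uniform.

## Genome-only bounds and numerical choices

`rate_bound_proper()` returns `1/2 − 3s/(8d + 2s)` and
`rate_bound_shortest()` returns `⌈E/4⌉/(d − ⌈E/4⌉)`. Conventions:

* `E` can be negative for fragmented pairs; it is clipped at 0 before the
  ceiling, and the proper bound is likewise clipped at 0 — a negative lower
  bound carries no information and the clip keeps all rates in `[0, 1)`.
* Identical genomes (`d = 0`) make both formulas 0/0; all bounds and rates
  are defined as 0 there.
* All component counts use exact integer arithmetic; `p_even/2` is exact
  because even paths pair up telomeres of the two genomes.

## The synthetic generator

Because real synteny-block datasets are external inputs, every experiment
in the tests runs on generated data:

* `random_genome(n, chroms, topology_mix, seed)` — uniform signed
  permutation split into chromosomes, each circular with probability
  `topology_mix` (default 0.5: mixed karyotypes exercise both path and
  cycle machinery).
* `scramble(g, recipe)` — applies `k` events; with probability
  `transposition_prob` an event is a 3-break *planted as an ordered weakly
  dependent DCJ pair*, so the dependency-graph machinery sees it exactly as
  an implicit transposition. The default `transposition_prob = 0.1` mirrors
  the common empirical estimate that transpositions are under 10% of
  rearrangements.
* `detour_scenario(P, Q, extra, seed)` — proper but non-shortest scenarios:
  `extra` distance-neutral internal DCJs (candidates are rejected if they
  would recreate a removed adjacency, strongly depend on an earlier step,
  or cut a final adjacency), then a randomized shortest sort. Distance-
  neutral internal moves preserve `c`, `p_even` and the PP-/QQ-path counts,
  so the combined scenario meets (P3) with equality; the candidate is
  validated with `check_proper()` and regenerated on failure (at most 100
  attempts, then an error with the seed — never a silent fallback).

What the generator does *not* emulate: breakpoint reuse hot-spots, length-
biased rearrangements, unequal gene content (insertions, deletions,
duplications). Passing tests therefore demonstrate the combinatorial
guarantees — distance realization, properness, bound validity, clean
recovery — on uniform random karyotypes, not biological realism of the
simulated histories.

## Problem sizes used by the test suite

The suites sample: 200 random pairs on ≤ 4 genes for the BFS distance
oracle (the full single-DCJ move graph is searched breadth-first,
independently of the distance formula); 100 seeded shortest scenarios on
8–30 genes for the theorem properties; detour scenarios with `extra` ∈
{1, 2, 3} on 10–15 genes; exhaustive shortcut/adjacency equivalence on all
labeled DAGs with up to 5 vertices; and brute-force DIT maxima on
scenarios of length ≤ 8. These sizes keep each suite in the minutes range
while covering every code path; all guarantees are scale-free, so larger
instances add runtime, not new structure.

## Limitations

* Exact DIT(*t*) is computed only by brute force on short scenarios; the
  general complexity of maximum shortcut-free matchings in these DAGs is
  open, and the package ships lower-bound constructions as its guarantees.
* Replacement of weakly dependent pairs by equivalent pairs ((T2)-style
  rewriting) is out of scope: the constructive recovery needs only (T1)
  reordering.
* Published synteny-block tables for mammalian and yeast genome sets rely
  on external data files; `pairwise_report()` reproduces the table
  *structure* (distance, proper bound, shortest bound, with original and
  circularized values side by side) on any user-supplied GRIMM file, with
  full-precision values by default and two-decimal display via
  `format_pairwise_report()`. The colon-joined "original:circularized"
  notation seen in print is rendered as two separate columns, in that
  order.
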