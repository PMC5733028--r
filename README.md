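# dcjtrans

Tools for double-cut-and-join (DCJ) analysis of gene orders, centered on a
question from genome rearrangement studies: **how many transpositions hide
inside DCJ scenarios?** A DCJ (2-break) cuts up to two gene adjacencies and
rejoins the four loose ends, modeling reversals, translocations, fusions and
fissions. A transposition, which relocates a chromosomal segment, is *not* a
single DCJ — it is a 3-break, equivalent to a pair of *weakly dependent*
DCJs. Parsimony-style reconstructions therefore silently encode
transpositions as DCJ pairs scattered through the scenario. `dcjtrans`
recovers them constructively and bounds their rate from the genomes alone.

## The model

For genomes *P* and *Q* over the same *n* genes, the breakpoint graph
*G*(*P*, *Q*) superposes their adjacencies on the gene extremities (black =
*P*, red = *Q*; each chromosome end gets its own telomere vertex).
Components are alternating cycles and paths, counted as: cycles *c* (trivial
*c₂*), paths *p* (trivial *p₂*), even paths *p_even*, odd paths *p_odd*
(PP- and QQ-paths by end color). The classical DCJ distance is

    d(P,Q) = n − c − p_even/2.

A scenario is **proper** when (P1) no adjacency is recreated after removal,
(P2) no step pair is replaceable by one DCJ, and (P3) fusion/fission counts
stay within the PP-/QQ-path counts; every shortest scenario is proper. The
**dependency graph** DG(*t*) of a scenario has an arc (α, β) whenever β
removes an edge created by α; it is acyclic with in/out degrees ≤ 2, and for
shortest scenarios its underlying graph is a forest. A non-shortcut arc
marks an **implicit transposition**: its two DCJs can be made adjacent by
swapping independent neighbors (T1) and merged into one 3-break. Any
shortcut-free matching *M* of DG(*t*) is simultaneously recoverable, giving
a mixed scenario of |*t*| − |*M*| steps and a transposition rate
r(*t*) = DIT/(|*t*| − DIT). With *e*(*t*) arcs, constructive matchings give

    DIT(t) ≥ ⌈e(t)/6⌉   (proper scenarios, via a layered spanning forest)
    DIT(t) ≥ ⌈e(t)/4⌉   (shortest scenarios, greedy leaf matching)

and two genome-only statistics turn these into uniform rate bounds valid
for *every* scenario of the class:

    s(P,Q) = n + p_odd + p_even/2 − c₂ − p₂,   r(t) ≥ 1/2 − 3s/(8d + 2s)   (proper)
    E(P,Q) = n − 2c − p − p_even/2 + c₂ + p₂,  r(t) ≥ ⌈E/4⌉/(d − ⌈E/4⌉)    (shortest)

## Worked example

The pair: circular *P* = {+a −b +c −d} and linear *Q* = (+a +b +d +c).

```r
library(dcjtrans)
gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
P <- gs[[1]]; Q <- gs[[2]]

component_stats(build_breakpoint_graph(P, Q))
#> Breakpoint graph components (n =  4)
#>   cycles c = 0  trivial c2 = 0
#>   paths p = 1  trivial p2 = 0  even = 0  odd = 1  (PP = 0 , QQ = 1 )

dcj_distance(P, Q)
#> [1] 4

t <- sort_scenario(P, Q)
t
#> DCJ scenario 'P' -> 'Q': 4 step(s)
#>   1  REMOVE {d:t,a:t} CREATE {d:t,*} {a:t,*}  [fission]
#>   2  REMOVE {a:h,b:h} {b:t,c:t} CREATE {a:h,b:t} {b:h,c:t}  [internal]
#>   3  REMOVE {b:h,c:t} {d:t,*} CREATE {b:h,d:t} {c:t,*}  [end]
#>   4  REMOVE {c:h,d:h} {c:t,*} CREATE {d:h,c:t} {c:h,*}  [end]

b <- dit_lower_bound(t, "shortest")
b
#> DIT lower bound (shortest mode): 1  [e(t) = 3, matching size 1]

recover_transpositions(t, b$matching)
#> Mixed scenario 'P' -> 'Q': 3 step(s), 1 transposition(s), rate 0.3333
#>   1  REMOVE {a:h,b:h} {b:t,c:t} CREATE {a:h,b:t} {b:h,c:t}
#>   2  3BREAK REMOVE {d:t,a:t} {b:h,c:t} CREATE {a:t,*} {b:h,d:t} {c:t,*}
#>   3  REMOVE {c:h,d:h} {c:t,*} CREATE {d:h,c:t} {c:h,*}

rate_bound_proper(P, Q)    # 1/7
#> [1] 0.1428571
rate_bound_shortest(P, Q)  # 1/3
#> [1] 0.3333333
```

The single odd path of the breakpoint graph forces a 4-step scenario; its
dependency graph has 3 arcs, so at least one transposition is recoverable
from *every* shortest scenario — a rate of at least 1/3.

Pairwise tables over many genomes (one row per pair, with optional columns
after artificially circularizing each chromosome, as used when comparing
against circular-only methods):

```r
pairwise_report(gs, circularize_also = TRUE)
#>   genome1 genome2 d proper_bound shortest_bound d_circ proper_bound_circ
#> 1       P       Q 4    0.1428571      0.3333333      3             0.125
#>   shortest_bound_circ
#> 1                 0.5
```

(Circularizing the linear genome removes the odd path — the breakpoint
graph becomes a single non-trivial cycle, the distance drops to 3 and the
shortest-scenario bound rises to 1/2.)

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","dcj.R",package="dcjtrans"))')" \
    report genomes.grimm --circularize-also --digits 2 --out table.tsv
```

Subcommands: `report`, `distance`, `sort`, `recover`, `simulate` (synthetic
genome pairs with planted transpositions). Input is GRIMM-style gene-order
text: `>name` headers, one chromosome per line, signed labels ending in `$`
(linear) or `@` (circular).

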