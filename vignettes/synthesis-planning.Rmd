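---
title: "Ranked synthesis planning on hypergraphs of reactions"
author: "synthor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked synthesis planning on hypergraphs of reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthor)
```

## The problem

The first phase of synthesis planning is skeleton construction: choose the
carbon–carbon bonds of a target molecule that will be formed ("fixed") by
construction reactions — *affixations*, which unite two precursor molecules
by one new bond, and *cyclizations*, which close a ring inside one
molecule — and decide the order in which to fix them. The chosen bonds form
the *bond set*, and one bond set typically admits many synthesis plans that
differ in intermediates, convergency, and material consumption. A greedy
retrosynthetic search returns a single plan and can miss plans with costly
late steps but much better early ones; and the single best plan under a
simplified model often turns out infeasible when chemical detail is added.
`synthor` instead enumerates and *ranks* plans: it returns the K best plans
under an additive quality measure, exactly.

## Plans, hypergraphs of reactions, hyperpaths

A molecule here is a connected simple graph with element-labelled atoms; a
synthesis plan is a DAG whose vertices are molecules (each label unique),
whose building blocks are construction reactions, with a unique in-degree-0
root (the target) and starting materials at the leaves. The package
represents the available chemistry as a directed B-hypergraph, the
*hypergraph of reactions* (HoR): one vertex per distinct molecule, one
hyperarc per reaction pointing from the reactant multiset (tail, size 1 or
2) to the product (single head), plus a dummy source vertex `s` with one
dummy arc to each starting material. Synthesis plans for a molecule `t`
then correspond one-to-one to *hyperpaths* from `s` to `t`: sub-hypergraphs
whose arcs can be ordered so that every tail is covered by `s` and earlier
heads, where every non-target vertex has an outgoing arc, and every
non-source vertex has exactly one ingoing arc (its *predecessor*). Because
every construction reaction strictly increases the bond count from
reactants to product, every HoR is acyclic, and its size
$\sum_e (|T(e)|+1)$ is at most $3|E|$.

Two ways to build a HoR are provided. `build_hor_from_bond_set()` breaks
the bond-set bonds of the target recursively in all possible ways; a
fragment containing no bond-set bond is a starting material.
`build_hor_from_reactions()` takes explicit reaction and starting-material
lists (e.g. merging several known plans, which may create new hybrid plans)
and validates that each reaction adds exactly one bond.

## Molecule identity: isomorphism vs embedding

HoR vertices are molecules "up to identity", and the package supports two
identities.

* **isomorphism** (default): two fragments are the same molecule when they
  are isomorphic as element-labelled graphs. This is the chemically natural
  reading — a pentyl fragment is a pentyl fragment wherever it was cut —
  and it is the mode under which the package reproduces the published
  decalin counts (4/18/47/92 bond-set classes; 1711 size-4 plans, maximum
  38 per bond set). Canonical labels are computed with BLISS via igraph.
* **embedding**: two fragments are the same only if they occupy the same
  atoms of the original target *and* retain the same bonds. The atom set
  alone would be ambiguous — decalin minus its ring-fusion bond is a
  10-cycle on the same ten atoms — so the identity key includes the
  surviving bond ids.

The distinction matters for what "all plans" means. Under embedding
identity every hyperpath corresponds to an order of fixing the bonds of the
one embedded target, and the plan set equals a forward enumeration of all
bond-addition orders (the test suite checks this exactly). Under
isomorphism identity the HoR merges isomorphic fragments from different
embeddings, and hyperpaths additionally contain *hybrid* plans whose
reactions are individually realizable but are recombined across embeddings;
the bond-addition orders are then a strict subset. Both semantics are
useful; the isomorphism mode is what the ranked search and the survey
default to.

## Quality measures

An additive weight function assigns each (arc, tail-occurrence) pair a
non-negative coefficient $a_{v,e}$; the weight of the trivial hyperpath is
1 and otherwise
$W(\pi_{st}) = \sum_{v \in T(p(t))} a_{v,p(t)}\, W(\pi_{sv})$,
with the sub-hyperpaths $\pi_{sv}$ unique (extracted by `backtrack()`).

**TW — total weight of starting materials.** The *retro yield* $r_{v,e}$ is
the grams of reactant $v$ consumed per gram of the product of reaction $e$;
mass conservation forces $\sum_v r_{v,e} \ge 1$, and dummy arcs carry
$r = 1$. TW is the additive weight function with $a = r$: grams of starting
materials per gram of target. Equivalently it is the sum over all plain
source-to-target paths of the product of retro yields along the path
(`tw_path_oracle()` implements this form independently as a cross-check; a
tail that repeats a vertex is traversed once per occurrence).
`assign_retro_yields()` implements the carbon-proportional scheme: every
reaction receives a total retro yield `rho_total` (`1.25` ≙ 80% yield,
`2.5` ≙ 40%), given wholly to a cyclization's single reactant and split
between an affixation's two tail occurrences in proportion to their carbon
counts. Setting per-gram prices on the dummy arcs turns TW into total price;
that option is off by default. Values quoted at printed precision use
`round_half_up()` (half away from zero), which is the convention the
reference values follow (e.g. 15.625 → 15.63).

**EPL — external path length.** The sum over the leaves of the plan's
unary–binary *tree expansion* (shared sub-plans duplicated) of the
root-to-leaf reaction count; balanced ("fully convergent") trees minimize
it. EPL is deliberately computed only on `plan_tree` objects, never on the
DAG, because EPL is *not* an additive weight function: the best sub-plan
for a molecule under EPL depends on the depth at which the molecule is
used. The test suite exhibits a synthetic fixture (a molecule of two fused
four-cliques joined by a bridge, makeable either by one affixation of two
identical halves or by a chain of four ring closures, used at depths 1 and
3 of a larger target) where the optimal tree uses *different* sub-plans for
the two occurrences of the same molecule — a plan no practitioner would
run, which is why TW, not EPL, drives the ranking machinery.

## Ranking: K shortest hyperpaths

On an acyclic B-hypergraph the single shortest hyperpath under a
non-negative additive weight function is computed by dynamic programming
over a topological order of the projection graph
(`W(v) = min_e \sum_{u \in T(e)} a_{u,e} W(u)`), with ties broken towards
the lowest arc id. The K best are found Yen-style: emit the cheapest
hyperpath `⟨e_1..e_q⟩`, then for every position `i` re-solve the subproblem
that forces `e_{i+1}..e_q` as the predecessors of their heads (deleting the
heads' other ingoing arcs) and bans `e_i`. Branching from the target side
is a deliberate design choice: because the forcing starts at the target's
own predecessor, every hyperpath of a subproblem necessarily contains the
forced heads, so the deviation subspaces *partition* the remaining
hyperpaths and no hyperpath is generated twice. (Forcing a prefix from the
source side instead gives overlapping subspaces — a hyperpath may simply
avoid a deviation head — and duplicate branching made the search blow up
combinatorially on the denser decalin HoRs.) Subproblems are keyed by
their canonical deleted-arc set and never solved twice.

Two further numerical choices make the output deterministic and stable:

* candidates within one weight level (relative tolerance `1e-9`, which
  absorbs float noise in sums of identical products) are fully expanded
  before any is emitted, then emitted in lexicographic arc-sequence order —
  so equal-TW plans appear in a reproducible order and the K-list is always
  a prefix of the (K+1)-list, which exact ties (such as the two 2.34 g
  decalin plans) would otherwise break;
* `K = Inf` runs to queue exhaustion and equals the independent recursive
  enumeration `enumerate_all_hyperpaths()`, which chooses a predecessor
  arc per demanded vertex (smallest-id vertex first, so each assignment is
  produced exactly once) and serves as the oracle in the tests.

## Bond-set classes

Bond sets that differ only by a symmetry of the skeleton lead to the same
plans, so the survey enumerates one representative per orbit of k-subsets
of bonds under the automorphism group (`enumerate_bond_set_classes()`,
representative = lexicographically least member set). The group is obtained
by closing the BLISS generators under composition — decalin's group has
order 4, so explicit closure is trivial — and an independent Burnside count
(`orbit_count_burnside()`: average number of k-subsets fixed per group
element, via the cycle structure of the induced bond permutation) checks
the orbit enumeration in the tests. Explicit orbit enumeration was chosen
over a symbolic cycle-index computation because it also has to hand out the
representatives, not just count them.

## The decalin study

```{r, eval = FALSE}
d <- decalin()                       # 10 carbons, 11 bonds, fusion bond 6
vapply(1:4, function(k) length(enumerate_bond_set_classes(d, k)), 1L)
#> [1]  4 18 47 92
pcd <- plan_count_distribution(d, 4) # histogram over the 92 classes
pcd$total; pcd$max
#> [1] 1711
#> [1] 38
best_tw(d, 4, rho_total = 1.25)$tw   # global best TW at 80% yield
#> [1] 1.71875
```

`bond_set_survey()` adds, per class, the best TW at each configured
`rho_total` and the first rank at which the 80%- and 40%-yield orderings
disagree (`ranking_first_disagreement()`), a direct probe of how sensitive
a ranking is to imprecise yield estimates; the survey is written as one row
per class and is also exposed through the `inst/scripts/hyperroute.R`
command-line wrapper (`bondsets`, `survey`, `rank`, `enumerate`).

## Problem sizes, degenerate inputs, limitations

All shipped studies are desk-scale by construction: decalin has 11 bonds,
so size-4 surveys touch 330 subsets in 92 classes, each HoR has at most a
few dozen vertices and arcs, and the full survey (building every HoR,
enumerating all 1711 plans, and evaluating TW twice) runs in well under a
minute; the brute-force oracles in the test suite (all-permutation
isomorphism, all-orderings hyperpath recognition, all bond-addition orders)
are run on instances small enough for exactness to be cheap. Degenerate
inputs are defined, not rejected: the empty bond set makes the target its
own starting material (one trivial plan of TW 1), `source == target` is the
trivial hyperpath of weight 1, and an unreachable target yields an empty
ranking. The package models skeleton construction only: no
functionalization, protecting groups, stereochemistry, bond orders or
valence checking, and no reaction-database integration — a bond set or an
explicit reaction list is the entire chemistry it sees. Yields enter as
fixed per-reaction retro-yield totals split by carbon count, a deliberately
coarse stand-in for measured yields; rankings under two totals bracket the
uncertainty rather than model it.
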