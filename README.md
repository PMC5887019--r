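# synthor

Ranked synthesis planning on directed hypergraphs, for chemists and
cheminformaticians working on the skeleton-construction phase of route
design. Given a target molecule and a *bond set* (the carbon–carbon bonds
to be formed by construction reactions — affixations and cyclizations), or
an explicit list of reactions and starting materials, `synthor` builds the
**hypergraph of reactions (HoR)**: one vertex per distinct molecule, one
B-hyperarc per reaction from the reactant multiset to the single product,
plus a dummy source `s` with an arc to every starting material. Every
synthesis plan for the target is then exactly a **hyperpath** from `s` to
the target, so enumerating and ranking plans becomes a shortest-hyperpath
problem, solved exactly and in ranked order instead of greedily.

Plans are ranked by additive weight functions
`W(π_st) = Σ_{v∈T(p(t))} a_{v,p(t)} · W(π_sv)` (with `W = 1` at the
source). The built-in measure is **TW, the total weight of starting
materials**: with retro yields `r_{v,e}` (grams of reactant `v` per gram of
product of reaction `e`, `Σ_v r_{v,e} ≥ 1` by mass conservation, `r = 1` on
dummy arcs),

    TW(π_st) = Σ over plain s–t paths P in π_st  of  Π_{(v,e) ∈ P} r_{v,e}

i.e. grams of starting material per gram of target. Retro yields are
assigned carbon-proportionally from a per-reaction total (`rho_total =
1.25` ≙ 80% yield, `2.5` ≙ 40%). The classical convergency measure **EPL**
(external path length of the plan's tree expansion) is also provided — on
trees only, since it is provably not an additive hyperpath measure.

The K best plans are found by dynamic programming for the single shortest
hyperpath plus Yen-style deviation branching (force the arc suffix from the
target down, ban one arc), which partitions the search space so `K = Inf`
enumerates every plan exactly once. Bond sets equivalent under the
skeleton's automorphism group are surveyed once per orbit. The decalin
skeleton (bicyclo[4.4.0]decane: 10 carbons, 11 bonds) ships as the worked
fixture.

## Worked example

Decalin with the size-4 bond set `{2, 4, 8, 10}` (1-based bond ids; the
four "outer" ring bonds two steps from the fusion bond):

```r
library(synthor)
d  <- decalin()
h  <- build_hor_from_bond_set(d, c(2, 4, 8, 10))
h
#> <hor> 8 molecules + source, 8 reaction arcs, 2 starting materials (mode: isomorphism)

r  <- assign_retro_yields(h, rho_total = 1.25)   # 80% yield per reaction
k_shortest_hyperpaths(h, r)                      # K = Inf: all plans, ranked
#> <ranked_plans> 3 plans (K = Inf)
#>    1. weight 2.26562  arcs <1,2,3,4,5,10>
#>    2. weight 2.34375  arcs <1,2,3,6,7,10>
#>    3. weight 2.34375  arcs <1,2,3,8,9,10>
```

This bond set admits three plans. The best needs 2.27 g of starting
materials per gram of decalin (printed precision, `round_half_up`) — it
interleaves affixation and cyclization, so less material is carried through
long reaction chains — while the two plans that postpone both ring closures
to the end tie at 2.34 g. At 40% yield (`rho_total = 2.5`) the same plans
cost 32.5 g and 34.4 g. Converting the winner to its plan DAG:

```r
plan <- hyperpath_to_plan(h, k_shortest_hyperpaths(h, r, K = 1)$entries[[1]]$hyperpath)
plan
#> <synthesis_plan> 6 molecules, 4 reactions, 2 starting materials
epl(expand_to_tree(plan))
#> [1] 10
```

Survey functions aggregate over all non-isomorphic bond sets of a size:
`enumerate_bond_set_classes()` (decalin: 4, 18, 47, 92 classes for sizes
1–4), `plan_count_distribution()` (the 92 size-4 classes admit 1711 plans
in total, at most 38 for a single bond set), `best_tw()` (global best TW:
1.72 g at 80% yield, 10.0 g at 40%), and `bond_set_survey()`, which also
reports where the 80%- and 40%-yield rankings first disagree. A thin CLI
over these functions is installed at `inst/scripts/hyperroute.R`
(subcommands `bondsets`, `survey`, `rank`, `enumerate`).

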