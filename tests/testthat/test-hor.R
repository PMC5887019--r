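test_that("empty bond set gives the one-plan HoR {s, t}", {
  h <- build_hor_from_bond_set(decalin(), integer(0))
  expect_equal(length(h$graph$labels), 2L)
  expect_equal(length(h$graph$arcs), 1L)
  expect_equal(h$starting_vertices, h$target_vertex)
  paths <- enumerate_all_hyperpaths(h)
  expect_equal(length(paths), 1L)
  plan <- hyperpath_to_plan(h, paths[[1]])
  expect_equal(length(plan$labels), 1L)
  expect_true(validate_plan(plan, h))
})

test_that("HoR invariants hold for every small decalin bond set", {
  d <- decalin()
  for (k in 0:3) {
    for (bs in enumerate_bond_set_classes(d, k)) {
      h <- build_hor_from_bond_set(d, bs)
      expect_true(is_acyclic(h$graph))
      expect_lte(hypergraph_size(h$graph), 3L * length(h$graph$arcs))
      heads <- vapply(h$graph$arcs, `[[`, 1L, "head")
      expect_false(any(heads == h$source)) # s has no ingoing arc
      for (e in seq_along(h$graph$arcs)) {
        tl <- h$graph$arcs[[e]]$tail
        if (e %in% h$dummy_arcs) {
          expect_identical(tl, h$source)
        } else {
          expect_true(length(tl) %in% c(1L, 2L))
        }
      }
      # every starting vertex has exactly one dummy ingoing arc
      for (v in h$starting_vertices) {
        expect_equal(sum(heads[h$dummy_arcs] == v), 1L)
      }
    }
  }
})

test_that("a 3-fragment size-4 bond set yields 2 affixations + 2 cyclizations per plan", {
  d <- decalin()
  # find a size-4 class whose full removal leaves 3 pairwise non-isomorphic
  # components (isomorphic fragments would share one starting vertex)
  cls <- enumerate_bond_set_classes(d, 4)
  pick <- which(vapply(cls, function(bs) {
    keys <- vapply(remove_bonds(d, bs$members),
                   function(f) canonical_key(f$fragment), "")
    length(keys) == 3L && !anyDuplicated(keys)
  }, TRUE))
  bs <- cls[[pick[1]]]
  h <- build_hor_from_bond_set(d, bs)
  for (pi in enumerate_all_hyperpaths(h)) {
    dummies <- intersect(pi$arcs, h$dummy_arcs)
    rx <- setdiff(pi$arcs, h$dummy_arcs)
    tl <- vapply(h$graph$arcs[rx], function(a) length(a$tail), 1L)
    expect_equal(length(dummies), 3L)
    expect_equal(sum(tl == 2L), 2L) # affixations
    expect_equal(sum(tl == 1L), 2L) # cyclizations
  }
})

test_that("reaction-list HoR reproduces the bond-set HoR it was read from", {
  d <- decalin()
  # pick one of the two 3-plan size-4 classes and rebuild its HoR from the
  # explicit reaction list
  cls <- enumerate_bond_set_classes(d, 4)
  counts <- vapply(cls, function(bs) {
    length(enumerate_all_hyperpaths(build_hor_from_bond_set(d, bs)))
  }, 1L)
  bs <- cls[[which(counts == 3L)[1]]]
  h <- build_hor_from_bond_set(d, bs)
  rx <- lapply(setdiff(seq_along(h$graph$arcs), h$dummy_arcs), function(e) {
    a <- h$graph$arcs[[e]]
    list(reactants = h$molecules[a$tail], product = h$molecules[[a$head]])
  })
  sm <- h$molecules[h$starting_vertices]
  h2 <- build_hor_from_reactions(rx, sm)
  expect_equal(length(enumerate_all_hyperpaths(h2)), 3L)
  expect_equal(sort(h2$graph$labels), sort(h$graph$labels))
})

test_that("reaction-list HoR validates construction reactions", {
  a <- path_molecule(2); b <- path_molecule(3)
  t5 <- path_molecule(5)
  h <- build_hor_from_reactions(list(list(reactants = list(a, b), product = t5)),
                                list(a, b))
  expect_equal(length(enumerate_all_hyperpaths(h)), 1L)

  # "reaction" adding two bonds is rejected
  t6 <- cycle_molecule(5)
  expect_error(
    build_hor_from_reactions(list(list(reactants = list(a, b), product = t6)),
                             list(a, b)),
    "one bond|one new bond")
  # starting material that never reacts is rejected
  expect_error(
    build_hor_from_reactions(list(list(reactants = list(a, b), product = t5)),
                             list(a, b, path_molecule(4))),
    "not appearing")
})

test_that("plan <-> hyperpath round trip is the identity (bijection)", {
  d <- decalin()
  set.seed(3)
  cls <- enumerate_bond_set_classes(d, 4)
  for (bs in cls[sample(length(cls), 8)]) {
    h <- build_hor_from_bond_set(d, bs)
    paths <- enumerate_all_hyperpaths(h)
    sigs <- character(0)
    for (pi in paths) {
      plan <- hyperpath_to_plan(h, pi)
      expect_true(validate_plan(plan, h))
      back <- plan_to_hyperpath(h, plan)
      expect_identical(sort(back$arcs), sort(pi$arcs))
      sigs <- c(sigs, paste(sort(pi$arcs), collapse = ","))
    }
    expect_false(anyDuplicated(sigs) > 0) # injective over the enumeration
  }
})

test_that("tree expansion duplicates shared sub-plans", {
  d <- decalin()
  # a linear plan: no shared vertices, tree has as many leaves as plan leaves
  h1 <- build_hor_from_bond_set(d, c(1, 2))
  pi1 <- enumerate_all_hyperpaths(h1)[[1]]
  plan1 <- hyperpath_to_plan(h1, pi1)
  tr1 <- expand_to_tree(plan1)
  cnt <- function(node) if (!length(node$children)) 1L else sum(vapply(node$children, cnt, 1L))
  expect_equal(cnt(tr1), length(plan1$leaves))

  # a plan whose target affixes two copies of the same 5-carbon fragment:
  # bond set {3, 9, 6} splits decalin symmetrically
  h2 <- build_hor_from_bond_set(d, c(3, 6, 9))
  tails <- lapply(h2$graph$arcs, `[[`, "tail")
  rep_arc <- which(vapply(tails, function(tl) length(tl) == 2 && tl[1] == tl[2], TRUE))
  expect_gte(length(rep_arc), 1L)
  for (pi in enumerate_all_hyperpaths(h2)) {
    if (any(rep_arc %in% pi$arcs)) {
      plan <- hyperpath_to_plan(h2, pi)
      tr <- expand_to_tree(plan)
      # the shared fragment's sub-plan appears twice: tree leaves exceed
      # distinct plan leaves
      expect_gt(cnt(tr), length(plan$leaves))
    }
  }
})

test_that("hyperpath plans match the brute-force bond-addition-order plans", {
  # In embedding mode every hyperpath is an assembly of one fixed embedding,
  # so the plan set equals the forward bond-addition-order enumeration
  # exactly. In isomorphism mode the HoR merges isomorphic fragments across
  # embeddings and its hyperpaths additionally contain hybrid plans that no
  # single addition order realizes, so the order plans are a subset.
  d <- decalin()
  set.seed(9)
  for (k in 2:3) {
    cls <- enumerate_bond_set_classes(d, k)
    for (bs in cls[sample(length(cls), min(6, length(cls)))]) {
      he <- build_hor_from_bond_set(d, bs, mode = "embedding")
      expect_identical(hor_plan_sigs(he),
                       brute_order_plans(d, bs$members, mode = "embedding"),
                       info = paste("bond set", paste(bs$members, collapse = ",")))
      hi <- build_hor_from_bond_set(d, bs)
      expect_true(all(brute_order_plans(d, bs$members) %in% hor_plan_sigs(hi)))
    }
  }
})
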