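# The two-fused-K4 fixture used for the EPL inconsistency demonstration: a
# molecule M that can be made either by a single affixation of two identical
# K4 halves (2 leaves, shallow) or by a chain of four cyclizations from one
# ring-opened starting material (1 leaf, deep), embedded twice -- at depths 1
# and 3 -- in a larger synthetic target T.
k4 <- function(off = 0L) {
  molecule_graph(rep("C", 4), t(utils::combn(4, 2)) + off)
}
epl_fixture <- function() {
  m_bonds <- rbind(t(utils::combn(4, 2)), t(utils::combn(4, 2)) + 4L, c(4L, 5L))
  M <- molecule_graph(rep("C", 8), m_bonds)
  drop_rows <- function(b, rows) b[-rows, , drop = FALSE]
  # rows of m_bonds: K4a = 1..6 ((1,2),(1,3),(1,4),(2,3),(2,4),(3,4)), K4b = 7..12, bridge = 13
  W  <- molecule_graph(rep("C", 8), drop_rows(m_bonds, c(1, 2, 7, 8)))
  M1 <- molecule_graph(rep("C", 8), drop_rows(m_bonds, c(2, 7, 8)))
  M2 <- molecule_graph(rep("C", 8), drop_rows(m_bonds, c(7, 8)))
  M3 <- molecule_graph(rep("C", 8), drop_rows(m_bonds, 8))
  Z  <- molecule_graph("C", NULL)
  Y2 <- molecule_graph(rep("C", 9), rbind(m_bonds, c(8L, 9L)))
  Y1 <- molecule_graph(rep("C", 9), rbind(m_bonds, c(8L, 9L), c(7L, 9L)))
  Tm <- molecule_graph(rep("C", 17),
                       rbind(m_bonds, c(8L, 9L), c(7L, 9L),
                             m_bonds + 9L, c(9L, 10L)))
  reactions <- list(
    list(reactants = list(W),  product = M1),
    list(reactants = list(M1), product = M2),
    list(reactants = list(M2), product = M3),
    list(reactants = list(M3), product = M),
    list(reactants = list(k4(), k4()), product = M),
    list(reactants = list(M, Z), product = Y2),
    list(reactants = list(Y2), product = Y1),
    list(reactants = list(M, Y1), product = Tm)
  )
  list(hor = build_hor_from_reactions(reactions, list(W, k4(), Z)),
       M_key = canonical_key(M))
}

test_that("carbon-proportional retro yields split by reactant carbons", {
  p2 <- path_molecule(2); p8 <- path_molecule(8); p10 <- path_molecule(10)
  h <- build_hor_from_reactions(
    list(list(reactants = list(p2, p8), product = p10),
         list(reactants = list(p10), product = cycle_molecule(10))),
    list(p2, p8))
  r <- assign_retro_yields(h, 1.25)
  for (e in setdiff(seq_along(h$graph$arcs), h$dummy_arcs)) {
    a <- h$graph$arcs[[e]]
    if (length(a$tail) == 2L) {
      cc <- vapply(a$tail, function(v) carbon_count(h$molecules[[v]]), 1)
      expect_equal(sort(r$coef[[e]]), sort(1.25 * cc / 10))
      expect_setequal(round(r$coef[[e]], 10), c(1.0, 0.25))
    }
  }
  r40 <- assign_retro_yields(h, 2.5)
  cyc <- which(vapply(seq_along(h$graph$arcs), function(e) {
    !(e %in% h$dummy_arcs) && length(h$graph$arcs[[e]]$tail) == 1L
  }, TRUE))
  expect_equal(r40$coef[[cyc]], 2.5)
  for (e in h$dummy_arcs) expect_equal(r$coef[[e]], 1)

  expect_error(assign_retro_yields(h, 0.9), "mass conservation")
})

test_that("weight evaluation follows the inductive definition", {
  # trivial hyperpath has weight one
  h0 <- build_hor_from_bond_set(decalin(), integer(0))
  expect_equal(evaluate_weight(hyperpath(h0$graph, 1L, 1L),
                               weight_function(h0$graph, list(1))), 1)

  # chain of unary arcs with unit coefficients keeps weight one
  hc <- hypergraph(c("s", "a", "b", "t"),
                   list(list(tail = 1, head = 2), list(tail = 2, head = 3),
                        list(tail = 3, head = 4)))
  wc <- weight_function(hc, list(1, 1, 1))
  pc <- hyperpath(hc, 1L, 4L, 1:3)
  expect_equal(evaluate_weight(pc, wc), 1)
  expect_equal(tw_path_oracle(pc, wc), 1)
})

test_that("recursive TW equals the path-product form and the closed form", {
  d <- decalin()
  cls <- enumerate_bond_set_classes(d, 4)
  ncomp <- vapply(cls, function(bs) length(remove_bonds(d, bs$members)), 1L)
  bs <- cls[[which(ncomp == 3L)[1]]]
  h <- build_hor_from_bond_set(d, bs)
  for (rho in c(1.25, 2.5)) {
    r <- assign_retro_yields(h, rho)
    for (pi in enumerate_all_hyperpaths(h)) {
      v <- tw(pi, r)
      expect_equal(v, tw_path_oracle(pi, r), tolerance = 1e-9)
      # carbon-proportional closed form: sum over tree leaves of
      # (leaf carbons / target carbons) * rho^depth
      plan <- hyperpath_to_plan(h, pi)
      leafdat <- local({
        acc <- list()
        rec <- function(node, depth) {
          if (!length(node$children)) {
            acc[[length(acc) + 1L]] <<- c(
              carbon_count(plan$molecules[[as.character(node$vertex)]]), depth)
          } else {
            for (ch in node$children) rec(ch, depth + 1L)
          }
        }
        rec(expand_to_tree(plan), 0L)
        do.call(rbind, acc)
      })
      expect_equal(v, sum(leafdat[, 1] / 10 * rho^leafdat[, 2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("TW is monotone in every retro-yield coefficient it uses", {
  h <- build_hor_from_bond_set(decalin(), c(2, 6, 8, 10))
  r <- assign_retro_yields(h, 1.25)
  pi <- enumerate_all_hyperpaths(h)[[1]]
  base <- tw(pi, r)
  for (e in pi$arcs) {
    for (j in seq_along(r$coef[[e]])) {
      co <- r$coef
      co[[e]][j] <- co[[e]][j] + 0.5
      expect_gte(tw(pi, weight_function(h$graph, co)), base)
    }
  }
})

test_that("unit coefficients count tree leaves with multiplicity", {
  h <- build_hor_from_bond_set(decalin(), c(3, 6, 9))
  ones <- weight_function(h$graph, lapply(h$graph$arcs,
                                          function(a) rep(1, length(a$tail))))
  cnt <- function(node) if (!length(node$children)) 1L else sum(vapply(node$children, cnt, 1L))
  for (pi in enumerate_all_hyperpaths(h)) {
    tree <- expand_to_tree(hyperpath_to_plan(h, pi))
    expect_equal(evaluate_weight(pi, ones), cnt(tree))
  }
})

test_that("EPL basics: leaf depth sums and convergency", {
  # single starting material, no reactions
  h0 <- build_hor_from_bond_set(decalin(), integer(0))
  pl0 <- hyperpath_to_plan(h0, enumerate_all_hyperpaths(h0)[[1]])
  expect_equal(epl(expand_to_tree(pl0)), 0L)

  # a 4-atom chain built from single atoms: balanced plan has EPL 8 (four
  # leaves at depth two), the linear plans 9; the balanced tree is minimal
  p4 <- path_molecule(4)
  h <- build_hor_from_bond_set(p4, 1:3)
  epls <- vapply(enumerate_all_hyperpaths(h), function(pi) {
    epl(expand_to_tree(hyperpath_to_plan(h, pi)))
  }, 1L)
  expect_equal(min(epls), 8L)
  expect_equal(max(epls), 9L)
  expect_equal(sum(epls == 8L), 1L) # unique fully convergent plan
})

test_that("EPL prefers different sub-plans for the same molecule at different depths", {
  fx <- epl_fixture()
  h <- fx$hor
  paths <- enumerate_all_hyperpaths(h)
  expect_equal(length(paths), 2L) # consistent plans: all-deep or all-shallow
  trees <- lapply(paths, function(pi) expand_to_tree(hyperpath_to_plan(h, pi)))
  epls <- vapply(trees, epl, 1L)
  expect_equal(sort(epls), c(15L, 15L))

  # splice: in one consistent tree, replace the depth-3 occurrence of M with
  # the other tree's sub-plan for M -> a cheaper but inconsistent plan
  find_at <- function(node, key, depth, d = 0) {
    if (d == depth && identical(node$label, key)) return(node)
    for (ch in node$children) {
      r <- find_at(ch, key, depth, d + 1)
      if (!is.null(r)) return(r)
    }
    NULL
  }
  replace_at <- function(node, key, depth, sub, d = 0) {
    if (d == depth && identical(node$label, key)) return(sub)
    node$children <- lapply(node$children, replace_at, key = key, depth = depth,
                            sub = sub, d = d + 1)
    node
  }
  leafcnt <- function(node) if (!length(node$children)) 1L else sum(vapply(node$children, leafcnt, 1L))
  tree_chain <- trees[[which.min(vapply(trees, leafcnt, 1L))]] # cyclization chain: 3 leaves
  tree_affix <- trees[[which.max(vapply(trees, leafcnt, 1L))]] # K4+K4 affixation: 5 leaves
  chain_sub <- find_at(tree_chain, fx$M_key, 3)
  mixed <- replace_at(tree_affix, fx$M_key, 3, chain_sub)
  expect_equal(epl(mixed), 14L)
  expect_lt(epl(mixed), min(epls))
})

test_that("half-up rounding reproduces printed precision", {
  expect_equal(round_half_up(2.2656, 2), 2.27)
  expect_equal(round_half_up(34.375, 1), 34.4)
  expect_equal(round_half_up(15.625, 2), 15.63)
  expect_equal(round_half_up(-1.25, 1), -1.3) # halves go away from zero
})
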