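# Additive weight functions on hyperpaths, the total-weight-of-starting-
# materials (TW) measure under retro yields, an independent path-product
# evaluation used as a cross-check, and external path length (EPL) on plan
# trees.
#
# An additive weight function assigns every (arc, tail occurrence) a
# non-negative coefficient a_{v,e}; the weight of the trivial hyperpath is
# one, and otherwise W(pi) = sum over tail occurrences v of the last arc
# p(t) of a_{v,p(t)} * W(pi_sv). TW is the special case a = r where the
# retro yield r_{v,e} is the grams of reactant v consumed per gram of
# product of reaction e (so sum_v r_{v,e} >= 1 by mass conservation), and
# r = 1 on dummy arcs.

#' Construct an additive weight function
#'
#' @param h a `hypergraph` or `hor`.
#' @param coef list with one numeric vector per arc, aligned with the arc's
#'   tail occurrences; all coefficients must be non-negative.
#' @return an object of class `weight_function`.
#' @export
weight_function <- function(h, coef) {
  hh <- if (inherits(h, "hor")) h$graph else h
  if (length(coef) != n_arcs(hh)) stop("need one coefficient vector per arc")
  for (e in seq_along(coef)) {
    co <- as.numeric(coef[[e]])
    if (length(co) != length(hh$arcs[[e]]$tail)) {
      stop(sprintf("arc %d: coefficient vector does not match its tail", e))
    }
    if (any(co < 0) || any(is.na(co))) stop("coefficients must be non-negative")
    coef[[e]] <- co
  }
  structure(list(coef = coef), class = "weight_function")
}

#' Assign retro yields to the arcs of a HoR
#'
#' With the carbon-proportional scheme, every reaction arc receives a total
#' retro yield of `rho_total` grams of reactants per gram of product:
#' a cyclization (one tail occurrence) gets `rho_total` outright, an
#' affixation splits it between the two tail occurrences in proportion to
#' their carbon counts (a repeated tail vertex gets its own share per
#' occurrence). Dummy arcs get 1, unless per-gram prices for the starting
#' materials are supplied, in which case the dummy arc below each leaf
#' carries the price and the measure becomes total price rather than total
#' weight. `rho_total = 1.25` corresponds to a per-reaction yield of
#' `1/1.25 = 80%`, `2.5` to `40%`.
#'
#' @param h a `hor`.
#' @param rho_total per-reaction total retro yield, `>= 1` (mass
#'   conservation).
#' @param scheme `"carbon-proportional"` or `"table"` (explicit per-arc
#'   coefficients via `table`).
#' @param table for `scheme = "table"`: list with one numeric vector per
#'   arc of the HoR (including dummy arcs).
#' @param prices optional named numeric vector of per-gram prices keyed by
#'   starting vertex id; replaces the 1 on the corresponding dummy arcs.
#' @return a `weight_function` with attribute `rho_total`.
#' @export
assign_retro_yields <- function(h, rho_total,
                                scheme = c("carbon-proportional", "table"),
                                table = NULL, prices = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "table") {
    w <- weight_function(h, table)
    for (e in setdiff(seq_len(n_arcs(h$graph)), h$dummy_arcs)) {
      if (sum(w$coef[[e]]) < 1) stop("reaction arc with total retro yield < 1 violates mass conservation")
    }
    attr(w, "rho_total") <- NA_real_
    return(w)
  }
  if (!is.numeric(rho_total) || rho_total < 1) {
    stop("rho_total < 1 violates mass conservation")
  }
  coef <- vector("list", n_arcs(h$graph))
  for (e in seq_len(n_arcs(h$graph))) {
    a <- h$graph$arcs[[e]]
    if (e %in% h$dummy_arcs) {
      p <- 1
      if (!is.null(prices) && as.character(a$head) %in% names(prices)) {
        p <- as.numeric(prices[[as.character(a$head)]])
      }
      coef[[e]] <- p
    } else if (length(a$tail) == 1L) {
      coef[[e]] <- rho_total
    } else {
      cc <- vapply(a$tail, function(v) carbon_count(h$molecules[[v]]), 1)
      if (sum(cc) == 0) stop("carbon-proportional yields need reactants with carbon atoms")
      coef[[e]] <- rho_total * cc / sum(cc)
    }
  }
  w <- weight_function(h$graph, coef)
  attr(w, "rho_total") <- rho_total
  w
}

#' Evaluate an additive weight function on a hyperpath
#'
#' Implements the inductive definition: the trivial hyperpath has weight 1;
#' otherwise the weight is the coefficient-weighted sum over the tail
#' occurrences of the last arc of the weights of the unique sub-hyperpaths
#' to those vertices. Evaluation is memoized along the hyperpath's arc
#' order so each vertex is evaluated once.
#'
#' @param pi a `hyperpath`.
#' @param w a `weight_function` covering every arc of `pi`.
#' @return a non-negative numeric weight.
#' @export
evaluate_weight <- function(pi, w) {
  h <- pi$graph
  if (pi$source == pi$target && !length(pi$arcs)) return(1)
  W <- rep(NA_real_, n_vertices(h))
  W[pi$source] <- 1
  for (e in pi$arcs) {
    if (e > length(w$coef) || is.null(w$coef[[e]])) stop("missing coefficient for arc ", e)
    a <- h$arcs[[e]]
    tv <- W[a$tail]
    if (any(is.na(tv))) stop("hyperpath arcs are not in a valid order")
    W[a$head] <- sum(w$coef[[e]] * tv)
  }
  W[pi$target]
}

#' Total weight of starting materials of a plan
#'
#' Grams of starting materials needed per gram of target, for the plan
#' represented by hyperpath `pi` under retro yields `r`:
#' [evaluate_weight()] specialized to retro-yield coefficients.
#'
#' @param pi a `hyperpath`.
#' @param r a `weight_function` of retro yields (see
#'   [assign_retro_yields()]).
#' @return grams per gram of target.
#' @export
tw <- function(pi, r) evaluate_weight(pi, r)

#' Path-product evaluation of TW (independent cross-check)
#'
#' Enumerates every plain source-to-target path inside the hyperpath (one
#' edge per tail occurrence, so a path through a twice-occurring tail vertex
#' is counted once per occurrence) and sums the products of the retro
#' yields along each path. Mathematically equal to [tw()]; implemented as
#' an explicit forward depth-first path enumeration so the two can be
#' compared as independent routes.
#'
#' @inheritParams tw
#' @return grams per gram of target.
#' @export
tw_path_oracle <- function(pi, r) {
  h <- pi$graph
  if (pi$source == pi$target && !length(pi$arcs)) return(1)
  from <- integer(0); to <- integer(0); rr <- numeric(0)
  for (e in pi$arcs) {
    a <- h$arcs[[e]]
    from <- c(from, a$tail)
    to <- c(to, rep(a$head, length(a$tail)))
    rr <- c(rr, r$coef[[e]])
  }
  total <- 0
  rec <- function(v, prod) {
    if (v == pi$target) {
      total <<- total + prod
      return(invisible())
    }
    for (i in which(from == v)) rec(to[i], prod * rr[i])
  }
  rec(pi$source, 1)
  total
}

#' Round half away from zero
#'
#' Rounding to a fixed number of decimals with halves rounded up (away from
#' zero), the convention used when quoting TW values at printed precision
#' (e.g. 15.625 prints as 15.63); base `round()` rounds half to even.
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' External path length of a plan tree
#'
#' The sum over the tree's leaves (starting materials, with multiplicity)
#' of the number of reactions on the root-to-leaf path. Fully convergent
#' (balanced) plans minimize it, linear plans maximize it. EPL is defined
#' on the tree expansion, not on the plan DAG: the same molecule reached at
#' two different depths contributes differently, which is exactly why EPL
#' is not expressible as an additive weight function on hyperpaths.
#'
#' @param tree a `plan_tree` (see [expand_to_tree()]).
#' @return integer.
#' @export
epl <- function(tree) {
  as.integer(tree_stats(tree)[["epl"]])
}
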