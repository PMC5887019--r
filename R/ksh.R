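# Shortest and K-shortest hyperpaths on acyclic B-hypergraphs.
#
# The single shortest hyperpath under an additive weight function is found
# by dynamic programming over a topological order of the projection graph;
# the K best are found by a Yen-style branching scheme: each emitted
# hyperpath <e_1..e_q> spawns, for every position i, the subproblem that
# forces e_1..e_{i-1} as the predecessors of their heads (all other ingoing
# arcs of those heads are deleted) and bans e_i, re-solved by the dynamic
# program. Exhaustive enumeration (K = Inf) is also available through an
# independent recursive predecessor-assignment enumeration, which doubles
# as the test oracle for the branching search.

ksh_prep <- function(hh) {
  if (!is_acyclic(hh)) stop("cyclic hypergraph")
  nA <- n_arcs(hh)
  heads <- if (nA) vapply(hh$arcs, `[[`, 1L, "head") else integer(0)
  tails <- lapply(hh$arcs, `[[`, "tail")
  incoming <- vector("list", n_vertices(hh))
  for (e in seq_len(nA)) {
    incoming[[heads[e]]] <- c(incoming[[heads[e]]], e)
  }
  topo <- as.integer(igraph::topo_sort(projection_graph(hh), mode = "out"))
  list(incoming = incoming, heads = heads, tails = tails,
       topo = topo, topo_pos = order(topo))
}

# Core DP. removed: logical mask over arc ids (a forced predecessor arc e for
# vertex h(e) is expressed by removing all other ingoing arcs of h(e)).
ksh_solve <- function(hh, prep, w, s, t, removed) {
  nV <- n_vertices(hh)
  if (s == t) return(list(hyperpath = hyperpath(hh, s, t), weight = 1))
  W <- rep(Inf, nV)
  argE <- rep(NA_integer_, nV)
  W[s] <- 1
  coef <- w$coef
  tails <- prep$tails
  for (v in prep$topo) {
    if (v == s) next
    best <- Inf
    bestE <- NA_integer_
    for (e in prep$incoming[[v]]) {
      if (removed[e]) next
      tv <- W[tails[[e]]]
      val <- sum(coef[[e]] * tv)
      if (is.nan(val)) val <- Inf  # 0 * Inf from an unreachable tail
      if (val < best) {
        best <- val
        bestE <- e
      }
    }
    W[v] <- best
    argE[v] <- bestE
  }
  if (!is.finite(W[t])) return(NULL)
  # reconstruct arcs backward from t, order by topological position of head
  needed <- t
  arcset <- integer(0)
  i <- 1L
  while (i <= length(needed)) {
    u <- needed[i]
    i <- i + 1L
    if (u == s) next
    e <- argE[u]
    if (!(e %in% arcset)) {
      arcset <- c(arcset, e)
      for (x in tails[[e]]) {
        if (!(x %in% needed)) needed <- c(needed, x)
      }
    }
  }
  arcs <- arcset[order(prep$topo_pos[prep$heads[arcset]])]
  list(hyperpath = hyperpath(hh, s, t, arcs), weight = W[t])
}

#' Single shortest hyperpath by dynamic programming
#'
#' Processes vertices in a topological order of the projection graph with
#' `W(s) = 1` and `W(v) = min` over allowed ingoing arcs `e` of
#' `sum_{u in T(e)} a_{u,e} W(u)`; ties are broken towards the lowest arc
#' id, making the result deterministic. Requires an acyclic hypergraph and
#' non-negative weights.
#'
#' @param h a `hor` (source/target default to its own) or a `hypergraph`.
#' @param w a `weight_function`.
#' @param s,t source and target vertex ids (defaults from a `hor`).
#' @param banned integer vector of arc ids excluded from the solution.
#' @param forced named/indexed constraint: integer vector of arc ids, one
#'   per selected vertex, that must be the predecessor of that vertex (all
#'   of the vertex's other ingoing arcs are dropped). Supply as a full
#'   length-`|V|` vector with `NA` where unconstrained, or a named vector
#'   `c("7" = 3)` mapping vertex to arc.
#' @return `list(hyperpath =, weight =)`, or `NULL` if `t` is unreachable
#'   under the constraints.
#' @export
shortest_hyperpath <- function(h, w, s = NULL, t = NULL,
                               banned = integer(0), forced = NULL) {
  rs <- resolve_hor(h, s, t)
  prep <- ksh_prep(rs$h)
  removed <- logical(n_arcs(rs$h))
  removed[as.integer(banned)] <- TRUE
  if (!is.null(forced)) {
    if (is.null(names(forced)) || !all(nzchar(names(forced)))) {
      stop("forced must be a named vector mapping vertex id to arc id")
    }
    for (i in seq_along(forced)) {
      v <- as.integer(names(forced)[i])
      e <- as.integer(forced[[i]])
      if (!(e %in% prep$incoming[[v]])) stop("forced arc is not an ingoing arc of its vertex")
      removed[setdiff(prep$incoming[[v]], e)] <- TRUE
    }
  }
  ksh_solve(rs$h, prep, w, rs$s, rs$t, removed)
}

seq_key <- function(arcs) paste(sprintf("%05d", arcs), collapse = ",")

#' K shortest hyperpaths (K best synthesis plans)
#'
#' Yen-style deviation search: pop the cheapest candidate, emit it, and for
#' each position `i` of its arc sequence `<e_1..e_q>` push the subproblem
#' that forces the suffix `e_{i+1}..e_q` as the predecessors of their heads
#' (deleting the heads' other ingoing arcs) and bans `e_i`, re-solved by the
#' shortest-hyperpath dynamic program under the accumulated constraints.
#' Branching from the target side makes the deviation subspaces a partition
#' of the remaining hyperpaths, and subproblems are keyed by their canonical
#' deleted-arc set so no subproblem is solved twice. Candidates at
#' an equal weight level are fully expanded before emission and then emitted
#' in lexicographic arc-sequence order, so output is deterministic and the
#' K-list is always a prefix of the (K+1)-list. Duplicate hyperpaths found
#' through overlapping subproblem spaces are emitted once. With `K = Inf`
#' the search runs to queue exhaustion and returns every s-t hyperpath.
#'
#' @inheritParams shortest_hyperpath
#' @param K positive integer or `Inf`.
#' @return an object of class `ranked_plans`: `list(entries = list of
#'   list(hyperpath =, weight =), K =)` with non-decreasing weights and
#'   pairwise-distinct arc sets.
#' @export
k_shortest_hyperpaths <- function(h, w, s = NULL, t = NULL, K = Inf) {
  if (!(is.infinite(K) || (K == floor(K) && K >= 1))) stop("K must be a positive integer or Inf")
  rs <- resolve_hor(h, s, t)
  hh <- rs$h
  prep <- ksh_prep(hh)
  nA <- n_arcs(hh)

  # A subproblem is fully characterized by its set of removed arcs (forcing a
  # predecessor arc = removing its head's other ingoing arcs), so subproblems
  # reached through different deviation histories collapse onto one key.
  queue <- list()       # list(path, weight, removed, expanded)
  sub_seen <- new.env(parent = emptyenv())
  push <- function(removed) {
    key <- paste0("r", paste(which(removed), collapse = ","))
    if (exists(key, envir = sub_seen, inherits = FALSE)) return(invisible())
    assign(key, TRUE, envir = sub_seen)
    sol <- ksh_solve(hh, prep, w, rs$s, rs$t, removed)
    if (!is.null(sol)) {
      queue[[length(queue) + 1L]] <<- list(path = sol$hyperpath, weight = sol$weight,
                                           removed = removed, expanded = FALSE)
    }
  }
  # Deviation branching in demand order from the target down: for position i
  # of the emitted sequence <e_1..e_q> (e_q = p(t)), force e_{i+1}..e_q as the
  # predecessors of their heads and ban e_i. Because forcing starts at t,
  # every hyperpath of the subproblem demands the forced heads, so the
  # subspaces partition the remainder and each hyperpath is found once.
  expand <- function(cand) {
    arcs <- cand$path$arcs
    q <- length(arcs)
    if (!q) return(invisible())
    nr <- cand$removed
    for (i in q:1) {
      if (i < q) {
        sib <- prep$incoming[[prep$heads[arcs[i + 1L]]]]
        nr[sib[sib != arcs[i + 1L]]] <- TRUE
      }
      nri <- nr
      nri[arcs[i]] <- TRUE
      push(nri)
    }
  }

  push(logical(nA))
  emitted <- list()
  emit_sigs <- character(0)
  eps <- 1e-9
  while (length(queue) && length(emitted) < K) {
    wts <- vapply(queue, `[[`, 1, "weight")
    wmin <- min(wts)
    lvl_tol <- eps * max(1, abs(wmin))
    # expand every candidate at this weight level (children never weigh less)
    repeat {
      idx <- which(wts <= wmin + lvl_tol &
                     !vapply(queue, `[[`, TRUE, "expanded"))
      if (!length(idx)) break
      for (ii in idx) {
        queue[[ii]]$expanded <- TRUE
        expand(queue[[ii]])
      }
      wts <- vapply(queue, `[[`, 1, "weight")
    }
    lvl <- which(wts <= wmin + lvl_tol)
    lvl <- lvl[order(vapply(queue[lvl], function(c) seq_key(c$path$arcs), ""))]
    for (ii in lvl) {
      sig <- arc_set_signature(queue[[ii]]$path$arcs)
      if (!(sig %in% emit_sigs) && length(emitted) < K) {
        emit_sigs <- c(emit_sigs, sig)
        emitted[[length(emitted) + 1L]] <- list(hyperpath = queue[[ii]]$path,
                                                weight = queue[[ii]]$weight)
      }
    }
    queue <- queue[-which(wts <= wmin + lvl_tol)]
  }
  structure(list(entries = emitted, K = K), class = "ranked_plans")
}

#' @export
print.ranked_plans <- function(x, ...) {
  cat(sprintf("<ranked_plans> %d plans (K = %s)\n", length(x$entries),
              format(x$K)))
  for (i in seq_along(x$entries)) {
    cat(sprintf("  %2d. weight %.6g  arcs <%s>\n", i, x$entries[[i]]$weight,
                paste(x$entries[[i]]$hyperpath$arcs, collapse = ",")))
  }
  invisible(x)
}

#' Exhaustively enumerate all s-t hyperpaths of an acyclic B-hypergraph
#'
#' Independent recursion over predecessor assignments: starting from the
#' target, pick an ingoing arc for each still-unresolved vertex (always the
#' smallest-id unresolved vertex, so each assignment is produced exactly
#' once); in an acyclic hypergraph every complete assignment is a valid
#' hyperpath. Serves both as the `K = Inf` API and as the test oracle for
#' [k_shortest_hyperpaths()].
#'
#' @inheritParams shortest_hyperpath
#' @return list of `hyperpath`s (empty if `t` is unreachable).
#' @export
enumerate_all_hyperpaths <- function(h, s = NULL, t = NULL) {
  rs <- resolve_hor(h, s, t)
  hh <- rs$h
  s <- rs$s
  t <- rs$t
  if (s == t) return(list(hyperpath(hh, s, t)))
  prep <- ksh_prep(hh)
  results <- list()
  rec <- function(pending, assigned_v, assigned_e) {
    if (!length(pending)) {
      heads <- assigned_v
      arcs <- assigned_e[order(prep$topo_pos[heads])]
      results[[length(results) + 1L]] <<- hyperpath(hh, s, t, arcs)
      return(invisible())
    }
    v <- min(pending)
    rest <- pending[pending != v]
    for (e in prep$incoming[[v]]) {
      tl <- unique(hh$arcs[[e]]$tail)
      need <- tl[tl != s & !(tl %in% assigned_v) & !(tl %in% rest)]
      rec(c(rest, need), c(assigned_v, v), c(assigned_e, e))
    }
  }
  rec(t, integer(0), integer(0))
  results
}
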