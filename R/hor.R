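# The Hypergraph of Reactions (HoR): construction from a target plus a bond
# set (retrosynthetic recursion) or from an explicit reaction list, the
# plan <-> hyperpath correspondence, and tree expansion of plans.
#
# A HoR has one vertex per distinct molecule (under the chosen identity
# mode), one B-hyperarc per construction reaction pointing from the
# reactant(s) to the product, a dummy source vertex s, and one dummy arc
# from s to each starting material. Reactions strictly increase the number
# of bonds from reactants to product, so every HoR is acyclic.

connected_parts <- function(n_atoms_total, atoms, bond_rows) {
  # components of the subgraph on `atoms` with the given bond rows
  g <- igraph::make_empty_graph(n = n_atoms_total, directed = FALSE)
  if (nrow(bond_rows)) g <- igraph::add_edges(g, t(bond_rows))
  memb <- igraph::components(g)$membership[atoms]
  split(atoms, memb)
}

frag_molecule <- function(target, atoms, bonds_present) {
  sel <- target$bonds[bonds_present, , drop = FALSE]
  molecule_graph(
    target$elements[atoms],
    matrix(match(sel, atoms), ncol = 2L),
    provenance_atoms = atoms,
    provenance_bonds = bonds_present
  )
}

#' Build a HoR from a target molecule and a bond set
#'
#' Generates the reactions by recursively breaking the bond-set bonds of the
#' target in all possible ways: deleting one bond-set bond from a fragment
#' either splits it in two (a retro-affixation, recorded as the hyperarc
#' `({m1, m2}, {m})`) or leaves it connected (a retro-cyclization,
#' `({m'}, {m})`). Fragments containing no bond-set bond are starting
#' materials and receive a dummy arc from the source. Molecules are
#' identified under `mode` ("isomorphism": equal canonical graph;
#' "embedding": equal set of original target atoms and surviving bonds), and
#' duplicate reactions (same tail multiset and head) are stored once.
#'
#' @param target a `molecule_graph`.
#' @param b a `bond_set` or an integer vector of bond ids of `target`.
#' @param mode molecule identity mode, `"isomorphism"` (default) or
#'   `"embedding"`.
#' @return an object of class `hor` with fields `graph` (the
#'   `hypergraph`), `source`, `target_vertex`, `starting_vertices`,
#'   `dummy_arcs`, `molecules` (one representative `molecule_graph` per
#'   non-source vertex) and `mode`.
#' @examples
#' h <- build_hor_from_bond_set(decalin(), c(1, 3, 6, 8))
#' length(enumerate_all_hyperpaths(h))
#' @export
build_hor_from_bond_set <- function(target, b,
                                    mode = c("isomorphism", "embedding")) {
  mode <- match.arg(mode)
  members <- if (inherits(b, "bond_set")) b$members else sort(unique(as.integer(b)))
  nb <- nrow(target$bonds)
  if (length(members) && (any(members < 1L) || any(members > nb))) {
    stop("bond not in target")
  }
  n_at <- length(target$elements)

  fkey <- function(atoms, bonds) {
    paste(paste(atoms, collapse = ","), paste(bonds, collapse = ","), sep = "|")
  }
  env <- new.env(parent = emptyenv())
  env$frags <- list()     # discovery-ordered list(atoms =, bonds =)
  env$reactions <- list() # list(tails = <frag keys>, head = <frag key>)
  env$seen <- new.env(parent = emptyenv())

  expand <- function(atoms, bonds) {
    k <- fkey(atoms, bonds)
    if (exists(k, envir = env$seen, inherits = FALSE)) return(invisible())
    assign(k, TRUE, envir = env$seen)
    env$frags[[length(env$frags) + 1L]] <- list(atoms = atoms, bonds = bonds, key = k)
    for (bb in intersect(bonds, members)) {
      rb <- setdiff(bonds, bb)
      parts <- connected_parts(n_at, atoms,
                               target$bonds[rb, , drop = FALSE])
      child_keys <- character(0)
      for (pa in parts) {
        pa <- sort(pa)
        pb <- rb[target$bonds[rb, 1L] %in% pa & target$bonds[rb, 2L] %in% pa]
        child_keys <- c(child_keys, fkey(pa, pb))
        expand(pa, pb)
      }
      env$reactions[[length(env$reactions) + 1L]] <- list(tails = child_keys, head = k)
    }
  }
  expand(seq_len(n_at), seq_len(nb))

  # map embedded fragments to HoR vertices under the identity mode
  mol_by_fkey <- lapply(env$frags, function(fr) frag_molecule(target, fr$atoms, fr$bonds))
  names(mol_by_fkey) <- vapply(env$frags, `[[`, "", "key")
  id_by_fkey <- vapply(mol_by_fkey, canonical_key, "", mode = mode)

  labels <- "(s)"
  molecules <- list(NULL)
  vid_by_key <- new.env(parent = emptyenv())
  vid_of <- function(fk) {
    idk <- id_by_fkey[[fk]]
    if (!exists(idk, envir = vid_by_key, inherits = FALSE)) {
      labels <<- c(labels, idk)
      molecules[[length(labels)]] <<- mol_by_fkey[[fk]]
      assign(idk, length(labels), envir = vid_by_key)
    }
    get(idk, envir = vid_by_key)
  }
  for (fr in env$frags) vid_of(fr$key)

  # dummy arcs first: fragments with no bond-set bond are starting materials
  is_start <- vapply(env$frags, function(fr) !any(fr$bonds %in% members), TRUE)
  starting <- sort(unique(vapply(env$frags[is_start], function(fr) vid_of(fr$key), 1L)))
  arcs <- lapply(starting, function(v) list(tail = 1L, head = v))
  dummy_arcs <- seq_along(arcs)

  seen_arc <- new.env(parent = emptyenv())
  for (r in env$reactions) {
    tl <- sort(vapply(r$tails, vid_of, 1L))
    hd <- vid_of(r$head)
    sig <- paste(paste(tl, collapse = ","), hd, sep = ">")
    if (!exists(sig, envir = seen_arc, inherits = FALSE)) {
      assign(sig, TRUE, envir = seen_arc)
      arcs[[length(arcs) + 1L]] <- list(tail = tl, head = hd)
    }
  }

  h <- hypergraph(labels, arcs)
  out <- structure(
    list(graph = h, source = 1L, target_vertex = vid_of(fkey(seq_len(n_at), seq_len(nb))),
         starting_vertices = starting, dummy_arcs = dummy_arcs,
         molecules = molecules, mode = mode, bond_set = members),
    class = "hor"
  )
  stopifnot(is_acyclic(h), hypergraph_size(h) <= 3L * n_arcs(h))
  out
}

#' @export
print.hor <- function(x, ...) {
  cat(sprintf(
    "<hor> %d molecules + source, %d reaction arcs, %d starting materials (mode: %s)\n",
    length(x$graph$labels) - 1L, n_arcs(x$graph) - length(x$dummy_arcs),
    length(x$starting_vertices), x$mode))
  invisible(x)
}

# Classify/validate a construction reaction: the product must equal the
# disjoint union of the reactants plus exactly one new bond. Returns
# "cyclization" or "affixation", or stops.
check_construction_reaction <- function(reactants, product) {
  if (!length(reactants) %in% c(1L, 2L)) {
    stop("a construction reaction has one or two reactants")
  }
  n_r <- sum(vapply(reactants, function(m) length(m$elements), 1L))
  b_r <- sum(vapply(reactants, function(m) nrow(m$bonds), 1L))
  if (length(product$elements) != n_r || nrow(product$bonds) != b_r + 1L) {
    stop("product must be the reactants plus exactly one new bond")
  }
  want <- sort(vapply(reactants, canonical_key, ""))
  for (bb in seq_len(nrow(product$bonds))) {
    parts <- remove_bonds(product, bb)
    got <- sort(vapply(parts, function(p) canonical_key(p$fragment), ""))
    if (length(got) == length(want) && all(got == want)) {
      return(if (length(reactants) == 1L) "cyclization" else "affixation")
    }
  }
  stop("product is not obtainable from the reactants by adding one bond")
}

#' Build a HoR from explicit reactions and starting materials
#'
#' @param reactions list of `list(reactants = <list of molecule_graph, 1 or
#'   2>, product = <molecule_graph>)`. Every reaction must be a valid
#'   construction reaction (product = reactants plus exactly one new bond).
#' @param starting_materials list of `molecule_graph`s that may be acquired
#'   without synthesis; each must appear as a reactant of some reaction.
#' @param target optional `molecule_graph` naming the target; defaults to
#'   the unique product that is never consumed by another reaction.
#' @param mode molecule identity mode (see [build_hor_from_bond_set()]).
#' @return an object of class `hor`.
#' @export
build_hor_from_reactions <- function(reactions, starting_materials,
                                     target = NULL,
                                     mode = c("isomorphism", "embedding")) {
  mode <- match.arg(mode)
  labels <- "(s)"
  molecules <- list(NULL)
  vid_by_key <- new.env(parent = emptyenv())
  vid_of <- function(m) {
    idk <- canonical_key(m, mode = mode)
    if (!exists(idk, envir = vid_by_key, inherits = FALSE)) {
      labels <<- c(labels, idk)
      molecules[[length(labels)]] <<- m
      assign(idk, length(labels), envir = vid_by_key)
    }
    get(idk, envir = vid_by_key)
  }

  arc_specs <- list()
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    tryCatch(check_construction_reaction(r$reactants, r$product),
             error = function(e) stop(sprintf("reaction %d: %s", i, conditionMessage(e))))
    hd <- vid_of(r$product)
    tl <- sort(vapply(r$reactants, vid_of, 1L))
    arc_specs[[length(arc_specs) + 1L]] <- list(tail = tl, head = hd)
  }
  all_tail_vids <- sort(unique(unlist(lapply(arc_specs, `[[`, "tail"))))
  starting <- integer(0)
  for (m in starting_materials) {
    v <- vid_of(m)
    if (!(v %in% all_tail_vids)) {
      stop("starting material not appearing in any reaction tail")
    }
    starting <- c(starting, v)
  }
  starting <- sort(unique(starting))

  heads <- vapply(arc_specs, `[[`, 1L, "head")
  if (is.null(target)) {
    roots <- setdiff(unique(heads), all_tail_vids)
    if (length(roots) != 1L) {
      stop("target is ambiguous; pass it explicitly")
    }
    tvid <- roots
  } else {
    tvid <- vid_of(target)
  }

  arcs <- lapply(starting, function(v) list(tail = 1L, head = v))
  dummy_arcs <- seq_along(arcs)
  seen_arc <- new.env(parent = emptyenv())
  for (a in arc_specs) {
    sig <- paste(paste(a$tail, collapse = ","), a$head, sep = ">")
    if (!exists(sig, envir = seen_arc, inherits = FALSE)) {
      assign(sig, TRUE, envir = seen_arc)
      arcs[[length(arcs) + 1L]] <- a
    }
  }
  h <- hypergraph(labels, arcs)
  out <- structure(
    list(graph = h, source = 1L, target_vertex = tvid,
         starting_vertices = starting, dummy_arcs = dummy_arcs,
         molecules = molecules, mode = mode, bond_set = NULL),
    class = "hor"
  )
  if (!is_acyclic(h)) stop("reaction set induces a cyclic hypergraph")
  stopifnot(hypergraph_size(h) <= 3L * n_arcs(h))
  out
}

# resolve (hypergraph, s, t, weight-lookup helpers) from either a hor or a
# bare hypergraph
resolve_hor <- function(h, s = NULL, t = NULL) {
  if (inherits(h, "hor")) {
    list(h = h$graph, s = if (is.null(s)) h$source else as.integer(s),
         t = if (is.null(t)) h$target_vertex else as.integer(t))
  } else {
    if (is.null(s) || is.null(t)) stop("source and target are required for a bare hypergraph")
    list(h = h, s = as.integer(s), t = as.integer(t))
  }
}

#' Convert a hyperpath of a HoR into a synthesis plan
#'
#' Drops the dummy source and dummy arcs and reverses every remaining
#' hyperarc into a building block of a plan DAG: for a reaction arc with
#' head `u` and tail occurrences `v1[, v2]` the DAG gets edges `u -> v1`
#' (`, u -> v2`), with parallel edges kept when a tail repeats a vertex.
#'
#' @param h a `hor`.
#' @param pi a valid `hyperpath` of `h` from the source.
#' @return an object of class `synthesis_plan` with fields `labels`
#'   (canonical keys by HoR vertex id), `molecules`, `edges` (two-column
#'   matrix product -> reactant, with multiplicity), `root`, `leaves`.
#' @export
hyperpath_to_plan <- function(h, pi) {
  rep_ <- validate_hyperpath(h$graph, pi)
  if (!rep_$ok) stop("pi is not a valid hyperpath of the HoR")
  reaction_arcs <- setdiff(pi$arcs, h$dummy_arcs)
  edges <- do.call(rbind, lapply(reaction_arcs, function(e) {
    a <- h$graph$arcs[[e]]
    cbind(a$head, a$tail)
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  verts <- setdiff(hyperpath_vertices(pi), h$source)
  leaves <- setdiff(verts, edges[, 1L])
  plan <- structure(
    list(labels = stats::setNames(h$graph$labels[verts], verts),
         molecules = stats::setNames(h$molecules[verts], verts),
         edges = edges, root = pi$target, leaves = sort(leaves)),
    class = "synthesis_plan"
  )
  plan
}

#' @export
print.synthesis_plan <- function(x, ...) {
  cat(sprintf("<synthesis_plan> %d molecules, %d reactions, %d starting materials\n",
              length(x$labels), length(unique(x$edges[, 1L])), length(x$leaves)))
  invisible(x)
}

#' Validate a synthesis plan
#'
#' Checks the four plan properties: unique molecule labels, every building
#' block a construction reaction (product = children plus one bond), a
#' unique in-degree-zero root, and every leaf a starting material of the
#' HoR (when `h` is supplied).
#'
#' @param plan a `synthesis_plan`.
#' @param h the `hor` it came from, or `NULL` to skip the leaf check.
#' @return `TRUE`, invisibly; stops on violation.
#' @export
validate_plan <- function(plan, h = NULL) {
  if (anyDuplicated(plan$labels)) stop("plan labels are not unique")
  verts <- as.integer(names(plan$labels))
  indeg <- vapply(verts, function(v) sum(plan$edges[, 2L] == v), 1L)
  roots <- verts[indeg == 0L]
  if (!identical(sort(roots), plan$root)) stop("plan must have exactly one in-degree-0 vertex, the target")
  internal <- setdiff(verts, plan$leaves)
  for (v in internal) {
    ch <- plan$edges[plan$edges[, 1L] == v, 2L]
    if (!length(ch) %in% c(1L, 2L)) stop("building block with out-degree not in {1, 2}")
    check_construction_reaction(plan$molecules[as.character(ch)],
                                plan$molecules[[as.character(v)]])
  }
  if (!is.null(h)) {
    if (!all(plan$leaves %in% h$starting_vertices)) {
      stop("plan leaf is not a starting material")
    }
  }
  invisible(TRUE)
}

#' Convert a synthesis plan back into a hyperpath of a HoR
#'
#' Looks up each building block of the plan as a reaction arc of `h`
#' (matching on the tail multiset and head), adds the dummy arcs for the
#' plan's leaves, and orders the arcs along a topological order of the plan
#' DAG (reactants before products).
#'
#' @param h a `hor`.
#' @param plan a `synthesis_plan` whose reactions all exist in `h`.
#' @return a `hyperpath` of `h` from the source to the plan root.
#' @export
plan_to_hyperpath <- function(h, plan) {
  arcsig <- vapply(h$graph$arcs, function(a) {
    paste(paste(sort(a$tail), collapse = ","), a$head, sep = ">")
  }, "")
  verts <- as.integer(names(plan$labels))
  internal <- setdiff(verts, plan$leaves)

  dummy <- vapply(plan$leaves, function(v) {
    e <- which(arcsig == paste("1", v, sep = ">"))
    if (!length(e)) stop("plan leaf has no dummy arc in the HoR")
    e[1L]
  }, 1L)

  reaction <- vapply(internal, function(v) {
    ch <- sort(plan$edges[plan$edges[, 1L] == v, 2L])
    e <- which(arcsig == paste(paste(ch, collapse = ","), v, sep = ">"))
    if (!length(e)) stop("plan uses a reaction absent from the HoR")
    e[1L]
  }, 1L)

  # topological order of the plan DAG: products late
  gg <- igraph::make_empty_graph(n = n_vertices(h$graph), directed = TRUE)
  if (nrow(plan$edges)) gg <- igraph::add_edges(gg, t(plan$edges[, c(2L, 1L)]))
  topo <- as.integer(igraph::topo_sort(gg, mode = "out"))
  reaction <- reaction[order(match(internal, topo))]
  arcs <- c(sort(dummy), reaction)
  pi <- hyperpath(h$graph, h$source, plan$root, arcs)
  rep_ <- validate_hyperpath(h$graph, pi)
  if (!rep_$ok) stop("plan does not induce a valid hyperpath")
  hyperpath(h$graph, h$source, plan$root, rep_$order)
}

#' Expand a synthesis plan DAG into a unary-binary plan tree
#'
#' Depth-first expansion from the root which revisits shared vertices,
#' duplicating shared sub-plans; the leaves of the tree are the plan's
#' starting materials, with multiplicity.
#'
#' @param plan a `synthesis_plan`.
#' @return an object of class `plan_tree`: nested
#'   `list(vertex =, label =, children = list(...))`.
#' @export
expand_to_tree <- function(plan) {
  kids <- function(v) plan$edges[plan$edges[, 1L] == v, 2L]
  rec <- function(v) {
    list(vertex = v, label = plan$labels[[as.character(v)]],
         children = lapply(kids(v), rec))
  }
  structure(rec(plan$root), class = "plan_tree")
}

tree_stats <- function(node) {
  if (!length(node$children)) return(c(leaves = 1, epl = 0))
  st <- vapply(node$children, tree_stats, c(leaves = 0, epl = 0))
  c(leaves = sum(st["leaves", ]), epl = sum(st["epl", ] + st["leaves", ]))
}

#' @export
print.plan_tree <- function(x, ...) {
  st <- tree_stats(x)
  cat(sprintf("<plan_tree> %d leaves, external path length %d\n",
              as.integer(st[["leaves"]]), as.integer(st[["epl"]])))
  invisible(x)
}
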