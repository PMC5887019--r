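# Directed B-hypergraph core: types, acyclicity, size, hyperpath validation
# and the Backtrack extraction of the unique sub-hyperpath to a vertex.
#
# A B-hyperarc is an ordered pair (tail, head) where the tail is a non-empty
# multiset of vertex ids and the head is a single vertex id. Tails are stored
# as integer vectors with repetition: the same vertex may occur twice in a
# tail when two isomorphic co-reactants are identified, and all size and
# weight computations count that multiplicity.

#' Construct a directed B-hypergraph
#'
#' @param labels character vector of vertex labels; vertex ids are the
#'   positions `1..n`.
#' @param arcs list of `list(tail = <int vector, multiset>, head = <int>)`;
#'   arc ids are the positions in the list.
#' @return an object of class `hypergraph`.
#' @export
hypergraph <- function(labels, arcs = list()) {
  labels <- as.character(labels)
  n <- length(labels)
  arcs <- lapply(seq_along(arcs), function(i) {
    a <- arcs[[i]]
    tail <- as.integer(a$tail)
    head <- as.integer(a$head)
    if (!length(tail)) stop(sprintf("arc %d has an empty tail", i))
    if (length(head) != 1L) stop(sprintf("arc %d must have a single head vertex", i))
    if (any(tail < 1L) || any(tail > n) || head < 1L || head > n) {
      stop(sprintf("arc %d references a non-existent vertex", i))
    }
    list(tail = tail, head = head)
  })
  structure(list(labels = labels, arcs = arcs), class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d vertices, %d arcs, size %d\n",
              length(x$labels), length(x$arcs), hypergraph_size(x)))
  invisible(x)
}

n_vertices <- function(h) length(h$labels)
n_arcs <- function(h) length(h$arcs)

# Standard-graph projection: one directed edge u -> h(e) per tail occurrence.
projection_graph <- function(h) {
  el <- do.call(rbind, lapply(h$arcs, function(a) cbind(a$tail, a$head)))
  g <- igraph::make_empty_graph(n = n_vertices(h), directed = TRUE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  g
}

#' Test a hypergraph for acyclicity
#'
#' A hypergraph is acyclic when no plain path (a vertex/arc alternating
#' sequence threading tails to heads) returns to a tail vertex of its first
#' arc; equivalently, when the standard-graph projection with one edge
#' `u -> h(e)` per tail occurrence `u` of each arc `e` has no directed cycle.
#'
#' @param h a `hypergraph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_acyclic <- function(h) {
  igraph::is_dag(projection_graph(h))
}

#' Size of a B-hypergraph
#'
#' The sum over arcs of (tail cardinality + 1), counting tail multiplicity.
#'
#' @param h a `hypergraph`.
#' @return integer.
#' @export
hypergraph_size <- function(h) {
  if (!n_arcs(h)) return(0L)
  sum(vapply(h$arcs, function(a) length(a$tail) + 1L, 1L))
}

#' Construct a hyperpath
#'
#' A hyperpath from `source` to `target` is stored as its ordered arc
#' sequence plus the predecessor map assigning each non-source vertex its
#' unique ingoing arc. The trivial hyperpath (`source == target`) has no
#' arcs. The constructor records the parent hypergraph so that downstream
#' operations can resolve arc tails; use [validate_hyperpath()] for the full
#' definition check.
#'
#' @param h the parent `hypergraph`.
#' @param source,target vertex ids.
#' @param arcs integer vector of arc ids in sequence order.
#' @param pred named integer vector: `pred[["v"]]` is the ingoing arc of
#'   vertex `v`. Computed from `arcs` when omitted.
#' @return an object of class `hyperpath`.
#' @export
hyperpath <- function(h, source, target, arcs = integer(0), pred = NULL) {
  arcs <- as.integer(arcs)
  if (is.null(pred)) {
    heads <- vapply(h$arcs[arcs], `[[`, 1L, "head")
    pred <- stats::setNames(arcs, as.character(heads))
  }
  structure(list(graph = h, source = as.integer(source),
                 target = as.integer(target), arcs = arcs, pred = pred),
            class = "hyperpath")
}

#' @export
print.hyperpath <- function(x, ...) {
  cat(sprintf("<hyperpath> %d -> %d via arcs <%s>\n",
              x$source, x$target, paste(x$arcs, collapse = ",")))
  invisible(x)
}

hyperpath_vertices <- function(pi) {
  h <- pi$graph
  sort(unique(c(pi$source, pi$target,
                unlist(lapply(h$arcs[pi$arcs], function(a) c(a$tail, a$head))))))
}

arc_set_signature <- function(arcs) paste(sort(as.integer(arcs)), collapse = ",")

# Greedy ordering for hyperpath condition (1): repeatedly append any arc
# whose tail is covered by {s} plus earlier heads. Availability only grows,
# so greedy succeeds whenever some valid ordering exists.
order_arcs_greedy <- function(h, s, arcs) {
  remaining <- as.integer(arcs)
  avail <- s
  ord <- integer(0)
  while (length(remaining)) {
    ok <- vapply(remaining, function(e) all(unique(h$arcs[[e]]$tail) %in% avail), TRUE)
    if (!any(ok)) return(NULL)
    e <- remaining[which(ok)[1L]]
    ord <- c(ord, e)
    avail <- c(avail, h$arcs[[e]]$head)
    remaining <- setdiff(remaining, e)
  }
  ord
}

#' Validate a candidate hyperpath against the four defining conditions
#'
#' A sub-hypergraph with arc set `E` is a hyperpath from `s` to `t` when
#' (1) its arcs can be ordered so that each tail is covered by `s` and
#' earlier heads, (2) `t` is the head of the last arc, (3) every vertex
#' except `t` has at least one outgoing arc and `t` has none, and (4) every
#' vertex except `s` has exactly one ingoing arc and `s` has none. The
#' candidate's arcs may be supplied in any order; a valid order is
#' reconstructed greedily and returned.
#'
#' @param h a `hypergraph`.
#' @param candidate a `hyperpath`, or a bare
#'   `list(source =, target =, arcs =)`.
#' @return a list with logical fields `cond1`..`cond4`, `ok` (all four),
#'   and `order` (a valid arc sequence, or `NULL`).
#' @export
validate_hyperpath <- function(h, candidate) {
  s <- as.integer(candidate$source)
  t <- as.integer(candidate$target)
  arcs <- as.integer(candidate$arcs)
  if (any(arcs < 1L) || any(arcs > n_arcs(h))) stop("candidate references unknown arcs")
  if (s < 1L || s > n_vertices(h) || t < 1L || t > n_vertices(h)) {
    stop("candidate references unknown vertices")
  }
  if (anyDuplicated(arcs)) arcs <- unique(arcs)

  if (!length(arcs)) {
    ok <- s == t
    return(list(cond1 = TRUE, cond2 = ok, cond3 = ok, cond4 = ok, ok = ok,
                order = if (ok) integer(0) else NULL))
  }

  heads <- vapply(h$arcs[arcs], `[[`, 1L, "head")
  tails <- lapply(h$arcs[arcs], `[[`, "tail")
  vp <- sort(unique(c(s, t, heads, unlist(tails))))

  indeg <- vapply(vp, function(v) sum(heads == v), 1L)
  cond4 <- all(indeg[vp != s] == 1L) && indeg[match(s, vp)] == 0L

  hasout <- vapply(vp, function(v) any(vapply(tails, function(tl) v %in% tl, TRUE)), TRUE)
  cond3 <- all(hasout[vp != t]) && !hasout[match(t, vp)]

  ord <- order_arcs_greedy(h, s, arcs)
  cond1 <- !is.null(ord)

  cond2 <- FALSE
  if (cond1) {
    last <- ord[length(ord)]
    if (h$arcs[[last]]$head == t) {
      cond2 <- TRUE
    } else {
      et <- arcs[heads == t]
      if (length(et) == 1L) {
        ord2 <- c(setdiff(ord, et), et)
        avail <- s
        valid <- TRUE
        for (e in ord2) {
          if (!all(unique(h$arcs[[e]]$tail) %in% avail)) { valid <- FALSE; break }
          avail <- c(avail, h$arcs[[e]]$head)
        }
        if (valid) { ord <- ord2; cond2 <- TRUE }
      }
    }
  }
  ok <- cond1 && cond2 && cond3 && cond4 && (s != t)
  list(cond1 = cond1, cond2 = cond2, cond3 = cond3, cond4 = cond4, ok = ok,
       order = if (cond1) ord else NULL)
}

#' Extract the unique sub-hyperpath from the source to a vertex
#'
#' Marks `v`, then repeatedly pulls each marked non-source vertex's
#' predecessor arc and marks that arc's tail vertices; the collected arcs,
#' in the order they appear in `pi`, form the unique sub-hyperpath from the
#' source of `pi` to `v`.
#'
#' @param pi a `hyperpath`.
#' @param v a vertex of `pi`.
#' @return a `hyperpath` from `pi$source` to `v`.
#' @export
backtrack <- function(pi, v) {
  v <- as.integer(v)
  h <- pi$graph
  if (!(v %in% hyperpath_vertices(pi))) stop("vertex not in hyperpath")
  if (v == pi$source) return(hyperpath(h, pi$source, v))
  marked <- v
  arcset <- integer(0)
  i <- 1L
  while (i <= length(marked)) {
    u <- marked[i]
    i <- i + 1L
    if (u == pi$source) next
    e <- pi$pred[[as.character(u)]]
    if (!(e %in% arcset)) {
      arcset <- c(arcset, e)
      for (w in unique(h$arcs[[e]]$tail)) {
        if (!(w %in% marked)) marked <- c(marked, w)
      }
    }
  }
  arcs <- pi$arcs[pi$arcs %in% arcset]
  heads <- vapply(h$arcs[arcs], `[[`, 1L, "head")
  hyperpath(h, pi$source, v, arcs, stats::setNames(arcs, as.character(heads)))
}

#' Read a hypergraph from JSON
#'
#' Format: `{"vertices": [{"id": 0, "label": "..."}, ...],
#' "arcs": [{"id": 0, "tail": [..], "head": ..}, ...]}` with 0-based,
#' contiguous ids in order.
#'
#' @param source a file path or literal JSON string.
#' @return a `hypergraph`.
#' @export
read_hypergraph <- function(source) {
  txt <- if (length(source) == 1L && !grepl("[{\\[]", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  labels <- vapply(x$vertices, function(v) as.character(v$label), "")
  arcs <- lapply(x$arcs, function(a) {
    list(tail = as.integer(unlist(a$tail)) + 1L, head = as.integer(a$head) + 1L)
  })
  hypergraph(labels, arcs)
}

#' Write a hypergraph to JSON
#' @param h a `hypergraph`.
#' @param path output file path.
#' @param header optional named list merged into the top level (e.g. source
#'   and target vertex ids of a HoR, already 0-based).
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(h, path, header = list()) {
  x <- c(header, list(
    vertices = lapply(seq_along(h$labels), function(i) {
      list(id = i - 1L, label = h$labels[[i]])
    }),
    arcs = lapply(seq_along(h$arcs), function(i) {
      a <- h$arcs[[i]]
      list(id = i - 1L, tail = as.list(a$tail - 1L), head = a$head - 1L)
    })
  ))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' Export a hypergraph as a DOT file
#'
#' Vertices are drawn as boxes and each hyperarc as a small junction node
#' with edges from its tail vertices and to its head.
#'
#' @param h a `hypergraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypergraph_dot <- function(h, path) {
  lines <- c("digraph hor {", "  node [shape=box];")
  for (i in seq_along(h$labels)) {
    lines <- c(lines, sprintf('  v%d [label="%s"];', i, gsub('"', "'", h$labels[[i]])))
  }
  for (i in seq_along(h$arcs)) {
    a <- h$arcs[[i]]
    lines <- c(lines, sprintf('  e%d [shape=point, label=""];', i),
               sprintf("  v%d -> e%d;", a$tail, i),
               sprintf("  e%d -> v%d;", i, a$head))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
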