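# Independent oracles used throughout the suite: brute-force graph
# isomorphism, brute-force hyperpath recognition (all arc orderings),
# union-find connectivity, a forward bond-addition-order planner, and a
# generator of random acyclic B-hypergraphs.

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

# label-preserving isomorphism by trying every vertex permutation (n <= 8)
brute_iso <- function(m1, m2) {
  n <- length(m1$elements)
  if (n != length(m2$elements) || nrow(m1$bonds) != nrow(m2$bonds)) return(FALSE)
  adj <- function(m) {
    a <- matrix(FALSE, n, n)
    for (i in seq_len(nrow(m$bonds))) a[m$bonds[i, 1], m$bonds[i, 2]] <- a[m$bonds[i, 2], m$bonds[i, 1]] <- TRUE
    a
  }
  a1 <- adj(m1); a2 <- adj(m2)
  for (p in all_perms(n)) {
    if (all(m2$elements[p] == m1$elements) && identical(a2[p, p], a1)) return(TRUE)
  }
  FALSE
}

# union-find component count of a molecule after deleting a bond subset
uf_components <- function(m, subset) {
  n <- length(m$elements)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (b in setdiff(seq_len(nrow(m$bonds)), subset)) {
    ra <- find(m$bonds[b, 1]); rb <- find(m$bonds[b, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# brute-force hyperpath recognition: conditions (3)/(4) directly, condition
# (1)/(2) by trying every ordering of the arcs (arcs <= 8)
brute_is_hyperpath <- function(h, s, t, arcs) {
  if (!length(arcs)) return(s == t)
  if (s == t) return(FALSE)
  heads <- vapply(h$arcs[arcs], `[[`, 1L, "head")
  tails <- lapply(h$arcs[arcs], `[[`, "tail")
  vp <- sort(unique(c(s, t, heads, unlist(tails))))
  indeg <- vapply(vp, function(v) sum(heads == v), 1L)
  if (!(all(indeg[vp != s] == 1L) && indeg[match(s, vp)] == 0L)) return(FALSE)
  hasout <- vapply(vp, function(v) any(vapply(tails, function(tl) v %in% tl, TRUE)), TRUE)
  if (!(all(hasout[vp != t]) && !hasout[match(t, vp)])) return(FALSE)
  for (p in all_perms(length(arcs))) {
    seqa <- arcs[unlist(p)]
    avail <- s
    good <- TRUE
    for (e in seqa) {
      if (!all(unique(h$arcs[[e]]$tail) %in% avail)) { good <- FALSE; break }
      avail <- c(avail, h$arcs[[e]]$head)
    }
    if (good && h$arcs[[seqa[length(seqa)]]]$head == t) return(TRUE)
  }
  FALSE
}

# exhaustive hyperpath enumeration over all arc subsets (arcs(h) small)
brute_all_hyperpaths <- function(h, s, t) {
  nA <- length(h$arcs)
  out <- list()
  for (code in 0:(2^nA - 1L)) {
    arcs <- which(bitwAnd(code, 2^(seq_len(nA) - 1L)) > 0L)
    if (brute_is_hyperpath(h, s, t, arcs)) out[[length(out) + 1L]] <- arcs
  }
  out
}

# random acyclic B-hypergraph with s = 1, t = n; tails draw from
# lower-numbered vertices only, so the vertex numbering is a topological order
random_bhypergraph <- function(n_vertices = 6L, n_arcs = 6L) {
  repeat {
    arcs <- list()
    for (v in 2:n_vertices) { # every non-source vertex gets >= 1 ingoing arc
      tl <- sample(seq_len(v - 1L), size = sample(1:min(2L, v - 1L), 1L),
                   replace = TRUE)
      arcs[[length(arcs) + 1L]] <- list(tail = tl, head = v)
    }
    while (length(arcs) < n_arcs) {
      v <- sample(2:n_vertices, 1L)
      tl <- sample(seq_len(v - 1L), size = sample(1:min(2L, v - 1L), 1L),
                   replace = TRUE)
      arcs[[length(arcs) + 1L]] <- list(tail = tl, head = v)
    }
    h <- hypergraph(sprintf("v%d", seq_len(n_vertices)), arcs)
    if (length(enumerate_all_hyperpaths(h, 1L, n_vertices)) > 0L) return(h)
  }
}

random_weights <- function(h) {
  weight_function(h, lapply(h$arcs, function(a) stats::runif(length(a$tail), 0.2, 2)))
}

arcset_sigs <- function(paths) {
  sort(vapply(paths, function(p) paste(sort(p$arcs), collapse = ","), ""))
}

ranked_sigs <- function(rk) {
  vapply(rk$entries, function(e) paste(sort(e$hyperpath$arcs), collapse = ","), "")
}

# Forward planner: try every order of fixing the bond-set bonds; each
# addition is an affixation if it merges two fragments, a cyclization
# otherwise. A sequence yields a valid plan only if no molecule (under the
# identity mode) ends up with two different building blocks. Returns the set
# of plans, each as the sorted set of reaction signatures
# "tailkey[,tailkey]>headkey".
brute_order_plans <- function(target, members, mode = "isomorphism") {
  nb <- nrow(target$bonds)
  key_cache <- new.env(parent = emptyenv())
  frag_key <- function(atoms, bonds) {
    kk <- paste(paste(atoms, collapse = ","), paste(bonds, collapse = ","), sep = "|")
    if (!exists(kk, envir = key_cache, inherits = FALSE)) {
      mol <- molecule_graph(
        target$elements[atoms],
        matrix(match(target$bonds[bonds, , drop = FALSE], atoms), ncol = 2L),
        provenance_atoms = atoms, provenance_bonds = bonds)
      assign(kk, canonical_key(mol, mode), envir = key_cache)
    }
    get(kk, envir = key_cache)
  }
  start_state <- function() {
    keep <- setdiff(seq_len(nb), members)
    g <- igraph::make_empty_graph(n = length(target$elements), directed = FALSE)
    if (length(keep)) g <- igraph::add_edges(g, t(target$bonds[keep, , drop = FALSE]))
    memb <- igraph::components(g)$membership
    lapply(split(seq_along(memb), memb), function(atoms) {
      atoms <- sort(atoms)
      list(atoms = atoms,
           bonds = keep[target$bonds[keep, 1] %in% atoms & target$bonds[keep, 2] %in% atoms])
    })
  }
  plans <- character(0)
  if (!length(members)) return("")
  for (p in all_perms(length(members))) {
    frs <- start_state()
    rxn <- character(0)
    for (b in members[unlist(p)]) {
      u <- target$bonds[b, 1]; v <- target$bonds[b, 2]
      iu <- which(vapply(frs, function(f) u %in% f$atoms, TRUE))
      iv <- which(vapply(frs, function(f) v %in% f$atoms, TRUE))
      if (iu == iv) {
        f <- frs[[iu]]
        nf <- list(atoms = f$atoms, bonds = sort(c(f$bonds, b)))
        rxn <- c(rxn, paste0(frag_key(f$atoms, f$bonds), ">",
                             frag_key(nf$atoms, nf$bonds)))
        frs[[iu]] <- nf
      } else {
        f1 <- frs[[iu]]; f2 <- frs[[iv]]
        nf <- list(atoms = sort(c(f1$atoms, f2$atoms)),
                   bonds = sort(c(f1$bonds, f2$bonds, b)))
        rxn <- c(rxn, paste0(paste(sort(c(frag_key(f1$atoms, f1$bonds),
                                          frag_key(f2$atoms, f2$bonds))), collapse = ","),
                             ">", frag_key(nf$atoms, nf$bonds)))
        frs <- c(frs[-c(iu, iv)], list(nf))
      }
    }
    rxn <- unique(rxn)
    # validity: each product molecule synthesized exactly one way
    prods <- sub(".*>", "", rxn)
    if (anyDuplicated(prods)) next
    plans <- c(plans, paste(sort(rxn), collapse = ";"))
  }
  sort(unique(plans))
}

# signature set of the plans of a HoR in the same reaction-key format
hor_plan_sigs <- function(h) {
  labs <- h$graph$labels
  sigs <- vapply(enumerate_all_hyperpaths(h), function(pi) {
    rxn <- vapply(setdiff(pi$arcs, h$dummy_arcs), function(e) {
      a <- h$graph$arcs[[e]]
      paste0(paste(sort(labs[a$tail]), collapse = ","), ">", labs[a$head])
    }, "")
    paste(sort(unique(rxn)), collapse = ";")
  }, "")
  sort(unique(sigs))
}

path_molecule <- function(n) {
  molecule_graph(rep("C", n), if (n > 1) cbind(1:(n - 1), 2:n) else NULL)
}

cycle_molecule <- function(n) {
  molecule_graph(rep("C", n), rbind(cbind(1:(n - 1), 2:n), c(1L, n)))
}
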