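# Molecule graphs, canonical identity, bond sets and orbit enumeration.
#
# A molecule (or skeleton) is a connected simple undirected graph whose
# vertices are atoms labelled by element symbol and whose edges are bonds.
# Bond identifiers are positional (row index in the bond table) and are
# never renumbered; fragments carry provenance back to the atoms and bonds
# of the molecule they were cut from.

#' Construct a molecule graph
#'
#' @param elements character vector of element symbols, one per atom. Atom
#'   ids are the positions `1..n`.
#' @param bonds two-column integer matrix (or list of pairs) of atom ids;
#'   each row is one undirected bond. The bond id is the row index.
#' @param provenance_atoms optional integer vector mapping each atom to an
#'   atom id of an original parent molecule (used by fragments so that two
#'   fragments can be compared as embeddings rather than up to isomorphism).
#' @param provenance_bonds optional integer vector mapping each bond to a
#'   bond id of the parent molecule.
#' @return an object of class `molecule_graph`.
#' @examples
#' ethane <- molecule_graph(c("C", "C"), rbind(c(1, 2)))
#' carbon_count(ethane)
#' @export
molecule_graph <- function(elements, bonds,
                           provenance_atoms = NULL, provenance_bonds = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (is.list(bonds)) {
    bonds <- if (length(bonds)) do.call(rbind, lapply(bonds, as.integer)) else NULL
  }
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (any(is.na(bonds)) || any(bonds < 1L) || any(bonds > n)) {
    bad <- which(apply(bonds, 1L, function(b) any(is.na(b)) || any(b < 1L) || any(b > n)))
    stop(sprintf("bond %d references a non-existent atom", bad[1L]))
  }
  if (any(bonds[, 1L] == bonds[, 2L])) {
    stop(sprintf("bond %d is a self-loop", which(bonds[, 1L] == bonds[, 2L])[1L]))
  }
  if (nrow(bonds)) {
    bonds <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  }
  if (anyDuplicated(paste(bonds[, 1L], bonds[, 2L]))) {
    stop("parallel bonds are not allowed")
  }
  m <- structure(
    list(elements = elements, bonds = bonds,
         provenance_atoms = provenance_atoms,
         provenance_bonds = provenance_bonds),
    class = "molecule_graph"
  )
  if (!is_connected_molecule(m)) stop("molecule graph must be connected")
  m
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d atoms (%s), %d bonds\n",
              length(x$elements),
              paste(sort(unique(x$elements)), collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

as_igraph <- function(m) {
  g <- igraph::make_empty_graph(n = length(m$elements), directed = FALSE)
  if (nrow(m$bonds)) g <- igraph::add_edges(g, t(m$bonds))
  g
}

is_connected_molecule <- function(m) {
  igraph::components(as_igraph(m))$no == 1L
}

#' Number of carbon atoms of a molecule
#' @param m a `molecule_graph`.
#' @return integer count of atoms with element `"C"`.
#' @export
carbon_count <- function(m) sum(m$elements == "C")

#' The decalin skeleton
#'
#' Bicyclo[4.4.0]decane: two fused cyclohexane rings, 10 carbon atoms and
#' 11 carbon-carbon bonds. Atoms 1..6 form one ring, atoms 1 and 6..10 the
#' other; bond 6 (atoms 1-6) is the ring-fusion bond.
#'
#' @return a `molecule_graph` with 10 atoms and 11 bonds.
#' @export
decalin <- function() {
  molecule_graph(
    rep("C", 10L),
    rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L),
          c(1L, 6L),
          c(6L, 7L), c(7L, 8L), c(8L, 9L), c(9L, 10L), c(1L, 10L))
  )
}

#' Parse a molecule from its JSON edge-list representation
#'
#' The JSON format is `{"atoms": [{"element": "C"}, ...],
#' "bonds": [[i, j], ...]}` with 0-based atom indices; the bond id is the
#' 0-based position in `"bonds"` (internally bonds are numbered from 1 in
#' input order).
#'
#' @param source a file path or a literal JSON string.
#' @return a validated `molecule_graph`.
#' @export
parse_molecule <- function(source) {
  txt <- if (length(source) == 1L && !grepl("[{\\[]", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  x <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                error = function(e) stop("molecule JSON parse failure: ",
                                         conditionMessage(e)))
  if (is.null(x$atoms) || !length(x$atoms)) stop("molecule JSON: no atoms")
  elements <- vapply(seq_along(x$atoms), function(i) {
    el <- x$atoms[[i]]$element
    if (is.null(el)) stop(sprintf("molecule JSON: atom %d has no element", i - 1L))
    as.character(el)
  }, "")
  bonds <- lapply(seq_along(x$bonds), function(i) {
    b <- unlist(x$bonds[[i]])
    if (length(b) != 2L) stop(sprintf("molecule JSON: bond %d is not a pair", i - 1L))
    as.integer(b) + 1L
  })
  molecule_graph(elements, bonds)
}

#' Write a molecule to its JSON edge-list representation
#' @param m a `molecule_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molecule <- function(m, path) {
  x <- list(
    atoms = lapply(m$elements, function(e) list(element = e)),
    bonds = lapply(seq_len(nrow(m$bonds)), function(i) as.list(m$bonds[i, ] - 1L))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' Canonical identity key of a molecule
#'
#' In `"isomorphism"` mode two molecules receive the same key exactly when
#' they are isomorphic as element-labelled graphs (canonical labelling via
#' BLISS with element colours). In `"embedding"` mode identity is the
#' embedding into the original parent molecule: the set of provenance atoms
#' together with the set of provenance bonds still present (the atom set
#' alone does not determine the fragment once ring bonds have been cut).
#'
#' @param m a `molecule_graph`.
#' @param mode `"isomorphism"` (default) or `"embedding"`.
#' @return a character key, deterministic across runs.
#' @export
canonical_key <- function(m, mode = c("isomorphism", "embedding")) {
  mode <- match.arg(mode)
  if (mode == "embedding") {
    if (is.null(m$provenance_atoms)) {
      stop("embedding identity requires provenance atoms")
    }
    return(paste0("emb|", paste(sort(m$provenance_atoms), collapse = ","),
                  "|", paste(sort(m$provenance_bonds), collapse = ",")))
  }
  n <- length(m$elements)
  cols <- match(m$elements, sort(unique(m$elements)))
  perm <- if (n == 1L) 1L else {
    as.integer(igraph::canonical_permutation(as_igraph(m), colors = cols)$labeling)
  }
  el <- character(n)
  el[perm] <- m$elements
  estr <- ""
  if (nrow(m$bonds)) {
    eb <- cbind(perm[m$bonds[, 1L]], perm[m$bonds[, 2L]])
    eb <- t(apply(eb, 1L, sort))
    eb <- eb[order(eb[, 1L], eb[, 2L]), , drop = FALSE]
    estr <- paste(eb[, 1L], eb[, 2L], sep = "-", collapse = ";")
  }
  paste0("iso|", n, "|", paste(el, collapse = ","), "|", estr)
}

#' Fragment a molecule by deleting a set of bonds
#'
#' Deletes the given bonds and returns the connected components, each as a
#' `molecule_graph` carrying provenance (original atom and bond ids) plus
#' an explicit atom map. Components are ordered by canonical key (ties by
#' smallest original atom id) for determinism.
#'
#' @param m a `molecule_graph`.
#' @param subset integer vector of bond ids of `m` to delete (may be empty).
#' @return a list of `list(fragment = <molecule_graph>, atom_map = <int>)`
#'   where `atom_map[i]` is the atom of `m` behind fragment atom `i`.
#' @export
remove_bonds <- function(m, subset) {
  subset <- as.integer(subset)
  nb <- nrow(m$bonds)
  if (length(subset) && (any(is.na(subset)) || any(subset < 1L) || any(subset > nb))) {
    stop("unknown bond id in subset")
  }
  keep <- setdiff(seq_len(nb), subset)
  g <- igraph::make_empty_graph(n = length(m$elements), directed = FALSE)
  if (length(keep)) g <- igraph::add_edges(g, t(m$bonds[keep, , drop = FALSE]))
  memb <- igraph::components(g)$membership
  out <- lapply(sort(unique(memb)), function(ci) {
    atoms <- which(memb == ci)
    bsel <- keep[m$bonds[keep, 1L] %in% atoms & m$bonds[keep, 2L] %in% atoms]
    local <- match(m$bonds[bsel, , drop = FALSE], atoms)
    frag <- molecule_graph(
      m$elements[atoms],
      matrix(local, ncol = 2L),
      provenance_atoms = if (is.null(m$provenance_atoms)) atoms else m$provenance_atoms[atoms],
      provenance_bonds = if (is.null(m$provenance_bonds)) bsel else m$provenance_bonds[bsel]
    )
    list(fragment = frag, atom_map = atoms)
  })
  keys <- vapply(out, function(f) canonical_key(f$fragment), "")
  tie <- vapply(out, function(f) min(f$atom_map), 1L)
  out[order(keys, tie)]
}

#' A bond set of a target molecule
#'
#' @param target a `molecule_graph`.
#' @param members integer vector of bond ids of `target`.
#' @return an object of class `bond_set`.
#' @export
bond_set <- function(target, members) {
  members <- sort(unique(as.integer(members)))
  nb <- nrow(target$bonds)
  if (length(members) && (any(members < 1L) || any(members > nb))) {
    stop("bond set member outside target bond ids")
  }
  structure(list(target = target, members = members, k = length(members)),
            class = "bond_set")
}

#' @export
print.bond_set <- function(x, ...) {
  cat(sprintf("<bond_set> k=%d {%s}\n", x$k, paste(x$members, collapse = ",")))
  invisible(x)
}

#' Parse a bond set from JSON
#'
#' Format: `{"molecule": "<path>", "bonds": [ids]}` with 0-based bond ids,
#' or `{"molecule": {...inline molecule JSON...}, "bonds": [ids]}`. Relative
#' molecule paths are resolved against the bond-set file's directory.
#'
#' @param source a file path or literal JSON string.
#' @return a `bond_set`.
#' @export
parse_bond_set <- function(source) {
  is_file <- length(source) == 1L && !grepl("[{\\[]", source) && file.exists(source)
  txt <- if (is_file) paste(readLines(source, warn = FALSE), collapse = "\n") else source
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(x$molecule)) stop("bond set JSON: no molecule")
  target <- if (is.character(x$molecule)) {
    path <- x$molecule
    if (is_file && !file.exists(path)) path <- file.path(dirname(source), path)
    parse_molecule(path)
  } else {
    parse_molecule(jsonlite::toJSON(x$molecule, auto_unbox = TRUE))
  }
  bond_set(target, as.integer(unlist(x$bonds)) + 1L)
}

#' Automorphism group of a molecule graph
#'
#' Full group of element-preserving vertex permutations, obtained by closing
#' the BLISS generator set under composition (the graphs handled here are
#' small, so explicit closure is cheap).
#'
#' @param m a `molecule_graph`.
#' @return list of integer permutation vectors; `p[v]` is the image of atom `v`.
#' @export
automorphism_perms <- function(m) {
  n <- length(m$elements)
  cols <- match(m$elements, sort(unique(m$elements)))
  gens <- igraph::automorphism_group(as_igraph(m), colors = cols)
  gens <- lapply(gens, as.integer)
  id <- seq_len(n)
  key <- function(p) paste(p, collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(id), TRUE, envir = seen)
  out <- list(id)
  queue <- list(id)
  while (length(queue)) {
    p <- queue[[1L]]
    queue <- queue[-1L]
    for (g in gens) {
      q <- g[p]
      k <- key(q)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <- q
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out
}

#' Bond permutation induced by an atom permutation
#'
#' @param m a `molecule_graph`.
#' @param perm integer atom permutation (e.g. one element of
#'   [automorphism_perms()]).
#' @return integer vector: position `b` holds the bond id that bond `b` maps to.
#' @export
edge_permutation <- function(m, perm) {
  idx <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(m$bonds))) {
    assign(paste(m$bonds[b, ], collapse = "-"), b, envir = idx)
  }
  vapply(seq_len(nrow(m$bonds)), function(b) {
    uv <- sort(perm[m$bonds[b, ]])
    get(paste(uv, collapse = "-"), envir = idx)
  }, 1L)
}

pad_ids <- function(v) paste(sprintf("%04d", v), collapse = ",")

#' Enumerate non-isomorphic bond sets of a given size
#'
#' Groups the k-subsets of the target's bonds into orbits under the action
#' of the target's automorphism group and returns one representative per
#' orbit (the lexicographically least member set).
#'
#' @param target a `molecule_graph`.
#' @param k size of the bond sets, `0 <= k <=` number of bonds.
#' @return list of `bond_set` objects, one per orbit, each with an
#'   `orbit_size` attribute; ordered by representative.
#' @examples
#' length(enumerate_bond_set_classes(decalin(), 1)) # 4
#' @export
enumerate_bond_set_classes <- function(target, k) {
  nb <- nrow(target$bonds)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > nb) stop("k out of range")
  if (k == 0L) {
    bs <- bond_set(target, integer(0))
    attr(bs, "orbit_size") <- 1L
    return(list(bs))
  }
  eperms <- lapply(automorphism_perms(target), edge_permutation, m = target)
  subs <- utils::combn(nb, k)
  out <- list()
  for (j in seq_len(ncol(subs))) {
    ss <- sort(subs[, j])
    imgs <- vapply(eperms, function(ep) pad_ids(sort(ep[ss])), "")
    if (pad_ids(ss) == min(imgs)) {
      bs <- bond_set(target, ss)
      attr(bs, "orbit_size") <- length(unique(imgs))
      out[[length(out) + 1L]] <- bs
    }
  }
  out[order(vapply(out, function(b) pad_ids(b$members), ""))]
}

#' Burnside count of bond-set orbits
#'
#' Independent count of the number of orbits of k-subsets of bonds under
#' the automorphism group, via Burnside's lemma: the average over group
#' elements of the number of k-subsets fixed by the element (a fixed subset
#' is a union of whole cycles of the induced bond permutation).
#'
#' @inheritParams enumerate_bond_set_classes
#' @return the number of orbits, as a numeric (always integral).
#' @export
orbit_count_burnside <- function(target, k) {
  nb <- nrow(target$bonds)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > nb) stop("k out of range")
  perms <- automorphism_perms(target)
  total <- 0
  for (p in perms) {
    ep <- edge_permutation(target, p)
    lens <- integer(0)
    done <- logical(nb)
    for (b in seq_len(nb)) {
      if (done[b]) next
      len <- 0L
      cur <- b
      repeat {
        done[cur] <- TRUE
        len <- len + 1L
        cur <- ep[cur]
        if (cur == b) break
      }
      lens <- c(lens, len)
    }
    poly <- c(1, rep(0, k))  # coefficients of x^0..x^k in prod (1 + x^len)
    for (len in lens) {
      if (len <= k) {
        poly[(len + 1L):(k + 1L)] <- poly[(len + 1L):(k + 1L)] + poly[1L:(k + 1L - len)]
      }
    }
    total <- total + poly[k + 1L]
  }
  total / length(perms)
}
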