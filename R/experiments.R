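# The decalin-style survey: plan-count distribution over bond-set classes,
# best-TW search, and yield-sensitivity comparison of rankings.

#' Distribution of plan counts over bond-set classes
#'
#' For every non-isomorphic bond set of size `k` of the target, builds the
#' HoR and counts its source-to-target hyperpaths (= synthesis plans), then
#' histograms the counts.
#'
#' @param target a `molecule_graph`.
#' @param k bond-set size.
#' @param mode molecule identity mode (see [build_hor_from_bond_set()]).
#' @return list with `histogram` (named integer: plan count -> number of
#'   classes), `counts` (per class), `total`, `max`, and `classes` (the
#'   `bond_set` representatives).
#' @examples
#' plan_count_distribution(decalin(), 1)$histogram
#' @export
plan_count_distribution <- function(target, k, mode = "isomorphism") {
  classes <- enumerate_bond_set_classes(target, k)
  counts <- vapply(classes, function(bs) {
    h <- build_hor_from_bond_set(target, bs, mode)
    length(enumerate_all_hyperpaths(h))
  }, 1L)
  tab <- table(counts)
  list(histogram = stats::setNames(as.integer(tab), names(tab)),
       counts = counts, total = sum(counts), max = max(counts),
       classes = classes)
}

#' Best total weight of starting materials over all size-k bond sets
#'
#' Minimum TW over all plans of all non-isomorphic size-`k` bond sets of
#' the target, with carbon-proportional retro yields summing to
#' `rho_total` per reaction.
#'
#' @inheritParams plan_count_distribution
#' @param rho_total per-reaction total retro yield (>= 1).
#' @return list with `tw` (the minimum, grams per gram of target),
#'   `bond_set`, `hyperpath`, `plan`, and `hor`.
#' @export
best_tw <- function(target, k, rho_total, mode = "isomorphism") {
  classes <- enumerate_bond_set_classes(target, k)
  best <- NULL
  for (bs in classes) {
    h <- build_hor_from_bond_set(target, bs, mode)
    r <- assign_retro_yields(h, rho_total)
    sol <- shortest_hyperpath(h, r)
    if (!is.null(sol) && (is.null(best) || sol$weight < best$tw)) {
      best <- list(tw = sol$weight, bond_set = bs, hyperpath = sol$hyperpath,
                   hor = h)
    }
  }
  best$plan <- hyperpath_to_plan(best$hor, best$hyperpath)
  best
}

#' First position at which two plan rankings disagree
#'
#' Both rankings must contain the same plans (as arc sets); returns the
#' smallest index `i` at which the i-th plans differ, or `"same"` when the
#' rankings are identical throughout. Ties within each ranking are assumed
#' already resolved by the deterministic tie-break of
#' [k_shortest_hyperpaths()].
#'
#' @param a,b `ranked_plans` over the same plan set.
#' @return an integer index, or the string `"same"`.
#' @export
ranking_first_disagreement <- function(a, b) {
  siga <- vapply(a$entries, function(e) arc_set_signature(e$hyperpath$arcs), "")
  sigb <- vapply(b$entries, function(e) arc_set_signature(e$hyperpath$arcs), "")
  if (length(siga) != length(sigb) || !setequal(siga, sigb)) {
    stop("rankings are over different plan sets")
  }
  d <- which(siga != sigb)
  if (!length(d)) "same" else min(d)
}

#' Survey all size-k bond-set classes of a target
#'
#' For each class: the plan count, the best TW at each retro-yield total,
#' and the first position at which the rankings under the first two
#' `rho_totals` disagree.
#'
#' @inheritParams plan_count_distribution
#' @param rho_totals numeric vector of per-reaction retro-yield totals.
#' @return a `data.frame` with one row per bond-set class.
#' @export
bond_set_survey <- function(target, k, rho_totals = c(1.25, 2.5),
                            mode = "isomorphism") {
  classes <- enumerate_bond_set_classes(target, k)
  rows <- lapply(seq_along(classes), function(i) {
    bs <- classes[[i]]
    h <- build_hor_from_bond_set(target, bs, mode)
    rankings <- lapply(rho_totals, function(rho) {
      k_shortest_hyperpaths(h, assign_retro_yields(h, rho))
    })
    row <- data.frame(
      class = i,
      members = paste(bs$members, collapse = ","),
      orbit_size = attr(bs, "orbit_size"),
      n_components = length(remove_bonds(target, bs$members)),
      plan_count = length(rankings[[1L]]$entries)
    )
    for (j in seq_along(rho_totals)) {
      row[[sprintf("best_tw_rho_%g", rho_totals[j])]] <-
        rankings[[j]]$entries[[1L]]$weight
    }
    if (length(rho_totals) >= 2L) {
      fd <- ranking_first_disagreement(rankings[[1L]], rankings[[2L]])
      row$first_disagreement <- as.character(fd)
    }
    row
  })
  do.call(rbind, rows)
}
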