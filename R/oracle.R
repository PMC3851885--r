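# Brute-force ground truth on small instances: exhaustive enumeration of
# rooted binary topologies, constraint-satisfaction checks, and exact
# minimum-RF / maximum-shared-triplet searches.  These certify the
# polynomial algorithms; they are not meant to scale.

#' Enumerate all rooted binary tree topologies on a leaf set
#'
#' Leaf-insertion recursion: the i-th leaf is inserted on every edge
#' (including above the root) of every tree on the first i-1 leaves, which
#' yields each of the 1*3*...*(2n-3) topologies exactly once, in a
#' deterministic order.
#'
#' @param labels character vector of leaf labels (n of them).
#' @param cap refuse to enumerate above this many leaves (the count is
#'   (2n-3)!!, double-factorial growth).
#' @return a list of binary `rtree` objects.
#' @export
enumerate_rooted_binary_trees <- function(labels, cap = 8L) {
  labels <- lsort(unique(as.character(labels)))
  n <- length(labels)
  if (n < 1L) stop("need at least one leaf")
  if (n > cap) stop("refusing to enumerate ", n, " leaves (cap = ", cap, ")")
  trees <- list(rt_leaf(labels[1L]))
  if (n == 1L) return(trees)
  insert_all <- function(t, lf) {
    out <- list(rt_node(list(t, rt_leaf(lf)))) # insertion above this node
    if (!is_leaf(t)) {
      for (i in seq_along(t$children)) {
        for (sub in insert_all(t$children[[i]], lf)) {
          tt <- t
          tt$children[[i]] <- sub
          out[[length(out) + 1L]] <- tt
        }
      }
    }
    out
  }
  for (i in 2L:n) {
    trees <- unlist(lapply(trees, insert_all, lf = labels[i]),
                    recursive = FALSE)
  }
  trees
}

#' Constraint satisfaction of a candidate tree
#'
#' `satisfies_pairs()`: every pair of `P` is orthologous (speciation lca)
#' once `T` is reconciled.  `satisfies_clades()`: the lca of every leaf set
#' of `C` is a speciation node (the leaf set need not be a clade of `T`).
#'
#' @param T candidate gene tree (`rtree`).
#' @param S binary species tree.
#' @param map gene -> species map.
#' @param P,C constraint sets as elsewhere.
#' @return logical scalar.
#' @export
satisfies_pairs <- function(T, S, map, P) {
  P <- as_pairs(P)
  if (nrow(P) == 0L) return(TRUE)
  r <- reconcile(T, S, map)
  all(vapply(seq_len(nrow(P)), function(i)
    is_orthologous(r, P[i, 1L], P[i, 2L]), logical(1)))
}

#' @rdname satisfies_pairs
#' @export
satisfies_clades <- function(T, S, map, C) {
  C <- as_clades(C)
  if (length(C) == 0L) return(TRUE)
  r <- reconcile(T, S, map)
  all(vapply(C, function(cl)
    identical(lca_event(r, cl), "speciation"), logical(1)))
}

#' Exhaustive minimum-RF correction search
#'
#' Enumerates every rooted binary topology on the gene tree's leaves, keeps
#' those satisfying the constraints, and reports the exact minimum RF
#' distance to the input together with the full argmin set.
#' `brute_force_coc()` additionally reports which argmin trees attain the
#' maximum number of rooted triplets shared with the input.
#'
#' @param recon a `recon` object (small: the search visits (2n-3)!! trees).
#' @param P,C constraint sets.
#' @param cap passed to [enumerate_rooted_binary_trees()].
#' @return a list with `min_rf` (NA and an empty argmin set when no
#'   enumerated tree satisfies the constraints -- only possible for clade
#'   constraints), `argmin` (canonical Newick strings), `n_satisfying`, and
#'   for the clade version `triplet_max` (the triplet-maximal subset of
#'   `argmin`) and `max_shared_triplets`.
#' @export
brute_force_goc <- function(recon, P, cap = 8L) {
  bf_search(recon, function(T)
    satisfies_pairs(T, recon$stree, recon$map, P), with_triplets = FALSE, cap = cap)
}

#' @rdname brute_force_goc
#' @export
brute_force_coc <- function(recon, C, cap = 8L) {
  bf_search(recon, function(T)
    satisfies_clades(T, recon$stree, recon$map, C), with_triplets = TRUE, cap = cap)
}

#' @noRd
bf_search <- function(recon, satisfies, with_triplets, cap) {
  G <- recon$tree
  all_trees <- enumerate_rooted_binary_trees(tree_leaves(G), cap = cap)
  ok <- Filter(satisfies, all_trees)
  if (length(ok) == 0L) {
    out <- list(min_rf = NA_integer_, argmin = character(0), n_satisfying = 0L)
    if (with_triplets) {
      out$triplet_max <- character(0)
      out$max_shared_triplets <- NA_integer_
    }
    return(out)
  }
  rfs <- vapply(ok, rf_distance, integer(1), t2 = G)
  mn <- min(rfs)
  arg <- ok[rfs == mn]
  out <- list(min_rf = mn,
              argmin = lsort(vapply(arg, write_newick, character(1))),
              n_satisfying = length(ok))
  if (with_triplets) {
    tg <- triplets(G)
    sh <- vapply(arg, function(t) length(intersect(triplets(t), tg)),
                 integer(1))
    out$max_shared_triplets <- max(sh)
    out$triplet_max <- lsort(vapply(arg[sh == max(sh)], write_newick,
                                    character(1)))
  }
  out
}
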