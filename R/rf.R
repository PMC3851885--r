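# Rooted Robinson-Foulds distance and rooted-triplet comparison.

#' Rooted Robinson-Foulds distance
#'
#' The cardinality of the symmetric difference between the two trees' clade
#' sets.  For binary rooted trees on the same leaves this equals twice the
#' number of clades of one tree missing from the other, so the distance is
#' always even; it is zero iff the trees are topologically equal.
#'
#' @param t1,t2 `rtree` objects on identical leaf sets.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- lsort(tree_leaves(t1)); l2 <- lsort(tree_leaves(t2))
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ: ",
         if (length(only1)) paste0("only in first: {", paste(only1, collapse = ","), "} ") else "",
         if (length(only2)) paste0("only in second: {", paste(only2, collapse = ","), "}") else "")
  }
  k1 <- clade_keys(t1); k2 <- clade_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Rooted triplets of a binary tree
#'
#' A triplet ((a,b),c) is a set of three leaves whose three-leaf restriction
#' of the tree pairs a with b: the lca of all three is strictly more ancient
#' than the lca of a and b.  A binary tree on n leaves resolves all
#' choose(n,3) triplets.
#'
#' @param tree a binary `rtree`.
#' @return a character vector of canonical triplet codes `"a,b|c"` with
#'   `a < b` lexicographically.
#' @export
triplets <- function(tree) {
  if (!is_binary_tree(tree)) stop("triplets() requires a binary tree")
  all_lv <- tree_leaves(tree)
  if (length(all_lv) < 3L) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (is_leaf(node)) return(node$label)
    lv_kids <- lapply(node$children, rec)
    here <- unlist(lv_kids, use.names = FALSE)
    outg <- setdiff(all_lv, here)
    a <- lv_kids[[1L]]; b <- lv_kids[[2L]]
    if (length(outg) > 0L) {
      pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      lo <- pmin(pairs$a, pairs$b); hi <- pmax(pairs$a, pairs$b)
      codes <- as.vector(outer(paste0(lo, ",", hi), outg,
                               function(p, c) paste0(p, "|", c)))
      out <<- c(out, codes)
    }
    here
  }
  rec(tree)
  lsort(out)
}

#' Number of triplets shared by two binary trees
#'
#' @param t1,t2 binary `rtree` objects (leaf sets may differ; only triplets
#'   on shared leaves can coincide).
#' @return an integer.
#' @export
shared_triplets <- function(t1, t2) {
  length(intersect(triplets(t1), triplets(t2)))
}
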