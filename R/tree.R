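# Rooted-tree data model.
#
# A tree is a recursive structure of class "rtree": every node is a list with
#   $label    character(1) or NULL (mandatory and unique for leaves)
#   $children list of child nodes (empty for leaves; order is meaningful
#             only until canonicalisation)
# Any node is itself a valid rtree, so subtrees can be passed around freely.
# Node identity across operations is by clade key: the sorted, comma-joined
# leaf labels under the node (Newick labels cannot contain commas, so the key
# is unambiguous).  In a tree without unary nodes, clade keys are unique.

#' @noRd
lsort <- function(x) sort(x, method = "radix")

#' Clade key of a set of leaf labels
#'
#' Nodes are addressed throughout the package by their clade: the sorted,
#' comma-joined labels of the leaves below them.
#'
#' @param labels character vector of leaf labels.
#' @return a single string.
#' @export
clade_key <- function(labels) paste(lsort(labels), collapse = ",")

#' @rdname clade_key
#' @param key a clade key.
#' @export
key_leaves <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

#' Construct tree nodes
#'
#' `rt_leaf()` makes a leaf, `rt_node()` an internal node from a list of
#' child nodes.  Labels must be Newick-safe (no parentheses, commas, colons,
#' semicolons or whitespace).
#'
#' @param label node label; mandatory for leaves.
#' @param children list of `rtree` nodes.
#' @return an object of class `rtree`.
#' @export
rt_leaf <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (grepl("[(),;:[:space:]]", label)) {
    stop("leaf label contains characters not allowed in Newick: ", label)
  }
  structure(list(label = label, children = list()), class = "rtree")
}

#' @rdname rt_leaf
#' @export
rt_node <- function(children, label = NULL) {
  stopifnot(is.list(children), length(children) >= 1L)
  structure(list(label = label, children = children), class = "rtree")
}

#' @noRd
is_leaf <- function(node) length(node$children) == 0L

#' Leaf labels of a tree
#'
#' @param tree an `rtree`.
#' @return character vector of leaf labels in tree order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Number of leaves / binarity check
#'
#' @param tree an `rtree`.
#' @export
n_leaves <- function(tree) length(tree_leaves(tree))

#' @rdname n_leaves
#' @return `is_binary_tree()`: TRUE iff every internal node has exactly two
#'   children.
#' @export
is_binary_tree <- function(tree) {
  if (is_leaf(tree)) return(TRUE)
  if (length(tree$children) != 2L) return(FALSE)
  all(vapply(tree$children, is_binary_tree, logical(1)))
}

#' Clades of a tree
#'
#' One clade per node, singletons and the full leaf set included.
#'
#' @param tree an `rtree`.
#' @return `clades()`: a list of sorted character vectors; `clade_keys()`:
#'   the corresponding keys.
#' @export
clades <- function(tree) {
  out <- vector("list", 0L)
  rec <- function(node) {
    lv <- if (is_leaf(node)) node$label else
      unlist(lapply(node$children, rec), use.names = FALSE)
    out[[length(out) + 1L]] <<- lsort(lv)
    lv
  }
  rec(tree)
  out
}

#' @rdname clades
#' @export
clade_keys <- function(tree) {
  vapply(clades(tree), paste, character(1), collapse = ",")
}

# smallest leaf label under a node -- the canonical sort key
#' @noRd
min_leaf <- function(node) lsort(tree_leaves(node))[1L]

#' Canonical form of a tree
#'
#' Orders every child list by the smallest descendant leaf label
#' (lexicographic, C locale), so that equal topologies serialise to
#' byte-identical Newick.
#'
#' @param tree an `rtree`.
#' @return an `rtree`.
#' @export
rt_canonical <- function(tree) {
  if (is_leaf(tree)) return(tree)
  kids <- lapply(tree$children, rt_canonical)
  keys <- vapply(kids, min_leaf, character(1))
  tree$children <- kids[order(keys, method = "radix")]
  tree
}

#' Topological equality of rooted trees
#'
#' Two rooted trees are equal iff they have the same clade sets (internal
#' node labels are ignored).
#'
#' @param t1,t2 `rtree` objects.
#' @export
trees_equal <- function(t1, t2) {
  setequal(clade_keys(t1), clade_keys(t2))
}

#' Lowest common ancestor of a set of leaves
#'
#' The farthest-from-root node that is an ancestor of (or equal to) every
#' named leaf.
#'
#' @param tree an `rtree`.
#' @param labels non-empty character vector of leaf labels.
#' @return the lca node, as an `rtree` (a single leaf if `labels` has one
#'   element).
#' @export
lca <- function(tree, labels) {
  stopifnot(length(labels) >= 1L)
  lv <- tree_leaves(tree)
  unknown <- setdiff(labels, lv)
  if (length(unknown) > 0L) {
    stop("labels not in tree: ", paste(unknown, collapse = ", "))
  }
  node <- tree
  repeat {
    if (is_leaf(node)) return(node)
    nxt <- NULL
    for (ch in node$children) {
      if (all(labels %in% tree_leaves(ch))) { nxt <- ch; break }
    }
    if (is.null(nxt)) return(node)
    node <- nxt
  }
}

# Path from the root to a leaf, as a list of nodes (root first, leaf last).
#' @noRd
path_to_leaf <- function(tree, label) {
  path <- list()
  node <- tree
  repeat {
    path[[length(path) + 1L]] <- node
    if (is_leaf(node)) {
      if (!identical(node$label, label)) stop("leaf not found: ", label)
      return(path)
    }
    nxt <- NULL
    for (ch in node$children) {
      if (label %in% tree_leaves(ch)) { nxt <- ch; break }
    }
    if (is.null(nxt)) stop("leaf not found: ", label)
    node <- nxt
  }
}

#' Extract the subtree whose clade is exactly a given leaf set
#'
#' @param tree an `rtree`.
#' @param leafset character vector of leaf labels (or a single clade key).
#' @return the matching node; error if no node has exactly this clade.
#' @export
subtree_at <- function(tree, leafset) {
  if (length(leafset) == 1L && grepl(",", leafset, fixed = TRUE)) {
    leafset <- key_leaves(leafset)
  }
  key <- clade_key(leafset)
  rec <- function(node) {
    if (clade_key(tree_leaves(node)) == key) return(node)
    for (ch in node$children) {
      if (all(leafset %in% tree_leaves(ch))) return(rec(ch))
    }
    NULL
  }
  found <- rec(tree)
  if (is.null(found)) stop("no node has clade {", key, "}")
  found
}

# Replace the subtree whose clade is `leafset` with `new` (leaf sets may
# differ; used by the COC pushes, which preserve the leaf set overall).
#' @noRd
replace_clade <- function(tree, leafset, new) {
  key <- clade_key(leafset)
  rec <- function(node) {
    if (clade_key(tree_leaves(node)) == key) return(new)
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, rec)
    node
  }
  out <- rec(tree)
  if (identical(clade_keys(out), clade_keys(tree)) && key != clade_key(tree_leaves(new))) {
    # nothing matched; be loud rather than silently returning the input
    if (!(key %in% clade_keys(tree))) stop("no node has clade {", key, "}")
  }
  out
}

# Height of a node: max number of edges to a descendant leaf.
#' @noRd
node_height <- function(node) {
  if (is_leaf(node)) return(0L)
  1L + max(vapply(node$children, node_height, integer(1)))
}

#' Node table of a tree
#'
#' One row per node with its clade key, label (NA when unlabelled), leaf
#' count and leaf flag.  Useful for mapping clade keys back to the input
#' tree's node labels.
#'
#' @param tree an `rtree`.
#' @return a data.frame.
#' @export
node_table <- function(tree) {
  keys <- character(0); labs <- character(0); nl <- integer(0); lf <- logical(0)
  rec <- function(node) {
    lv <- tree_leaves(node)
    keys[length(keys) + 1L] <<- clade_key(lv)
    labs[length(labs) + 1L] <<- if (is.null(node$label)) NA_character_ else node$label
    nl[length(nl) + 1L] <<- length(lv)
    lf[length(lf) + 1L] <<- is_leaf(node)
    for (ch in node$children) rec(ch)
  }
  rec(tree)
  data.frame(key = keys, label = labs, n_leaves = nl, is_leaf = lf,
             stringsAsFactors = FALSE)
}

#' Standardize a tree to a set of extant leaves
#'
#' Removes every node with no descendant in `extant`, then contracts non-root
#' degree-2 nodes and a degree-1 root.  This is the cleanup both correction
#' algorithms apply after removing skeleton leaves or one side of a pushed
#' duplication.
#'
#' @param tree an `rtree`.
#' @param extant character vector of leaf labels to keep.
#' @return an `rtree` whose leaf set is `extant` intersected with the input
#'   leaves; error if that intersection is empty.
#' @export
standardize <- function(tree, extant) {
  rec <- function(node) {
    if (is_leaf(node)) {
      if (node$label %in% extant) return(node)
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])  # contract degree-2 node
    node$children <- kids
    node
  }
  out <- rec(tree)
  if (is.null(out)) stop("standardize: no extant leaf remains")
  out
}

# corrected trees carry no internal labels: the correction invalidates them
# (nodes move), just like branch lengths
#' @noRd
strip_internal_labels <- function(tree) {
  if (is_leaf(tree)) return(tree)
  tree$label <- NULL
  tree$children <- lapply(tree$children, strip_internal_labels)
  tree
}

#' @export
print.rtree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(sprintf("Rooted tree with %d leaves%s\n", length(lv),
              if (is_binary_tree(x)) "" else " (multifurcating)"))
  cat(write_newick(x), "\n")
  invisible(x)
}

# internal validation used by parsers and generators
#' @noRd
validate_rtree <- function(tree) {
  lv <- tree_leaves(tree)
  dup <- unique(lv[duplicated(lv)])
  if (length(dup) > 0L) {
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  invisible(tree)
}
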