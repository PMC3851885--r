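# LCA reconciliation of a gene tree with a species tree, and the
# duplication/speciation event labelling it implies.

# Index of a species tree for fast lca/ancestry queries.  Species-tree nodes
# are identified by their clade key; `label_of` maps keys to display names
# (the node label when present, the leaf name for leaves).
#' @noRd
stree_index <- function(S) {
  keys <- character(0); cl <- list(); labs <- character(0)
  children_keys <- list()
  rec <- function(node) {
    lv <- lsort(tree_leaves(node))
    k <- paste(lv, collapse = ",")
    keys[length(keys) + 1L] <<- k
    cl[[length(cl) + 1L]] <<- lv
    labs[length(labs) + 1L] <<- if (!is.null(node$label)) node$label else k
    children_keys[[k]] <<- vapply(node$children, function(ch)
      clade_key(tree_leaves(ch)), character(1))
    for (ch in node$children) rec(ch)
  }
  rec(S)
  ord <- order(lengths(cl), keys, method = "radix")
  list(tree = S, keys = keys[ord], clades = cl[ord],
       label_of = stats::setNames(labs[ord], keys[ord]),
       children_keys = children_keys, leaves = lsort(tree_leaves(S)),
       root_key = clade_key(tree_leaves(S)))
}

# lowest species-tree node whose clade contains all of `species`
#' @noRd
species_lca_key <- function(sidx, species) {
  species <- unique(species)
  for (i in seq_along(sidx$keys)) {
    if (all(species %in% sidx$clades[[i]])) return(sidx$keys[i])
  }
  stop("species not all present in the species tree: ",
       paste(species, collapse = ", "))
}

# is species node k1 a (strict) descendant of k2?  Clades of one tree are
# laminar, so descent is exactly (proper) subset.
#' @noRd
s_descends <- function(k1, k2, strict = FALSE) {
  a <- key_leaves(k1); b <- key_leaves(k2)
  all(a %in% b) && (!strict || length(a) < length(b))
}

#' Reconcile a gene tree with a species tree
#'
#' Assigns to every gene-tree node g the species s(g): the lowest common
#' ancestor in the species tree of the species of the leaves below g.  Every
#' internal node is labelled speciation when s(g) differs from the species
#' of all its children, and duplication otherwise.  Multifurcating gene
#' trees (intermediates of the clade correction) are accepted; the species
#' tree must be binary.
#'
#' @param G gene tree (`rtree`).
#' @param S binary species tree (`rtree`).
#' @param map named character vector: gene leaf label -> species leaf label.
#'   Must be total on the leaves of `G`.
#' @return an object of class `recon`: a list with the gene tree (`$tree`),
#'   species tree (`$stree`), `$map`, and named character vectors `$species`
#'   (gene clade key -> species clade key) and `$event` (gene clade key ->
#'   `"speciation"`, `"duplication"` or `"leaf"`).
#' @export
reconcile <- function(G, S, map) {
  stopifnot(inherits(G, "rtree"), inherits(S, "rtree"))
  if (!is_binary_tree(S)) stop("the species tree must be binary")
  validate_rtree(G); validate_rtree(S)
  glv <- tree_leaves(G)
  missing <- setdiff(glv, names(map))
  if (length(missing) > 0L) {
    stop("gene leaves missing from the gene-species map: ",
         paste(missing, collapse = ", "))
  }
  slv <- tree_leaves(S)
  bad <- setdiff(unique(map[glv]), slv)
  if (length(bad) > 0L) {
    stop("mapped species absent from the species tree: ",
         paste(bad, collapse = ", "))
  }
  sidx <- stree_index(S)
  species <- character(0); event <- character(0)
  rec <- function(node) {
    lv <- tree_leaves(node)
    k <- clade_key(lv)
    if (is_leaf(node)) {
      sk <- clade_key(map[[node$label]])
      species[[k]] <<- sk
      event[[k]] <<- "leaf"
      return(sk)
    }
    ch_sp <- vapply(node$children, rec, character(1))
    sk <- species_lca_key(sidx, unique(unlist(lapply(ch_sp, key_leaves))))
    species[[k]] <<- sk
    event[[k]] <<- if (any(ch_sp == sk)) "duplication" else "speciation"
    sk
  }
  rec(G)
  structure(list(tree = G, stree = S, map = map[glv], sidx = sidx,
                 species = species, event = event),
            class = "recon")
}

#' Node-by-node reconciliation summary
#'
#' @param recon a `recon` object.
#' @return a data.frame with one row per gene-tree node: clade key, node
#'   label (NA if none), assigned species (display name) and event.
#' @export
node_events <- function(recon) {
  tab <- node_table(recon$tree)
  tab$species <- unname(recon$sidx$label_of[recon$species[tab$key]])
  tab$event <- unname(recon$event[tab$key])
  tab
}

# event at the lca of a set of gene leaf labels
#' @noRd
lca_event <- function(recon, labels) {
  node <- lca(recon$tree, labels)
  recon$event[[clade_key(tree_leaves(node))]]
}

#' Orthology test under a reconciliation
#'
#' Two genes are orthologous iff the event at their lca is a speciation,
#' paralogous iff it is a duplication.
#'
#' @param recon a `recon` object.
#' @param a,b gene leaf labels.
#' @export
is_orthologous <- function(recon, a, b) {
  identical(lca_event(recon, c(a, b)), "speciation")
}

#' Count duplication nodes of a reconciled tree
#'
#' @param recon a `recon` object.
#' @export
n_duplications <- function(recon) sum(recon$event == "duplication")

#' Verify the internal consistency of a reconciliation
#'
#' Recomputes the LCA species assignment and the event rule, and asserts the
#' ancestor property: a node with the same species as a strict ancestor
#' forces that ancestor to be a duplication.  Errors on the first violation.
#'
#' @param recon a `recon` object.
#' @return `TRUE`, invisibly.
#' @export
check_reconciliation <- function(recon) {
  fresh <- reconcile(recon$tree, recon$stree, recon$map)
  ks <- names(recon$species)
  if (!identical(recon$species[lsort(ks)], fresh$species[lsort(ks)]) ||
      !identical(recon$event[lsort(ks)], fresh$event[lsort(ks)])) {
    stop("reconciliation is stale: recomputation differs")
  }
  # ancestor/same-species => duplication, along every root-to-leaf path
  rec <- function(node, anc_keys) {
    k <- clade_key(tree_leaves(node))
    for (ak in anc_keys) {
      if (recon$species[[ak]] == recon$species[[k]] &&
          recon$event[[ak]] != "duplication") {
        stop("ancestor ", ak, " shares species with ", k,
             " but is not a duplication")
      }
    }
    for (ch in node$children) rec(ch, c(anc_keys, k))
  }
  rec(recon$tree, character(0))
  invisible(TRUE)
}

#' @export
print.recon <- function(x, ...) {
  ev <- x$event
  cat(sprintf("Reconciled gene tree: %d leaves, %d speciations, %d duplications\n",
              sum(ev == "leaf"), sum(ev == "speciation"),
              sum(ev == "duplication")))
  cat("gene tree:    ", write_newick(x$tree), "\n")
  cat("species tree: ", write_newick(x$stree), "\n")
  invisible(x)
}
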