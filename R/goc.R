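# Gene Orthology Correction: given a reconciled gene tree and a set P of
# gene pairs required to be orthologous, build the closest tree (rooted
# Robinson-Foulds) in which every pair of P joins at a speciation node.
#
# The machinery: for a required pair (a, b) with lca r and species lca s_ab,
# h_{a,b} is the highest node on the path from a towards r whose species
# maps strictly below s_ab -- the apex above which b can be re-attached so
# the pair becomes orthologous.  Nodes strictly between any h_{a,b} and its
# r are "forbidden": their clades cannot survive in any tree satisfying P.
# All other ("preservable") nodes provably keep their clades, so the
# correction costs exactly twice the number of forbidden nodes.

# Normalise an orthology constraint set to a 2-column character matrix of
# unordered pairs, deduplicated.
#' @noRd
as_pairs <- function(P) {
  if (is.null(P) || (is.data.frame(P) && nrow(P) == 0L) ||
      (is.matrix(P) && nrow(P) == 0L) || length(P) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("g1", "g2"))))
  }
  if (is.data.frame(P)) P <- as.matrix(P[, 1:2])
  if (!is.matrix(P) || ncol(P) != 2L) {
    stop("P must be a 2-column matrix or data.frame of gene pairs")
  }
  storage.mode(P) <- "character"
  if (any(P[, 1L] == P[, 2L])) {
    stop("orthology constraints must pair two distinct genes")
  }
  lo <- pmin(P[, 1L], P[, 2L]); hi <- pmax(P[, 1L], P[, 2L])
  unique(cbind(g1 = lo, g2 = hi))
}

#' Validate an orthology constraint set against a reconciled tree
#'
#' Checks that every pair names two distinct leaves of the gene tree mapped
#' to different species (a same-species pair can never be orthologous).
#'
#' @param recon a `recon` object.
#' @param P gene pairs: 2-column matrix or data.frame.
#' @return the normalised pair matrix, invisibly usable downstream.
#' @export
validate_orthology_pairs <- function(recon, P) {
  P <- as_pairs(P)
  lv <- tree_leaves(recon$tree)
  unknown <- setdiff(unique(c(P)), lv)
  if (length(unknown) > 0L) {
    stop("constraint genes not in the gene tree: ",
         paste(unknown, collapse = ", "))
  }
  same <- recon$map[P[, 1L]] == recon$map[P[, 2L]]
  if (any(same)) {
    bad <- P[same, , drop = FALSE]
    stop("constraint pairs map to the same species (cannot be orthologous): ",
         paste(paste0("(", bad[, 1L], ",", bad[, 2L], ")"), collapse = " "))
  }
  P
}

#' False paralogous pairs
#'
#' The subset of required-ortholog pairs whose lca in the current tree is a
#' duplication: the pairs the tree contradicts.
#'
#' @inheritParams validate_orthology_pairs
#' @return a 2-column character matrix (subset of the rows of `P`).
#' @export
false_paralogs <- function(recon, P) {
  P <- validate_orthology_pairs(recon, P)
  if (nrow(P) == 0L) return(P)
  dup <- vapply(seq_len(nrow(P)), function(i)
    identical(lca_event(recon, P[i, ]), "duplication"), logical(1))
  P[dup, , drop = FALSE]
}

#' Movable apex h of an ordered gene pair
#'
#' The highest node on the path from leaf `a` towards `lca(a, b)` whose
#' species maps strictly below `lca_S(s(a), s(b))`.  It can be `a` itself
#' but never the lca.  Everything strictly between this apex and the lca is
#' forbidden once the pair must become orthologous.
#'
#' @param recon a `recon` object.
#' @param a,b distinct gene leaf labels with different species.
#' @return the apex node, as an `rtree`.
#' @export
movable_apex <- function(recon, a, b) {
  stopifnot(a != b)
  sab <- species_lca_key(recon$sidx,
                         c(recon$map[[a]], recon$map[[b]]))
  path <- path_to_leaf(recon$tree, a)
  r_key <- clade_key(tree_leaves(lca(recon$tree, c(a, b))))
  ridx <- which(vapply(path, function(nd)
    clade_key(tree_leaves(nd)), character(1)) == r_key)
  stopifnot(length(ridx) == 1L)
  # below r, species along the path weakly decrease towards the leaf; the
  # apex is the first node after r mapping strictly below s_ab
  for (i in (ridx + 1L):length(path)) {
    k <- clade_key(tree_leaves(path[[i]]))
    if (s_descends(recon$species[[k]], sab, strict = TRUE)) return(path[[i]])
  }
  stop("internal error: no movable apex found for (", a, ",", b, ")")
}

#' Forbidden nodes H of an orthology constraint set
#'
#' For every ordered pair (a,b) among the false paralogs, the strict
#' ancestors of the movable apex h_{a,b} that are strict descendants of
#' lca(a,b); H is the union over all ordered pairs.  No tree satisfying the
#' constraints can contain the clade of a node of H, and the correction
#' loses exactly these clades.
#'
#' @param recon a `recon` object.
#' @param P gene pairs (the false-paralog subset; pairs whose lca is already
#'   a speciation contribute nothing and are skipped).
#' @return a character vector of clade keys of the gene tree.
#' @export
forbidden_nodes <- function(recon, P) {
  P <- validate_orthology_pairs(recon, P)
  H <- character(0)
  if (nrow(P) == 0L) return(H)
  for (i in seq_len(nrow(P))) {
    pr <- P[i, ]
    if (!identical(lca_event(recon, pr), "duplication")) next
    for (ord in list(pr, rev(pr))) {
      a <- ord[[1L]]; b <- ord[[2L]]
      path <- path_to_leaf(recon$tree, a)
      keys <- vapply(path, function(nd) clade_key(tree_leaves(nd)),
                     character(1))
      r_key <- clade_key(tree_leaves(lca(recon$tree, c(a, b))))
      ridx <- which(keys == r_key)
      h_key <- clade_key(tree_leaves(movable_apex(recon, a, b)))
      hidx <- which(keys == h_key)
      if (hidx - ridx >= 2L) {
        H <- c(H, keys[(ridx + 1L):(hidx - 1L)])
      }
    }
  }
  lsort(unique(H))
}

#' Highest preservable descendants of a node
#'
#' The maximal preservable nodes strictly below `x` whose every intermediate
#' ancestor (below `x`) is forbidden.  Their leaf sets partition the leaves
#' of `x`.  This is the set of subtrees the correction reassembles at each
#' recursion level.
#'
#' @param recon a `recon` object.
#' @param H character vector of forbidden clade keys (from
#'   [forbidden_nodes()]).
#' @param x the node to expand: an `rtree` subtree of the gene tree, a clade
#'   key, or `NULL` for the root.
#' @return a list of `rtree` subtrees, ordered by smallest leaf label.
#' @export
highest_preservable_descendants <- function(recon, H, x = NULL) {
  if (is.null(x)) x <- recon$tree
  if (is.character(x)) x <- subtree_at(recon$tree, x)
  out <- list()
  dig <- function(node) {
    for (ch in node$children) {
      if (clade_key(tree_leaves(ch)) %in% H) dig(ch)
      else out[[length(out) + 1L]] <<- ch
    }
  }
  dig(x)
  out[order(vapply(out, min_leaf, character(1)), method = "radix")]
}

#' Full diagnostic analysis of a pair-constraint instance
#'
#' @inheritParams validate_orthology_pairs
#' @return a list: normalised `pairs`, `false_paralogs`, a data.frame
#'   `apexes` with per ordered pair the lca (`r`), species lca (`s`) and
#'   apex (`h`) keys, the forbidden set `H` (clade keys) and the
#'   `preservable` clade keys.
#' @export
goc_analysis <- function(recon, P) {
  P <- validate_orthology_pairs(recon, P)
  Pf <- false_paralogs(recon, P)
  rows <- list()
  if (nrow(Pf) > 0L) {
    for (i in seq_len(nrow(Pf))) for (ord in list(Pf[i, ], rev(Pf[i, ]))) {
      a <- ord[[1L]]; b <- ord[[2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, b = b,
        r = clade_key(tree_leaves(lca(recon$tree, c(a, b)))),
        s = species_lca_key(recon$sidx, c(recon$map[[a]], recon$map[[b]])),
        h = clade_key(tree_leaves(movable_apex(recon, a, b))),
        stringsAsFactors = FALSE)
    }
  }
  H <- forbidden_nodes(recon, Pf)
  list(pairs = P, false_paralogs = Pf,
       apexes = if (length(rows)) do.call(rbind, rows) else
         data.frame(a = character(0), b = character(0), r = character(0),
                    s = character(0), h = character(0)),
       H = H,
       preservable = setdiff(clade_keys(recon$tree), H))
}

#' Maximum orthology tree
#'
#' Joins a list of subtrees into a single tree in which every pair of
#' subtrees whose root species are unrelated in the species tree (neither an
#' ancestor of the other) meets at a speciation node, with each input
#' subtree kept intact.  The construction grafts each subtree immediately
#' above the skeleton node of a species-tree copy carrying its species, then
#' strips the skeleton leaves and standardizes.
#'
#' @param S binary species tree (`rtree`).
#' @param X non-empty list of `rtree` subtrees with pairwise disjoint leaf
#'   sets.
#' @param map named character vector mapping every leaf of every subtree to
#'   a species leaf of `S`.
#' @return an `rtree` whose leaf set is the union of the subtrees' leaves.
#' @export
max_orthology_tree <- function(S, X, map) {
  if (length(X) == 0L) stop("X must contain at least one subtree")
  if (length(X) == 1L) return(X[[1L]])
  gene_leaves <- unlist(lapply(X, tree_leaves), use.names = FALSE)
  if (anyDuplicated(gene_leaves)) stop("subtrees in X share leaves")
  sidx <- stree_index(S)

  # skeleton: a copy of S whose nodes remember their species clade and whose
  # leaves are renamed so they can never collide with gene labels
  skel <- function(node) {
    k <- clade_key(tree_leaves(node))
    if (is_leaf(node)) {
      nd <- rt_leaf(paste0(".skel.", node$label))
    } else {
      nd <- rt_node(lapply(node$children, skel))
    }
    nd$skel_key <- k
    nd
  }
  FF <- skel(S)

  graft_one <- function(F, key, sub) {
    if (!is.null(F$skel_key) && F$skel_key == key) {
      return(rt_node(list(sub, F)))
    }
    done <- FALSE
    rec <- function(node) {
      if (done || is_leaf(node)) return(node)
      for (i in seq_along(node$children)) {
        ch <- node$children[[i]]
        if (!done && !is.null(ch$skel_key) && ch$skel_key == key) {
          node$children[[i]] <- rt_node(list(sub, ch))
          done <<- TRUE
        } else if (!done) {
          node$children[[i]] <- rec(ch)
        }
      }
      node
    }
    out <- rec(F)
    if (!done) stop("internal error: skeleton node not found for species ", key)
    out
  }

  # grafted subtrees may themselves be outputs of this function; scrub any
  # skeleton markers they carry so later grafts cannot target them
  unskel <- function(node) {
    node$skel_key <- NULL
    node$children <- lapply(node$children, unskel)
    node
  }

  ord <- order(vapply(X, min_leaf, character(1)), method = "radix")
  for (i in ord) {
    sub <- unskel(X[[i]])
    skey <- species_lca_key(sidx, unique(unname(map[tree_leaves(sub)])))
    FF <- graft_one(FF, skey, sub)
  }
  unskel(standardize(FF, extant = gene_leaves))
}

#' Correct a gene tree for pair orthology constraints
#'
#' Produces the tree closest to the input (rooted Robinson-Foulds) in which
#' every constrained pair is orthologous.  Every preservable clade of the
#' input is preserved, the distance to the input equals twice the number of
#' forbidden nodes, and a solution always exists.
#'
#' @param recon a `recon` object with a binary gene tree.
#' @param P required-ortholog gene pairs (2-column matrix or data.frame).
#' @return an object of class `orthofix_correction`: the corrected tree
#'   (`$tree`, canonical), its reconciliation (`$recon`), `$rf` to the
#'   input, the forbidden clade keys (`$forbidden`), `$lost_clades`, a
#'   per-pair status data.frame (`$constraints`) and duplication counts
#'   before/after.
#' @export
correct_goc <- function(recon, P) {
  if (!is_binary_tree(recon$tree)) stop("the gene tree must be binary")
  an <- goc_analysis(recon, P)
  H <- an$H

  build <- function(node) {
    if (is_leaf(node)) return(node)
    X <- highest_preservable_descendants(recon, H, node)
    Xc <- lapply(X, build)
    max_orthology_tree(recon$stree, Xc, recon$map)
  }
  GP <- rt_canonical(strip_internal_labels(build(recon$tree)))
  out_recon <- reconcile(GP, recon$stree, recon$map)

  P <- an$pairs
  sat <- if (nrow(P) > 0L) vapply(seq_len(nrow(P)), function(i)
    is_orthologous(out_recon, P[i, 1L], P[i, 2L]), logical(1)) else logical(0)
  fp_keys <- if (nrow(an$false_paralogs) > 0L)
    paste0(an$false_paralogs[, 1L], "\r", an$false_paralogs[, 2L]) else character(0)
  constraints <- data.frame(
    g1 = P[, 1L], g2 = P[, 2L],
    false_paralog = if (nrow(P)) paste0(P[, 1L], "\r", P[, 2L]) %in% fp_keys else logical(0),
    satisfied = sat, stringsAsFactors = FALSE)

  lost <- setdiff(clade_keys(recon$tree), clade_keys(GP))
  structure(list(
    method = "goc",
    input = recon,
    tree = GP,
    recon = out_recon,
    rf = rf_distance(recon$tree, GP),
    forbidden = H,
    n_forbidden = length(H),
    lost_clades = lsort(lost),
    constraints = constraints,
    n_duplications_input = n_duplications(recon),
    n_duplications_output = n_duplications(out_recon)
  ), class = "orthofix_correction")
}

#' @export
print.orthofix_correction <- function(x, ...) {
  cat(sprintf("%s correction: RF to input = %d (%d clades lost)\n",
              toupper(x$method), x$rf, length(x$lost_clades)))
  if (x$method == "goc") {
    cat(sprintf("  constraints: %d pairs, %d false paralogs, |H| = %d\n",
                nrow(x$constraints), sum(x$constraints$false_paralog),
                x$n_forbidden))
  } else {
    cat(sprintf("  constraints: %d clades, %d pushed, %d satisfied\n",
                nrow(x$constraints), sum(x$constraints$status == "pushed"),
                sum(x$constraints$satisfied)))
  }
  cat(sprintf("  duplications: %d -> %d\n", x$n_duplications_input,
              x$n_duplications_output))
  cat("  corrected: ", write_newick(x$tree), "\n")
  invisible(x)
}
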