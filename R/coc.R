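# Clade Orthology Correction: given clades of the gene tree that should be
# rooted by speciation nodes (e.g. dubious duplications), rearrange the tree
# minimally under the rooted Robinson-Foulds distance so they are.
#
# Feasibility is decidable up front: a solution exists iff no constrained
# clade maps to a leaf species and no two overlapping constrained clades map
# to the same species.  All optima are the binary resolutions of the tree
# obtained by "pushing" each constrained duplication by multifurcation;
# pushing by tree duplication instead picks, among those optima, the one
# that shares the most rooted triplets with the input.

# Normalise clade constraints to a list of sorted character vectors.
#' @noRd
as_clades <- function(C) {
  if (is.null(C) || length(C) == 0L) return(list())
  if (is.character(C)) C <- list(C)
  stopifnot(is.list(C))
  lapply(C, function(x) lsort(as.character(x)))
}

# Resolve clade constraints to nodes of the gene tree; error when a leaf set
# is not exactly a clade.
#' @noRd
resolve_clade_keys <- function(recon, C) {
  C <- as_clades(C)
  keys <- vapply(C, paste, character(1), collapse = ",")
  present <- clade_keys(recon$tree)
  bad <- setdiff(keys, present)
  if (length(bad) > 0L) {
    stop("constraint leaf sets are not clades of the gene tree: {",
         paste(bad, collapse = "} {"), "}")
  }
  lv <- tree_leaves(recon$tree)
  unknown <- setdiff(unique(unlist(C)), lv)
  if (length(unknown) > 0L) {
    stop("constraint genes not in the gene tree: ",
         paste(unknown, collapse = ", "))
  }
  unique(keys)
}

#' Feasibility of a clade-constraint set
#'
#' A correction making every constrained clade a speciation exists iff every
#' constrained clade maps to an internal species (two genes of one species
#' can only descend from a duplication) and no two overlapping constrained
#' clades map to the same species (the outer one would again be forced to be
#' a duplication).
#'
#' @param recon a `recon` object.
#' @param C clade constraints: a list of leaf-label vectors, each exactly a
#'   clade of the gene tree.
#' @return a list with `feasible` (logical) and `violations`, a data.frame
#'   naming the offending clades and the condition violated.
#' @export
coc_feasible <- function(recon, C) {
  keys <- resolve_clade_keys(recon, C)
  v <- list()
  for (k in keys) {
    sk <- recon$species[[k]]
    if (length(key_leaves(sk)) == 1L) {
      v[[length(v) + 1L]] <- data.frame(
        type = "leaf_species", clade1 = k, clade2 = NA_character_,
        detail = paste0("maps to leaf species ", sk), stringsAsFactors = FALSE)
    }
  }
  if (length(keys) >= 2L) {
    for (i in seq_len(length(keys) - 1L)) for (j in (i + 1L):length(keys)) {
      li <- key_leaves(keys[i]); lj <- key_leaves(keys[j])
      disjoint <- length(intersect(li, lj)) == 0L
      if (!disjoint && recon$species[[keys[i]]] == recon$species[[keys[j]]]) {
        v[[length(v) + 1L]] <- data.frame(
          type = "nested_same_species", clade1 = keys[i], clade2 = keys[j],
          detail = paste0("overlapping clades share species ",
                          recon$species[[keys[i]]]), stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(0), clade1 = character(0),
               clade2 = character(0), detail = character(0))
  list(feasible = nrow(violations) == 0L, violations = violations)
}

# Common preconditions of the two push operations.  Returns the duplication
# node and the clade keys of the two children of its species in S.
#' @noRd
push_preconditions <- function(recon, x) {
  if (is.character(x) && length(x) == 1L && !grepl(",", x, fixed = TRUE)) {
    x <- key_leaves(x)
  }
  if (inherits(x, "rtree")) x <- tree_leaves(x)
  if (is.character(x) && length(x) == 1L) x <- key_leaves(x)
  key <- clade_key(x)
  node <- subtree_at(recon$tree, x)
  ev <- recon$event[[key]]
  if (!identical(ev, "duplication")) {
    stop("node {", key, "} is not a duplication (event: ", ev, ")")
  }
  sk <- recon$species[[key]]
  ab <- recon$sidx$children_keys[[sk]]
  if (length(ab) == 0L) {
    stop("node {", key, "} maps to a leaf species; it cannot be pushed")
  }
  list(node = node, key = key, A = ab[[1L]], B = ab[[2L]])
}

#' Push a duplication node by multifurcation
#'
#' Replaces the clade of duplication node `x` (species s with children A and
#' B in the species tree) by a root joining two multifurcations: one over
#' the maximal subtrees of `x` whose leaves all map below A, one over those
#' mapping below B.  Every clade of the tree outside `x`'s same-species
#' spine is preserved; the binary resolutions of the result are exactly the
#' optimal corrections for `x`.
#'
#' @param recon a `recon` object.
#' @param x the duplication node: an `rtree`, a leaf-label vector, or a
#'   clade key.
#' @return an `rtree`, in general multifurcating (the reconciliation
#'   annotations do not carry over; re-run [reconcile()]).
#' @export
push_multifurcation <- function(recon, x) {
  pc <- push_preconditions(recon, x)
  side <- function(side_key) {
    members <- list()
    dig <- function(node) {
      sp <- unique(unname(recon$map[tree_leaves(node)]))
      if (all(sp %in% key_leaves(side_key))) {
        members[[length(members) + 1L]] <<- node
      } else {
        for (ch in node$children) dig(ch)
      }
    }
    dig(pc$node)
    members <- members[order(vapply(members, min_leaf, character(1)),
                             method = "radix")]
    if (length(members) == 0L) {
      stop("internal error: empty side when pushing {", pc$key, "}")
    }
    if (length(members) == 1L) members[[1L]] else rt_node(members)
  }
  new_sub <- rt_node(list(side(pc$A), side(pc$B)))
  strip_internal_labels(replace_clade(recon$tree, key_leaves(pc$key), new_sub))
}

# The tree obtained by pushing every constrained clade (still a duplication
# when reached) by multifurcation, re-reconciling between pushes.  Its binary
# resolutions are exactly the optimal corrections; used by the verification
# suites.
#' @noRd
multifurcation_pushed <- function(recon, C) {
  keys <- lsort(resolve_clade_keys(recon, C))
  cur_tree <- recon$tree
  for (k in keys) {
    r <- reconcile(cur_tree, recon$stree, recon$map)
    if (identical(r$event[[k]], "duplication")) {
      cur_tree <- push_multifurcation(r, k)
    }
  }
  cur_tree
}

# product of odd numbers 1*3*...*(2k-3): rooted binary topologies on k leaves
#' @noRd
dfact_topologies <- function(k) {
  if (k <= 2L) return(1)
  prod(seq(3L, 2L * k - 3L, by = 2L))
}

#' All binary resolutions of a (multifurcating) rooted tree
#'
#' Yields every binary tree containing all clades of the input, i.e. every
#' way of resolving each multifurcation independently.  A binary input
#' yields exactly itself.
#'
#' @param tree an `rtree`.
#' @param limit maximum number of resolutions to materialise; exceeding it
#'   is an error (this is an exhaustive-verification device, not a sampler).
#' @return a list of binary `rtree` objects, deterministic order.
#' @export
binary_resolutions <- function(tree, limit = 1e6) {
  count <- function(node) {
    if (is_leaf(node)) return(1)
    dfact_topologies(length(node$children)) *
      prod(vapply(node$children, count, numeric(1)))
  }
  n_total <- count(tree)
  if (n_total > limit) {
    stop("the tree has ", format(n_total, big.mark = ","),
         " binary resolutions, more than limit = ", limit)
  }
  rec <- function(node) {
    if (is_leaf(node)) return(list(node))
    kid_res <- lapply(node$children, rec)
    d <- length(kid_res)
    combos <- expand.grid(lapply(kid_res, seq_along), KEEP.OUT.ATTRS = FALSE)
    shapes <- if (d == 2L) NULL else
      enumerate_rooted_binary_trees(as.character(seq_len(d)), cap = d)
    out <- list()
    for (ci in seq_len(nrow(combos))) {
      picked <- lapply(seq_len(d), function(j) kid_res[[j]][[combos[ci, j]]])
      if (d == 2L) {
        out[[length(out) + 1L]] <- rt_node(picked)
      } else {
        for (sh in shapes) {
          subst <- function(nd) {
            if (is_leaf(nd)) return(picked[[as.integer(nd$label)]])
            rt_node(lapply(nd$children, subst))
          }
          out[[length(out) + 1L]] <- subst(sh)
        }
      }
    }
    out
  }
  rec(tree)
}

#' Push a duplication node by tree duplication
#'
#' Replaces the clade of duplication node `x` by a speciation joining two
#' pruned copies of it: one keeping only the leaves mapping below species
#' child A, one keeping only those below B, each standardized.  Among all
#' Robinson-Foulds-optimal ways of making `x` a speciation, this one shares
#' the most rooted triplets with the input.
#'
#' @inheritParams push_multifurcation
#' @return a `recon` object (the result is re-reconciled; the new node at
#'   `x`'s position is a speciation).
#' @export
push_tree_duplication <- function(recon, x) {
  pc <- push_preconditions(recon, x)
  lv <- tree_leaves(pc$node)
  side <- function(side_key) {
    keep <- lv[recon$map[lv] %in% key_leaves(side_key)]
    if (length(keep) == 0L) {
      stop("internal error: empty side when pushing {", pc$key, "}")
    }
    standardize(pc$node, extant = keep)
  }
  new_sub <- rt_node(list(side(pc$A), side(pc$B)))
  out <- strip_internal_labels(replace_clade(recon$tree, key_leaves(pc$key),
                                             new_sub))
  reconcile(out, recon$stree, recon$map)
}

#' Correct a gene tree for clade constraints
#'
#' In `strict` mode the constraint set must be feasible (see
#' [coc_feasible()]); each constrained clade whose root is still a
#' duplication is pushed by tree duplication, in an order that does not
#' affect the result.  The output is Robinson-Foulds-optimal and, among the
#' optima, shares the maximum number of rooted triplets with the input.  In
#' `force` mode infeasible sets are allowed: constraints are processed from
#' the highest node downwards, each pushed if still possible, and the
#' unsatisfied ones are reported; no optimality is claimed.
#'
#' @param recon a `recon` object with a binary gene tree.
#' @param C clade constraints: list of leaf-label vectors, each a clade of
#'   the gene tree.
#' @param mode `"strict"` (default) or `"force"`.
#' @param order optional permutation of `seq_along(C)` fixing the processing
#'   order in strict mode; exposed so order-independence can be exercised.
#' @return an `orthofix_correction` object; `$constraints` reports per clade
#'   a `status` (`"pushed"`, `"already_speciation"`, `"clade_lost"`,
#'   `"leaf_species"`) and final `satisfied` flag.
#' @export
correct_coc <- function(recon, C, mode = c("strict", "force"), order = NULL) {
  mode <- match.arg(mode)
  if (!is_binary_tree(recon$tree)) stop("the gene tree must be binary")
  keys <- resolve_clade_keys(recon, C)

  if (mode == "strict") {
    feas <- coc_feasible(recon, C)
    if (!feas$feasible) {
      stop(errorCondition(
        paste0("no correction satisfies the clade constraints; ",
               nrow(feas$violations), " violation(s), e.g. ",
               feas$violations$detail[1L],
               ". Use mode = \"force\" for the best-effort heuristic."),
        class = c("orthofix_infeasible", "error"),
        violations = feas$violations))
    }
    keys <- if (is.null(order)) lsort(keys) else {
      stopifnot(length(order) == length(keys), setequal(order, seq_along(keys)))
      keys[order]
    }
  } else {
    # heuristic: highest (tallest) constrained nodes first
    h <- vapply(keys, function(k)
      node_height(subtree_at(recon$tree, k)), integer(1))
    keys <- keys[order(-h, keys, method = "radix")]
  }

  cur <- recon
  status <- character(0)
  for (k in keys) {
    if (!(k %in% clade_keys(cur$tree))) { status[[k]] <- "clade_lost"; next }
    ev <- cur$event[[k]]
    if (identical(ev, "speciation")) {
      if (identical(recon$event[[k]], "speciation")) {
        warning("clade {", k, "} is already rooted by a speciation; skipped")
      }
      status[[k]] <- "already_speciation"
      next
    }
    if (length(key_leaves(cur$species[[k]])) == 1L) {
      # only reachable in force mode: strict mode rejected it up front
      status[[k]] <- "leaf_species"
      next
    }
    cur <- push_tree_duplication(cur, k)
    status[[k]] <- "pushed"
  }

  final_keys <- clade_keys(cur$tree)
  satisfied <- vapply(keys, function(k)
    k %in% final_keys && identical(cur$event[[k]], "speciation"), logical(1))
  if (mode == "strict" && !all(satisfied)) {
    stop("internal error: strict-mode correction left a constraint unsatisfied")
  }
  GP <- rt_canonical(strip_internal_labels(cur$tree))
  out_recon <- reconcile(GP, recon$stree, recon$map)
  lost <- setdiff(clade_keys(recon$tree), final_keys)
  structure(list(
    method = "coc",
    mode = mode,
    input = recon,
    tree = GP,
    recon = out_recon,
    rf = rf_distance(recon$tree, GP),
    pushed = names(status)[status == "pushed"],
    lost_clades = lsort(lost),
    constraints = data.frame(clade = names(status),
                             status = unname(status),
                             satisfied = unname(satisfied[names(status)]),
                             stringsAsFactors = FALSE),
    n_duplications_input = n_duplications(recon),
    n_duplications_output = n_duplications(out_recon)
  ), class = "orthofix_correction")
}
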