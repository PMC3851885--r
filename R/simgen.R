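# Seeded instance generators and the packaged worked-example fixtures.
#
# The duplication-loss model is deliberately discrete: a lineage entering a
# species-tree branch is lost with probability `loss_prob`, duplicates with
# probability `dup_prob` (both daughters re-entering the same branch), and
# otherwise reaches the species node, where it either becomes an extant gene
# (leaf species) or speciates into both child branches.  This produces
# exactly the discrete structures the corrections consume -- reconciled
# topologies with known true duplication nodes -- without modelling branch
# lengths, which the corrections ignore anyway.

#' Simulate a random rooted binary species tree
#'
#' Sequential random attachment: starting from a two-species cherry, each
#' further species is attached on an edge (or above the root) chosen
#' uniformly at random.  Species are labelled A, B, C, ... (then S27, S28,
#' ... beyond 26).
#'
#' @param n_species number of species (at least 2).
#' @param seed integer seed; the generator is a pure function of
#'   `(n_species, seed)`.
#' @return a binary `rtree`.
#' @export
simulate_species_tree <- function(n_species, seed) {
  stopifnot(n_species >= 2L)
  labels <- if (n_species <= 26L) LETTERS[seq_len(n_species)] else
    c(LETTERS, paste0("S", 27:n_species))[seq_len(n_species)]
  withr::with_seed(as.integer(seed), {
    tree <- rt_node(list(rt_leaf(labels[1L]), rt_leaf(labels[2L])))
    if (n_species > 2L) for (i in 3L:n_species) {
      positions <- count_nodes(tree)          # one insertion point per node
      at <- sample.int(positions, 1L)
      tree <- insert_leaf_at(tree, labels[i], at)
    }
    rt_canonical(tree)
  })
}

#' @noRd
count_nodes <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + sum(vapply(tree$children, count_nodes, integer(1)))
}

# insert `lf` above the `at`-th node in preorder (1 = root, i.e. new root)
#' @noRd
insert_leaf_at <- function(tree, lf, at) {
  counter <- 0L
  rec <- function(node) {
    counter <<- counter + 1L
    if (counter == at) return(rt_node(list(node, rt_leaf(lf))))
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, rec)
    node
  }
  rec(tree)
}

#' Simulate a gene tree along a species tree under duplication and loss
#'
#' See the model description above.  Surviving genes are named by the
#' lower-cased species label plus an index (`a1`, `a2`, ...).  Simulation
#' retries (up to `max_retries`) until at least two genes survive.
#'
#' @param S binary species tree.
#' @param dup_prob,loss_prob per-branch duplication / loss probabilities in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param max_retries attempts before giving up on extinction.
#' @param max_leaves families larger than this are redrawn (the birth
#'   process has heavy upper tails at high duplication rates); counts as a
#'   retry.
#' @return a list: `recon` (the reconciled simulated tree), `true_dups`
#'   (clade keys of the surviving true duplication nodes), `map`, and the
#'   trees `gene` and `species`.
#' @export
simulate_gene_tree <- function(S, dup_prob, loss_prob, seed,
                               max_retries = 100L, max_leaves = Inf) {
  stopifnot(dup_prob >= 0, dup_prob < 1, loss_prob >= 0, loss_prob < 1)
  counts <- new.env(parent = emptyenv())
  gene_name <- function(sp) {
    n <- (if (is.null(counts[[sp]])) 0L else counts[[sp]]) + 1L
    counts[[sp]] <- n
    paste0(tolower(sp), n)
  }
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_retries)) {
      rm(list = ls(counts), envir = counts)
      evolve <- function(sp_node) {
        if (stats::runif(1) < loss_prob) return(NULL)
        if (stats::runif(1) < dup_prob) {
          kids <- Filter(Negate(is.null),
                         list(evolve(sp_node), evolve(sp_node)))
          if (length(kids) == 0L) return(NULL)
          if (length(kids) == 1L) return(kids[[1L]])
          nd <- rt_node(kids)
          nd$true_dup <- TRUE
          return(nd)
        }
        if (is_leaf(sp_node)) return(rt_leaf(gene_name(sp_node$label)))
        kids <- Filter(Negate(is.null), lapply(sp_node$children, evolve))
        if (length(kids) == 0L) return(NULL)
        if (length(kids) == 1L) return(kids[[1L]])
        rt_node(kids)
      }
      G <- evolve(S)
      if (!is.null(G) && n_leaves(G) > max_leaves) next
      if (!is.null(G) && n_leaves(G) >= 2L) {
        true_dups <- character(0)
        mark <- function(node) {
          if (isTRUE(node$true_dup)) {
            true_dups <<- c(true_dups, clade_key(tree_leaves(node)))
          }
          for (ch in node$children) mark(ch)
        }
        mark(G)
        G <- rt_canonical(G)
        lv <- tree_leaves(G)
        map <- stats::setNames(toupper(sub("[0-9]+$", "", lv)), lv)
        return(list(recon = reconcile(G, S, map), gene = G, species = S,
                    map = map, true_dups = lsort(true_dups)))
      }
    }
    stop("gene family went extinct in all ", max_retries, " attempts")
  })
}

#' Sample a pair-constraint instance from a simulated gene tree
#'
#' Draws `k_pairs` cross-species leaf pairs, preferring pairs whose lca is a
#' duplication (false paralogs), so instances usually have a non-trivial
#' forbidden set.
#'
#' @param sim result of [simulate_gene_tree()].
#' @param k_pairs number of pairs to draw.
#' @param seed integer seed.
#' @return a list `(recon, P)`; error if fewer than `k_pairs` cross-species
#'   pairs exist.
#' @export
make_goc_instance <- function(sim, k_pairs, seed) {
  recon <- sim$recon
  lv <- lsort(tree_leaves(recon$tree))
  prs <- utils::combn(lv, 2L)
  cross <- recon$map[prs[1L, ]] != recon$map[prs[2L, ]]
  prs <- prs[, cross, drop = FALSE]
  if (ncol(prs) < k_pairs) {
    stop("only ", ncol(prs), " cross-species pairs available, need ", k_pairs)
  }
  if (k_pairs == 0L) {
    return(list(recon = recon,
                P = matrix(character(0), ncol = 2L,
                           dimnames = list(NULL, c("g1", "g2")))))
  }
  dup <- vapply(seq_len(ncol(prs)), function(i)
    identical(lca_event(recon, prs[, i]), "duplication"), logical(1))
  withr::with_seed(as.integer(seed), {
    take_dup <- min(sum(dup), k_pairs)
    di <- which(dup); oi <- which(!dup)
    idx <- c(di[sample.int(length(di), take_dup)],
             if (take_dup < k_pairs)
               oi[sample.int(length(oi), k_pairs - take_dup)])
  })
  P <- t(prs[, idx, drop = FALSE])
  colnames(P) <- c("g1", "g2")
  list(recon = recon, P = as_pairs(P))
}

#' Sample a clade-constraint instance from a simulated gene tree
#'
#' Draws `k_clades` duplication-node clades.  With `feasible_only = TRUE`
#' (default) candidate sets are rejection-sampled until they pass the
#' feasibility conditions (internal species; pairwise disjoint or
#' different-species); otherwise an arbitrary duplication-clade set is
#' returned, which may be infeasible.
#'
#' @param sim result of [simulate_gene_tree()].
#' @param k_clades number of clades to draw.
#' @param seed integer seed.
#' @param feasible_only reject infeasible candidate sets.
#' @param max_tries rejection-sampling budget.
#' @return a list `(recon, C)`, or `NULL` if no admissible set was found.
#' @export
make_coc_instance <- function(sim, k_clades, seed, feasible_only = TRUE,
                              max_tries = 200L) {
  recon <- sim$recon
  dup_keys <- lsort(names(recon$event)[recon$event == "duplication"])
  if (k_clades == 0L) return(list(recon = recon, C = list()))
  if (length(dup_keys) < k_clades) return(NULL)
  if (!feasible_only) {
    return(withr::with_seed(as.integer(seed), {
      list(recon = recon, C = lapply(sample(dup_keys, k_clades), key_leaves))
    }))
  }
  # feasible sampling: only internal-species duplications qualify at all, and
  # any two picked clades must be disjoint or differ in species
  cand <- dup_keys[vapply(dup_keys, function(k)
    length(key_leaves(recon$species[[k]])) > 1L, logical(1))]
  if (length(cand) < k_clades) return(NULL)
  compatible <- function(k1, k2) {
    length(intersect(key_leaves(k1), key_leaves(k2))) == 0L ||
      recon$species[[k1]] != recon$species[[k2]]
  }
  withr::with_seed(as.integer(seed), {
    if (k_clades == 1L) {
      return(list(recon = recon, C = list(key_leaves(sample(cand, 1L)))))
    }
    if (k_clades == 2L) {
      prs <- utils::combn(cand, 2L)
      ok <- vapply(seq_len(ncol(prs)), function(i)
        compatible(prs[1L, i], prs[2L, i]), logical(1))
      if (!any(ok)) return(NULL)
      idx <- which(ok)
      pick <- prs[, idx[sample.int(length(idx), 1L)]]
      return(list(recon = recon, C = lapply(pick, key_leaves)))
    }
    for (i in seq_len(max_tries)) {
      ks <- sample(cand, k_clades)
      C <- lapply(ks, key_leaves)
      if (coc_feasible(recon, C)$feasible) return(list(recon = recon, C = C))
    }
    NULL
  })
}

#' Load a packaged worked-example fixture
#'
#' Small worked-example instances used throughout the documentation and
#' tests, shipped as plain Newick/TSV under `extdata`.  Each
#' bundle contains the species tree, gene tree, gene-species map and the
#' constraint set, plus the expected corrected tree where one is defined.
#' `"fig3_X"` is the maximum-orthology instance: the highest preservable
#' descendants of the root of the `"fig2"` tree, with the expected assembled
#' tree.  The `"fig5"` fish (ZNF800-like) instance is a synthetic
#' reconstruction of a real correction scenario: a minimal topology
#' exhibiting the documented constraint set, the non-apparent duplication
#' placement, and a correction that removes one duplication.
#'
#' @param name one of `"fig1"`, `"fig2"`, `"fig3_X"`, `"fig4"`, `"fig5"`.
#' @return a list; common fields: `stree`, `gene`, `map`, `recon`, and per
#'   instance `P` / `C` / `X` and `expected_*` trees.
#' @export
load_fixture <- function(name = c("fig1", "fig2", "fig3_X", "fig4", "fig5")) {
  name <- match.arg(name)
  dir_name <- if (name == "fig3_X") "fig2" else name
  path <- function(f) system.file("extdata", dir_name, f, package = "orthofix",
                                  mustWork = TRUE)
  stree <- parse_newick(readLines(path("species.nwk"))[1L])
  gene <- parse_newick(readLines(path("gene.nwk"))[1L], check_binary = TRUE)
  map <- read_gene_species_map(path("map.tsv"))
  recon <- reconcile(gene, stree, map)
  out <- list(name = name, stree = stree, gene = gene, map = map,
              recon = recon)
  exp_tree <- function(f) parse_newick(readLines(path(f))[1L])
  switch(name,
    fig1 = {
      out$P <- read_orthology_pairs(path("pairs.tsv"))
      out$C <- read_clade_constraints(path("clades.txt"))
      out$expected_goc <- exp_tree("expected_goc.nwk")
      out$expected_coc <- exp_tree("expected_coc.nwk")
      out$orders <- read_gene_orders(path("orders.tsv"))
      fams <- c("family_left.nwk", "family_right.nwk")
      out$companions <- lapply(fams, function(f) {
        g <- parse_newick(readLines(path(f))[1L], check_binary = TRUE)
        m <- read_gene_species_map(path("map_companions.tsv"))
        reconcile(g, stree, m)
      })
    },
    fig2 = {
      out$P <- read_orthology_pairs(path("pairs.tsv"))
      out$expected_goc <- exp_tree("expected_goc.nwk")
      out$expected_H_labels <- c("e1", "e2", "d1")
    },
    fig3_X = {
      P <- read_orthology_pairs(path("pairs.tsv"))
      H <- forbidden_nodes(recon, false_paralogs(recon, P))
      out$P <- P
      out$X <- highest_preservable_descendants(recon, H)
      out$expected_F <- exp_tree("expected_fig3_F.nwk")
    },
    fig4 = {
      out$C <- read_clade_constraints(path("clades.txt"))
      out$expected_coc <- exp_tree("expected_coc.nwk")
    },
    fig5 = {
      out$P <- read_orthology_pairs(path("pairs.tsv"))
      out$expected_goc <- exp_tree("expected_goc.nwk")
      out$expected_nad <- lsort(c("m1", "t1", "s1"))
    })
  out
}

# ---- internal batches used by the verification suites -------------------

# Collect n pair-constraint instances with leaf counts in [min_l, max_l].
# Pure function of the arguments; sub-seeds stay far below 2^31.
#' @noRd
collect_goc_instances <- function(n, min_l, max_l, dup = 0.2, loss = 0.1,
                                  k_pairs = 2L, n_species = 5L, seed = 1L) {
  out <- vector("list", 0L)
  s <- as.integer(seed) * 1000L
  attempt <- 0L
  while (length(out) < n && attempt < n * 200L) {
    attempt <- attempt + 1L
    s <- s + 1L
    sim <- tryCatch(
      simulate_gene_tree(simulate_species_tree(n_species, s), dup, loss, s,
                         max_leaves = max_l),
      error = function(e) NULL)
    if (is.null(sim)) next
    nl <- n_leaves(sim$gene)
    if (nl < min_l || nl > max_l) next
    inst <- tryCatch(make_goc_instance(sim, min(k_pairs, nl - 1L), s + 1L),
                     error = function(e) NULL)
    if (is.null(inst)) next
    out[[length(out) + 1L]] <- inst
  }
  if (length(out) < n) stop("could not collect ", n, " instances")
  out
}

#' @noRd
collect_coc_instances <- function(n, min_l, max_l, dup = 0.3, loss = 0.1,
                                  k_clades = 1L, n_species = 4L, seed = 1L,
                                  feasible_only = TRUE) {
  out <- vector("list", 0L)
  s <- as.integer(seed) * 1000L
  attempt <- 0L
  while (length(out) < n && attempt < n * 500L) {
    attempt <- attempt + 1L
    s <- s + 1L
    sim <- tryCatch(
      simulate_gene_tree(simulate_species_tree(n_species, s), dup, loss, s,
                         max_leaves = max_l),
      error = function(e) NULL)
    if (is.null(sim)) next
    nl <- n_leaves(sim$gene)
    if (nl < min_l || nl > max_l) next
    inst <- make_coc_instance(sim, k_clades, s + 1L,
                              feasible_only = feasible_only)
    if (is.null(inst)) next
    out[[length(out) + 1L]] <- inst
  }
  if (length(out) < n) stop("could not collect ", n, " instances")
  out
}
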