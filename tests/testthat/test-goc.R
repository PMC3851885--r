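# Pair-orthology correction: false paralogs, movable apexes, forbidden
# nodes, the maximum orthology tree, and the full correction.

lab_of <- function(tree) {
  nt <- node_table(tree)
  stats::setNames(nt$label, nt$key)
}

test_that("false_paralogs keeps exactly the duplication-lca pairs", {
  fx <- load_fixture("fig1")
  expect_equal(nrow(false_paralogs(fx$recon, fx$P)), 1L)

  fx2 <- load_fixture("fig2")
  pf <- false_paralogs(fx2$recon, fx2$P)
  # (a1,b2) and (a1,c2) contradict the tree; (a1,c1) already joins at a
  # speciation, so it stays in P but not in the false-paralog set
  expect_setequal(paste(pf[, 1], pf[, 2]), c("a1 b2", "a1 c2"))

  ortho <- matrix(c("a2", "b2"), ncol = 2) # already orthologous in fig1
  expect_equal(nrow(false_paralogs(fx$recon, ortho)), 0L)
  # same-species pairs are invalid constraints
  expect_error(false_paralogs(fx$recon, matrix(c("a1", "a2"), ncol = 2)),
               "same species")
})

test_that("movable apexes match the worked example and a path-scan oracle", {
  fx <- load_fixture("fig2")
  expect_identical(movable_apex(fx$recon, "a1", "c2")$label, "d2")
  expect_identical(movable_apex(fx$recon, "c2", "a1")$label, "c2")

  # when a's parent is already the pair's lca, the apex is a itself
  r <- toy_recon("((a1,b1),c1);", "((A,B),C);")
  expect_identical(tree_leaves(movable_apex(r, "a1", "b1")), "a1")

  # independent oracle: scan upward from a, stop before the first node whose
  # species is not a strict descendant of lca_S(s(a), s(b))
  scan_oracle <- function(recon, a, b) {
    path <- rev(orthofix:::path_to_leaf(recon$tree, a)) # leaf first
    sab <- orthofix:::species_lca_key(recon$sidx,
                                      c(recon$map[[a]], recon$map[[b]]))
    best <- path[[1L]]
    for (nd in path[-1L]) {
      k <- clade_key(tree_leaves(nd))
      if (!orthofix:::s_descends(recon$species[[k]], sab, strict = TRUE)) break
      best <- nd
    }
    clade_key(tree_leaves(best))
  }
  insts <- goc_batch(20, 4, 12, seed = 21, n_species = 5, k_pairs = 2)
  for (inst in insts) {
    P <- inst$P
    for (i in seq_len(nrow(P))) for (ord in list(P[i, ], rev(P[i, ]))) {
      a <- ord[[1]]; b <- ord[[2]]
      expect_identical(
        clade_key(tree_leaves(movable_apex(inst$recon, a, b))),
        scan_oracle(inst$recon, a, b))
    }
  }
})

test_that("forbidden nodes reproduce the worked example and its geometry", {
  fx <- load_fixture("fig2")
  H <- forbidden_nodes(fx$recon, false_paralogs(fx$recon, fx$P))
  expect_setequal(unname(lab_of(fx$gene)[H]), c("e1", "e2", "d1"))
  expect_length(forbidden_nodes(fx$recon, NULL), 0L)

  # the root and all leaves are always preservable
  for (inst in goc_batch(10, 4, 12, seed = 31)) {
    H <- forbidden_nodes(inst$recon, inst$P)
    ks <- clade_keys(inst$recon$tree)
    lv <- tree_leaves(inst$recon$tree)
    expect_false(clade_key(lv) %in% H)
    expect_length(intersect(lv, H), 0L)
  }
})

test_that("highest preservable descendants partition the leaves", {
  fx <- load_fixture("fig2")
  H <- forbidden_nodes(fx$recon, fx$P)
  X <- highest_preservable_descendants(fx$recon, H)
  # worked example: subtrees rooted at d2, c1, b3 and c2
  expect_setequal(vapply(X, function(x) clade_key(tree_leaves(x)),
                         character(1)),
                  c("a1,b1,b2", "c1", "b3", "c2"))
  expect_setequal(unlist(lapply(X, tree_leaves)), tree_leaves(fx$gene))

  # with nothing forbidden, a node's expansion is its two children
  r <- toy_recon("((a1,b1),c1);", "((A,B),C);")
  X <- highest_preservable_descendants(r, character(0))
  expect_equal(lengths(lapply(X, tree_leaves)), c(2L, 1L))
})

test_that("max orthology tree joins unrelated-species subtrees at speciations", {
  fx <- load_fixture("fig3_X")
  F <- max_orthology_tree(fx$stree, fx$X, fx$map)
  expect_true(trees_equal(F, fx$expected_F))
  # every input subtree appears unchanged
  for (x in fx$X) {
    expect_true(all(clade_keys(x) %in% clade_keys(F)))
  }

  single <- list(fx$X[[1]])
  expect_identical(canon(max_orthology_tree(fx$stree, single, fx$map)),
                   canon(fx$X[[1]]))
  expect_error(max_orthology_tree(fx$stree, list(), fx$map), "at least one")

  # random small X: unrelated-species pairs always end up orthologous
  for (i in 1:10) {
    sim <- simulate_gene_tree(simulate_species_tree(5, 40L + i), 0.3, 0.1,
                              seed = 40L + i)
    recon <- sim$recon
    X <- lapply(tree_leaves(recon$tree), rt_leaf)  # leaves as subtrees
    F <- max_orthology_tree(recon$stree, X, recon$map)
    rf <- reconcile(F, recon$stree, recon$map)
    lv <- tree_leaves(F)
    prs <- combn(lv, 2L)
    for (j in seq_len(ncol(prs))) {
      s1 <- recon$map[[prs[1, j]]]; s2 <- recon$map[[prs[2, j]]]
      if (s1 != s2) expect_true(is_orthologous(rf, prs[1, j], prs[2, j]))
    }
  }
})

test_that("correct_goc reproduces both worked examples", {
  fx1 <- load_fixture("fig1")
  res1 <- correct_goc(fx1$recon, fx1$P)
  expect_true(trees_equal(res1$tree, fx1$expected_goc))
  expect_identical(res1$rf, 2L)

  fx2 <- load_fixture("fig2")
  res2 <- correct_goc(fx2$recon, fx2$P)
  expect_true(trees_equal(res2$tree, fx2$expected_goc))
  expect_identical(res2$rf, 6L)
  expect_identical(res2$n_forbidden, 3L)
  # "preserves every possible clade": everything outside H survives
  pres <- setdiff(clade_keys(fx2$gene), res2$forbidden)
  expect_true(all(pres %in% clade_keys(res2$tree)))
})

test_that("an empty constraint set leaves the tree untouched", {
  fx <- load_fixture("fig1")
  res <- correct_goc(fx$recon, NULL)
  expect_identical(res$rf, 0L)
  expect_true(trees_equal(res$tree, fx$gene))
})

test_that("the fish example correction removes the dubious duplication", {
  fx <- load_fixture("fig5")
  res <- correct_goc(fx$recon, fx$P)
  expect_true(trees_equal(res$tree, fx$expected_goc))
  expect_true(all(res$constraints$satisfied))
  expect_identical(res$n_duplications_output, res$n_duplications_input - 1L)
  expect_length(flag_non_apparent_duplications(res$recon), 0L)
})

test_that("correction restricted to a preservable subtree equals the full run", {
  for (inst in goc_batch(10, 6, 14, seed = 51, k_pairs = 3)) {
    res <- correct_goc(inst$recon, inst$P)
    H <- res$forbidden
    # pick a preservable internal node and the constraints inside it
    ks <- clade_keys(inst$recon$tree)
    cand <- setdiff(ks[nchar(ks) > 8], c(H, clade_key(tree_leaves(inst$recon$tree))))
    for (k in cand) {
      sub <- subtree_at(inst$recon$tree, k)
      inside <- apply(inst$P, 1L, function(p) all(p %in% tree_leaves(sub)))
      sub_rec <- reconcile(sub, inst$recon$stree, inst$recon$map)
      sub_res <- correct_goc(sub_rec, inst$P[inside, , drop = FALSE])
      expect_true(all(clade_keys(sub_res$tree) %in% clade_keys(res$tree)))
    }
  }
})

test_that("identical inputs give byte-identical corrected Newick", {
  fx <- load_fixture("fig2")
  s1 <- write_newick(correct_goc(fx$recon, fx$P)$tree)
  s2 <- write_newick(correct_goc(load_fixture("fig2")$recon, fx$P)$tree)
  expect_identical(s1, s2)
})
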