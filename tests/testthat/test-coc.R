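# Clade-orthology correction: feasibility, the two push operations, binary
# resolutions, and the full correction.

test_that("coc_feasible implements both existence conditions", {
  # two same-species genes: the constrained clade maps to a leaf species
  r <- toy_recon("((a1,a2),b1);", "(A,B);")
  f <- coc_feasible(r, list(c("a1", "a2")))
  expect_false(f$feasible)
  expect_identical(f$violations$type, "leaf_species")

  # nested clades with the same species assignment
  r2 <- toy_recon("(((a1,b1),(a2,b2)),c1);", "((A,B),C);")
  f2 <- coc_feasible(r2, list(c("a1", "a2", "b1", "b2"), c("a1", "b1")))
  expect_false(f2$feasible)
  expect_identical(f2$violations$type, "nested_same_species")

  expect_true(coc_feasible(r2, list())$feasible)
  expect_true(coc_feasible(r2, list(c("a1", "a2", "b1", "b2")))$feasible)

  # a leaf set that is not a clade cannot be resolved
  expect_error(coc_feasible(r2, list(c("a1", "b2"))), "not clades")
})

test_that("pushing by multifurcation splits a duplication into pure sides", {
  # each side a single maximal subtree: the output stays binary, the sides
  # are exactly those subtrees
  r <- toy_recon("((((a1,a2),b1),b2),c1);", "((A,B),C);")
  out <- push_multifurcation(r, c("a1", "a2", "b1", "b2"))
  expect_true(is_binary_tree(out))
  expect_true(all(c("a1,a2", "b1,b2") %in% clade_keys(out)))

  # the two-pair example: sides are the two-leaf species groups
  fx <- load_fixture("fig1")
  out <- push_multifurcation(fx$recon, fx$C[[1]])
  expect_true(all(c("a1,a2", "b1,b2") %in% clade_keys(out)))
  expect_true(setequal(
    clade_keys(out)[!clade_keys(out) %in% clade_keys(fx$gene)],
    c("a1,a2", "b1,b2")))

  # pushing is only defined for duplications with an internal species
  expect_error(push_multifurcation(fx$recon, c("a2", "b2")),
               "not a duplication")
  r2 <- toy_recon("((a1,a2),b1);", "(A,B);")
  expect_error(push_multifurcation(r2, c("a1", "a2")), "leaf species")
})

test_that("pushing distinct feasible clades commutes", {
  insts <- coc_batch(8, 5, 10, seed = 61, k_clades = 2L, dup = 0.4,
                     n_species = 5)
  for (inst in insts) {
    keys <- vapply(inst$C, clade_key, character(1))
    push_in_order <- function(ord) {
      cur <- inst$recon$tree
      for (k in keys[ord]) {
        r <- reconcile(cur, inst$recon$stree, inst$recon$map)
        if (identical(r$event[[k]], "duplication")) {
          cur <- push_multifurcation(r, k)
        }
      }
      canon(cur)
    }
    expect_identical(push_in_order(1:2), push_in_order(2:1))
  }
})

test_that("binary_resolutions yields every resolution exactly once", {
  t <- nwk("((a,b),c);")
  res <- binary_resolutions(t)
  expect_length(res, 1L)
  expect_true(trees_equal(res[[1]], t))

  tri <- rt_node(list(rt_leaf("a"), rt_leaf("b"), rt_leaf("c")))
  res3 <- binary_resolutions(tri)
  expect_length(res3, 3L)
  expect_length(unique(vapply(res3, canon, character(1))), 3L)

  # every resolution contains every clade of the multifurcating input
  multi <- rt_node(list(rt_node(list(rt_leaf("a"), rt_leaf("b"),
                                     rt_leaf("c"))), rt_leaf("d")))
  for (b in binary_resolutions(multi)) {
    expect_true(all(clade_keys(multi) %in% clade_keys(b)))
    expect_true(is_binary_tree(b))
  }
  # a 4-fan has 15 resolutions; a limit below that must error, not truncate
  fan <- rt_node(lapply(letters[1:4], rt_leaf))
  expect_length(binary_resolutions(fan), 15L)
  expect_error(binary_resolutions(fan, limit = 10), "more than limit")
})

test_that("pushing by tree duplication reproduces the worked example", {
  fx <- load_fixture("fig4")
  out <- push_tree_duplication(fx$recon, fx$C[[1]])
  # G^A keeps a1,a2 (b1,b2 removed), G^B keeps b1,b2; joined under the root
  expect_true(trees_equal(out$tree, fx$expected_coc))
  expect_identical(out$event[["a1,a2,b1,b2"]], "speciation")

  # same-species cherry: precondition fails
  r <- toy_recon("((a1,a2),b1);", "(A,B);")
  expect_error(push_tree_duplication(r, c("a1", "a2")), "leaf species")

  # the result is one of the binary resolutions of the multifurcation push
  insts <- coc_batch(10, 4, 8, seed = 71, dup = 0.4)
  for (inst in insts) {
    k <- clade_key(inst$C[[1]])
    if (!identical(inst$recon$event[[k]], "duplication")) next
    td <- push_tree_duplication(inst$recon, k)
    mf <- push_multifurcation(inst$recon, k)
    expect_true(canon(td$tree) %in%
                  vapply(binary_resolutions(mf), canon, character(1)))
  }
})

test_that("correct_coc satisfies constraints and matches the worked example", {
  fx <- load_fixture("fig1")
  res <- correct_coc(fx$recon, fx$C)
  expect_true(trees_equal(res$tree, fx$expected_coc))
  expect_identical(res$rf, 4L)
  expect_true(all(res$constraints$satisfied))
  expect_identical(res$recon$event[["a1,a2,b1,b2"]], "speciation")

  empty <- correct_coc(fx$recon, list())
  expect_identical(empty$rf, 0L)
  expect_true(trees_equal(empty$tree, fx$gene))

  # already-speciation constraint: warning and no-op
  expect_warning(res2 <- correct_coc(fx$recon, list(c("a2", "b2"))),
                 "already")
  expect_identical(res2$rf, 0L)
})

test_that("strict mode on an infeasible set raises a condition with the violations", {
  r <- toy_recon("((a1,a2),b1);", "(A,B);")
  err <- tryCatch(correct_coc(r, list(c("a1", "a2"))), condition = identity)
  expect_s3_class(err, "orthofix_infeasible")
  expect_identical(err$violations$type, "leaf_species")
})

test_that("strict-mode output is independent of the push order", {
  insts <- coc_batch(8, 5, 10, seed = 81, k_clades = 2L, dup = 0.4,
                     n_species = 5)
  for (inst in insts) {
    a <- canon(correct_coc(inst$recon, inst$C, order = 1:2)$tree)
    b <- canon(correct_coc(inst$recon, inst$C, order = 2:1)$tree)
    expect_identical(a, b)
  }
})

test_that("force mode pushes what it can, highest first, and reports the rest", {
  # nested same-species clades are jointly unsatisfiable; the outer (higher)
  # one is pushed, the inner one disappears and is reported unsatisfied
  r <- toy_recon("(((a1,b1),(a2,b2)),c1);", "((A,B),C);")
  C <- list(c("a1", "a2", "b1", "b2"), c("a1", "b1"))
  res <- correct_coc(r, C, mode = "force")
  st <- stats::setNames(res$constraints$status, res$constraints$clade)
  expect_identical(unname(st["a1,a2,b1,b2"]), "pushed")
  expect_identical(unname(st["a1,b1"]), "clade_lost")
  expect_identical(sum(res$constraints$satisfied), 1L)
  expect_identical(res$recon$event[["a1,a2,b1,b2"]], "speciation")

  # a leaf-species clade can never be pushed
  r2 <- toy_recon("((a1,a2),b1);", "(A,B);")
  res2 <- correct_coc(r2, list(c("a1", "a2")), mode = "force")
  expect_identical(res2$constraints$status, "leaf_species")
  expect_false(any(res2$constraints$satisfied))
  expect_identical(res2$rf, 0L)
})
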