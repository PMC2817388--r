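# Logic regression: Boolean evaluation, coefficient fitting, the move set,
# the annealing search, and the text grammar.

worked_expr <- function()
  logic_or(logic_and(logic_leaf(1), logic_leaf(2)),
           logic_and(logic_leaf(3), logic_leaf(4, neg = TRUE)))

test_that("Boolean trees evaluate with complement at the leaves", {
  tr <- worked_expr()
  expect_equal(evaluate_tree(tr, rbind(c(1, 1, 0, 1))), 1L)  # first conjunct
  expect_equal(evaluate_tree(tr, rbind(c(0, 1, 1, 0))), 1L)  # second conjunct
  expect_equal(evaluate_tree(tr, rbind(c(0, 1, 0, 1))), 0L)
  expect_equal(evaluate_tree(NULL, rbind(c(1, 1))), 0L)      # constant-0 tree
  expect_equal(count_leaves(tr), 4L)
  expect_equal(tree_vars(tr), 1:4)
  expect_error(evaluate_tree(logic_leaf(9), rbind(c(1, 0))),
               class = "flowtrees_reference_error")
})

test_that("coefficients hit the logistic closed form and the GLM oracle", {
  set.seed(31)
  x <- matrix(rbinom(400, 1, .5), 200)
  y <- rbinom(200, 1, plogis(-1 + 1.5 * x[, 1]))
  f <- fit_coefficients(list(logic_leaf(1)), x, y)
  expect_equal(f$coefficients[1],
               log(odds_ratio(tabulate_2x2(x[, 1], y))), tolerance = 1e-8)
  # all-zero tree column is dropped; the model collapses to the intercept
  f0 <- fit_coefficients(list(logic_and(logic_leaf(1), logic_leaf(1, neg = TRUE))), x, y)
  expect_equal(f0$dropped, 1L)
  expect_equal(f0$intercept, qlogis(mean(y)), tolerance = 1e-8)
  expect_equal(f0$deviance, f0$null_deviance, tolerance = 1e-8)
  # identity link reproduces least squares
  trees <- list(logic_leaf(1), logic_and(logic_leaf(2), logic_leaf(1)))
  fi <- fit_coefficients(trees, x, y, link = "identity")
  L <- vapply(trees, evaluate_tree, integer(200), x = x)
  lmfit <- lm(y ~ L)
  expect_equal(fi$deviance, sum(residuals(lmfit)^2), tolerance = 1e-8)
  expect_equal(unname(fi$coefficients), unname(coef(lmfit)[-1]), tolerance = 1e-8)
})

test_that("moves respect the leaf budget and change at most one leaf", {
  set.seed(33)
  # deleting the only leaf yields the constant-0 tree
  res <- propose_move(list(logic_leaf(2)), "split_delete_leaf", p = 5, max_leaves = 1)
  while (!is.null(res$trees[[1]]) || !res$applied)
    res <- propose_move(list(logic_leaf(2)), "split_delete_leaf", p = 5, max_leaves = 1)
  expect_null(res$trees[[1]])
  # growth at the budget is rejected with a flag
  full <- list(worked_expr())
  res <- propose_move(full, "grow_branch", p = 5, max_leaves = 4)
  expect_false(res$applied)
  expect_identical(res$trees, full)
  # random move stream: leaf deltas in {-1, 0, 1}, budget never exceeded
  trees <- list(logic_leaf(1), logic_leaf(2))
  for (i in 1:400) {
    mv <- sample(c("alternate_leaf", "toggle_complement", "alternate_operator",
                   "grow_branch", "prune_branch", "split_delete_leaf"), 1)
    res <- propose_move(trees, mv, p = 6, max_leaves = 6)
    n_before <- sum(vapply(trees, count_leaves, 0L))
    n_after <- sum(vapply(res$trees, count_leaves, 0L))
    expect_lte(abs(n_after - n_before), 1L)
    expect_lte(n_after, 6L)
    trees <- res$trees
  }
})

test_that("truth-table equivalence captures commutativity and De Morgan", {
  expect_true(truth_table_equivalence(logic_and(logic_leaf(1), logic_leaf(2)),
                                      logic_and(logic_leaf(2), logic_leaf(1))))
  # complement of (X1 or X2) == not X1 and not X2
  expect_true(truth_table_equivalence(
    logic_and(logic_leaf(1, neg = TRUE), logic_leaf(2, neg = TRUE)),
    parse_logic("not X1 and not X2")))
  expect_false(truth_table_equivalence(logic_leaf(1), logic_leaf(1, neg = TRUE)))
  big <- Reduce(logic_or, lapply(1:21, logic_leaf))
  expect_error(truth_table_equivalence(big, big), class = "flowtrees_size_error")
})

test_that("rendered expressions parse back to equivalent trees", {
  expect_equal(render_logic(worked_expr()), "(X1 and X2) or (X3 and not X4)")
  set.seed(35)
  random_tree <- function(depth) {
    if (depth == 0 || runif(1) < 0.4) return(logic_leaf(sample(8, 1), runif(1) < .5))
    op <- if (runif(1) < .5) logic_and else logic_or
    op(random_tree(depth - 1), random_tree(depth - 1))
  }
  for (i in 1:40) {
    tr <- random_tree(3)
    expect_true(truth_table_equivalence(tr, parse_logic(render_logic(tr))))
  }
  vars <- c("CD3-DR-CD56+CD16+", "Lin-DR-")
  tr <- logic_and(logic_leaf(1), logic_leaf(2, neg = TRUE))
  txt <- render_logic(tr, vars)
  expect_true(truth_table_equivalence(tr, parse_logic(txt, vars)))
  expect_error(parse_logic("X1 and"), class = "flowtrees_parse_error")
})

test_that("the annealer improves monotonically and reduces to logistic fits", {
  set.seed(37)
  x <- matrix(rbinom(150 * 6, 1, .5), 150)
  y <- rbinom(150, 1, plogis(-1 + 2 * x[, 3]))
  m <- anneal_search(x, y, config = anneal_config(iterations = 1500, seed = 38))
  expect_true(all(diff(m$best_trace) <= 1e-12))        # best score never worsens
  expect_lte(m$deviance, m$null_deviance + 1e-9)
  # one tree of one leaf: the search is best-single-variable logistic regression
  m1 <- anneal_search(x, y, config = anneal_config(n_trees = 1, max_leaves = 1,
                                                   iterations = 800, seed = 39))
  per_var_dev <- vapply(seq_len(ncol(x)), function(j) {
    devs <- c(fit_coefficients(list(logic_leaf(j)), x, y)$deviance,
              fit_coefficients(list(logic_leaf(j, neg = TRUE)), x, y)$deviance)
    min(devs)
  }, 0)
  expect_equal(m1$deviance, min(per_var_dev), tolerance = 1e-8)
})

test_that("pure-noise searches stay near the intercept-only deviance", {
  set.seed(41)
  x <- matrix(rbinom(200 * 10, 1, .5), 200)
  y <- rbinom(200, 1, 0.3)
  m <- anneal_search(x, y, config = anneal_config(iterations = 4000, seed = 42))
  # at most the chance improvement of ~8 adaptively chosen Boolean features
  expect_lt(m$null_deviance - m$deviance, 45)
})

test_that("planted Boolean rules are recovered on strong-signal panels", {
  sc <- make_scenario(spec_andnot(), n = 500, seed = 121)
  m <- anneal_search(sc$am, config = anneal_config(iterations = 8000,
                                                   score = "bic", seed = 122))
  rule <- logic_and(logic_leaf(sc$idx[1]), logic_leaf(sc$idx[2], neg = TRUE))
  expect_true(model_matches_rule(m, rule))
  expect_false(model_matches_rule(m, logic_leaf(sc$idx[1])))
})
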