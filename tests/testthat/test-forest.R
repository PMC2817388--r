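# Random forests: bootstrap structure, OOB error, reduction to a single
# CART tree, and both importance flavours.

test_that("forests are reproducible and reduce to CART when mtry = p, B = 1", {
  sc <- make_scenario(spec_marginal(), n = 80, seed = 101)
  f1 <- grow_forest(sc$am, config = forest_config(n_trees = 50, seed = 5))
  f2 <- grow_forest(sc$am, config = forest_config(n_trees = 50, seed = 5))
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  p <- ncol(sc$am$X)
  expect_warning(
    fb <- grow_forest(sc$am, config = forest_config(n_trees = 1, mtry = p, seed = 9)),
    "never out-of-bag")
  rows <- rep(seq_len(nrow(sc$am$X)), fb$inbag[, 1])
  ref <- grow_tree(sc$am$X[rows, ], as.integer(sc$am$y)[rows], min_node = 1)
  cpp <- fb$trees[[1]]
  fr <- ref$frame
  expect_identical(cpp$var, ifelse(is.na(fr$var), -1L, fr$var - 1L))
  expect_identical(cpp$pred, fr$pred)
  expect_error(grow_forest(sc$am, config = forest_config(mtry = p + 1)),
               class = "flowtrees_config_error")
})

test_that("per-tree OOB fractions match bootstrap theory", {
  sc <- make_scenario(spec_null(), n = 78, seed = 103)
  fo <- grow_forest(sc$am, config = forest_config(n_trees = 1000, seed = 7))
  oob_frac <- colMeans(fo$inbag == 0L)
  expect_lt(abs(mean(oob_frac) - (1 - 1 / 78)^78), 0.01)
  # OOB set is exactly the complement of the in-bag support
  expect_true(all((fo$inbag[, 1] == 0L) == !(seq_len(78) %in%
                                               rep(seq_len(78), fo$inbag[, 1]))))
})

test_that("OOB error tracks the base rate on null data and a test set on signal", {
  sc <- make_scenario(spec_null(0.25), n = 1000, seed = 105)
  fo <- grow_forest(sc$am, config = forest_config(n_trees = 500, seed = 11))
  oe <- oob_error(fo)
  expect_lt(abs(oe$aggregate - 0.25), 0.03)
  # perfectly separable single predictor
  y <- rep(c(0L, 1L), 40)
  fo2 <- grow_forest(cbind(x = y), y, config = forest_config(n_trees = 100, seed = 3))
  expect_lt(oob_error(fo2)$aggregate, 0.01)
  # OOB error approximates error on an independently simulated test set
  spec <- spec_marginal()
  tr <- make_scenario(spec, n = 400, seed = 107)
  te <- make_scenario(spec, n = 2000, seed = 207)
  fo3 <- grow_forest(tr$am, config = forest_config(n_trees = 500, seed = 13))
  test_err <- mean(predict(fo3, te$am) != as.integer(te$am$y))
  expect_lt(abs(oob_error(fo3)$aggregate - test_err), 0.05)
})

test_that("permutation importance is zero for unused variables, centred on null", {
  set.seed(15)
  X <- cbind(signal = rbinom(200, 1, .5), flat = 0L, noise = rbinom(200, 1, .5))
  y <- X[, 1]
  fo <- grow_forest(X, y, config = forest_config(n_trees = 100, mtry = 3, seed = 17))
  pi <- permutation_importance(fo, seed = 18)
  expect_identical(pi$importance[pi$variable == "flat"], 0)
  expect_gt(pi$importance[pi$variable == "signal"], 0.2)
  # pure noise: mean importance within 2 SE of zero
  Xn <- matrix(rbinom(200 * 20, 1, .5), 200)
  yn <- rbinom(200, 1, .3)
  fon <- grow_forest(Xn, yn, config = forest_config(n_trees = 500, seed = 19))
  pin <- permutation_importance(fon, seed = 20)
  m <- mean(pin$importance)
  se <- sd(pin$importance) / sqrt(nrow(pin))
  expect_lt(abs(m), 2 * se + 1e-3)
})

test_that("impurity-decrease importance is nonnegative and finds the signal", {
  sc <- make_scenario(spec_marginal(), n = 400, seed = 109)
  fo <- grow_forest(sc$am, config = forest_config(n_trees = 300, seed = 21))
  gi <- gini_importance(fo)
  expect_true(all(gi$importance >= 0))
  expect_equal(gi$variable[1], TARGET1)
  pi <- permutation_importance(fo, seed = 22)
  expect_equal(pi$variable[1], TARGET1)
  both <- importance_table(fo, seed = 22)
  expect_identical(names(both), c("variable", "permutation", "se", "impurity"))
  # a variable never split on carries no impurity decrease
  unused <- setdiff(fo$var_names,
                    fo$var_names[unlist(lapply(fo$trees, function(t)
                      t$var[t$var >= 0] + 1L))])
  if (length(unused))
    expect_true(all(gi$importance[gi$variable %in% unused] == 0))
})

test_that("duplicating a predictor dilutes, never boosts, its importance", {
  sc <- make_scenario(spec_marginal(), n = 400, seed = 111)
  X <- sc$am$X
  y <- as.integer(sc$am$y)
  base <- grow_forest(X, y, config = forest_config(n_trees = 500, seed = 23))
  imp_base <- permutation_importance(base, seed = 24)
  theta <- imp_base$importance[imp_base$variable == TARGET1]
  Xd <- cbind(X, dup1 = X[, TARGET1], dup2 = X[, TARGET1])
  dup <- grow_forest(Xd, y, config = forest_config(n_trees = 500, seed = 23))
  imp_dup <- permutation_importance(dup, seed = 24)
  copies <- imp_dup$importance[imp_dup$variable %in% c(TARGET1, "dup1", "dup2")]
  expect_true(all(copies <= theta + 2 * max(imp_base$se)))
})

test_that("importance rankings agree with the reference forest implementation", {
  skip_if_not_installed("randomForest")
  sc <- make_scenario(spec_marginal(), n = 300, seed = 115)
  fo <- grow_forest(sc$am, config = forest_config(n_trees = 500, seed = 27))
  ours <- permutation_importance(fo, seed = 28)
  set.seed(29)
  rf <- randomForest::randomForest(x = data.frame(sc$am$X, check.names = TRUE),
                                   y = factor(as.integer(sc$am$y)),
                                   ntree = 500, importance = TRUE)
  ref <- randomForest::importance(rf, type = 1, scale = FALSE)
  expect_equal(make.names(ours$variable[1]), rownames(ref)[which.max(ref)])
  # both agree on the aggregate OOB error to within sampling noise
  expect_lt(abs(oob_error(fo)$aggregate - mean(rf$err.rate[500, 1])), 0.06)
})

test_that("subject order does not change forest results under a fixed seed", {
  sc <- make_scenario(spec_marginal(), n = 100, seed = 113)
  fo <- grow_forest(sc$am, config = forest_config(n_trees = 50, seed = 25))
  oe <- oob_error(fo)$aggregate
  perm <- sample(nrow(sc$am$X))
  fo2 <- grow_forest(sc$am$X[perm, ], as.integer(sc$am$y)[perm],
                     config = forest_config(n_trees = 50, seed = 25))
  expect_lt(abs(oob_error(fo2)$aggregate - oe), 0.06)
})
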