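# Random forests over the binary analysis matrix: bootstrap sampling,
# unpruned Gini trees on random predictor subsets, out-of-bag error, and
# both permutation and impurity-decrease variable importance.

#' Forest configuration
#'
#' @param n_trees number of trees `B` (default 500).
#' @param mtry predictors sampled as split candidates at each node;
#'   default `ceiling(sqrt(p))`, resolved at fit time when `NULL`.
#' @param min_node child-size floor for the unpruned trees (default 1).
#' @param seed master seed; it spawns one independent stream per tree, so
#'   increasing `n_trees` leaves earlier trees unchanged.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, mtry = NULL, min_node = 1L, seed = 1L) {
  if (n_trees < 1L) stop_ft("n_trees must be >= 1", class = "flowtrees_config_error")
  if (min_node < 1L) stop_ft("min_node must be >= 1", class = "flowtrees_config_error")
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "forest_config")
}

#' Grow a random forest
#'
#' Each of `B` trees is grown, unpruned, on an independent bootstrap sample
#' of size n drawn with replacement (so about 63 percent of subjects are
#' unique in-bag and about 37 percent are out-of-bag per tree); at every
#' node the split search is restricted to a fresh random subset of `mtry`
#' predictors.
#'
#' @param x an `analysis_matrix` or 0/1 matrix.
#' @param y binary outcome (ignored for an `analysis_matrix`).
#' @param config a [forest_config()].
#' @return Object of class `flow_forest`: list with `trees`, `inbag`
#'   (n x B bootstrap counts), `gini` (p x B per-tree impurity decreases),
#'   `config`, `var_names`, and the training `x`, `y`.
#' @export
grow_forest <- function(x, y = NULL, config = forest_config()) {
  if (inherits(y, "forest_config")) { config <- y; y <- NULL }
  if (inherits(x, "analysis_matrix")) { y <- as.integer(x$y); x <- x$X }
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  p <- ncol(x)
  mtry <- config$mtry %||% ceiling(sqrt(p))
  if (mtry > p) stop_ft("mtry (%d) exceeds the number of predictors (%d)",
                        mtry, p, class = "flowtrees_config_error")
  set.seed(config$seed)
  tree_seeds <- draw_seeds(config$n_trees)
  fit <- rf_grow_cpp(x, y, config$n_trees, as.integer(mtry),
                     config$min_node, tree_seeds)
  never_oob <- sum(rowSums(fit$inbag == 0L) == 0L)
  if (never_oob > 0L)
    warning(sprintf("%d subject(s) never out-of-bag; increase n_trees", never_oob))
  structure(list(trees = fit$trees, inbag = fit$inbag, gini = fit$gini,
                 config = config, mtry = as.integer(mtry),
                 var_names = colnames(x) %||% paste0("X", seq_len(p)),
                 x = x, y = y),
            class = "flow_forest")
}

#' Out-of-bag error of a forest
#'
#' Per-tree misclassification on each tree's own out-of-bag subjects, and
#' the aggregate error of the per-subject majority vote over the trees for
#' which the subject is out-of-bag.  Ties in the vote predict class 0.
#'
#' @param forest a `flow_forest`.
#' @return List with `aggregate`, `per_tree`, `votes` (n x 2 count matrix)
#'   and `n_scored` (subjects out-of-bag at least once).
#' @export
oob_error <- function(forest) {
  res <- rf_oob_cpp(forest$trees, forest$inbag, forest$x, forest$y)
  votes <- res$votes
  scored <- rowSums(votes) > 0L
  pred <- as.integer(votes[, 2L] > votes[, 1L])
  list(aggregate = mean(pred[scored] != forest$y[scored]),
       per_tree = res$per_tree, votes = votes, n_scored = sum(scored))
}

#' Permutation variable importance
#'
#' For each tree `b` and predictor `j`, the importance increment is the
#' tree's out-of-bag misclassification after permuting predictor `j` within
#' the out-of-bag subjects minus its unpermuted out-of-bag
#' misclassification; the overall score is the average increment over the
#' `B` trees.  Predictors never used by a tree contribute an exact 0 for
#' that tree.
#'
#' @param forest a `flow_forest`.
#' @param seed seed for the permutation streams (one per tree).
#' @return A data frame of class `importance_table` with columns `variable`,
#'   `importance` (mean increment), `se` (standard error over trees),
#'   sorted descending by importance.
#' @export
permutation_importance <- function(forest, seed = 1L) {
  set.seed(seed)
  perm_seeds <- draw_seeds(length(forest$trees))
  res <- rf_perm_cpp(forest$trees, forest$inbag, forest$x, forest$y, perm_seeds)
  d <- res$delta
  keep <- !is.na(res$oob_err)           # trees without OOB data carry no signal
  d <- d[keep, , drop = FALSE]
  imp <- colMeans(d)
  se <- apply(d, 2L, sd) / sqrt(nrow(d))
  out <- data.frame(variable = forest$var_names, importance = imp, se = se)
  out <- out[order(-out$importance, out$variable), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  attr(out, "kind") <- "permutation"
  out
}

#' Mean decrease in node impurity
#'
#' For each predictor, the sum over its splits of the node size times the
#' impurity reduction `phi`, averaged over the trees of the forest.
#'
#' @param forest a `flow_forest`.
#' @return A data frame of class `importance_table` with columns `variable`
#'   and `importance`, sorted descending.
#' @export
gini_importance <- function(forest) {
  imp <- rowMeans(forest$gini)
  out <- data.frame(variable = forest$var_names, importance = imp)
  out <- out[order(-out$importance, out$variable), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  attr(out, "kind") <- "impurity"
  out
}

#' Combined importance table
#'
#' Both importance flavours side by side (permutation increments and mean
#' impurity decrease), sorted by permutation importance.
#'
#' @inheritParams permutation_importance
#' @return A data frame with `variable`, `permutation`, `se`, `impurity`.
#' @export
importance_table <- function(forest, seed = 1L) {
  pi <- permutation_importance(forest, seed = seed)
  gi <- gini_importance(forest)
  out <- data.frame(variable = pi$variable, permutation = pi$importance,
                    se = pi$se,
                    impurity = gi$importance[match(pi$variable, gi$variable)])
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.flow_forest <- function(x, ...) {
  cat(sprintf("flow_forest: %d trees, mtry = %d, min_node = %d, n = %d, p = %d\n",
              length(x$trees), x$mtry, x$config$min_node, nrow(x$x), ncol(x$x)))
  oe <- oob_error(x)
  cat(sprintf("  aggregate OOB error: %.4f (%d/%d subjects scored)\n",
              oe$aggregate, oe$n_scored, nrow(x$x)))
  invisible(x)
}

#' @export
predict.flow_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "analysis_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "integer"
  votes <- rf_predict_cpp(object$trees, newdata)
  if (type == "prob") return(votes[, 2L] / rowSums(votes))
  as.integer(votes[, 2L] > votes[, 1L])
}

#' Horizontal bar chart of an importance table
#'
#' @param x an `importance_table`.
#' @param n number of top variables shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.importance_table <- function(x, n = 20L, ...) {
  df <- head(as.data.frame(x), n)
  col <- if ("importance" %in% names(df)) "importance" else "permutation"
  op <- par(mar = c(4, 12, 2, 1))
  on.exit(par(op))
  barplot(rev(df[[col]]), names.arg = rev(df$variable), horiz = TRUE,
          las = 1, cex.names = 0.6,
          xlab = sprintf("variable importance (%s)", attr(x, "kind") %||% col), ...)
  invisible(x)
}
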