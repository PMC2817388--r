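# Classification trees: Gini splitting on pre-dichotomized predictors,
# minimum-child-size stopping, weakest-link cost-complexity pruning and
# cross-validated subtree selection.

#' Gini impurity of a binary node
#'
#' `2 p (1 - p)` where `p` is the within-node responder fraction.
#'
#' @param p_hat responder proportion(s) in \[0, 1\].
#' @return Impurity value(s) in \[0, 0.5\].
#' @examples
#' gini(0.5)      # 0.5, the maximum
#' gini(19 / 78)  # root impurity with 19 responders of 78
#' @export
gini <- function(p_hat) {
  if (any(!is.finite(p_hat)) || any(p_hat < 0 | p_hat > 1))
    stop_ft("p_hat must lie in [0, 1]", class = "flowtrees_domain_error")
  2 * p_hat * (1 - p_hat)
}

#' Best single split of a node
#'
#' Evaluates, for every candidate binary predictor, the impurity reduction
#' `phi = i(node) - pi_L i(left) - pi_R i(right)` with `pi_L`, `pi_R` the
#' within-node child fractions, and returns the maximizing variable.  The
#' left child collects subjects with predictor value 1 ("high").  Ties are
#' broken toward the lowest variable index.
#'
#' @param x 0/1 matrix of the node's subjects (rows) by predictors.
#' @param y binary outcome for the node's subjects.
#' @param min_child smallest admissible child size.
#' @param candidates optional integer vector restricting the columns searched.
#' @return A list with `var` (column index), `phi`, `pi_l`, `pi_r`,
#'   `impurity_left`, `impurity_right`, `n_left`, `n_right`; or `NULL` when
#'   no admissible split has `phi > 0`.
#' @export
best_split <- function(x, y, min_child = 1L, candidates = NULL) {
  n <- length(y)
  if (n < 2L) return(NULL)
  if (is.null(candidates)) candidates <- seq_len(ncol(x))
  xc <- x[, candidates, drop = FALSE]
  n1 <- sum(y)
  p0 <- n1 / n
  i0 <- 2 * p0 * (1 - p0)
  if (i0 <= 0) return(NULL)
  nl <- colSums(xc)
  n1l <- as.numeric(crossprod(xc, y))
  nr <- n - nl
  n1r <- n1 - n1l
  pl <- n1l / nl
  pr <- n1r / nr
  il <- 2 * pl * (1 - pl)
  ir <- 2 * pr * (1 - pr)
  phi <- i0 - (nl / n) * il - (nr / n) * ir
  phi[nl < min_child | nr < min_child] <- -Inf
  j <- which.max(phi)                       # first max = lowest index
  if (!is.finite(phi[j]) || phi[j] <= 0) return(NULL)
  list(var = candidates[j], phi = unname(phi[j]),
       pi_l = unname(nl[j] / n), pi_r = unname(nr[j] / n),
       impurity_left = unname(il[j]), impurity_right = unname(ir[j]),
       n_left = unname(nl[j]), n_right = unname(nr[j]))
}

#' Grow a classification tree
#'
#' Recursive partitioning by [best_split()]: a node is split only when some
#' split has a positive impurity reduction and both children would contain
#' at least `min_node` subjects.  Leaf predictions are the majority class,
#' with ties predicted as 0.
#'
#' @param x an `analysis_matrix` or 0/1 predictor matrix.
#' @param y binary outcome (ignored when `x` is an `analysis_matrix`).
#' @param min_node smallest admissible child size (default 5, a stopping
#'   rule of five individuals per node).
#' @param mtry optional number of predictors sampled (without replacement)
#'   as split candidates at each node, for use inside random forests;
#'   `NULL` searches all predictors.
#' @return Object of class `flowcart`.
#' @export
grow_tree <- function(x, y = NULL, min_node = 5L, mtry = NULL) {
  if (inherits(x, "analysis_matrix")) { y <- as.integer(x$y); x <- x$X }
  x <- as.matrix(x)
  if (nrow(x) == 0L || length(y) == 0L)
    stop_ft("empty data", class = "flowtrees_empty_input_error")
  stopifnot(nrow(x) == length(y), min_node >= 1L)
  y <- as.integer(y)
  p <- ncol(x)
  env <- new.env()
  env$rows <- list()
  add_node <- function(idx, depth, parent) {
    id <- length(env$rows) + 1L
    n <- length(idx); n1 <- sum(y[idx])
    env$rows[[id]] <- list(id = id, parent = parent, depth = depth,
                           var = NA_integer_, left = NA_integer_, right = NA_integer_,
                           n = n, n1 = n1, prob = n / nrow(x), p_hat = n1 / n,
                           pred = as.integer(n1 > n - n1), leaf = TRUE)
    bs <- if (n >= 2L)
      best_split(x[idx, , drop = FALSE], y[idx], min_child = min_node,
                 candidates = if (is.null(mtry)) NULL
                              else sort(sample.int(p, min(mtry, p))))
    else NULL
    if (!is.null(bs)) {
      go_left <- x[idx, bs$var] == 1L
      lid <- add_node(idx[go_left], depth + 1L, id)
      rid <- add_node(idx[!go_left], depth + 1L, id)
      env$rows[[id]]$var <- bs$var
      env$rows[[id]]$left <- lid
      env$rows[[id]]$right <- rid
      env$rows[[id]]$leaf <- FALSE
    }
    id
  }
  add_node(seq_len(nrow(x)), 0L, NA_integer_)
  frame <- do.call(rbind, lapply(env$rows, function(r) as.data.frame(r)))
  structure(list(frame = frame, var_names = colnames(x) %||% paste0("X", seq_len(p)),
                 min_node = as.integer(min_node), n_root = nrow(x)),
            class = "flowcart")
}

#' Number of terminal nodes
#' @param tree a `flowcart`.
#' @export
n_leaves <- function(tree) sum(tree$frame$leaf)

#' Resubstitution risk of a classification tree
#'
#' Sum over terminal nodes of the node probability times the node
#' misclassification rate; equals the overall training misclassification
#' proportion under majority-rule predictions.
#'
#' @param tree a `flowcart`.
#' @return The risk `R(T)`.
#' @export
tree_risk <- function(tree) {
  f <- tree$frame[tree$frame$leaf, ]
  sum(f$prob * pmin(f$p_hat, 1 - f$p_hat))
}

#' @export
predict.flowcart <- function(object, newdata, type = c("class", "prob", "leaf"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "analysis_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  f <- object$frame
  at <- rep(1L, nrow(newdata))                  # row index into frame (root first)
  repeat {
    open <- which(!f$leaf[at])
    if (!length(open)) break
    v <- f$var[at[open]]
    goes_left <- newdata[cbind(open, v)] == 1
    nxt <- ifelse(goes_left, f$left[at[open]], f$right[at[open]])
    at[open] <- match(nxt, f$id)
  }
  switch(type,
         class = f$pred[at],
         prob = f$p_hat[at],
         leaf = f$id[at])
}

#' @export
print.flowcart <- function(x, digits = 3L, ...) {
  f <- x$frame
  cat(sprintf("flowcart: %d nodes, %d leaves, risk %.4f (min_node = %d)\n",
              nrow(f), n_leaves(x), tree_risk(x), x$min_node))
  show <- function(id, prefix, label) {
    r <- f[match(id, f$id), ]
    tag <- if (r$leaf) sprintf("* pred=%d", r$pred) else
      sprintf("split: %s", x$var_names[r$var])
    cat(sprintf("%s%s%d/%d (%.1f%%) %s\n", prefix, label, r$n1, r$n,
                100 * r$p_hat, tag))
    if (!r$leaf) {
      show(r$left, paste0(prefix, "  "), sprintf("[%s high] ", x$var_names[r$var]))
      show(r$right, paste0(prefix, "  "), sprintf("[%s low]  ", x$var_names[r$var]))
    }
  }
  show(f$id[1], "", "")
  invisible(x)
}

#' @export
summary.flowcart <- function(object, ...) {
  f <- object$frame
  used <- unique(f$var[!f$leaf])
  cat(sprintf("Classification tree on %d subjects\n", object$n_root))
  cat(sprintf("  leaves: %d, depth: %d, training risk: %.4f\n",
              n_leaves(object), max(f$depth), tree_risk(object)))
  if (length(used))
    cat("  split variables:", paste(object$var_names[used], collapse = ", "), "\n")
  invisible(object)
}

# risk contribution if node id were a leaf (prob-weighted misclassification)
node_leaf_risk <- function(f, i) f$prob[i] * pmin(f$p_hat[i], 1 - f$p_hat[i])

# per-node branch statistics (leaves, branch risk) over the current frame
branch_stats <- function(f) {
  ord <- order(f$depth, decreasing = TRUE)          # children before parents
  leaves <- ifelse(f$leaf, 1L, 0L)
  brisk <- ifelse(f$leaf, node_leaf_risk(f, seq_len(nrow(f))), 0)
  pos <- function(id) match(id, f$id)
  for (i in ord) {
    if (!f$leaf[i]) {
      l <- pos(f$left[i]); r <- pos(f$right[i])
      leaves[i] <- leaves[l] + leaves[r]
      brisk[i] <- brisk[l] + brisk[r]
    }
  }
  list(leaves = leaves, risk = brisk)
}

# drop all strict descendants of node id and make it a leaf
collapse_node <- function(tree, id) {
  f <- tree$frame
  drop <- integer(0)
  stack <- c(f$left[match(id, f$id)], f$right[match(id, f$id)])
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    if (is.na(cur)) next
    i <- match(cur, f$id)
    drop <- c(drop, i)
    if (!f$leaf[i]) stack <- c(stack, f$left[i], f$right[i])
  }
  i <- match(id, f$id)
  f$leaf[i] <- TRUE; f$var[i] <- NA_integer_
  f$left[i] <- NA_integer_; f$right[i] <- NA_integer_
  if (length(drop)) f <- f[-drop, , drop = FALSE]
  tree$frame <- f
  tree
}

#' Weakest-link cost-complexity pruning sequence
#'
#' Repeatedly collapses the internal node(s) minimizing
#' `g(t) = (R(t as leaf) - R(branch of t)) / (|branch leaves| - 1)`,
#' producing the nested subtree sequence with its critical complexity
#' thresholds.  The first element (threshold 0) is the initial tree after
#' collapsing branches that do not reduce the resubstitution risk; the last
#' is the root-only tree.
#'
#' @param tree a fitted `flowcart`.
#' @return Object of class `prune_sequence`: list with `alpha`, `size`,
#'   `risk` (parallel vectors) and `trees` (list of nested `flowcart`s).
#' @export
prune_sequence <- function(tree) {
  eps <- 1e-12
  weakest <- function(tr) {
    f <- tr$frame
    internal <- which(!f$leaf)
    if (!length(internal)) return(NULL)
    bs <- branch_stats(f)
    g <- (node_leaf_risk(f, internal) - bs$risk[internal]) /
      (bs$leaves[internal] - 1L)
    list(ids = f$id[internal][g <= min(g) + eps], g = min(g))
  }
  # initial tree: collapse links whose removal leaves the risk unchanged
  current <- tree
  repeat {
    w <- weakest(current)
    if (is.null(w) || w$g > eps) break
    for (id in w$ids)
      if (id %in% current$frame$id) current <- collapse_node(current, id)
  }
  alphas <- 0; trees <- list(current)
  repeat {
    w <- weakest(current)
    if (is.null(w)) break
    gcur <- w$g
    repeat {                 # absorb any links tied with the current threshold
      for (id in w$ids)
        if (id %in% current$frame$id) current <- collapse_node(current, id)
      w <- weakest(current)
      if (is.null(w) || w$g > gcur + eps) break
    }
    alphas <- c(alphas, gcur)
    trees <- c(trees, list(current))
  }
  structure(list(alpha = alphas,
                 size = vapply(trees, n_leaves, 0L),
                 risk = vapply(trees, tree_risk, 0),
                 trees = trees),
            class = "prune_sequence")
}

#' @export
print.prune_sequence <- function(x, ...) {
  cat("cost-complexity pruning sequence\n")
  print(data.frame(alpha = x$alpha, leaves = x$size, risk = x$risk),
        row.names = FALSE)
  invisible(x)
}

# subtree of the sequence in force at complexity alpha
subtree_at <- function(seq, alpha) {
  k <- max(which(seq$alpha <= alpha + 1e-12))
  seq$trees[[k]]
}

# stratified fold assignment: balanced responders/nonresponders per fold
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated subtree selection
#'
#' Grows the full tree, derives its pruning sequence, estimates
#' misclassification by stratified V-fold cross-validation at the geometric
#' midpoints of the complexity intervals, and returns the subtree chosen by
#' the minimum-error rule or the one-standard-error rule (default).
#'
#' @param x an `analysis_matrix` or 0/1 matrix.
#' @param y binary outcome (ignored for an `analysis_matrix`).
#' @param min_node stopping rule passed to [grow_tree()].
#' @param folds number of cross-validation folds (default 10).
#' @param rule `"1se"` (smallest tree within one standard error of the
#'   minimum, the default) or `"min"`.
#' @param seed integer seed for the fold assignment.
#' @return The selected `flowcart`, with attributes `cv` (a data frame of
#'   per-threshold cross-validated error and standard error) and `sequence`.
#' @export
select_subtree_cv <- function(x, y = NULL, min_node = 5L, folds = 10L,
                              rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  if (inherits(x, "analysis_matrix")) { y <- as.integer(x$y); x <- x$X }
  x <- as.matrix(x); y <- as.integer(y)
  n <- length(y)
  if (folds < 2L || folds > n)
    stop_ft("folds must lie in [2, n]", class = "flowtrees_config_error")
  full_seq <- prune_sequence(grow_tree(x, y, min_node = min_node))
  K <- length(full_seq$alpha)
  if (K == 1L) {
    out <- full_seq$trees[[1L]]
    attr(out, "sequence") <- full_seq
    return(out)
  }
  # representative alpha per interval: geometric midpoint (0 for the first)
  a <- full_seq$alpha
  rep_alpha <- c(0, sqrt(a[-c(1L, K)] * a[-c(1L, 2L)]), a[K])
  if (K == 2L) rep_alpha <- c(0, a[2L])
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  wrong <- matrix(0, folds, K)
  for (v in seq_len(folds)) {
    tr <- fold != v
    fs <- prune_sequence(grow_tree(x[tr, , drop = FALSE], y[tr], min_node = min_node))
    for (k in seq_len(K)) {
      pred <- predict(subtree_at(fs, rep_alpha[k]), x[!tr, , drop = FALSE])
      wrong[v, k] <- sum(pred != y[!tr])
    }
  }
  err <- colSums(wrong) / n
  se <- sqrt(err * (1 - err) / n)
  kmin <- max(which(err == min(err)))               # prefer the smaller tree
  k <- if (rule == "min") kmin else max(which(err <= err[kmin] + se[kmin]))
  out <- full_seq$trees[[k]]
  attr(out, "cv") <- data.frame(alpha = a, rep_alpha = rep_alpha,
                                size = full_seq$size, cv_error = err, se = se)
  attr(out, "sequence") <- full_seq
  out
}

#' Serialize a tree as JSON
#' @param tree a `flowcart`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  f <- tree$frame
  f$variable <- ifelse(is.na(f$var), NA_character_, tree$var_names[f$var])
  js <- jsonlite::toJSON(list(min_node = tree$min_node, n = tree$n_root,
                              nodes = f),
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
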