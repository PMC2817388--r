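# Logic regression: generalized linear models whose covariates are Boolean
# (AND/OR/complement) combinations of the binary predictors, fitted by
# simulated annealing over a set of tree-edit moves.

#' Boolean tree constructors
#'
#' A logic tree is either a leaf — a predictor index with an optional
#' complement — or an operator node (`"and"` / `"or"`) with exactly two
#' children.  Complements live at leaves only; De Morgan's laws make
#' internal complements redundant.
#'
#' @param var predictor column index.
#' @param neg complement flag.
#' @return A logic tree node.
#' @examples
#' tr <- logic_or(logic_and(logic_leaf(1), logic_leaf(2)),
#'                logic_and(logic_leaf(3), logic_leaf(4, neg = TRUE)))
#' render_logic(tr)  # "(X1 and X2) or (X3 and not X4)"
#' @export
logic_leaf <- function(var, neg = FALSE) {
  stopifnot(length(var) == 1L, var >= 1)
  structure(list(type = "leaf", var = as.integer(var), neg = isTRUE(neg)),
            class = "logic_tree")
}

#' @rdname logic_leaf
#' @param l,r child trees.
#' @export
logic_and <- function(l, r) structure(list(type = "and", l = l, r = r), class = "logic_tree")

#' @rdname logic_leaf
#' @export
logic_or <- function(l, r) structure(list(type = "or", l = l, r = r), class = "logic_tree")

#' Evaluate a Boolean tree on binary data
#'
#' @param tree a logic tree (or `NULL`, the constant-0 tree).
#' @param x 0/1 matrix or data frame whose columns the leaves reference.
#' @return Integer 0/1 vector, one value per row of `x`.
#' @export
evaluate_tree <- function(tree, x) {
  x <- as.matrix(x)
  if (is.null(tree)) return(integer(nrow(x)))
  ev <- function(t) {
    if (t$type == "leaf") {
      if (t$var > ncol(x))
        stop_ft("leaf references variable %d but data has %d columns",
                t$var, ncol(x), class = "flowtrees_reference_error")
      v <- x[, t$var]
      if (t$neg) 1L - as.integer(v) else as.integer(v)
    } else if (t$type == "and") ev(t$l) * ev(t$r)
    else as.integer(ev(t$l) + ev(t$r) > 0L)
  }
  ev(tree)
}

#' Leaf count and referenced variables of a logic tree
#' @param tree a logic tree or `NULL`.
#' @export
count_leaves <- function(tree) {
  if (is.null(tree)) return(0L)
  if (tree$type == "leaf") return(1L)
  count_leaves(tree$l) + count_leaves(tree$r)
}

#' @rdname count_leaves
#' @export
tree_vars <- function(tree) {
  if (is.null(tree)) return(integer(0))
  if (tree$type == "leaf") return(tree$var)
  sort(unique(c(tree_vars(tree$l), tree_vars(tree$r))))
}

# paths to leaves / internal nodes; a path is a character vector of "l"/"r"
node_paths <- function(tree, want = c("leaf", "op"), path = character()) {
  if (is.null(tree)) return(list())
  want <- match.arg(want)
  here <- if ((tree$type == "leaf") == (want == "leaf")) list(path) else list()
  if (tree$type == "leaf") return(here)
  c(here,
    node_paths(tree$l, want, c(path, "l")),
    node_paths(tree$r, want, c(path, "r")))
}

get_at <- function(tree, path) { for (s in path) tree <- tree[[s]]; tree }

set_at <- function(tree, path, value) {
  if (!length(path)) return(value)
  tree[[path[1L]]] <- set_at(tree[[path[1L]]], path[-1L], value)
  tree
}

random_leaf <- function(p) logic_leaf(sample.int(p, 1L), neg = runif(1) < 0.5)

#' Propose one annealing move
#'
#' Applies one of the six tree-edit move types to a uniformly chosen tree of
#' the state: alternate a leaf's variable, toggle a leaf's complement,
#' alternate an operator, grow a branch (replace a leaf by an operator over
#' it and a new random leaf), prune a branch (replace an operator that has a
#' leaf child by its other child), or split/delete a leaf.  Moves that would
#' exceed the total leaf budget, or that are inapplicable to the chosen
#' tree, return the state unchanged with `applied = FALSE`.  Every applied
#' move changes the total leaf count by at most one.
#'
#' @param trees list of logic trees (entries may be `NULL`).
#' @param move move type; see above.
#' @param p number of predictor columns.
#' @param max_leaves total leaf budget across trees.
#' @return List with `trees` and `applied`.
#' @export
propose_move <- function(trees,
                         move = c("alternate_leaf", "toggle_complement",
                                  "alternate_operator", "grow_branch",
                                  "prune_branch", "split_delete_leaf"),
                         p, max_leaves = Inf) {
  move <- match.arg(move)
  k <- sample.int(length(trees), 1L)
  tr <- trees[[k]]
  total <- sum(vapply(trees, count_leaves, 0L))
  can_add <- total < max_leaves
  reject <- function() list(trees = trees, applied = FALSE)
  pick <- function(paths) paths[[sample.int(length(paths), 1L)]]

  new_tr <- switch(move,
    alternate_leaf = {
      paths <- node_paths(tr, "leaf")
      if (!length(paths) || p < 2L) return(reject())
      pa <- pick(paths); lf <- get_at(tr, pa)
      lf$var <- sample(setdiff(seq_len(p), lf$var), 1L)
      set_at(tr, pa, lf)
    },
    toggle_complement = {
      paths <- node_paths(tr, "leaf")
      if (!length(paths)) return(reject())
      pa <- pick(paths); lf <- get_at(tr, pa)
      lf$neg <- !lf$neg
      set_at(tr, pa, lf)
    },
    alternate_operator = {
      paths <- node_paths(tr, "op")
      if (!length(paths)) return(reject())
      pa <- pick(paths); nd <- get_at(tr, pa)
      nd$type <- if (nd$type == "and") "or" else "and"
      set_at(tr, pa, nd)
    },
    grow_branch = {
      if (!can_add) return(reject())
      if (is.null(tr)) random_leaf(p)
      else {
        paths <- node_paths(tr, "leaf")
        pa <- pick(paths)
        joiner <- if (runif(1) < 0.5) logic_and else logic_or
        set_at(tr, pa, joiner(get_at(tr, pa), random_leaf(p)))
      }
    },
    prune_branch = {
      paths <- Filter(function(pa) {
        nd <- get_at(tr, pa)
        nd$l$type == "leaf" || nd$r$type == "leaf"
      }, node_paths(tr, "op"))
      if (!length(paths)) return(reject())
      pa <- pick(paths); nd <- get_at(tr, pa)
      keep <- if (nd$l$type == "leaf" && nd$r$type == "leaf") {
        if (runif(1) < 0.5) nd$l else nd$r
      } else if (nd$l$type == "leaf") nd$r else nd$l
      set_at(tr, pa, keep)
    },
    split_delete_leaf = {
      paths <- node_paths(tr, "leaf")
      do_split <- if (can_add && length(paths)) runif(1) < 0.5
                  else if (can_add) TRUE else FALSE
      if (do_split) {
        if (is.null(tr)) random_leaf(p)
        else {
          pa <- pick(paths)
          joiner <- if (runif(1) < 0.5) logic_and else logic_or
          set_at(tr, pa, joiner(get_at(tr, pa), random_leaf(p)))
        }
      } else {
        if (!length(paths)) return(reject())
        if (is.null(tr) || tr$type == "leaf") NULL  # deleting the only leaf
        else {
          pa <- pick(paths)
          parent <- pa[-length(pa)]
          nd <- get_at(tr, parent)
          sib <- if (identical(pa[length(pa)], "l")) nd$r else nd$l
          set_at(tr, parent, sib)
        }
      }
    })
  trees[k] <- list(new_tr)          # [k] <- list(...): keep NULL entries
  list(trees = trees, applied = TRUE, tree = k)
}

#' Maximum-likelihood coefficients for fixed Boolean trees
#'
#' Evaluates each tree into a 0/1 column and fits the generalized linear
#' model `g(E[Y | X]) = b0 + sum_j b_j L_j` by iteratively reweighted least
#' squares on the collapsed covariate patterns (logit link), or by weighted
#' least squares (identity link).  Constant and aliased columns are dropped
#' with a flag; under separation coefficients are capped at `cap` and
#' flagged.
#'
#' @param trees list of logic trees (`NULL` entries allowed).
#' @param x 0/1 predictor matrix.
#' @param y binary outcome.
#' @param link `"logit"` or `"identity"`.
#' @param cap absolute coefficient bound applied under separation.
#' @return List with `intercept`, `coefficients` (one per tree, `NA` for
#'   dropped trees), `deviance`, `null_deviance`, `dropped`, `separation`.
#' @export
fit_coefficients <- function(trees, x, y, link = c("logit", "identity"), cap = 10) {
  link <- match.arg(link)
  x <- as.matrix(x)
  y <- as.integer(y)
  L <- vapply(trees, function(t) as.numeric(evaluate_tree(t, x)), numeric(nrow(x)))
  L <- matrix(L, nrow = nrow(x))
  fit_columns(L, y, link = link, cap = cap)
}

# core fitter on evaluated 0/1 columns; rows may carry binomial weights
# (w trials, s successes), which the annealer uses after collapsing the
# design matrix to its unique covariate patterns
fit_columns <- function(L, y = NULL, w = NULL, s = NULL, link = "logit", cap = 10) {
  if (is.null(w)) { w <- rep(1, length(y)); s <- as.numeric(y) }
  t_all <- ncol(L)
  ntot <- sum(w)
  cs <- as.vector(crossprod(L, w))
  keep <- which(cs > 0 & cs < ntot)                 # non-constant columns
  if (length(keep) > 1L) {                          # drop aliased columns
    Lk <- L[, keep, drop = FALSE]
    if (length(keep) == 2L) {
      dup <- all(Lk[, 1L] == Lk[, 2L]) || all(Lk[, 1L] == 1 - Lk[, 2L])
      if (dup) keep <- keep[1L]
    } else {
      q <- qr(cbind(1, Lk))
      if (q$rank < length(keep) + 1L)
        keep <- keep[sort(q$pivot[seq_len(q$rank)][-1L] - 1L)]
    }
  }
  U <- cbind(`(Intercept)` = 1, L[, keep, drop = FALSE])
  key <- as.vector(U %*% 2^(seq_len(ncol(U)) - 1L))
  agg <- rowsum(cbind(w, s), key)
  Upat <- U[match(as.numeric(rownames(agg)), key), , drop = FALSE]
  w <- agg[, 1L]; s <- agg[, 2L]
  if (link == "identity") {
    A <- crossprod(Upat, w * Upat)
    fit <- as.vector(solve(A, crossprod(Upat, s)))
    mu <- as.vector(Upat %*% fit)
    dev <- sum(s * (1 - mu)^2 + (w - s) * mu^2)
    sep <- FALSE
  } else {
    beta <- numeric(ncol(Upat))
    dev <- Inf
    sep <- FALSE
    for (it in 1:30) {
      eta <- as.vector(Upat %*% beta)
      mu <- plogis(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      Wd <- w * mu * (1 - mu)
      z <- eta + (s / w - mu) / (mu * (1 - mu))
      beta_new <- tryCatch(
        as.vector(solve(crossprod(Upat, Wd * Upat), crossprod(Upat, Wd * z))),
        error = function(e) beta)
      clamped <- pmin(pmax(beta_new, -cap), cap)
      sep <- any(clamped != beta_new)
      beta_new <- clamped
      eta <- as.vector(Upat %*% beta_new)
      mu <- pmin(pmax(plogis(eta), 1e-15), 1 - 1e-15)
      dev_new <- -2 * sum(s * log(mu) + (w - s) * log(1 - mu))
      done <- abs(dev - dev_new) < 1e-10
      beta <- beta_new; dev <- dev_new
      if (done) break
    }
    fit <- beta
  }
  ybar <- sum(s) / ntot
  null_dev <- if (link == "identity") sum(s * (1 - ybar)^2 + (w - s) * ybar^2)
              else -2 * ntot * (ybar * log(max(ybar, 1e-15)) +
                                (1 - ybar) * log(max(1 - ybar, 1e-15)))
  coefs <- rep(NA_real_, t_all)
  coefs[keep] <- fit[-1L]
  list(intercept = unname(fit[1L]), coefficients = coefs, deviance = dev,
       null_deviance = null_dev, dropped = setdiff(seq_len(t_all), keep),
       separation = sep)
}

#' Annealing configuration for the logic-model search
#'
#' @param n_trees number of Boolean trees `t` (default 2).
#' @param max_leaves total leaf budget across all trees (default 6).
#' @param iterations number of annealing iterations (default 50000).
#' @param t_start,t_end geometric cooling schedule endpoints (temperatures,
#'   positive and decreasing).  The default `NULL` scales the schedule to
#'   the data at fit time: `t_start = 0.05 * null deviance` (so early moves
#'   are accepted liberally whatever the sample size) and `t_end = 0.05`
#'   (well below the smallest score difference that matters).
#' @param move_probs probabilities over the six move types (uniform by
#'   default), in the order of [propose_move()]'s `move` argument.
#' @param score `"deviance"` (default), `"aic"` or `"bic"` — the latter two
#'   add `2` or `log(n)` per leaf, for searches meant to recover a sparse
#'   rule rather than to saturate the leaf budget.
#' @param link passed to [fit_coefficients()].
#' @param seed integer seed.
#' @return A list of class `anneal_config`.
#' @export
anneal_config <- function(n_trees = 2L, max_leaves = 6L, iterations = 50000L,
                          t_start = NULL, t_end = NULL,
                          move_probs = rep(1 / 6, 6L),
                          score = c("deviance", "aic", "bic"),
                          link = c("logit", "identity"), seed = 1L) {
  score <- match.arg(score); link <- match.arg(link)
  if (iterations < 1L) stop_ft("iteration budget must be >= 1", class = "flowtrees_config_error")
  if (!is.null(t_start) && !is.null(t_end) &&
      (t_start <= 0 || t_end <= 0 || t_end > t_start))
    stop_ft("temperatures must be positive and decreasing", class = "flowtrees_config_error")
  if (length(move_probs) != 6L || any(move_probs < 0) ||
      abs(sum(move_probs) - 1) > 1e-8)
    stop_ft("move_probs must be 6 nonnegative values summing to 1", class = "flowtrees_config_error")
  structure(list(n_trees = as.integer(n_trees), max_leaves = as.integer(max_leaves),
                 iterations = as.integer(iterations), t_start = t_start,
                 t_end = t_end, move_probs = move_probs, score = score,
                 link = link, seed = as.integer(seed)),
            class = "anneal_config")
}

MOVE_TYPES <- c("alternate_leaf", "toggle_complement", "alternate_operator",
                "grow_branch", "prune_branch", "split_delete_leaf")

#' Fit a logic-regression model by simulated annealing
#'
#' Starting from single random leaves, tree-edit moves are proposed and
#' accepted with the Metropolis rule: always when the score improves,
#' otherwise with probability `exp(-delta / temperature)` under a geometric
#' cooling schedule.  The score is the model deviance from
#' [fit_coefficients()] (optionally with a per-leaf AIC/BIC penalty).  The
#' best state visited is returned.
#'
#' @param x an `analysis_matrix` or 0/1 matrix.
#' @param y binary outcome (ignored for an `analysis_matrix`).
#' @param config an [anneal_config()].
#' @return Object of class `logic_model`: list with `trees`, `intercept`,
#'   `coefficients`, `deviance`, `null_deviance`, `score`, `link`,
#'   `var_names`, `dropped`, `separation`, `config`, and `best_trace` (the
#'   best score after each iteration).
#' @export
anneal_search <- function(x, y = NULL, config = anneal_config()) {
  if (inherits(y, "anneal_config")) { config <- y; y <- NULL }
  if (inherits(x, "analysis_matrix")) { y <- as.integer(x$y); x <- x$X }
  x <- as.matrix(x)
  y <- as.integer(y)
  p <- ncol(x)
  n <- nrow(x)
  penalty <- switch(config$score, deviance = 0, aic = 2, bic = log(n))
  set.seed(config$seed)

  # collapse to unique covariate patterns: the likelihood only depends on
  # per-pattern trial and success counts, which makes scoring O(#patterns)
  key <- do.call(paste0, asplit(x, 2L))
  agg <- rowsum(cbind(1, y), key)
  first <- !duplicated(key)
  xu <- x[first, , drop = FALSE]
  ord <- match(key[first], rownames(agg))
  wts <- agg[ord, 1L]; succ <- agg[ord, 2L]
  nu <- nrow(xu)

  trees <- replicate(config$n_trees,
                     if (config$max_leaves >= 1L) random_leaf(p),
                     simplify = FALSE)
  # keep initial state inside the budget
  while (sum(vapply(trees, count_leaves, 0L)) > config$max_leaves) {
    k <- which(vapply(trees, count_leaves, 0L) > 0L)[1L]
    trees[k] <- list(NULL_TREE)
  }
  cols <- vapply(trees, function(t) as.numeric(evaluate_tree(t, xu)), numeric(nu))
  cols <- matrix(cols, nrow = nu)
  score_state <- function(cols, trees) {
    f <- fit_columns(cols, w = wts, s = succ, link = config$link)
    f$deviance + penalty * sum(vapply(trees, count_leaves, 0L))
  }
  cur_score <- score_state(cols, trees)
  best <- list(trees = trees, score = cur_score)
  iters <- config$iterations
  null_fit <- fit_columns(matrix(0, nu, 1L), w = wts, s = succ, link = config$link)
  t_start <- config$t_start %||% max(2, 0.05 * null_fit$deviance)
  t_end <- config$t_end %||% min(0.05, t_start / 2)
  temp <- t_start * (t_end / t_start)^
    (if (iters > 1L) (seq_len(iters) - 1L) / (iters - 1L) else 0)
  best_trace <- numeric(iters)
  for (i in seq_len(iters)) {
    move <- sample(MOVE_TYPES, 1L, prob = config$move_probs)
    prop <- propose_move(trees, move, p = p, max_leaves = config$max_leaves)
    if (prop$applied) {
      k <- prop$tree
      new_cols <- cols
      new_cols[, k] <- as.numeric(evaluate_tree(prop$trees[[k]], xu))
      new_score <- score_state(new_cols, prop$trees)
      delta <- new_score - cur_score
      if (delta <= 0 || runif(1) < exp(-delta / temp[i])) {
        trees <- prop$trees
        cols <- new_cols
        cur_score <- new_score
        if (cur_score < best$score - 1e-12)
          best <- list(trees = trees, score = cur_score)
      }
    }
    best_trace[i] <- best$score
  }
  final <- fit_columns(
    matrix(vapply(best$trees, function(t) as.numeric(evaluate_tree(t, xu)),
                  numeric(nu)), nrow = nu),
    w = wts, s = succ, link = config$link)
  structure(list(trees = best$trees, intercept = final$intercept,
                 coefficients = final$coefficients, deviance = final$deviance,
                 null_deviance = final$null_deviance, score = best$score,
                 link = config$link,
                 var_names = colnames(x) %||% paste0("X", seq_len(p)),
                 dropped = final$dropped, separation = final$separation,
                 config = config, best_trace = best_trace),
            class = "logic_model")
}

NULL_TREE <- NULL  # the constant-0 tree

#' Render a logic tree or model as text
#'
#' Produces expressions such as `"(X1 and X2) or (X3 and not X4)"`.
#'
#' @param tree a logic tree (or `NULL`).
#' @param vars optional variable names; leaf indices are used otherwise.
#' @return A character string.
#' @export
render_logic <- function(tree, vars = NULL) {
  if (is.null(tree)) return("0")
  nm <- function(j) if (is.null(vars)) paste0("X", j) else vars[j]
  rl <- function(t, top = FALSE) {
    if (t$type == "leaf") {
      s <- nm(t$var)
      if (t$neg) paste("not", s) else s
    } else {
      s <- paste(rl(t$l), t$type, rl(t$r))
      if (top) s else paste0("(", s, ")")
    }
  }
  rl(tree, top = TRUE)
}

#' Parse a logic expression
#'
#' Accepts the grammar emitted by [render_logic()]: identifiers (optionally
#' preceded by `not`), `and`, `or`, and parentheses; `and` binds tighter
#' than `or`, complements attach to identifiers.
#'
#' @param text expression string.
#' @param vars optional variable names used to resolve identifiers;
#'   otherwise identifiers must be of the form `X<j>`.
#' @return A logic tree (or `NULL` for `"0"`).
#' @export
parse_logic <- function(text, vars = NULL) {
  if (identical(trimws(text), "0")) return(NULL_TREE)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  resolve <- function(id) {
    if (!is.null(vars)) {
      j <- match(id, vars)
      if (!is.na(j)) return(j)
    }
    if (grepl("^X[0-9]+$", id)) return(as.integer(sub("^X", "", id)))
    stop_ft("cannot resolve identifier '%s'", id, class = "flowtrees_parse_error")
  }
  parse_or <- function() {
    t <- parse_and()
    while (identical(peek(), "or")) { take(); t <- logic_or(t, parse_and()) }
    t
  }
  parse_and <- function() {
    t <- parse_factor()
    while (identical(peek(), "and")) { take(); t <- logic_and(t, parse_factor()) }
    t
  }
  parse_factor <- function() {
    tk <- take()
    if (is.na(tk)) stop_ft("unexpected end of expression", class = "flowtrees_parse_error")
    if (tk == "(") {
      t <- parse_or()
      if (!identical(take(), ")"))
        stop_ft("expected ')'", class = "flowtrees_parse_error")
      t
    } else if (tk == "not") {
      id <- take()
      logic_leaf(resolve(id), neg = TRUE)
    } else logic_leaf(resolve(tk))
  }
  out <- parse_or()
  if (!is.na(peek()))
    stop_ft("trailing tokens from '%s'", peek(), class = "flowtrees_parse_error")
  out
}

#' Truth-table equivalence of two Boolean trees
#'
#' Exhaustively evaluates both trees over every assignment of the variables
#' either tree references (at most 20) and reports whether they agree
#' everywhere.
#'
#' @param t1,t2 logic trees (or `NULL`).
#' @return `TRUE` or `FALSE`.
#' @export
truth_table_equivalence <- function(t1, t2) {
  vars <- sort(unique(c(tree_vars(t1), tree_vars(t2))))
  if (length(vars) > 20L)
    stop_ft("trees reference %d variables; at most 20 supported", length(vars),
            class = "flowtrees_size_error")
  if (!length(vars)) return(TRUE)  # both constant 0
  grid <- as.matrix(expand.grid(rep(list(0:1), length(vars))))
  x <- matrix(0L, nrow(grid), max(vars))
  x[, vars] <- grid
  identical(evaluate_tree(t1, x), evaluate_tree(t2, x))
}

#' Does a fitted logic model discriminate exactly like a Boolean rule?
#'
#' Computes the model's linear predictor over every assignment of the
#' variables referenced by the model or the rule, thresholds it at the
#' midpoint of its range, and compares the resulting indicator with the
#' rule's truth table.  This treats the model as a classifier of its
#' high-probability stratum; a model whose linear predictor is constant is
#' equivalent only to a constant rule.
#'
#' @param model a `logic_model`.
#' @param rule a logic tree.
#' @return `TRUE` or `FALSE`.
#' @export
model_matches_rule <- function(model, rule) {
  used <- sort(unique(c(unlist(lapply(model$trees, tree_vars)), tree_vars(rule))))
  if (!length(used)) return(is.null(rule))
  if (length(used) > 20L)
    stop_ft("too many referenced variables", class = "flowtrees_size_error")
  grid <- as.matrix(expand.grid(rep(list(0:1), length(used))))
  x <- matrix(0L, nrow(grid), max(used))
  x[, used] <- grid
  eta <- rep(model$intercept, nrow(x))
  for (k in seq_along(model$trees)) {
    b <- model$coefficients[k]
    if (!is.na(b)) eta <- eta + b * evaluate_tree(model$trees[[k]], x)
  }
  if (diff(range(eta)) < 1e-9) return(FALSE)
  f <- as.integer(eta > mean(range(eta)))
  identical(f, evaluate_tree(rule, x))
}

#' @export
print.logic_model <- function(x, digits = 3L, ...) {
  cat(sprintf("logic_model (%s link): deviance %.3f (null %.3f)\n",
              x$link, x$deviance, x$null_deviance))
  cat(sprintf("  intercept: %.*f\n", digits, x$intercept))
  for (k in seq_along(x$trees)) {
    b <- x$coefficients[k]
    tag <- if (is.na(b)) "dropped (constant/aliased)" else sprintf("%.*f", digits, b)
    cat(sprintf("  beta%d = %s   L%d = %s\n", k, tag, k,
                render_logic(x$trees[[k]], x$var_names)))
  }
  if (x$separation) cat("  note: separation; coefficients capped\n")
  invisible(x)
}

#' @export
coef.logic_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    setNames(object$coefficients, paste0("L", seq_along(object$coefficients))))
}

#' @export
predict.logic_model <- function(object, newdata, type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "analysis_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  eta <- rep(object$intercept, nrow(newdata))
  for (k in seq_along(object$trees)) {
    b <- object$coefficients[k]
    if (!is.na(b)) eta <- eta + b * evaluate_tree(object$trees[[k]], newdata)
  }
  mu <- if (object$link == "logit") plogis(eta) else eta
  switch(type, link = eta, response = mu, class = as.integer(mu > 0.5))
}

#' Serialize a logic model as JSON
#' @param model a `logic_model`.
#' @param path optional file path.
#' @export
logic_to_json <- function(model, path = NULL) {
  payload <- list(link = model$link, intercept = model$intercept,
                  coefficients = model$coefficients,
                  trees = vapply(model$trees, render_logic, "",
                                 vars = model$var_names),
                  deviance = model$deviance, score = model$score)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
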