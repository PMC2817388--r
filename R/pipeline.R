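# End-to-end orchestration: simulate (or read) -> preprocess -> univariate
# screen -> classification tree -> random forest -> logic regression ->
# report files.  One master seed determines every stochastic stage through
# independent per-stage seeds, so changing one stage's seed leaves the
# others byte-identical.

#' Read a subjects-by-variables CSV
#'
#' Expects a header row of variable names, one row per subject, numeric or
#' empty cells (empty means missing).
#'
#' @param path CSV path.
#' @return List with `values` (data frame) and `mask` (logical missingness
#'   matrix).
#' @export
read_dataset <- function(path) {
  values <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(values) == 0L)
    stop_ft("empty dataset: header only", class = "flowtrees_empty_dataset_error")
  if (anyDuplicated(colnames(values)))
    stop_ft("duplicate column name(s): %s",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
            class = "flowtrees_schema_error")
  for (j in seq_along(values)) {
    raw <- trimws(values[[j]])
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop_ft("non-numeric cell at row %d, column '%s': '%s'",
              bad[1L], colnames(values)[j], raw[bad[1L]],
              class = "flowtrees_parse_error")
    values[[j]] <- num
  }
  mask <- as.matrix(is.na(values))
  list(values = values, mask = mask)
}

#' Pipeline configuration
#'
#' A single nested list, serializable to/from JSON, that controls every
#' stage.  Unknown keys are rejected.
#'
#' @param input_csv path to an existing dataset, or `NULL` to simulate.
#' @param simulate list of [sim_config()] arguments plus an `outcome`
#'   sub-list of [outcome_spec()] arguments (used when `input_csv` is
#'   `NULL`).
#' @param outcome_column name of the week-36 CD4 count column.
#' @param screen list: `correct`, `pi0`.
#' @param cart list: `min_node`, `folds`, `rule`.
#' @param forest list: `n_trees`, `mtry`, `min_node`.
#' @param logicreg list: `n_trees`, `max_leaves`, `iterations`, `score`,
#'   `link`.
#' @param seeds optional per-stage seed overrides (`simulate`, `cart_cv`,
#'   `forest`, `perm`, `logic`); unset stages take seeds derived from the
#'   master seed, so overriding one stage leaves the others untouched.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL,
                            simulate = list(),
                            outcome_column = "CD4_wk36",
                            screen = list(),
                            cart = list(),
                            forest = list(),
                            logicreg = list(),
                            seeds = list(),
                            seed = 1L) {
  defaults <- list(
    input_csv = NULL,
    simulate = list(n_subjects = 78L, replicate_noise_sd = 1.5,
                    missing_rate = 0.05,
                    outcome = list(kind = "null", targets = character(),
                                   probs = 19 / 78,
                                   cd4_scale = list(meanlog = log(120),
                                                    sdlog = 0.5))),
    outcome_column = "CD4_wk36",
    screen = list(correct = TRUE, pi0 = 1),
    cart = list(min_node = 5L, folds = 10L, rule = "1se"),
    forest = list(n_trees = 500L, mtry = NULL, min_node = 1L),
    logicreg = list(n_trees = 2L, max_leaves = 6L, iterations = 50000L,
                    score = "deviance", link = "logit"),
    seeds = list(simulate = NULL, cart_cv = NULL, forest = NULL,
                 perm = NULL, logic = NULL),
    seed = 1L)
  user <- list(input_csv = input_csv, simulate = simulate,
               outcome_column = outcome_column, screen = screen,
               cart = cart, forest = forest, logicreg = logicreg,
               seeds = seeds, seed = seed)
  cfg <- merge_config(defaults, user)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_ft("unknown configuration key '%s$%s'", path, unknown[1L],
            class = "flowtrees_config_error")
  for (key in names(user)) {
    v <- user[[key]]
    if (is.list(v) && is.list(defaults[[key]]) && length(names(defaults[[key]])))
      defaults[[key]] <- merge_config(defaults[[key]], v, paste0(path, "$", key))
    else if (!is.null(v)) defaults[[key]] <- v
  }
  defaults
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file.
#' @param config a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full discovery pipeline
#'
#' Executes all four analyses on the same preprocessed matrix and writes the
#' report artifacts into `output_dir`: the screen table
#' (`screen.csv`), the pruned and cross-validated classification tree
#' (`cart.txt`, `cart.json`), the forest importance table
#' (`importance.csv`), the logic model (`logic.txt`, `logic.json`) and a
#' machine-readable `summary.json`.  Rerunning with the same configuration
#' and inputs reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for report files (created if needed);
#'   `NULL` skips file output.
#' @return A list of class `analysis_report` with elements `screen`,
#'   `cart`, `cart_cv`, `forest`, `importance`, `logic`, `data`, `matrix`
#'   and `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  seeds <- setNames(as.list(draw_seeds(5L)),
                    c("simulate", "cart_cv", "forest", "perm", "logic"))
  for (nm in names(seeds))
    if (!is.null(config$seeds[[nm]])) seeds[[nm]] <- as.integer(config$seeds[[nm]])
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  data <- run_stage("data", {
    if (!is.null(config$input_csv)) {
      stage_log("data", "reading %s", config$input_csv)
      raw <- read_dataset(config$input_csv)
      structure(list(values = raw$values, design = NULL, config = NULL,
                     acquisitions = NULL, mask = raw$mask, truth = NULL),
                class = "flow_dataset")
    } else {
      sc <- config$simulate
      stage_log("data", "simulating %d subjects (seed %d)",
                sc$n_subjects, seeds$simulate)
      spec <- do.call(outcome_spec, sc$outcome)
      ds <- simulate_panel(panel_design(),
                           sim_config(n_subjects = sc$n_subjects,
                                      replicate_noise_sd = sc$replicate_noise_sd,
                                      missing_rate = sc$missing_rate,
                                      outcome = spec, seed = seeds$simulate))
      ds <- simulate_outcome(ds, spec, seed = seeds$simulate)
      inject_missing(ds, rate = sc$missing_rate, seed = seeds$simulate)
    }
  })

  am <- run_stage("preprocess", {
    stage_log("preprocess", "dichotomizing and imputing")
    build_analysis_matrix(data, outcome_column = config$outcome_column)
  })

  screen <- run_stage("univariate", {
    stage_log("univariate", "screening %d predictors", ncol(am$X))
    univariate_screen(am, correct = config$screen$correct, pi0 = config$screen$pi0)
  })

  cart_full <- run_stage("cart", {
    stage_log("cart", "growing tree (min_node = %d)", config$cart$min_node)
    grow_tree(am, min_node = config$cart$min_node)
  })
  cart_cv <- run_stage("cart", {
    select_subtree_cv(am, min_node = config$cart$min_node,
                      folds = config$cart$folds, rule = config$cart$rule,
                      seed = seeds$cart_cv)
  })

  forest <- run_stage("rf", {
    stage_log("rf", "growing %d trees (seed %d)", config$forest$n_trees, seeds$forest)
    grow_forest(am, config = forest_config(n_trees = config$forest$n_trees,
                                           mtry = config$forest$mtry,
                                           min_node = config$forest$min_node,
                                           seed = seeds$forest))
  })
  imp <- run_stage("rf", importance_table(forest, seed = seeds$perm))

  logic <- run_stage("logicreg", {
    lg <- config$logicreg
    stage_log("logicreg", "annealing %d iterations (seed %d)",
              lg$iterations, seeds$logic)
    anneal_search(am, config = anneal_config(n_trees = lg$n_trees,
                                             max_leaves = lg$max_leaves,
                                             iterations = lg$iterations,
                                             score = lg$score, link = lg$link,
                                             seed = seeds$logic))
  })

  report <- structure(list(screen = screen, cart = cart_full, cart_cv = cart_cv,
                           forest = forest, importance = imp, logic = logic,
                           data = data, matrix = am, seeds = seeds,
                           config = config),
                      class = "analysis_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== analysis report ==\n\n-- univariate screen --\n")
  print(x$screen, n = 5L)
  cat("\n-- classification tree (unpruned) --\n")
  print(x$cart)
  cat(sprintf("\n-- cross-validated tree: %d leaves --\n", n_leaves(x$cart_cv)))
  cat("\n-- random forest --\n")
  print(x$forest)
  cat("  top importance:\n")
  print(head(as.data.frame(x$importance), 5L), row.names = FALSE)
  cat("\n-- logic regression --\n")
  print(x$logic)
  invisible(x)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(output_dir, f)
  write_screen(report$screen, fp("screen.csv"))
  writeLines(utils::capture.output(print(report$cart)), fp("cart.txt"))
  tree_to_json(report$cart_cv, fp("cart.json"))
  write.csv(as.data.frame(report$importance), fp("importance.csv"),
            row.names = FALSE)
  writeLines(utils::capture.output(print(report$logic)), fp("logic.txt"))
  logic_to_json(report$logic, fp("logic.json"))
  summary <- list(
    seeds = report$seeds,
    n_subjects = nrow(report$matrix$X),
    n_predictors = ncol(report$matrix$X),
    top_screen = head(as.data.frame(report$screen), 5L),
    cart_leaves_unpruned = n_leaves(report$cart),
    cart_leaves_cv = n_leaves(report$cart_cv),
    oob_error = oob_error(report$forest)$aggregate,
    top_importance = head(as.data.frame(report$importance), 5L),
    logic = list(intercept = report$logic$intercept,
                 coefficients = report$logic$coefficients,
                 trees = vapply(report$logic$trees, render_logic, "",
                                vars = report$logic$var_names),
                 deviance = report$logic$deviance))
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(output_dir)
}
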