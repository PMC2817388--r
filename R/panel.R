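# Synthetic flow-cytometry panel generator.
#
# The simulator emulates a 4-colour staining panel summarised as 2x2 quadrant
# percentages: each staining contributes four "percent of gated" variables
# that sum to 100 for every subject, which induces the strong negative
# correlations between complementary quadrants that are characteristic of
# quadrant-gated data.  Outcome signals are planted on the *dichotomized*
# (above/below median) versions of chosen variables, so the ground truth is
# known exactly and every downstream analysis stage can be evaluated.

#' Default staining-panel design
#'
#' Builds the panel layout used throughout the package: 16 quadrant sets
#' (a first CD3/CD8- or CD3/HLA-DR-style gate per staining plus quadrant sets
#' nested within gates of interest), yielding 63 reported flow variables plus
#' one baseline CD4 count column.  One quadrant (`CD3+CD8+CD7-CD154+`) is
#' simulated for compositional closure but not reported, mirroring panels in
#' which a quadrant is not tabulated.
#'
#' @param stainings optional character vector of staining names to retain,
#'   for reduced panels; `NULL` keeps the full design.
#' @return An object of class `panel_design`: a list with elements
#'   `stainings` (each a list with `name`, `markers`, `variables`,
#'   `replicated`, `dropped`, `concentration`) and `cd4_baseline`, the name
#'   of the baseline CD4 count column.
#' @examples
#' d <- panel_design()
#' length(panel_variables(d))  # 63
#' @export
panel_design <- function(stainings = NULL) {
  st <- function(name, markers, vars, conc, replicated = FALSE, dropped = character()) {
    stopifnot(length(vars) == 4L, length(conc) == 4L, all(conc > 0))
    list(name = name, markers = markers, variables = vars,
         concentration = conc, replicated = replicated, dropped = dropped)
  }
  all_st <- list(
    st("CD3xCD8", c("CD3", "CD8"),
       c("CD3-CD8-", "CD3+CD8-", "CD3-CD8+", "CD3+CD8+"),
       c(6, 10, 3, 11), replicated = TRUE),
    st("CD45RAxCD62L.CD8neg", c("CD45RA", "CD62L"),
       c("CD3+CD8-CD45RA+CD62L+", "CD3+CD8-CD45RA+CD62L-",
         "CD3+CD8-CD45RA-CD62L+", "CD3+CD8-CD45RA-CD62L"),
       c(8, 5, 7, 5)),
    st("CD45RAxCD62L.CD8pos", c("CD45RA", "CD62L"),
       c("CD3+CD8+CD45RA+CD62L+", "CD3+CD8+CD45RA+CD62L-",
         "CD3+CD8+CD45RA-CD62L+", "CD3+CD8+CD45RA-CD62L"),
       c(7, 8, 4, 6)),
    st("CD38xCD28.CD8neg", c("CD38", "CD28"),
       c("CD3+CD8-CD38+CD28+", "CD3+CD8-CD38+CD28-",
         "CD3+CD8-CD38-CD28+", "CD3+CD8-CD38-CD28-"),
       c(10, 3, 8, 4)),
    st("CD38xCD28.CD8pos", c("CD38", "CD28"),
       c("CD3+CD8+CD38+CD28+", "CD3+CD8+CD38+CD28-",
         "CD3+CD8+CD38-CD28+", "CD3+CD8+CD38-CD28-"),
       c(9, 6, 4, 5)),
    st("DRxCD95.CD8neg", c("HLA-DR", "CD95"),
       c("CD3+CD8-DR+CD95+", "CD3+CD8-DR+CD95-",
         "CD3+CD8-DR-CD95+", "CD3+CD8-DR-CD95-"),
       c(5, 3, 9, 8)),
    st("DRxCD95.CD8pos", c("HLA-DR", "CD95"),
       c("CD3+CD8+DR+CD95+", "CD3+CD8+DR+CD95-",
         "CD3+CD8+DR-CD95+", "CD3+CD8+DR-CD95-"),
       c(8, 3, 8, 5)),
    st("CD3xDR", c("CD3", "HLA-DR"),
       c("CD3-DR-", "CD3-DR+", "CD3+DR-", "CD3+DR+"),
       c(7, 3, 10, 4)),
    st("CD56xCD16.DRneg", c("CD56", "CD16"),
       c("CD3-DR-CD56+CD16+", "CD3-DR-CD56+CD16-",
         "CD3-DR-CD56-CD16+", "CD3-DR-CD56-CD16-"),
       c(9, 2, 2, 9)),
    st("CD56xCD16.DRpos", c("CD56", "CD16"),
       c("CD3-DR+CD56+CD16+", "CD3-DR+CD56+CD16-",
         "CD3-DR+CD56-CD16+", "CD3-DR+CD56-CD16-"),
       c(4, 3, 5, 10)),
    st("CD7xCD154.CD8neg", c("CD7", "CD154"),
       c("CD3+CD8-CD7+CD154+", "CD3+CD8-CD7+CD154-",
         "CD3+CD8-CD7-CD154+", "CD3+CD8-CD7-CD154-"),
       c(6, 10, 2, 5)),
    st("CD7xCD154.CD8pos", c("CD7", "CD154"),
       c("CD3+CD8+CD7+CD154+", "CD3+CD8+CD7+CD154-",
         "CD3+CD8+CD7-CD154+", "CD3+CD8+CD7-CD154-"),
       c(5, 11, 2, 5), dropped = "CD3+CD8+CD7-CD154+"),
    st("CD45xCD3", c("CD45", "CD3"),
       c("CD45+CD3+", "CD45+CD3-", "CD45-CD3+", "CD45-CD3-"),
       c(14, 7, 2, 2)),
    st("CD8xCD4.T", c("CD8", "CD4"),
       c("CD45+CD3+CD8+CD4+", "CD45+CD3+CD8+CD4-",
         "CD45+CD3+CD8-CD4+", "CD45+CD3+CD8-CD4-"),
       c(2, 11, 10, 2)),
    st("LinxDR", c("Lin-1", "HLA-DR"),
       c("Lin+DR+", "Lin+DR-", "Lin-DR+", "Lin-DR-"),
       c(10, 7, 3, 5)),
    st("CD123xCD11c.DC", c("CD123", "CD11c"),
       c("Lin-DR+CD123+CD11c+", "Lin-DR+CD123+CD11c-",
         "Lin-DR+CD123-CD11c+", "Lin-DR+CD123-CD11c-"),
       c(4, 6, 7, 4))
  )
  names(all_st) <- vapply(all_st, `[[`, "", "name")
  if (!is.null(stainings)) {
    unknown <- setdiff(stainings, names(all_st))
    if (length(unknown))
      stop_ft("unknown staining(s): %s", paste(unknown, collapse = ", "),
              class = "flowtrees_design_error")
    all_st <- all_st[stainings]
  }
  design <- structure(list(stainings = unname(all_st), cd4_baseline = "CD4+"),
                      class = "panel_design")
  vars <- panel_variables(design)
  if (anyDuplicated(vars))
    stop_ft("duplicate quadrant variables in design", class = "flowtrees_design_error")
  if (is.null(stainings) && length(vars) != 63L)
    stop_ft("default design must report 63 flow variables, got %d", length(vars),
            class = "flowtrees_design_error")
  design
}

#' Reported flow variables of a panel design
#'
#' @param design a `panel_design`.
#' @return Character vector of reported quadrant variable names (dropped
#'   quadrants excluded; baseline CD4 column not included).
#' @export
panel_variables <- function(design) {
  unlist(lapply(design$stainings, function(s) setdiff(s$variables, s$dropped)),
         use.names = FALSE)
}

#' Simulation configuration for the panel generator
#'
#' @param n_subjects number of subjects (default 78, the size of a completed
#'   trial cohort this simulator is calibrated to).
#' @param concentration optional named list of per-staining positive
#'   quadrant weights (Dirichlet-type concentrations); defaults come from the
#'   design.  Partial lists are merged over the defaults.
#' @param replicate_noise_sd acquisition-to-acquisition Gaussian noise, in
#'   percent units, for replicated stainings (default 1.5).
#' @param missing_rate probability in \[0, 1) that a flow value is masked
#'   (default 0.05).
#' @param outcome outcome specification from [outcome_spec()], or `NULL`.
#' @param seed integer seed controlling all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 78L, concentration = NULL,
                       replicate_noise_sd = 1.5, missing_rate = 0.05,
                       outcome = outcome_spec(), seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop_ft("n_subjects must be a positive integer", class = "flowtrees_config_error")
  if (replicate_noise_sd < 0)
    stop_ft("replicate_noise_sd must be nonnegative", class = "flowtrees_config_error")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_ft("missing_rate must lie in [0, 1)", class = "flowtrees_config_error")
  if (!is.null(concentration)) {
    bad <- vapply(concentration, function(w) any(!is.finite(w) | w <= 0), TRUE)
    if (any(bad))
      stop_ft("concentration weights must be strictly positive", class = "flowtrees_config_error")
  }
  structure(list(n_subjects = as.integer(n_subjects), concentration = concentration,
                 replicate_noise_sd = replicate_noise_sd, missing_rate = missing_rate,
                 outcome = outcome, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted outcome specification
#'
#' Describes how the binary responder status (week-36 CD4 count above
#' 450 cells/uL) is generated from the dichotomized values of up to three
#' target variables.
#'
#' @param kind one of `"null"` (constant responder probability),
#'   `"marginal"` (one target), `"conditional"` (two targets, arbitrary
#'   stratum probabilities) or `"interaction"` (two targets in an XOR
#'   structure: equal probabilities within XOR strata, so that with balanced
#'   targets neither has a marginal effect).
#' @param targets character vector of 0-3 target variable names.
#' @param probs responder probabilities in (0, 1): one value for `"null"`;
#'   for the other kinds a vector named by stratum label, where the label is
#'   the concatenated 0/1 codes of the targets in order (e.g. `"10"` means
#'   first target above its median and second below).
#' @param cd4_scale lognormal scale for the simulated week-36 CD4 count:
#'   responders are drawn as `450 + rlnorm(meanlog, sdlog)`, nonresponders
#'   as `450 - min(rlnorm(meanlog, sdlog), 450)`, so the count straddles the
#'   450 threshold exactly as the responder status dictates.
#' @return A list of class `outcome_spec`.
#' @examples
#' outcome_spec("marginal", "CD3-DR-CD56+CD16+", c("0" = 15/39, "1" = 4/39))
#' @export
outcome_spec <- function(kind = c("null", "marginal", "conditional", "interaction"),
                         targets = character(), probs = 19 / 78,
                         cd4_scale = list(meanlog = log(120), sdlog = 0.5)) {
  kind <- match.arg(kind)
  k <- length(targets)
  need <- switch(kind, null = 0L, marginal = 1L, conditional = 2L, interaction = 2L)
  if (k != need)
    stop_ft("kind '%s' requires %d target variable(s), got %d", kind, need, k,
            class = "flowtrees_spec_error")
  if (any(probs <= 0 | probs >= 1))
    stop_ft("responder probabilities must lie strictly in (0, 1)",
            class = "flowtrees_spec_error")
  if (kind == "null") {
    if (length(probs) != 1L)
      stop_ft("null outcome takes a single probability", class = "flowtrees_spec_error")
    probs <- setNames(unname(probs), "")
  } else {
    labs <- strata_labels(need)
    if (!setequal(names(probs), labs))
      stop_ft("probs must be named by stratum labels: %s", paste(labs, collapse = ", "),
              class = "flowtrees_spec_error")
    probs <- probs[labs]
  }
  if (kind == "interaction") {
    if (!isTRUE(all.equal(unname(probs["00"]), unname(probs["11"]))) ||
        !isTRUE(all.equal(unname(probs["01"]), unname(probs["10"]))))
      stop_ft("interaction outcome requires probs constant within XOR strata (p00 = p11, p01 = p10)",
              class = "flowtrees_spec_error")
  }
  structure(list(kind = kind, targets = targets, probs = probs, cd4_scale = cd4_scale),
            class = "outcome_spec")
}

strata_labels <- function(k) {
  if (k == 0L) return("")
  apply(as.matrix(expand.grid(rep(list(0:1), k))), 1L, paste, collapse = "")
}

# draw one compositional block: n x 4 Dirichlet(conc) * 100 via gamma draws
draw_composition <- function(n, conc) {
  g <- matrix(rgamma(n * 4L, shape = rep(conc, each = n)), nrow = n)
  100 * g / rowSums(g)
}

#' Simulate a flow-cytometry panel
#'
#' Draws, for each staining, a four-quadrant composition per subject from a
#' gamma-based (Dirichlet-type) distribution scaled to 100, so quadrants sum
#' to exactly 100 and complementary quadrants are negatively correlated.  For
#' replicated stainings four noisy acquisitions are generated, each
#' renormalized to 100, and their per-subject mean is stored (the acquisitions
#' themselves are kept in the returned object).  A baseline CD4 count column
#' (cells/uL, uniform over the 200-350 eligibility window) is appended.
#'
#' @param design a [panel_design()].
#' @param config a [sim_config()].
#' @return An object of class `flow_dataset`: list with `values` (data frame,
#'   subjects x variables), `design`, `config`, `acquisitions`, `mask`
#'   (logical missingness matrix over `values`), `truth` (`NULL` until
#'   [simulate_outcome()] is applied).
#' @examples
#' ds <- simulate_panel(panel_design(), sim_config(n_subjects = 10, seed = 7))
#' dim(ds$values)  # 10 x 64
#' @export
simulate_panel <- function(design, config = sim_config()) {
  stopifnot(inherits(design, "panel_design"), inherits(config, "sim_config"))
  if (length(design$stainings) == 0L)
    stop_ft("empty panel design", class = "flowtrees_design_error")
  n <- config$n_subjects
  set.seed(config$seed)
  conc <- lapply(design$stainings, `[[`, "concentration")
  names(conc) <- vapply(design$stainings, `[[`, "", "name")
  if (!is.null(config$concentration)) {
    unknown <- setdiff(names(config$concentration), names(conc))
    if (length(unknown))
      stop_ft("concentration given for unknown staining(s): %s",
              paste(unknown, collapse = ", "), class = "flowtrees_config_error")
    conc[names(config$concentration)] <- config$concentration
  }
  values <- list()
  acquisitions <- list()
  for (s in design$stainings) {
    comp <- draw_composition(n, conc[[s$name]])
    colnames(comp) <- s$variables
    if (s$replicated) {
      acqs <- lapply(1:4, function(r) {
        noisy <- comp + matrix(rnorm(n * 4L, sd = config$replicate_noise_sd), nrow = n)
        noisy <- pmax(noisy, 0)
        out <- 100 * noisy / rowSums(noisy)
        colnames(out) <- s$variables
        out
      })
      acquisitions[[s$name]] <- acqs
      comp <- average_replicates(acqs)
    }
    keep <- setdiff(s$variables, s$dropped)
    for (v in keep) values[[v]] <- comp[, v]
  }
  values[[design$cd4_baseline]] <- round(runif(n, 200, 350))
  values <- as.data.frame(values, check.names = FALSE, optional = TRUE)
  rownames(values) <- sprintf("S%03d", seq_len(n))
  ds <- structure(list(values = values, design = design, config = config,
                       acquisitions = acquisitions,
                       mask = matrix(FALSE, n, ncol(values),
                                     dimnames = dimnames(values)),
                       truth = NULL),
                  class = "flow_dataset")
  ds
}

#' Attach a simulated clinical outcome to a panel dataset
#'
#' Dichotomizes the target variables of `spec` at their sample medians,
#' assigns each subject a stratum, draws responder status Bernoulli with the
#' stratum probability, and appends a `CD4_wk36` count column that is above
#' 450 cells/uL exactly for responders.  The realized strata, responder
#' statuses and target medians are recorded in `$truth`.
#'
#' @param dataset a `flow_dataset`.
#' @param spec an [outcome_spec()].
#' @param seed integer seed.
#' @return The dataset with `CD4_wk36` appended and `$truth` filled in.
#' @export
simulate_outcome <- function(dataset, spec = outcome_spec(), seed = 1L) {
  stopifnot(inherits(dataset, "flow_dataset"), inherits(spec, "outcome_spec"))
  vals <- dataset$values
  missing_vars <- setdiff(spec$targets, colnames(vals))
  if (length(missing_vars))
    stop_ft("unknown target variable(s): %s", paste(missing_vars, collapse = ", "),
            class = "flowtrees_unknown_variable_error")
  n <- nrow(vals)
  set.seed(seed)
  if (length(spec$targets)) {
    meds <- vapply(spec$targets, function(v) median(vals[[v]], na.rm = TRUE), 0)
    bits <- vapply(spec$targets, function(v) as.integer(vals[[v]] > meds[[v]]),
                   integer(n))
    strata <- apply(matrix(bits, nrow = n), 1L, paste, collapse = "")
  } else {
    meds <- numeric(0)
    strata <- rep("", n)
  }
  p <- if (spec$kind == "null") rep(unname(spec$probs), n) else unname(spec$probs[strata])
  responder <- rbinom(n, 1L, p)
  sc <- spec$cd4_scale
  shift <- rlnorm(n, sc$meanlog, sc$sdlog)
  cd4 <- ifelse(responder == 1L, 450 + shift, 450 - pmin(shift, 450))
  vals$CD4_wk36 <- round(cd4)
  dataset$values <- vals
  dataset$mask <- cbind(dataset$mask, CD4_wk36 = rep(FALSE, n))
  dataset$truth <- list(spec = spec, strata = strata, responder = responder,
                        target_medians = meds, seed = seed)
  dataset
}

#' Inject missing values into the flow variables
#'
#' Masks each flow-variable cell independently with probability `rate`
#' (missing completely at random).  The outcome column, the baseline CD4
#' count and the recorded truth are never masked.
#'
#' @param dataset a `flow_dataset`.
#' @param rate masking probability in \[0, 1).
#' @param seed integer seed.
#' @return The dataset with `NA`s in `values` and the mask recorded.
#' @export
inject_missing <- function(dataset, rate = 0.05, seed = 1L) {
  stopifnot(inherits(dataset, "flow_dataset"))
  if (rate < 0 || rate >= 1)
    stop_ft("missing rate must lie in [0, 1)", class = "flowtrees_config_error")
  if (rate == 0) return(dataset)
  flow_vars <- panel_variables(dataset$design)
  set.seed(seed)
  n <- nrow(dataset$values)
  for (v in flow_vars) {
    hit <- runif(n) < rate
    dataset$values[[v]][hit] <- NA_real_
    dataset$mask[, v] <- dataset$mask[, v] | hit
  }
  dataset
}

#' @export
print.flow_dataset <- function(x, ...) {
  cat(sprintf("flow_dataset: %d subjects x %d variables (%d flow)\n",
              nrow(x$values), ncol(x$values), length(panel_variables(x$design))))
  if (!is.null(x$truth))
    cat(sprintf("  outcome: %s (%s)\n", x$truth$spec$kind,
                paste(x$truth$spec$targets, collapse = ", ")))
  n_miss <- sum(x$mask)
  if (n_miss) cat(sprintf("  missing cells: %d\n", n_miss))
  invisible(x)
}

#' Write / read a dataset as CSV plus a JSON truth sidecar
#'
#' The CSV has a header of variable names, one row per subject and empty
#' cells for missing values.  The sidecar (same path with `_truth.json`
#' appended to the stem) records the outcome specification and realized
#' truth so that simulated datasets round-trip.
#'
#' @param dataset a `flow_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_flow_dataset`
#'   returns a `flow_dataset` (with `design`/`acquisitions` absent when the
#'   CSV did not come from this simulator).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "flow_dataset"))
  write.csv(dataset$values, path, row.names = FALSE, na = "")
  sidecar <- paste0(sub("\\.csv$", "", path), "_truth.json")
  truth <- dataset$truth
  payload <- list(
    n_subjects = nrow(dataset$values),
    seed = dataset$config$seed,
    outcome = if (!is.null(truth)) list(
      kind = truth$spec$kind, targets = truth$spec$targets,
      probs = as.list(truth$spec$probs), strata = truth$strata,
      responder = truth$responder, target_medians = as.list(truth$target_medians)
    )
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_flow_dataset <- function(path) {
  raw <- read_dataset(path)
  sidecar <- paste0(sub("\\.csv$", "", path), "_truth.json")
  truth <- NULL
  if (file.exists(sidecar)) {
    payload <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(payload$outcome)) {
      o <- payload$outcome
      truth <- list(spec = outcome_spec(o$kind, unlist(o$targets) %||% character(),
                                        unlist(o$probs)),
                    strata = o$strata, responder = o$responder,
                    target_medians = unlist(o$target_medians))
    }
  }
  structure(list(values = raw$values, design = NULL, config = NULL,
                 acquisitions = NULL, mask = raw$mask, truth = truth),
            class = "flow_dataset")
}
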