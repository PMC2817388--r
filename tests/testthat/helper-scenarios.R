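# Shared scenario generators (planted-signal panels) and brute-force oracles.

TARGET1 <- "CD3-DR-CD56+CD16+"   # NK-gate quadrant used as the primary target
TARGET2 <- "Lin-DR-"             # lineage-negative target in another staining

# simulate a panel, attach an outcome, preprocess; returns the analysis
# matrix plus target column indices
make_scenario <- function(spec, n, seed, design = panel_design(),
                          missing_rate = 0) {
  ds <- simulate_panel(design, sim_config(n_subjects = n, outcome = spec,
                                          seed = seed))
  ds <- simulate_outcome(ds, spec, seed = seed + 1L)
  if (missing_rate > 0) ds <- inject_missing(ds, missing_rate, seed = seed + 2L)
  am <- build_analysis_matrix(ds)
  list(am = am, dataset = ds,
       idx = match(spec$targets, colnames(am$X)))
}

spec_null <- function(p0 = 19 / 78) outcome_spec("null", probs = p0)

spec_marginal <- function(p_low = 0.85, p_high = 0.15)
  outcome_spec("marginal", TARGET1, c("0" = p_low, "1" = p_high))

# TARGET2 matters only where TARGET1 is low; TARGET1's marginal effect
# (0.475 vs 0.05) dominates TARGET2's induced one (0.375 vs 0.15), so the
# planted hierarchy root -> nested split is unambiguous
spec_conditional <- function()
  outcome_spec("conditional", c(TARGET1, TARGET2),
               c("00" = 0.70, "01" = 0.25, "10" = 0.05, "11" = 0.05))

# responder-enriched stratum is exactly (TARGET1 high) and (TARGET2 low)
spec_andnot <- function()
  outcome_spec("conditional", c(TARGET1, TARGET2),
               c("00" = 0.10, "01" = 0.10, "10" = 0.85, "11" = 0.10))

XOR_T1 <- "CD3+CD8-CD38+CD28+"
XOR_T2 <- "Lin-DR+CD123+CD11c+"
xor_design <- function() panel_design(c("CD38xCD28.CD8neg", "CD123xCD11c.DC"))
spec_xor <- function()
  outcome_spec("interaction", c(XOR_T1, XOR_T2),
               c("00" = 0.15, "01" = 0.85, "10" = 0.85, "11" = 0.15))

# subjects x 1 predictor raw data whose median split against the responder
# status reproduces the 2x2 table (a, b, c, d) = (4, 35, 15, 24)
published_split_raw <- function() {
  marker <- c(seq_len(39), 61 + seq_len(39))        # 39 low, 39 high; median 50.5
  responder <- c(rep(c(1, 0), c(15, 24)),           # low half: 15 responders
                 rep(c(1, 0), c(4, 35)))            # high half: 4 responders
  data.frame(marker = marker,
             CD4_wk36 = ifelse(responder == 1, 600, 300))
}

# exhaustive split oracle: direct evaluation of the impurity reduction for
# every variable, independent of the vectorized implementation
oracle_best_split <- function(x, y, min_child = 1L) {
  n <- length(y)
  imp <- function(yy) {
    p <- mean(yy)
    2 * p * (1 - p)
  }
  phis <- rep(-Inf, ncol(x))
  for (j in seq_len(ncol(x))) {
    l <- y[x[, j] == 1]
    r <- y[x[, j] == 0]
    if (length(l) < min_child || length(r) < min_child) next
    phis[j] <- imp(y) - (length(l) / n) * imp(l) - (length(r) / n) * imp(r)
  }
  if (max(phis) <= 1e-15) return(NULL)
  list(var = which.max(phis), phi = max(phis), phis = phis)
}

# all pruned subtrees of a flowcart as (risk, size) pairs, by dynamic
# programming over the node lattice
oracle_subtree_profiles <- function(tree) {
  f <- tree$frame
  rec <- function(id) {
    i <- match(id, f$id)
    leaf_opt <- data.frame(risk = f$prob[i] * min(f$p_hat[i], 1 - f$p_hat[i]),
                           size = 1L)
    if (f$leaf[i]) return(leaf_opt)
    l <- rec(f$left[i]); r <- rec(f$right[i])
    combos <- merge(l, r, by = NULL)
    rbind(leaf_opt,
          data.frame(risk = combos$risk.x + combos$risk.y,
                     size = combos$size.x + combos$size.y))
  }
  rec(f$id[1])
}

# minimum penalized risk over all pruned subtrees at complexity alpha
oracle_min_cost <- function(profiles, alpha) min(profiles$risk + alpha * profiles$size)
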