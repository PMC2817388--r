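# Univariate contingency screen: per-variable 2x2 tables, odds ratios,
# Pearson chi-square tests, and multiplicity adjustments (Benjamini-Yekutieli
# and pFDR q-values).

#' Tabulate a binary exposure against the binary outcome
#'
#' Cell layout: `a` = exposed responders (x = 1, y = 1), `b` = exposed
#' nonresponders, `c` = unexposed responders, `d` = unexposed nonresponders.
#'
#' @param x binary exposure vector (1 = above median).
#' @param y binary outcome vector (1 = responder).
#' @return Object of class `table2x2`: named integer vector (a, b, c, d).
#' @examples
#' tabulate_2x2(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
tabulate_2x2 <- function(x, y) {
  if (length(x) != length(y))
    stop_ft("exposure and outcome lengths differ", class = "flowtrees_shape_error")
  if (anyNA(x) || anyNA(y))
    stop_ft("tabulate_2x2 expects complete data", class = "flowtrees_input_error")
  x <- as.integer(x); y <- as.integer(y)
  structure(c(a = sum(x == 1L & y == 1L), b = sum(x == 1L & y == 0L),
              c = sum(x == 0L & y == 1L), d = sum(x == 0L & y == 0L)),
            class = "table2x2")
}

#' Odds ratio of a 2x2 table
#'
#' The odds of response given exposure over the odds of response given no
#' exposure, i.e. `(a d) / (b c)`.  With a zero cell the ratio is reported
#' as `Inf` or `0`; if both products vanish the value is `NaN` with an
#' `"undefined"` attribute.  An optional Haldane correction adds 0.5 to
#' every cell (off by default).
#'
#' @param t a `table2x2` or a numeric vector (a, b, c, d).
#' @param haldane add 0.5 to each cell before forming the ratio.
#' @return The odds ratio.
#' @examples
#' odds_ratio(tabulate_2x2(rep(c(1, 0), c(39, 39)),
#'                         rep(c(1, 0, 1, 0), c(4, 35, 15, 24))))  # 0.183
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  t <- as.numeric(t)
  if (haldane) t <- t + 0.5
  num <- t[1] * t[4]; den <- t[2] * t[3]
  if (den == 0 && num == 0)
    return(structure(NaN, undefined = TRUE))
  if (den == 0) return(Inf)
  num / den
}

#' Pearson chi-square test for a 2x2 table
#'
#' One-degree-of-freedom Pearson statistic
#' `n (|ad - bc| - h)^2 / ((a+b)(c+d)(a+c)(b+d))`, with `h = n/2` under the
#' Yates continuity correction (the default) and `h = 0` otherwise; the
#' corrected `|ad - bc| - h` is floored at zero.  The p-value is the upper
#' tail of the chi-square distribution with one degree of freedom.
#'
#' @param t a `table2x2` or numeric vector (a, b, c, d).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_test <- function(t, correct = TRUE) {
  t <- as.numeric(t)
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n == 0 || any(margins == 0))
    stop_ft("degenerate 2x2 table: a zero margin", class = "flowtrees_degenerate_table_error")
  h <- if (correct) n / 2 else 0
  num <- max(abs(a * d - b * c) - h, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' Adjusted values `min over j >= rank of (m c(m) / j) p_(j)` capped at 1,
#' with `c(m) = sum_{k=1..m} 1/k`; valid under arbitrary dependence among
#' the tests.  Input order is preserved.
#'
#' @param p_values p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
adjust_benjamini_yekutieli <- function(p_values) {
  check_probs(p_values)
  p.adjust(p_values, method = "BY")
}

#' q-values via a positive false discovery rate adjustment
#'
#' Step-up q-values `q_(j) = min over i >= j of pi0 m p_(i) / i`, capped at
#' 1.  With `pi0 = 1` (the default) this is the Benjamini-Hochberg
#' adjustment; `pi0 = "estimate"` uses the Storey estimator with lambda =
#' 0.5, `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p_values p-values in \[0, 1\].
#' @param pi0 proportion of true nulls in (0, 1\], or `"estimate"`.
#' @return q-values in the input order.
#' @export
qvalue_pfdr <- function(p_values, pi0 = 1) {
  check_probs(p_values)
  if (identical(pi0, "estimate"))
    pi0 <- min(1, mean(p_values > 0.5) / 0.5)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop_ft("pi0 must lie in (0, 1]", class = "flowtrees_domain_error")
  pmin(pi0 * p.adjust(p_values, method = "BH"), 1)
}

check_probs <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_ft("p-values must lie in [0, 1]", class = "flowtrees_domain_error")
  invisible(p)
}

#' Univariate contingency screen over all predictors
#'
#' For each column of the analysis matrix: the 2x2 table against the
#' outcome, odds ratio, Pearson chi-square test, Benjamini-Yekutieli
#' adjusted p-value and pFDR q-value.  Results are sorted by ascending
#' p-value with ties broken lexicographically by variable name.
#'
#' @param am an `analysis_matrix` (or a 0/1 matrix, in which case `y` must
#'   be supplied).
#' @param y binary outcome; taken from `am` when it is an `analysis_matrix`.
#' @param correct continuity correction flag passed to [chi_square_test()].
#' @param pi0 passed to [qvalue_pfdr()].
#' @return A data frame of class `univariate_screen` with columns
#'   `variable`, `odds_ratio`, `chi2`, `p_value`, `p_by`, `q_value`, `rank`.
#' @export
univariate_screen <- function(am, y = NULL, correct = TRUE, pi0 = 1) {
  if (inherits(am, "analysis_matrix")) {
    X <- am$X
    y <- as.integer(am$y)
  } else {
    X <- as.matrix(am)
    if (is.null(y)) stop_ft("y required when am is a plain matrix",
                            class = "flowtrees_input_error")
    y <- as.integer(y)
  }
  vars <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
  rows <- lapply(seq_len(ncol(X)), function(j) {
    t <- tabulate_2x2(X[, j], y)
    ct <- tryCatch(chi_square_test(t, correct = correct),
                   flowtrees_degenerate_table_error = function(e)
                     list(statistic = NA_real_, p_value = NA_real_))
    data.frame(variable = vars[j], odds_ratio = odds_ratio(t),
               chi2 = ct$statistic, p_value = ct$p_value)
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p_value)
  res$p_by <- res$q_value <- NA_real_
  res$p_by[ok] <- adjust_benjamini_yekutieli(res$p_value[ok])
  res$q_value[ok] <- qvalue_pfdr(res$p_value[ok], pi0 = pi0)
  ord <- order(res$p_value, res$variable)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("univariate_screen", "data.frame")
  res
}

#' @export
print.univariate_screen <- function(x, n = 10L, ...) {
  cat(sprintf("univariate screen: %d predictors (showing top %d by p-value)\n",
              nrow(x), min(n, nrow(x))))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))), ]
  df$odds_ratio <- sprintf("%.3f", df$odds_ratio)
  for (cn in c("chi2", "p_value", "p_by", "q_value"))
    df[[cn]] <- sprintf("%.3f", df[[cn]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write the screen as a table-style CSV
#'
#' @param screen a `univariate_screen`.
#' @param path CSV path.
#' @export
write_screen <- function(screen, path) {
  write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}
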