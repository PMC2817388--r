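---
title: "Methods: tree-based discovery for flow-cytometry panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-based discovery for flow-cytometry panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowtrees)
```

## The problem

Four-colour flow cytometry summarises a blood sample as a panel of
"percent of gated" variables: each staining plate crosses two fluorochrome
intensity thresholds, producing four quadrant percentages that sum to 100.
A typical immune-monitoring panel of this design yields on the order of 63
such variables plus a baseline CD4 count.  The scientific question the
package addresses is which of these baseline cell-subset variables — alone
or in combination — predict a binary clinical endpoint, here immune
reconstitution on antiretroviral therapy, defined as a week-36 CD4 count
strictly above 450 cells/µL.

With tens of correlated predictors and well under a hundred subjects, no
single analysis is adequate.  The package therefore implements four
complementary views of the same preprocessed matrix:

1. **Univariate contingency screen** — per-variable odds ratios and Pearson
   χ² tests, with Benjamini–Yekutieli and pFDR (q-value) multiplicity
   adjustments.
2. **Classification tree (CART)** — Gini-impurity splitting with
   cost-complexity pruning, exposing the *structure* of association
   (conditional effects).
3. **Random forest** — an ensemble of unpruned trees on bootstrap samples
   with out-of-bag (OOB) permutation importance and mean decrease in node
   impurity, a collinearity-tolerant *ranking* of variables.
4. **Logic regression** — a generalized linear model whose covariates are
   Boolean (and/or/complement) combinations of the binary predictors,
   fitted by simulated annealing; it can represent combinations with *no*
   marginal signal, such as exclusive-or structures, that split-based
   methods cannot reach.

Because the motivating cohort is not publicly deposited, the package ships
a compositional panel *simulator* with planted, known-truth outcome
signals; every claim the test suite makes about the methods is made against
that known truth.

## Preprocessing

All predictors are dichotomized a priori: a value maps to 1 when strictly
greater than the median of the observed (non-missing) values of that
variable, 0 otherwise — ties at the median are 0 by the strict inequality.
Remaining missing cells are imputed with the most common observed value of
the column; an exact 0/1 tie imputes 0 (deterministic and conservative
toward "low").  Replicated acquisitions (four per subject for the CD3/CD8
gate) are averaged over the observed replicates.  The outcome is never
imputed: subjects missing the week-36 count are dropped with a warning.
These conventions make preprocessing idempotent on a complete binary
matrix whose zeros are in the majority, and equivariant under permutation
of subjects — both are tested properties.

## The univariate screen

For predictor $X_j$ and outcome $y$, the 2×2 table $(a, b, c, d)$ counts
exposed responders, exposed nonresponders, unexposed responders and
unexposed nonresponders; the odds ratio is $ad/bc$ and the test is the
1-df Pearson statistic

$$\chi^2 = \frac{n\,(|ad - bc| - h)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with $h = n/2$ under the Yates continuity correction (the package default)
and $h = 0$ without it.  On the canonical 39/39 split with 4 versus 15
responders, the corrected test gives p = 0.008 and the uncorrected one
p ≈ 0.004; the package verifies its closed form against
`stats::chisq.test` exactly.  The default is the corrected variant;
note that at n ≈ 78 the correction is deliberately conservative (measured
type-I rate ≈ 0.025 at nominal 0.05), which is why the *calibration*
property in the test suite is checked on the uncorrected statistic
(measured ≈ 0.05).

Multiplicity is handled two ways, both step-up procedures built on
`stats::p.adjust`: Benjamini–Yekutieli (valid under arbitrary dependence —
appropriate for compositionally coupled quadrants) and q-values
$q_{(j)} = \min_{i \ge j} \pi_0\, m\, p_{(i)}/i$ with $\pi_0 = 1$ by
default (then identical to Benjamini–Hochberg); a Storey estimate
$\pi_0 = \min(1, \overline{1\{p > 0.5\}}/0.5)$ is available behind a flag.

## Classification trees

Candidate splits are scored by the impurity reduction
$\phi = i(\Omega) - \pi_L i(\Omega_L) - \pi_R i(\Omega_R)$ with Gini
impurity $i = 2p(1-p)$ and $\pi_L, \pi_R$ the within-node child fractions.
A node is split only when some split has $\phi > 0$ *and* both children
would hold at least `min_node` subjects (default 5, reading the "five
individuals per node" stopping rule as a child-size floor).  Ties in
$\phi$ go to the lowest variable index; leaf predictions are the majority
class with ties to class 0.  `best_split` is validated against an
exhaustive oracle on 1000 random instances.

Pruning is weakest-link cost-complexity: repeatedly collapse the internal
node minimizing
$g(t) = \bigl(R(t\text{ as leaf}) - R(\text{branch})\bigr)/(|\text{branch leaves}| - 1)$,
yielding a nested sequence with strictly increasing critical $\alpha$
values; each element minimizes $R(T') + \alpha |T'|$ over *all* pruned
subtrees (verified by enumeration of the subtree lattice for trees up to
15 leaves).  Subtree selection uses stratified 10-fold cross-validation at
the geometric midpoints of the $\alpha$ intervals, with the
one-standard-error rule by default — on null panels this collapses the
tree to its root in ≥ 90% of replicates, the behaviour a practitioner
should expect from a weak-signal cohort.

## Random forests

Each of B = 500 trees (default) is grown unpruned on a bootstrap sample of
size n drawn with replacement — so the expected unique in-bag fraction is
$1-(1-1/n)^n \approx 63\%$ and the OOB fraction ≈ 37%, which is how the
"about two-thirds" description of bootstrap learning samples is
operationalized here.  At each node the split search is restricted to a
fresh random draw of `mtry` predictors (default $\lceil\sqrt p\,\rceil$);
`min_node = 1`.  One master seed spawns an independent stream per tree, so
enlarging B never reshuffles earlier trees.  The node-level search is the
same arithmetic as the CART grower (a forest of one tree with `mtry = p`
reproduces `grow_tree` exactly on the same bootstrap sample); the
tree-growing loop is implemented in C++, as is conventional for forest
implementations, because permutation importance revisits every tree once
per variable.

Two importance flavours are always computed side by side:

* **permutation importance** $\hat\theta_j = \frac1B \sum_b \delta_{bj}$,
  where $\delta_{bj}$ is the increase in tree *b*'s OOB misclassification
  after permuting $X_j$ within its OOB set (exactly 0 for variables a tree
  never uses), and
* **mean decrease in node impurity** — the sum over a variable's splits of
  node size × $\phi$, averaged over trees.

The two need not agree and are reported together.  Because complementary
quadrants are strongly negatively correlated (ρ ≈ −0.7 between the
dominant NK-gate quadrants under the default concentrations), importance
must be read in light of the correlation structure: duplicating a
predictor *dilutes* each copy's permutation importance — a tested
property, and the reason a variable's importance can be masked by a highly
correlated partner.

## Logic regression

Models have the form $g(E[Y \mid X]) = \beta_0 + \sum_{j=1}^t \beta_j L_j$
where each $L_j$ is a Boolean tree over the binary predictors with
operators and/or at internal nodes and optional complements at leaves
(internal complements are redundant by De Morgan's laws).  Coefficients
for a fixed set of trees are maximum-likelihood: a hand-rolled iteratively
reweighted least squares on the collapsed covariate patterns for the logit
link (weighted least squares for the identity link), verified to match a
GLM fit to 1e−6 in deviance on random instances.  Under separation,
coefficients are capped at ±10 and flagged.

The search is simulated annealing over six tree-edit moves (alternate a
leaf's variable, toggle a complement, alternate an operator, grow a
branch, prune a branch, split/delete a leaf), each changing the total leaf
count by at most one and respecting the total-leaf budget (default: two
trees, six leaves).  A worse state is accepted with probability
$\exp(-\Delta/T)$ under geometric cooling.  Two numerical choices deserve
comment:

* **Temperature scale.** Deviance differences grow linearly with n, so a
  fixed temperature schedule degenerates into greedy hill-climbing on
  large samples and overheats small ones.  By default the schedule is
  data-scaled: $T_{\text{start}} = 0.05 \times$ null deviance,
  $T_{\text{end}} = 0.05$.  Explicit temperatures remain available in
  `anneal_config`.
* **Score.** The default score is the model deviance.  Deviance alone,
  however, essentially always *saturates* the leaf budget — any extra leaf
  weakly improves the training fit — so exact-recovery experiments use the
  `score = "bic"` option (deviance + log(n) per leaf), under which the
  sparse planted rule is the optimum.  This is a property of
  maximum-likelihood scoring, not of the implementation.

Whether a fitted model "is" a given Boolean rule is decided by
`model_matches_rule`: the linear predictor is evaluated over every
assignment of the referenced variables and thresholded at the midpoint of
its range; the model matches the rule when this high-probability indicator
equals the rule's truth table.  This deliberately treats algebraically
different but discriminant-equivalent parameterizations (e.g.
NAND/NOR pairs versus two exclusive conjunctions for an XOR) as the same
discovery.

## The synthetic panel generator

Each staining's four quadrants are drawn per subject from a gamma-based
(Dirichlet-type) composition scaled to 100, one positive concentration
parameter per quadrant.  This guarantees exact sum-to-100 closure and the
negative correlation between complementary quadrants; the default NK-gate
concentrations (9, 2, 2, 9) give ρ ≈ −0.69 between the two dominant
quadrants, matching the strength of correlation seen in real quadrant
data.  Replicated stainings get four acquisitions with additive Gaussian
noise (sd 1.5 percent-units), each renormalized to 100 and averaged —
averaging renormalized replicates preserves closure exactly.  The default
design has 16 quadrant sets; one quadrant of the CD8+ CD7/CD154 plate is
simulated for closure but not reported, so the reported panel is 63 flow
variables plus a baseline CD4 count (uniform over the 200–350 cells/µL
eligibility window).  Missingness is injected completely at random
(default rate 5%; no missingness mechanism is modelled because none is
known), and the default cohort size is n = 78.

Outcomes are planted on the *dichotomized* targets: each subject's stratum
(the 0/1 pattern of its targets) determines a responder probability, the
responder status is Bernoulli, and the week-36 CD4 count is drawn as
450 ± a lognormal shift so that dichotomization at 450 recovers the
status exactly.  Four outcome kinds cover the study designs the methods
are meant to distinguish: `null`, `marginal`, `conditional` (a nested,
CART-style hierarchy) and `interaction` (an XOR with balanced targets and
therefore *no* marginal effects — the scenario in which split-based
methods are expected to fail and logic regression to succeed).

What the simulator does *not* emulate: event-level cytometry, instrument
compensation, isotype-control background, gate drift, or informative
missingness.  Passing tests therefore demonstrate correctness of the
algorithms and their behaviour under the declared generative assumptions,
not performance on real cytometry files.

### Scenario calibrations used by the test suite

* *Conditional recovery* (n = 400): stratum probabilities 0.70/0.25 when
  the primary target is low, 0.05 when high.  The primary marginal gap
  (0.475 vs 0.05) dominates the secondary's induced gap, so the planted
  hierarchy is unambiguous.
* *Marginal ranking* (n = 400, B = 500): responder probability 0.85 below
  the target median versus 0.15 above.
* *AND-NOT rule* (n = 500): probability 0.85 in the single
  target₁-high/target₂-low stratum, 0.10 elsewhere.
* *XOR* (n = 20000 on a reduced two-staining panel): probability 0.85 in
  discordant strata, 0.15 in concordant ones.  The large n is required by
  the claim being tested — that *every* univariate |log OR| stays below
  0.1 while the rule is recoverable: the sampling noise of a null log odds
  ratio is ≈ $\sqrt{16/n}$, which at n = 500 would exceed the bound for
  some variable with probability near 1 regardless of method quality.
* *Null calibration*: responder probability 19/78 (the base rate of the
  motivating cohort), n = 78, 500 screen replicates and 100
  cross-validated trees.

Replicate counts (100 for tree/forest recovery, 20 and 10 for the two
annealing scenarios) keep the full suite within a few minutes on one core
while leaving the pass thresholds (90–95%) binomially well separated from
the observed rates (98–100% in development runs).

## Degenerate inputs and tie-breaking, in one place

* Zero-margin 2×2 tables are a `degenerate-table` error for the test and a
  flagged `Inf`/`0`/`NaN` for the odds ratio (optional Haldane +0.5
  correction available, off by default).
* All-missing columns cannot be dichotomized or imputed (errors).
* Split ties → lowest variable index; leaf-prediction ties → class 0; mode
  ties → impute 0; vote ties in the forest → class 0.
* Boolean trees may be the constant-0 tree (`NULL`); constant or aliased
  logic columns are dropped from the GLM with a flag, and deleting the
  only leaf of a tree produces the constant tree rather than an error.
* Screen rows with degenerate tables carry `NA` statistics and sort last.

## Limitations

Exact reproduction of the motivating study's forest importance values and
logic coefficients is impossible without its (undeposited) data; the
package instead demonstrates, on planted-truth panels, that each method
recovers the kind of structure those values summarise.  The univariate
screen's corrected p-values are conservative at small n; the annealer is
stochastic and its guarantees are empirical rates, not certificates; and
the simulator's compositional model, while matching the first-order
correlation structure of quadrant data, is not a cytometer.
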