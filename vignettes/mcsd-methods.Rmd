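---
title: "Compressed-sensing subtype classification with mcsd: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing subtype classification with mcsd: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Molecular subtypes of a disease — for instance the pro-neural, neural,
classical and mesenchymal transcriptional classes of glioblastoma — often
look similar in any single data type, while different platforms measured on
the same patients (say, a small miRNA panel and a genome-wide mRNA array)
carry complementary information.  `mcsd` implements a multi-class
compressed-sensing detector for this setting: per-sample profiles from
several data types are *cascaded* (stacked feature-wise) into one long
vector, a small set of informative probes is identified, a sparse linear
projection into a low-dimensional space is *learned* from the training data
by l1-minimization, and classification happens in that compressed space with
a Bayesian ideal observer.

The pipeline behind `mcsd()` is, for a training matrix with `N` probes and
`c` samples in `n` classes:

1. **Cascade** the blocks: `x = [x_1; x_2; ...]`, one long profile per
   sample.
2. **Normalize** every row (probe) to `[0, 1]` by its training min/max.
3. **Score** every probe with five group statistics and keep the best `m`.
4. **Learn** the sparse compress matrix `Phi` (`m` rows, `N` columns) by
   basis pursuit.
5. **Classify** compressed observations `y = Phi x` by maximum expected
   utility under Gaussian class densities.

# Feature scoring

For probe `i` the profile `V_i = (MeanStd, StdStd, StdMean, MeanCorr,
StdCorr)` summarises, over the `n` classes: the mean and spread of the
within-class standard deviations, the spread of the class means, and the
mean and spread of `|r|`, the absolute Pearson correlation between the probe
and a one-vs-rest class indicator.  An informative probe is tight within
classes (low `MeanStd`, `StdStd`), separated between classes (high
`StdMean`), and consistently tracks membership (high `MeanCorr`, low
`StdCorr`).  All standard deviations are sample (`n - 1`) standard
deviations, and degenerate correlations (constant probe) are defined as 0,
so a constant probe scores `(0, 0, 0, 0, 0)`.

Two choices here were genuinely open:

* **Multi-class correlation.** A Pearson correlation against "the class
  label" is only defined for two classes.  We correlate against one
  one-vs-rest 0/1 indicator per class and aggregate `|r|` over classes
  (mean and spread).  This reduces to the two-class construction when
  `n = 2` and is symmetric under relabelling.  Absolute values keep all
  five components non-negative, so dividing each by its maximum across
  probes maps the profile into `[0, 1]`.
* **Selection rule.** Thresholding five coupled components needs five
  knobs.  `select_features()` instead ranks each component (ascending where
  low is good, descending where high is good), sums the five ranks, and
  keeps the best `m`: a single interpretable knob, deterministic ties
  (probe index), nested selections in `m`, and invariance to any monotone
  rescaling of a component.  One consequence, visible in the test suite, is
  that components carrying no signal for a given design (e.g. `StdStd`,
  whose distribution is identical for informative and null probes under
  the generator's equal-noise model) dilute the composite: with 10 planted
  probes among 200 at effect size 2 sigma the top 10 contains about 7 of
  them, with the full planted set inside the top 40.  End-to-end class
  recovery is unaffected at usual values of `m`, but users who want a
  sharper ranking should examine `feature_report()` and weight components
  for their design.

# The learned compression

The compressed representation solves `Y = Phi S`, where `S` is the
normalized training matrix (`N x c`) and `Y` is simply its selected-probe
submatrix (`m x c`): each compressed coordinate must reproduce one
informative probe *as a linear functional of the whole profile*.  Row `j`
of `Phi` is the basis-pursuit solution

    min ||phi||_1   subject to   S^T phi = (Y^T)_j ,

an underdetermined system (`c` equations, `N` unknowns) whose minimum-l1
solution is sparse.  `solve_l1_row()` follows the homotopy / least-angle
path of the lasso problem from `lambda = max|S y|` down to numerical zero;
the path is piecewise linear with at most `c` active coordinates, each step
costs one `N x c` product, and the endpoint is polished by an exact least
squares solve on the final active set.  The solver is deterministic, reports
per-row l1 norm, residual and step count, and flags degenerate (collinear)
active sets, where minimizers may be non-unique.

Two invariants make the solver auditable:

* **Feasibility bound.** When the targets are rows of a `[0, 1]`-normalized
  `S`, the unit selector row `e_j` is feasible, so no optimal row can have
  l1 norm above 1 (plus tolerance).  Every fit in the test suite checks
  this.
* **Oracle equivalence.** On small random instances the per-row objective
  is compared against an independent enumeration of basic solutions (the
  basis-pursuit linear program attains its optimum on a linearly
  independent column support); agreement is at machine precision.

Because each row solves a `c`-equation system, the compressed dimension
cannot exceed the training sample count: `mcsd()` enforces `m <= c` with an
explicit error.

# The ideal-observer classifier

The observation model is Gaussian.  Uncompressed, class `k` has density
`(2 pi sigma^2)^(-N/2) exp(-||x - s_k||^2 / (2 sigma^2))` with `s_k` the
class mean; after compression the density stays Gaussian with mean
`Phi s_k` and covariance `sigma^2 Phi Phi^T`.  Note the normalizer uses the
*compressed* dimension `m` — the density must integrate to one on the
compressed space (with equal-dimension comparisons the constant cancels in
the argmax anyway).  A sample is assigned to

    argmax_l  sum_k U[l, k] P_k p(y | g = pi_k) ,

the class of maximal expected utility given the utility matrix `U`, priors
`P_k`, and the class-conditional likelihoods.  With the identity utility
(`U = delta_ij`, the ideal detector) and equal priors this is exactly
maximum likelihood; that equivalence is verified numerically on random
models.

Numerical choices:

* all likelihood work happens in log space with log-sum-exp stabilization;
  argmax ties break to the lowest class index;
* `sigma^2 Phi Phi^T` is factorized by Cholesky, never inverted; if the
  factorization fails or the condition estimate exceeds `1e12`, a ridge of
  `1e-10 * trace/m` is added to the diagonal (duplicated target rows make
  `Phi Phi^T` rank-deficient).  The ridge is applied *only* on demand so
  that well-posed cases — in particular `Phi = I`, where the compressed
  density must equal the original one to machine precision — stay exact;
* `sigma` is the pooled within-class sample standard deviation over the
  selected probes of the normalized training data (one shared scale,
  matching the single-`sigma` observation model); a per-class mode is
  available.  A floor of `1e-8` keeps noise-free (perfectly separable)
  inputs well-defined without affecting the decision ordering;
* class means are arithmetic means of the normalized training columns, and
  the compressed means are their projections `Phi s_k`, which on training
  data coincide with the selected-probe class means.

**Utility matrices.** The utility of a correct decision is never smaller
than that of an error (validated on construction).  Besides the identity
default, two estimators are provided: `pairwise_br` uses the closed-form
two-class Bayes risk between each pair of compressed class Gaussians
(`pnorm(-Delta/2)` at Mahalanobis distance `Delta`) as the off-diagonal
payoff, and `mc_multiclass` uses the Monte-Carlo confusion matrix of the
maximum-likelihood rule (seeded, `n_mc >= 1000`).  Both approach the
identity as classes separate and give off-diagonals of 1/2 for coincident
classes.  The reference construction this follows is under-determined in the
source material; the identity default keeps the decision rule equal to
maximum likelihood and is what every reported experiment uses.

**Two-class Bayes risk.** `bayes_risk_two_class()` integrates the two tail
integrals `P2 * Int_{-inf}^{y0} p2 + P1 * Int_{y0}^{inf} p1` by adaptive
quadrature, and `bayes_risk_gaussian()` gives the Gaussian closed form; for
unit Gaussians at 0 and 2 with boundary 1 both give `pnorm(-1) = 0.1587`.

# Normalization and leakage

The row min/max are computed on the **training matrix only**, stored in the
model, and applied to test samples with clipping into `[0, 1]`; constant
training rows map to all zeros (keeping uninformative probes at the low end
and avoiding division by zero).  This keeps the fitted model applicable to
a single new sample and avoids test-set leakage.  A joint mode
(`normalize_rows(..., method = "joint")`) that pools train and test ranges
is provided for replicating analyses that normalized both sets together,
but the fitting function never uses it.

# The synthetic generator

`generate_synthetic()` is the package's test bed: baseline expression is
i.i.d. Gaussian with mean 0.5 (mimicking normalized expression in `[0, 1]`)
and standard deviation `noise_sigma`; each class owns
`informative_per_class_per_block` disjoint probes per block, up-shifted by
`effect_size * noise_sigma` in that class's samples, and `block_signal_map`
controls which classes are separable in which block.  The defaults — 4
classes, blocks of 150 and 2000 probes, 15 training and 14 test samples per
class, 10 planted probes per class per block, noise sigma 0.1 — echo a
two-platform tumour-subtyping design at desk scale: a small panel cascaded
with a much larger array, a balanced training arm, and a comparable test
arm.  Gaussian noise deliberately matches the classifier's observation
model, so recovery tests probe the matched regime; a standardized
log-normal mode exists for misspecification checks.

What the generator does *not* emulate: correlation between probes (real
miRNA–mRNA regulatory structure), platform-specific noise, heavy tails, or
batch effects.  Passing the recovery tests therefore demonstrates that the
pipeline implements its model correctly and recovers planted structure
under that model — not that it attains any particular accuracy on real
tumour data.

Key experiment sizes used by the acceptance checks (chosen as the study
design above): 20 seeds per condition; effect size 4 sigma for recovery
(mean test accuracy should approach 1), effect size 0 for the null (chance
= 1/4), and a complementary-blocks design (classes 1–2 separable only in
the small block, 3–4 only in the large one) where cascading must beat each
single block by a wide margin — single blocks top out near 75% because two
of the four classes are indistinguishable in them.

# Reproducibility and serialization

Every source of randomness (the generator, balanced splits, Monte-Carlo
utilities, simulation from fitted models) is funnelled through one seed
argument; fitting is otherwise deterministic, so identical seeds give
byte-identical serialized models.  `write_mcsd()` stores the model as four
plain-text artifacts (`model.json`, `phi.tsv` sparse triplets,
`row_stats.tsv`, `selected.tsv`) with 17 significant digits — lossless for
doubles — and `read_mcsd()` reconstructs a model whose predictions are
identical.  The full-probe class means are not serialized (they scale with
`N`); only the non-compressed *all-features* reference detector needs them,
and it requires an in-session fit.

# Limitations

* The compressed dimension is bounded by the training sample count, and
  the learned `Phi` frequently is (or is close to) a probe selector when
  single probes are the sparsest way to reproduce themselves; the
  compression pays off through the joint Gaussian geometry
  (`sigma^2 Phi Phi^T`) rather than through exotic mixing.
* The equal-weight rank-sum treats all five profile components as equally
  informative, which dilutes the ranking when some components carry no
  signal for a particular design (see above).
* Gaussian class densities with a shared scale are a strong assumption for
  expression data; the per-class sigma mode relaxes it only partially.
* No missing-value handling beyond rejection, no probe annotation, and no
  platform preprocessing — inputs are assumed to be expression matrices
  ready for row normalization.
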