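---
title: "Classifying pre-miRNA hairpins with explicitly mapped linear discriminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pre-miRNA hairpins with explicitly mapped linear discriminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mildrem)
```

## The problem

Precursor microRNAs (pre-miRNAs) are ~80-nt transcripts that fold into
hairpin secondary structures. Genomes contain thousands of other segments
that fold into similar hairpins ("pseudo hairpins"), and several families
of structural non-coding RNA (tRNA, snoRNA, snRNA, YRNA, rRNA) also adopt
hairpin-like folds. Telling true precursors apart from this background is
a binary classification problem with two awkward properties:

* **heavy class imbalance** — in the standard human benchmark there are
  691 positive hairpins against 8,494 pseudo hairpins plus 754 other
  ncRNAs, roughly 1:13, so raw accuracy rewards the classifier that calls
  everything negative;
* **non-linear structure** — thermodynamic and composition features do
  not separate the classes with a single hyperplane.

`mildrem` addresses both with a deliberately simple, fully generative
pipeline: model each class as a Gaussian, project onto a few directions
chosen by a class-separability criterion, and classify with the Bayes
rule. Non-linearity is handled *before* the linear step, by explicitly
mapping features to a higher-dimensional space in which linear directions
suffice.

## The model

Each class is a Gaussian, $x_i \sim N(m_i, S_i)$ with prior $p_i$
(class 1 = pre-miRNA). A $d \times n$ matrix $A$ reduces features to
$y = Ax$. Three criteria choose $A$, all built from the within-class and
between-class scatter

$$S_W = p_1 S_1 + p_2 S_2, \qquad S_E = (m_1 - m_2)(m_1 - m_2)^t .$$

**Fisher (FDA).** Maximize
$J(A) = \mathrm{tr}\{(A S_W A^t)^{-1} A S_E A^t\}$; the optimum is the
leading eigenvectors of $S_W^{-1} S_E$. With two classes $S_E$ has rank
one, so FDA offers exactly one informative direction.

**Heteroscedastic (HDA).** FDA ignores covariance differences. HDA
augments the between-class term with a matrix-logarithm correction,
replacing $S_E$ by
$$S_E - S_W^{1/2}\,
  \frac{p_1 \log \hat S_1 + p_2 \log \hat S_2}{p_1 p_2}\,
  S_W^{1/2},
  \qquad \hat S_i = S_W^{-1/2} S_i S_W^{-1/2},$$
and again solves an eigenproblem. Because
$p_1 \hat S_1 + p_2 \hat S_2 = I$ and $\log$ is matrix-concave, the
correction is positive semi-definite: it only adds separability, and it
vanishes identically when $S_1 = S_2$, collapsing HDA onto FDA (a
property the test suite asserts).

**Chernoff (CDA).** Directly maximize the Chernoff separability of the
projected pair,
$$J(A) = \mathrm{tr}\{p_1 p_2\, A S_E A^t (A S_W A^t)^{-1}\}
  + \log|A S_W A^t| - p_1 \log|A S_1 A^t| - p_2 \log|A S_2 A^t| .$$
No closed form exists; `fit_cda()` runs gradient ascent (central
differences, $h = 10^{-6}$) with a backtracking line search that halves
the step until the objective increases, so the per-iteration objective
trace is non-decreasing by construction. The ascent starts from the FDA
solution and additionally from the HDA solution and a few seeded random
matrices; the best final iterate wins. Stopping: objective change below
`tolerance` ($10^{-8}$) or 500 iterations; hitting the cap returns the
best iterate with `converged = FALSE` rather than an error.

Classification happens in the reduced space with a Gaussian-Bayes rule:
`"linear"` pools the class covariances as $p_1 S_1 + p_2 S_2$ (a
pooled-covariance reading of "linear classifier", the standard one),
`"quadratic"` keeps them separate. Exact posterior ties go to the
negative class — with a 1:13 prior imbalance this is the conservative
choice for false-positive control.

## Explicit feature maps

Rather than kernelizing the discriminants (hard for HDA/CDA, and the
kernel matrix would be ~10,000 × 10,000 on the benchmark), features are
mapped explicitly and the linear machinery is reused unchanged.

**Degree-2 polynomial.** `poly_map()` sends $x$ to
$(1, x_1, \dots, x_n, x_1^2, \dots, x_n^2, x_1 x_2, \dots, x_{n-1} x_n)$,
of dimension $C(n+2, 2)$. The exact factorization of the kernel
$(1 + x \cdot y)^2$ would put $\sqrt 2$ weights on the linear and cross
terms; the package implements the plain monomial list. The two differ by
a fixed invertible diagonal scaling, to which every criterion above is
invariant, so classification is unaffected — the tests assert both the
$\sqrt 2$-scaled kernel identity and the criterion invariance.

**Randomized RBF features.** `rbf_fit()` draws a frozen map with
frequencies $W_{ij} \sim N(0, 2\gamma)$ and phases
$b_i \sim U[0, 2\pi)$; `rbf_transform()` computes
$z(x) = \sqrt{2/m}\, \cos(W x + b)$, for which
$E[z(x) \cdot z(y)] = \exp(-\gamma \lVert x - y \rVert^2)$ — a
Monte-Carlo approximation of the Gaussian RBF kernel with
$O(1/\sqrt m)$ error. Defaults are $\gamma = 1.5$ and $m = n + 15$,
where $n$ is the size of the feature (sub)set actually used; during
feature selection $m$ is recomputed per subset size. `grid_search()`
tunes $(\gamma, m)$ over user grids (the reference grids are
$\gamma \in \{0.25, 0.5, 1, 2, 4, 8\}$ and
$m \in \{10, 15, 20, 25, 30\}$).

Features are z-scored with training-fold statistics before the RBF map
(`standardize = TRUE` by default for RBF only): $\gamma$ multiplies
squared Euclidean distance, so without a common scale its interpretation
would drift across feature subsets. The map itself is data-independent;
it is nevertheless fitted once per evaluation with a recorded seed so
that runs are exactly reproducible.

## Evaluation under imbalance

`cross_validate()` runs stratified k-fold CV (default k = 10): folds
preserve the class ratio to within one sample per class, and every
stage — standardization, mapping bookkeeping, projection, classifier —
is fitted on the training folds only. Each fold's confusion counts give

$$SE = \frac{TP}{TP + FN}, \qquad SP = \frac{TN}{TN + FP}, \qquad
  G_m = \sqrt{SE \cdot SP},$$

with positives = pre-miRNA. $G_m$ is the headline score because it
collapses to zero as soon as either class is ignored. The summary
reports the per-fold mean ± sd *and* the pooled-confusion metrics; the
per-fold mean is the headline (fold-level dispersion is what a ± figure
on a 10-fold experiment most plausibly means; both aggregates are
always available, so nothing hinges on that reading).

## Feature selection

`beam_search()` is a wrapper selector scored by cross-validated $G_m$:
evaluate all $C(n, 2)$ pairs, keep the best $B = 10$; extend each kept
subset by every unused feature, deduplicate, keep the best 10 triples;
continue to $K = 12$ features. Ties break toward the lexicographically
smallest subset, and with $B = 1$ the procedure reduces to plain greedy
forward selection. Although procedures of this family are often labelled
"floating" forward search, no backward-elimination step is specified
here and none is performed — the search is exactly the breadth-limited
beam just described. An optional `min_improvement` threshold can stop
early; it is off by default. The fold seed is frozen across all subset
evaluations (and the map seed per stage) so scores are comparable, and
every evaluation is cached under a fingerprint of subset, mapping
parameters, seeds, CV config and a data hash — a rerun over the same
inputs performs zero new cross-validations.

## The synthetic world

Real benchmark tables need an RNA folding engine for 31 of the 48
canonical features, so the test fixtures are synthetic and the generator
is itself first-class, tested code. `sim_spec()` defaults describe a
1:13.4 miniature of the benchmark: 69 positives vs 925 negatives, 48
features with two informative. Three structures are available:

* `gaussian_homo` — mean shift of `separation` (Mahalanobis units,
  split across informative dimensions) under shared covariance;
* `gaussian_hetero` — equal means, informative variance ratio
  `separation`;
* `xor` — positive blobs at $(\pm a, \pm a)$, negative at
  $(\mp a, \pm a)$, $a = \mathrm{separation}/2$, isotropic noise. A
  single Gaussian per class has equal means and mirrored covariances
  here, so unmapped discriminants fail by construction while the RBF map
  separates the quadrants.

Uninformative columns are i.i.d. noise. For the XOR fixtures the package
uses `separation = 4` with unit noise — blob centres two noise standard
deviations from the origin, the classic moderately-overlapping XOR
geometry. `bayes_gm_oracle()` Monte-Carlo-scores the true-density Bayes
rule on any spec, the ceiling a trained pipeline should approach but not
beat (the suite checks agreement within combined Monte-Carlo + fold
standard errors).

What a green suite does establish: the algebra of the criteria, their
optimality/equivalence properties, kernel-approximation quality,
leak-free evaluation, and the qualitative orderings (mapped beats
unmapped on XOR; planted features are recovered). What it does not:
performance numbers on the real benchmark — synthetic Gaussians do not
emulate thermodynamic feature distributions, and no claim is transferred.

## Numerical choices

* **Covariance conditioning.** Every inversion, square root or logarithm
  first adds a ridge $\lambda \cdot \mathrm{tr}(S)/n \cdot I$
  ($\lambda = 10^{-6}$, configurable); cosine features are near-collinear
  by construction, so this is load-bearing. `matrix_function()`
  additionally floors eigenvalues at $10^{-12}$.
* **Covariance estimator.** Biased ($1/N$), matching the distributional
  model; the unbiased variant is available via `cov_method`.
* **Priors.** Empirical class fractions by default; `"equal"` is
  provided because separability criteria are often quoted with balanced
  priors, and nothing downstream depends on the choice.
* **Determinism.** Eigenvector signs are fixed (largest-magnitude
  component positive), equal eigenvalues keep stable order, fold and map
  seeds are explicit everywhere, and every report carries a
  configuration hash.
* **Reduced dimension.** `d = 1` by default: with two classes the Fisher
  between-class scatter has rank one. The HDA/CDA target matrices can
  carry more directions, so `d` stays configurable rather than hard-coded.

## Limitations

The 31 folding/thermodynamic features (dG, zG, NEFE, MFEI1–4, dP, dQ,
…) are consumed as precomputed columns — computing them requires an RNA
secondary-structure engine that is out of scope; the schema registry
reserves their canonical names and units only. Only two-class problems
are supported, class models are Gaussian, and the polynomial map is
fixed at degree 2.
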