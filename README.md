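# mildrem

Classification of pre-microRNA hairpins against pseudo hairpins and other
non-coding RNAs, built from three plain ingredients: two-class Gaussian
models, linear dimensionality reduction (LDR), and explicit feature maps
that let the linear machinery handle non-linear structure.

MicroRNA precursors fold into ~80-nt hairpins, but so do thousands of
genomic pseudo hairpins and several structural ncRNA families; on the
standard human benchmark the classes are imbalanced roughly 1:13
(691 positives vs 8,494 + 754 negatives). `mildrem` models each class as
a Gaussian `x_i ~ N(m_i, S_i)` with prior `p_i`, projects with a
`d x n` matrix `A` chosen to maximize a separability criterion, and
classifies with the Gaussian-Bayes rule in the reduced space.

Three criteria are implemented, all built on the scatter matrices
`S_W = p1*S1 + p2*S2` and `S_E = (m1 - m2)(m1 - m2)'`:

* **FDA** — Fisher: `J(A) = tr{(A S_W A')^-1 A S_E A'}`, solved by the
  leading eigenvectors of `S_W^-1 S_E`;
* **HDA** — heteroscedastic: `S_E` is augmented by a matrix-log term
  `S_W^1/2 (p1 log Ŝ1 + p2 log Ŝ2)/(p1 p2) S_W^1/2`
  (`Ŝi = S_W^-1/2 Si S_W^-1/2`) that captures covariance differences and
  vanishes when `S1 = S2`;
* **CDA** — Chernoff: gradient ascent on the Chernoff separability of
  the projected class pair.

Non-linearity is handled *before* the linear step by explicit maps: the
exact degree-2 polynomial expansion (dimension `C(n+2, 2)`), or random
Fourier features `z(x) = sqrt(2/m) cos(Wx + b)` with
`W ~ N(0, 2*gamma)`, whose inner products approximate the RBF kernel
`exp(-gamma ||x - y||^2)` (defaults `gamma = 1.5`, `m = n + 15`).

Because of the imbalance, everything is scored by the geometric mean
`Gm = sqrt(SE * SP)` under stratified 10-fold cross-validation, with
`SE = TP/(TP+FN)`, `SP = TN/(TN+FP)` and positives = pre-miRNA. The
package also provides beam-width-10 wrapper feature selection with
result caching, `(gamma, m)` grid search, native computation of the 17
sequence-composition features from FASTA (the 31 folding/thermodynamic
features of the canonical 48-feature schema are consumed as precomputed
columns), a tested synthetic-data generator, and a CLI.

## Worked example

An XOR-structured fixture (positive blobs in same-sign quadrants,
negative in opposite-sign, 69 vs 925 samples) defeats unmapped
discriminants by construction — each class is a two-blob mixture whose
single-Gaussian fit has the same mean and a mirrored covariance — while
the RBF map separates the quadrants:

```r
library(mildrem)

tab <- simulate_features(sim_spec(n_pos = 69, n_neg = 925, n_features = 6,
                                  structure = "xor", separation = 4,
                                  seed = 1))
unmapped <- cross_validate(
  tab, ldr_pipeline(features = c("f1", "f2"), mapping = "none",
                    criterion = "hda", classifier = "quadratic"),
  fold_seed = 1)
mapped <- cross_validate(
  tab, ldr_pipeline(features = c("f1", "f2"), mapping = "rbf",
                    criterion = "hda", classifier = "quadratic"),
  fold_seed = 1)
round(rbind(unmapped = unmapped$mean, rbf = mapped$mean), 4)
#>              SE     SP     Gm
#> unmapped 0.4333 0.9946 0.6448
#> rbf      0.9000 0.9751 0.9348
```

The unmapped heteroscedastic discriminant recovers half the positives
(its only handle on XOR is the projected variance difference), for a
geometric mean of 0.64; the same pipeline after the random cosine map
reaches 0.93. Beam selection on a 12-feature table with signal planted
in columns 4 and 9 finds the pair:

```r
tab2 <- simulate_features(sim_spec(n_pos = 69, n_neg = 925,
                                   n_features = 12, informative = c(4, 9),
                                   separation = 3, seed = 1))
res <- beam_search(tab2, beam_config(beam_width = 10, max_size = 2,
                                     pipeline = ldr_pipeline(),
                                     fold_seed = 1))
res$stages[["2"]][[1]][c("subset", "mean_gm")]
#> $subset
#> [1] 4 9
#> $mean_gm
#> [1] 0.835902
```

## Command line

```sh
Rscript inst/cli/mildr.R simulate --output sim.tsv --structure xor --seed 1
Rscript inst/cli/mildr.R evaluate --input sim.tsv --output cv.tsv \
    --features f1,f2 --criterion hda --classifier quadratic --seed 1
Rscript inst/cli/mildr.R --help   # simulate / featurize / train / evaluate /
                                  # select-features / grid-search / predict
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the reference experiment from scratch against the installed
package: it generates the XOR fixture, cross-validates the unmapped and
RBF-mapped pipelines, runs beam feature selection on the planted-signal
table (logging each result to stderr), and writes the JSON report to
`--out`.

## Documentation

`vignettes/hairpin-classification.Rmd` describes the model, the maps,
the evaluation protocol, the synthetic world and every numerical choice;
function-level documentation lives in the roxygen comments under `R/`.
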