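---
title: "Methods: block-wise reduction, metaheuristic selection and target-mapped classification of microarray cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-wise reduction, metaheuristic selection and target-mapped classification of microarray cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`microdiab` implements a complete two-class classification pipeline for bulk
microarray gene-expression cohorts, built around the shape of a human
pancreatic-islet study: 28,735 genes measured over 70 donors, 20 diabetic and
50 non-diabetic. With four orders of magnitude more genes than samples, the
pipeline attacks dimensionality in two stages — a 10:1 block-wise
*dimensionality reduction* (28,735 genes to 2,870 features per sample)
followed by a further 10:1 *feature selection* (2,870 to 287) — before any
classifier sees the data. Seven classifiers and an eight-metric
confusion-matrix suite close the loop, all under stratified 10-fold
cross-validation.

Every stage is exercised on seeded synthetic cohorts, so the whole pipeline
is testable without any external accession.

## Standardization

Raw intensities are strictly positive and roughly log-normal. Each *sample*
(column) is log10-transformed and then z-scored to mean 0 and variance 1.
Two conventions are deliberate:

* standardization is per sample, not per gene — the normalization target is
  the donor profile;
* the population variance (divide by $n$) is the default, because the
  requirement is literally that the transformed column has variance 1 as a
  finite set of values; the Bessel-corrected sample variance is available via
  `standardize(..., variance = "sample")`.

Non-positive intensities are a hard error (the log10 domain), as are
zero-variance samples.

## Block-wise dimensionality reduction

The 10:1 reduction fixes only the output count, not the gene-to-feature map.
We use deterministic contiguous blocks of size
$\lfloor n_{genes}/n_{out}\rfloor$ (10 at the study shape), with the final
block absorbing the remainder (35 genes), so the output dimension is exact
for any input size. Order preservation keeps the map auditable; nothing in
the downstream pipeline depends on gene order, so no generality is lost.

Within each block, one feature per sample is computed by the configured
method:

* **DFA** — the detrended-fluctuation statistic of the block treated as a
  short series: mean-subtract, integrate into the profile
  $A(n)=\sum_{i\le n}(X_i-\bar X)$, fit a least-squares linear trend over the
  single window (the block), and return the RMS of the residuals. With
  blocks of length 10 there is no room for a multi-scale window sweep, so
  the single-window, linear-detrend form is used; the trend order is
  configurable.
* **Chi-square statistic** — $\sum_g (x_g - m_g)^2 / (|m_g| + c)$ against the
  per-gene *training* means $m_g$ of the block. Because standardized samples
  have mean 0, the classical positive "expected count" denominator does not
  exist; the stabilizer $c$ (default 1) keeps the statistic finite and
  well-scaled while preserving the defining property that a sample equal to
  the training means scores exactly 0.
* **Firefly / Cuckoo** — a swarm searches a weight vector
  $w \in [-1,1]^{L}$ per block; the fitness of $w$ is the absolute Welch
  $t$-statistic of the projection $w^\top X_{block}$ between the two
  training classes, and the sample's feature is its projection on the best
  $w$. The fireflies move toward brighter members with attractiveness
  $\beta_0 e^{-\alpha r^2}$ plus a uniform random kick drawn in $[-1,+1]$;
  the cuckoo variant proposes Lévy-flight steps (Mantegna sampler, tail
  exponent 0.2 by default, step size 1 — the two are independent knobs) and
  re-initializes the worst fraction $P_a = 0.25$ of nests each generation.
  Both best-fitness traces are monotone by construction.

Fold hygiene: reducers are *fitted* on training samples only
(`fit_reducer()`), freezing block means and swarm weights; held-out samples
are transformed with the frozen statistics (`predict()`), so no test
information leaks into the reference values.

## Feature selection

Both selectors search a continuous score vector in $[0,1]^{n_{features}}$;
the $k$ largest components define the candidate subset. This keeps the
velocity/position updates in their standard continuous form and makes subset
cardinality exact by construction.

* **PSO** — velocities follow the inertia/cognitive/social update with the
  linear inertia schedule $w(k) = w_{max} - (w_{max}-w_{min})\,k/k_{max}$
  (defaults 0.9 to 0.4, $c_1=c_2=1.5$); personal and global bests are
  replaced only on strict improvement, so the global best is monotone.
* **Harmony search** — memory of 20 harmonies; each improvisation draws each
  variable from memory with probability 0.9, pitch-adjusts within a 0.1
  bandwidth with probability 0.3, and otherwise redraws uniformly; the new
  harmony replaces the worst stored one only when better (minimization of
  the negated objective).

The wrapper objective is stratified 5-fold training accuracy of a
nearest-centroid classifier restricted to the subset — cheap, classifier-
agnostic, and computed on training samples only. A filter objective (sum of
per-feature |t| scores) can be swapped in. One particle/harmony is
warm-started from the per-feature |t|-score ranking, a standard memetic
device for wrapper selection in $p \gg n$ regimes: it anchors the search at
the univariate optimum, which the swarm then refines. The random remainder
of the population preserves exploration.

Selections are validated with per-feature two-sided Welch $t$-tests plus a
pooled test on the per-sample mean of the selected features. The
significance threshold defaults to $\alpha = 0.05$ and is configurable
(an $\alpha = 0.01$ convention also appears in the literature this design
follows; the knob covers both).

## Classifiers and the target map

Regression-type models are trained toward mapped class targets
$T_{ND} = 0.1$ and $T_{Dia} = 0.85$ — chosen on the 0-to-1 output scale with
the separation constraint $\lVert T_{Dia}-T_{ND}\rVert \ge 0.5$ — and
thresholded at the target midpoint 0.475 (a tie goes to the negative class).
Logistic scores cut at 0.5; mixture/softmax posteriors at 0.5; SVM decision
values at 0.

* **NLR** — bounded sigmoid link
  $T_{ND} + (T_{Dia}-T_{ND})\,\sigma(\theta_0+\theta^\top x)$ fitted by
  Levenberg–Marquardt: solve $(J^\top J + \tau I)\delta = J^\top r$ with
  damping $\tau$ divided by 10 on acceptance and multiplied by 10 on
  rejection. The accepted-step MSE trace is non-increasing by construction.
* **LR** — minimum-norm least squares onto the targets via the SVD
  pseudoinverse (exact one-shot solve; well-posed even at $p > n$).
* **LoR** — ridge-penalized logistic regression maximizing
  $\sum_i y_i\log\pi_i + (1-y_i)\log(1-\pi_i) - \tfrac{1}{2\tau^2}\lVert\upsilon\rVert^2$
  by IRLS (intercept unpenalized, $\tau = 1$ by default).
* **GMM** — one Gaussian mixture per class fitted by EM (via mclust),
  $g = 2$ components by default, full covariance when the sample count
  permits and diagonal otherwise, with a variance floor on degenerate
  covariances (warned); the score is the posterior probability of the
  diabetic class under the class priors.
* **BLDC** — the Gaussian-prior linear model whose posterior mean has the
  closed ridge form
  $\upsilon = \beta(\beta BB^\top + H'(\alpha))^{-1} B a$ with a bias row
  appended to $B$ and $H' = \mathrm{diag}(\alpha,\dots,\alpha,\varepsilon)$;
  prediction is $\upsilon^\top \hat b$.
* **SDC** — softmax discriminant: class score
  $\log\sum_j \exp(-\lambda\lVert v - z_{ij}\rVert^2)$ over the stored
  training samples of class $i$ ($\lambda = 1$), computed with a log-sum-exp
  guard.
* **SVM-RBF** — dual soft-margin SVM (via e1071/libsvm) with kernel
  $k(x,y)=e^{-\gamma\lVert x-y\rVert^2}$; $\gamma$ is the canonical knob and
  a `sigma` adapter maps the $1/(2\sigma)^2$ convention onto it. The default
  record is $C = 1$, $\gamma = 100$, positive-class weight 0.86 applied as a
  multiplier on $C$. Features are internally centred/scaled for the kernel
  (training statistics stored in the model). Predictions are recomputed from
  the stored support vectors and dual coefficients, so saved models are plain
  JSON text.

All iterative fits share the stopping rule: training MSE $\le 10^{-12}$ or
2000 iterations.

A note on the SDC parameter record: a conventional record for this family
also lists kernel-style C/gamma values, but the softmax discriminant has no
kernel; only $\lambda$ is honoured.

## Evaluation

The confusion matrix is oriented with diabetic as the positive class. The
eight metrics follow the standard formulas (accuracy, recall, precision, F1,
MCC, error rate, Jaccard/Tanimoto, Cohen's kappa with its $P_o$/$P_e$
components); 0/0 ratios are reported as 0 and flagged rather than silently
dropped. Two algebraic identities are enforced property-style in the tests:
$\mathrm{Jaccard} = F_1/(2-F_1)$ and $\mathrm{accuracy} + \mathrm{error} = 1$.

`invert_metrics()` reconstructs the unique integer confusion matrix behind a
printed (accuracy, recall) pair at fixed class sizes — on 20/50 cohorts
every printed metric row is algebraically forced by its integer matrix, which
is what the worked-example tests assert.

Cross-validation is stratified (2 diabetic / 5 non-diabetic per fold at the
70-sample shape) and every stage — reduction statistics, selection, classifier
— is refitted per fold on training samples only. Metrics aggregate over the
*pooled* out-of-fold confusion matrix by default, which keeps the cells
integer-consistent on small cohorts; macro averaging over folds is available
behind a flag. Folding is over samples; folding over features would not
produce 70-sample confusion matrices and is not supported.

## The synthetic generator

`generate_cohort()` emulates what the pipeline assumes about real cohorts:
positive log-normal intensities (per-gene baseline means around
`base_mean = 2` on the log10 scale with 0.25 SD of gene-to-gene spread,
observation noise `noise_sd = 0.4`), the 28,735 x (20 + 50) study shape as
the default, and an additive diabetic-class shift of `effect_size` (default
0.8 log10 units) on the first `n_informative` genes (default 300). The
defaults were fixed once as a realistic microarray regime — log10 spreads of
a few tenths and a two-fold-change-scale effect — and are not tuned per
experiment. One integer seed drives all randomness; identical seeds give
bit-identical cohorts.

What the generator does *not* emulate: probe-level noise models, batch
effects, dye bias, gene-gene correlation beyond what per-sample
standardization induces. Passing tests on synthetic cohorts therefore
demonstrate algorithmic correctness and end-to-end wiring — not clinical
performance on real islet data.

One consequence worth knowing: because standardization is per sample, a
strong shift on informative genes also shifts the remaining genes of
diabetic samples slightly in the opposite direction, so weak class signal
leaks into "uninformative" blocks. This is a property of the normalization,
not a bug, and it is why recovery tests plant signal directly in feature
space.

## Numerical choices and degenerate inputs

* Swarm and selection randomness runs under an explicit seed per call
  (`withr::with_seed`), so every result is reproducible and the global RNG
  state is left untouched.
* Ties: a score exactly at a decision threshold goes to the negative class;
  best-replacement in PSO/HS is on strict improvement, so plateaus do not
  churn.
* Degenerate variances: Welch tests report p = 1 (no evidence) when both
  classes are constant and equal, p = 0 when constant and different; mixture
  covariances get a 1e-8 variance floor with a warning; zero-variance
  features entering the SVM scaler fall back to unit scale.
* The Mantegna Lévy sampler is validated by a Hill-estimator check of the
  empirical tail exponent on 1e5 draws (within 0.3 of the configured value).
* `invert_metrics` accepts rates within 1e-3 of an integral cell count,
  covering 4-decimal truncated percentages.

## Problem sizes used by the tests

The test suite runs the full-shape cohort (28,735 x 70) through every
reducer once and through PSO/HS selection once; all other tests use
deliberately small cohorts (tens to thousands of genes, 12-70 samples) with
reduced swarm sizes — population 4-10, 3-10 generations — which the
monotonicity and recovery properties show to be sufficient for the planted
signal strengths used. The strong-signal end-to-end check runs
chi-square reduction + PSO + SVM over five seeds at 1,000 genes with 200
informative genes at five noise-SDs of effect, a scaled-down analogue of the
real study's regime, not a reproduction of its accuracy figures.

## Known limitations

* The swarm-reducer objective (per-block discriminative projection) and the
  wrapper selection objective are design choices on top of underspecified
  prose descriptions of these stages; both are pluggable.
* The chi-square block statistic's stabilized denominator is an
  interpretation forced by standardized (signed) inputs.
* `summarize_features()` must pick a pairing for its single per-class
  correlation number (mean pairwise sample-sample correlation; feature
  pairing behind a flag) and subsamples the larger class for the canonical
  correlation between class blocks — both are documented interpretations of
  an ambiguous convention.
* No probability calibration, multiclass support, ROC analysis, or GEO
  SOFT/series-matrix parsing; probe-to-gene annotation is out of scope.
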