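# microdiab

Two-class classification of microarray gene-expression cohorts — diabetic
versus non-diabetic donors — for researchers working in the p ≫ n regime
where tens of thousands of genes describe a few dozen samples. The package
implements the complete pipeline as a set of tested, seeded stages:

1. **Standardization** — per-sample log₁₀ transform and z-scoring to mean 0,
   variance 1 (population convention).
2. **Block-wise dimensionality reduction** (10:1, e.g. 28,735 genes → 2,870
   features): per contiguous gene block, a feature is computed by detrended
   fluctuation analysis (DFA), a chi-square statistic against training block
   means, or a swarm-optimized discriminative projection (Firefly attraction
   β₀e^(−αr²) or Cuckoo search with Mantegna Lévy flights).
3. **Metaheuristic feature selection** (10:1 again, 2,870 → 287): particle
   swarm optimization or harmony search over a continuous score vector whose
   top-k components define the subset; wrapper objective = stratified 5-fold
   nearest-centroid training accuracy; Welch t-test validation per feature
   and pooled.
4. **Seven classifiers** sharing one score-then-threshold interface:
   non-linear regression (Levenberg–Marquardt, sigmoid link), linear
   regression, ridge logistic regression, per-class Gaussian mixtures (EM),
   a Bayesian linear discriminant with the closed-form ridge posterior
   υ = β(βBBᵀ + H′(α))⁻¹Ba, a softmax discriminant over training-sample
   distances, and an RBF-kernel SVM. Regression models train toward mapped
   class targets T_ND = 0.1 and T_Dia = 0.85 (‖T_Dia − T_ND‖ ≥ 0.5) and cut
   at the midpoint 0.475.
5. **Evaluation** — stratified 10-fold cross-validation with per-fold
   refitting of every stage, pooled out-of-fold confusion matrix, and the
   eight-metric suite: accuracy, recall, precision, F1, MCC, error rate,
   Jaccard (= F1/(2−F1)), and Cohen's kappa (P₀−Pₑ)/(1−Pₑ).

A seeded synthetic cohort generator reproduces the statistical structure the
pipeline assumes (log-normal intensities, additive class effect on a block of
informative genes, the 20/50 cohort shape), so everything is testable
without external data. See `vignettes/microdiab-methods.Rmd` for the full
methods account.

## Worked example

```r
library(microdiab)

cohort <- generate_cohort(synthetic_config(
  n_genes = 1000, n_pos = 20, n_neg = 50,
  n_informative = 100, effect_size = 0.5, noise_sd = 0.4, seed = 42))

spec <- pipeline_spec(
  reduction = reduction_config("chi2pdf", n_out = 100),
  selection = pso_config(n_particles = 10, iterations = 8, k_select = 20),
  kind      = "svm_rbf",
  params    = list(gamma = 0.05, C = 1, class_weight_pos = 1))

res <- kfold_evaluate(cohort, spec, k = 10, seed = 42)
res
#> 10-fold cross-validation (pooled aggregation)
#>   accuracy     recall  precision         f1        mcc error_rate    jaccard
#>     0.8571     0.5000     1.0000     0.6667     0.6455     0.1429     0.5000
#>      kappa
#>     0.5882
res$confusion
#>                    pred diabetic pred non-diabetic
#> truth diabetic                10                10
#> truth non-diabetic             0                50
```

The cohort plants a 0.5 log₁₀ shift (1.25 noise-SDs) on 100 of 1,000 genes.
After chi-square block reduction, PSO selection and an RBF-SVM, pooled
10-fold accuracy is 0.857: every non-diabetic donor is recognized
(precision 1, no false positives) while half of the diabetic donors are
recovered at this weak effect size (recall 0.5). MCC (0.65) and kappa (0.59)
summarize that the agreement is well above chance; raising `effect_size`
to 2 drives all eight metrics to their perfect values.

The metric suite also works backwards: on a 20/50 cohort a printed
(accuracy, recall) pair forces a unique integer confusion matrix:

```r
metrics(invert_metrics(0.914285, 0.90, n_pos = 20, n_neg = 50))
#>   accuracy     recall  precision         f1        mcc error_rate    jaccard
#>     0.9143     0.9000     0.8182     0.8571     0.7980     0.0857     0.7500
#>      kappa
#>     0.7961
```

## Command line

A thin CLI over the package functions lives at `inst/cli/microdiab.R`
(subcommands: simulate, standardize, reduce, select, train, predict,
evaluate, stats, sweep; all take `--seed`).
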