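# Fixtures built in code: no data files.

# Feature matrix with the first `n_informative` features shifted by `effect`
# (in units of the unit noise SD) in the diabetic class.
planted_features <- function(n_features, n_informative, n_pos, n_neg,
                             effect, seed = 1L) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_features * (n_pos + n_neg)), n_features)
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    if (n_informative > 0L) {
      v[seq_len(n_informative), labels == 1L] <-
        v[seq_len(n_informative), labels == 1L] + effect
    }
  })
  feature_matrix(v, labels = labels, method = "planted")
}

# Small positive-intensity cohort for I/O and standardization tests.
toy_cohort <- function(n_genes = 12L, n_pos = 3L, n_neg = 4L, seed = 1L) {
  generate_cohort(synthetic_config(n_genes = n_genes, n_pos = n_pos,
                                   n_neg = n_neg, n_informative = 0L,
                                   seed = seed))
}

expect_monotone_nondecreasing <- function(x, tol = 1e-12) {
  expect_true(all(diff(x) >= -tol))
}
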