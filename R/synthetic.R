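# Seeded synthetic two-class cohort generator.
#
# The generator emulates the pancreatic-islet cohort shape the pipeline was
# designed around: 28,735 genes over 70 samples (20 diabetic / 50 non-diabetic),
# log-normal positive intensities (normal on the log10 scale), and an additive
# class effect on the log scale for a configurable block of informative genes.

#' Configuration for the synthetic cohort generator
#'
#' @param n_genes Number of genes (default 28735, the pancreas cohort).
#' @param n_pos Number of diabetic samples (default 20).
#' @param n_neg Number of non-diabetic samples (default 50).
#' @param n_informative Number of informative genes, placed at the first
#'   `n_informative` row indices for easy recovery checks (default 300).
#' @param effect_size Additive shift of the diabetic-class mean on the log10
#'   scale for informative genes (default 0.8).
#' @param noise_sd Per-gene standard deviation on the log10 scale; must be
#'   positive (default 0.4, a typical log10 microarray spread).
#' @param base_mean Baseline log10 intensity (default 2, i.e. intensities
#'   around 100 units).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 28735L, n_pos = 20L, n_neg = 50L,
                             n_informative = 300L, effect_size = 0.8,
                             noise_sd = 0.4, base_mean = 2, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  if (n_informative > n_genes) {
    stop_microdiab("n_informative must not exceed n_genes", "microdiab_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_microdiab("noise_sd must be > 0", "microdiab_config_error")
  }
  structure(list(n_genes = n_genes, n_pos = n_pos, n_neg = n_neg,
                 n_informative = n_informative,
                 effect_size = as.numeric(effect_size),
                 noise_sd = as.numeric(noise_sd),
                 base_mean = as.numeric(base_mean),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "synthetic_config")
}

#' Generate a synthetic two-class expression cohort
#'
#' Intensities are drawn log-normal: per-gene baseline means
#' `base_mean + N(0, 0.25)` on the log10 scale with per-observation noise
#' `noise_sd`, so the downstream log10 transform is the natural scale. For the
#' first `n_informative` genes the diabetic-class log-mean is shifted by
#' `effect_size`. Diabetic samples come first in column order.
#'
#' @param cfg A [synthetic_config].
#' @return An [expression_matrix] with `n_pos` positive labels then `n_neg`
#'   negative labels.
#' @examples
#' x <- generate_cohort(synthetic_config(n_genes = 50, n_pos = 4, n_neg = 6, seed = 7))
#' table(x$labels)
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_pos + cfg$n_neg
  labels <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  withr::with_seed(cfg$seed, {
    gene_mu <- cfg$base_mean + rnorm(cfg$n_genes, sd = 0.25)
    logv <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd), cfg$n_genes, n)
    logv <- logv + gene_mu
    if (cfg$n_informative > 0L && cfg$n_pos > 0L) {
      idx <- seq_len(cfg$n_informative)
      logv[idx, labels == 1L] <- logv[idx, labels == 1L] + cfg$effect_size
    }
    vals <- 10^logv
  })
  expression_matrix(vals,
                    gene_ids = paste0("g", seq_len(cfg$n_genes)),
                    sample_ids = paste0("s", seq_len(n)),
                    labels = labels)
}
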