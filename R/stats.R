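# Descriptive battery for reduced feature matrices: per-class moments,
# within-class sample correlation, and the first canonical correlation
# between the class feature blocks.

#' Descriptive statistics of a reduced feature matrix
#'
#' Per class: mean, variance, skewness and excess kurtosis over all feature
#' values, and the mean pairwise Pearson correlation between samples within
#' the class (`pairing = "sample"`, default) or between features
#' (`pairing = "feature"`). Across classes: the first canonical correlation
#' between the class feature blocks with samples as variables; classes of
#' unequal size are matched by seeded subsampling of the larger class.
#'
#' @param f A [feature_matrix] with >= 3 samples per class and >= 2 features.
#' @param pairing `"sample"` or `"feature"` correlation pairing.
#' @param seed Seed for the subsampling used by the canonical correlation.
#' @return A list of class `stat_summary` with per-class vectors `mean`,
#'   `variance`, `skewness`, `kurtosis_excess`, `pearson_cc` and the scalar
#'   `cca_first`.
#' @export
summarize_features <- function(f, pairing = c("sample", "feature"), seed = 1L) {
  stopifnot(inherits(f, "feature_matrix"))
  pairing <- match.arg(pairing)
  if (nrow(f$values) < 2L) {
    stop_microdiab("need >= 2 features", "microdiab_domain_error")
  }
  classes <- c(pos = 1L, neg = 0L)
  if (any(vapply(classes, function(cl) sum(f$labels == cl), 0L) < 3L)) {
    stop_microdiab("need >= 3 samples per class for the moment battery",
                   "microdiab_domain_error")
  }
  per_class <- lapply(classes, function(cl) {
    v <- f$values[, f$labels == cl, drop = FALSE]
    all_vals <- as.numeric(v)
    pc <- if (pairing == "sample") cor(v) else cor(t(v))
    list(mean = mean(all_vals),
         variance = var(all_vals),
         skewness = e1071::skewness(all_vals, type = 2L),
         kurtosis_excess = e1071::kurtosis(all_vals, type = 2L),
         pearson_cc = mean(pc[upper.tri(pc)]))
  })
  pick <- function(field) vapply(per_class, `[[`, numeric(1L), field)
  v1 <- f$values[, f$labels == 1L, drop = FALSE]
  v0 <- f$values[, f$labels == 0L, drop = FALSE]
  n_min <- min(ncol(v1), ncol(v0))
  withr::with_seed(seed, {
    v1 <- v1[, sort(sample.int(ncol(v1), n_min)), drop = FALSE]
    v0 <- v0[, sort(sample.int(ncol(v0), n_min)), drop = FALSE]
  })
  cca_first <- if (nrow(v1) > n_min) {
    cc <- cancor(v1, v0)
    cc$cor[1L]
  } else {
    NA_real_ # canonical correlation needs more features than samples per block
  }
  structure(list(mean = pick("mean"), variance = pick("variance"),
                 skewness = pick("skewness"),
                 kurtosis_excess = pick("kurtosis_excess"),
                 pearson_cc = pick("pearson_cc"),
                 cca_first = cca_first, pairing = pairing),
            class = "stat_summary")
}

#' @export
print.stat_summary <- function(x, digits = 4, ...) {
  tab <- rbind(mean = x$mean, variance = x$variance, skewness = x$skewness,
               kurtosis_excess = x$kurtosis_excess, pearson_cc = x$pearson_cc)
  colnames(tab) <- c("diabetic", "non-diabetic")
  print(round(tab, digits))
  cat(sprintf("first canonical correlation: %s\n",
              format(round(x$cca_first, digits))))
  invisible(x)
}

#' Export a stat summary as a one-row data frame (TSV-ready)
#'
#' @param x A `stat_summary`.
#' @return A data frame with one column per statistic and class.
#' @export
stat_summary_table <- function(x) {
  stopifnot(inherits(x, "stat_summary"))
  out <- data.frame(
    mean_dp = x$mean[["pos"]], mean_ndp = x$mean[["neg"]],
    variance_dp = x$variance[["pos"]], variance_ndp = x$variance[["neg"]],
    skewness_dp = x$skewness[["pos"]], skewness_ndp = x$skewness[["neg"]],
    kurtosis_dp = x$kurtosis_excess[["pos"]], kurtosis_ndp = x$kurtosis_excess[["neg"]],
    pearson_cc_dp = x$pearson_cc[["pos"]], pearson_cc_ndp = x$pearson_cc[["neg"]],
    cca_first = x$cca_first)
  out
}
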