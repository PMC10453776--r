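# Block-wise dimensionality reduction: each gene block (contiguous, size
# floor(n_genes / n_out), last block absorbing the remainder) is collapsed to
# one feature per sample by DFA, a chi-square block statistic against training
# reference means, or a swarm-optimized discriminative projection.

#' Feature matrix produced by reduction or selection
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param feature_ids Character vector of feature identifiers.
#' @param labels 0/1 label per sample, carried unchanged from the input cohort.
#' @param method Provenance tag (e.g. `"dfa"`, `"pso"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ids = NULL, labels = NULL,
                           method = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids %||% paste0("f", seq_len(nrow(values))))
  if (length(feature_ids) != nrow(values)) {
    stop_microdiab("length(feature_ids) must equal nrow(values)", "microdiab_format_error")
  }
  if (is.null(labels) || length(labels) != ncol(values)) {
    stop_microdiab("labels must have one entry per sample", "microdiab_label_error")
  }
  rownames(values) <- feature_ids
  structure(list(values = values, feature_ids = feature_ids,
                 labels = as.integer(labels), method = method),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d features x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Detrended fluctuation of a series over a single window
#'
#' The series is mean-subtracted and integrated into the profile
#' `A(n) = sum_{i<=n} (X(i) - mean(X))`; a least-squares polynomial trend of
#' order `detrend_order` is fitted to the profile over the whole window, and
#' the root-mean-square of the residuals is returned.
#'
#' @param series Numeric vector of length >= `detrend_order + 2`.
#' @param detrend_order Polynomial order of the trend (default 1, linear).
#' @return Non-negative fluctuation value.
#' @examples
#' dfa_fluctuation(c(5, 5, 5, 5)) # constant series integrates to zero
#' @export
dfa_fluctuation <- function(series, detrend_order = 1L) {
  detrend_order <- check_count(detrend_order, "detrend_order", min = 0L)
  n <- length(series)
  if (n < detrend_order + 2L) {
    stop_microdiab(sprintf("series of length %d too short for detrend order %d",
                           n, detrend_order),
                   "microdiab_length_error")
  }
  profile <- cumsum(series - mean(series))
  k <- seq_len(n)
  design <- stats::poly(k, degree = max(detrend_order, 1L), raw = TRUE)
  if (detrend_order == 0L) design <- design[, 0, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, design), profile)
  sqrt(mean(fit$residuals^2))
}

# Residual-maker matrix for DFA over a window of length L (linear detrend by
# default); lets a whole block of samples be detrended with one matrix product.
dfa_residual_projector <- function(L, detrend_order = 1L) {
  k <- seq_len(L)
  Xd <- cbind(1, stats::poly(k, degree = max(detrend_order, 1L), raw = TRUE))
  if (detrend_order == 0L) Xd <- Xd[, 1L, drop = FALSE]
  diag(L) - Xd %*% solve(crossprod(Xd), t(Xd))
}

#' Chi-square statistic between observed and expected values
#'
#' `sum((observed - expected)^2 / expected)`; zero exactly when the observed
#' values equal the expected ones.
#'
#' @param observed,expected Numeric vectors of equal length; `expected` must be
#'   strictly positive.
#' @return Non-negative statistic.
#' @examples
#' chi2_statistic(c(12, 8), c(10, 10)) # 0.8
#' @export
chi2_statistic <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop_microdiab("observed and expected must have the same length",
                   "microdiab_length_error")
  }
  if (any(expected <= 0)) {
    stop_microdiab("expected entries must be > 0", "microdiab_domain_error")
  }
  sum((observed - expected)^2 / expected)
}

#' Reduction configuration
#'
#' @param method One of `"dfa"`, `"chi2pdf"`, `"firefly"`, `"cuckoo"`.
#' @param n_out Number of output features (default 2870, the 10:1 reduction of
#'   the 28,735-gene cohort).
#' @param swarm A [swarm_params] for the firefly/cuckoo methods.
#' @param detrend_order DFA trend order (default 1).
#' @param chi2_stabilizer Constant added to the absolute training block means
#'   in the chi-square denominator; standardized samples have near-zero means,
#'   so the raw Eq.-style denominator would be unstable (default 1).
#' @param seed Integer seed for the swarm methods.
#' @return A list of class `reduction_config`.
#' @export
reduction_config <- function(method = c("dfa", "chi2pdf", "firefly", "cuckoo"),
                             n_out = 2870L, swarm = swarm_params(),
                             detrend_order = 1L, chi2_stabilizer = 1,
                             seed = 1L) {
  structure(list(method = match.arg(method), n_out = check_count(n_out, "n_out"),
                 swarm = swarm, detrend_order = check_count(detrend_order, "detrend_order", 0L),
                 chi2_stabilizer = check_scalar(chi2_stabilizer, "chi2_stabilizer", 0),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "reduction_config")
}

# Contiguous block index list: floor(n_genes/n_out) genes per block, final
# block absorbing the remainder, so exactly n_out blocks.
gene_blocks <- function(n_genes, n_out) {
  if (n_out > n_genes) {
    stop_microdiab("n_out must not exceed the number of genes", "microdiab_config_error")
  }
  size <- n_genes %/% n_out
  if (size < 2L) {
    stop_microdiab("block size floor(n_genes / n_out) must be >= 2", "microdiab_config_error")
  }
  starts <- (seq_len(n_out) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, n_genes)
  Map(seq.int, starts, ends)
}

# |Welch t| per row of a projections matrix, 0 where degenerate.
row_abs_t <- function(S, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  m1 <- rowMeans(S[, pos, drop = FALSE])
  m0 <- rowMeans(S[, !pos, drop = FALSE])
  v1 <- rowSums((S[, pos, drop = FALSE] - m1)^2) / (n1 - 1L)
  v0 <- rowSums((S[, !pos, drop = FALSE] - m0)^2) / (n0 - 1L)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- abs(m1 - m0) / se
  t[!is.finite(t)] <- 0
  t
}

#' Fit a block-wise dimensionality reducer on training data
#'
#' Computes, per contiguous gene block, whatever training statistics the
#' chosen method needs: nothing for DFA (stateless), per-gene training means
#' for the chi-square statistic, or a swarm-optimized weight vector in
#' \[-1, 1\]^L maximizing the |Welch t| of the projected block between the two
#' training classes (firefly/cuckoo). Test samples are reduced with these
#' frozen statistics via [predict.feature_reducer()], so no test information
#' leaks into the reference values.
#'
#' @param x A standardized [expression_matrix] of training samples.
#' @param config A [reduction_config].
#' @return An object of class `feature_reducer`.
#' @seealso [reduce_features()] for the fit-and-apply convenience wrapper.
#' @export
fit_reducer <- function(x, config = reduction_config()) {
  stopifnot(inherits(x, "expression_matrix"))
  blocks <- gene_blocks(nrow(x$values), config$n_out)
  r <- structure(list(method = config$method, config = config, blocks = blocks,
                      n_genes = nrow(x$values)),
                 class = "feature_reducer")
  if (config$method == "chi2pdf") {
    r$block_means <- lapply(blocks, function(idx) rowMeans(x$values[idx, , drop = FALSE]))
  } else if (config$method %in% c("firefly", "cuckoo")) {
    if (length(unique(x$labels)) < 2L) {
      stop_microdiab("swarm reducers need both classes in the training data",
                     "microdiab_class_error")
    }
    optimizer <- if (config$method == "firefly") firefly_optimize else cuckoo_optimize
    labels <- x$labels
    r$weights <- withr::with_seed(config$seed, lapply(blocks, function(idx) {
      B <- x$values[idx, , drop = FALSE]
      fitness <- function(W) row_abs_t(W %*% B, labels)
      optimizer(fitness, dim = length(idx), params = config$swarm)$best
    }))
  }
  r
}

#' @export
print.feature_reducer <- function(x, ...) {
  cat(sprintf("feature_reducer [%s]: %d genes -> %d features\n",
              x$method, x$n_genes, length(x$blocks)))
  invisible(x)
}

#' Apply a fitted reducer to new samples
#'
#' @param object A `feature_reducer` from [fit_reducer()].
#' @param newdata An [expression_matrix] with the same gene dimension as the
#'   training data.
#' @param ... Unused.
#' @return A [feature_matrix] with exactly `n_out` rows.
#' @export
predict.feature_reducer <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expression_matrix"))
  if (nrow(newdata$values) != object$n_genes) {
    stop_microdiab("gene dimension does not match the fitted reducer",
                   "microdiab_shape_error")
  }
  v <- newdata$values
  n_out <- length(object$blocks)
  out <- matrix(0, n_out, ncol(v))
  if (object$method == "dfa") {
    ord <- object$config$detrend_order
    # cache one residual projector per distinct block length
    lens <- lengths(object$blocks)
    projs <- lapply(unique(lens), dfa_residual_projector, detrend_order = ord)
    names(projs) <- as.character(unique(lens))
    for (j in seq_len(n_out)) {
      B <- v[object$blocks[[j]], , drop = FALSE]
      profile <- apply(sweep(B, 2L, colMeans(B)), 2L, cumsum)
      resid <- projs[[as.character(nrow(B))]] %*% profile
      out[j, ] <- sqrt(colMeans(resid^2))
    }
  } else if (object$method == "chi2pdf") {
    if (is.null(object$block_means)) {
      stop_microdiab("chi2pdf reducer has no training reference means",
                     "microdiab_missing_reference_error")
    }
    c0 <- object$config$chi2_stabilizer
    for (j in seq_len(n_out)) {
      m <- object$block_means[[j]]
      B <- v[object$blocks[[j]], , drop = FALSE]
      out[j, ] <- colSums((B - m)^2 / (abs(m) + c0))
    }
  } else {
    for (j in seq_len(n_out)) {
      out[j, ] <- drop(crossprod(object$weights[[j]],
                                 v[object$blocks[[j]], , drop = FALSE]))
    }
  }
  feature_matrix(out, feature_ids = paste0(object$method, "_b", seq_len(n_out)),
                 labels = newdata$labels, method = object$method)
}

#' Reduce a cohort to block features (fit and apply in one step)
#'
#' @inheritParams fit_reducer
#' @return A [feature_matrix] with `config$n_out` rows.
#' @examples
#' x <- standardize(generate_cohort(synthetic_config(n_genes = 40, n_pos = 4,
#'                                                   n_neg = 6, seed = 1)))
#' reduce_features(x, reduction_config("dfa", n_out = 4))
#' @export
reduce_features <- function(x, config = reduction_config()) {
  predict(fit_reducer(x, config), x)
}
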