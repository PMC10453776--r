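# Confusion matrix, the eight-metric suite, the metric-inversion helper used
# to reconstruct integer confusion matrices from printed accuracy/recall
# pairs, and stratified k-fold evaluation of a full pipeline.

#' Confusion matrix for diabetic (positive) vs non-diabetic detection
#'
#' @param truth,pred Equal-length 0/1 vectors (1 = diabetic).
#' @return Object of class `confusion_matrix` with integer cells `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop_microdiab("truth and pred must have equal length", "microdiab_shape_error")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  structure(list(tp = sum(truth == 1L & pred == 1L),
                 fn = sum(truth == 1L & pred == 0L),
                 fp = sum(truth == 0L & pred == 1L),
                 tn = sum(truth == 0L & pred == 0L)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from its four cells
#'
#' @param tp,fn,fp,tn Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_cells <- function(tp, fn, fp, tn) {
  cells <- c(tp, fn, fp, tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_microdiab("confusion cells must be non-negative integers",
                   "microdiab_domain_error")
  }
  cells <- as.integer(round(cells))
  structure(list(tp = cells[1L], fn = cells[2L], fp = cells[3L], tn = cells[4L]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, byrow = TRUE,
              dimnames = list(c("truth diabetic", "truth non-diabetic"),
                              c("pred diabetic", "pred non-diabetic")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) structure(0, flagged = TRUE) else num / den

#' Eight-metric performance report from a confusion matrix
#'
#' Computes accuracy, recall, precision, F1, Matthews correlation coefficient,
#' error rate, the Jaccard (Tanimoto) metric and Cohen's kappa with its
#' agreement components `po` and `pe`. Ratios that are 0/0 are reported as 0
#' and flagged in `attr(, "zero_division")`.
#'
#' @param cm A `confusion_matrix`.
#' @return A list of class `metrics_report`.
#' @examples
#' metrics(confusion_cells(18, 2, 4, 46))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop_microdiab("empty confusion matrix", "microdiab_domain_error")
  flagged <- character(0)
  grab <- function(val, name) {
    if (isTRUE(attr(val, "flagged"))) flagged <<- c(flagged, name)
    as.numeric(val)
  }
  accuracy <- (tp + tn) / n
  recall <- grab(safe_ratio(tp, tp + fn), "recall")
  precision <- grab(safe_ratio(tp, tp + fp), "precision")
  f1 <- grab(safe_ratio(2 * tp, 2 * tp + fp + fn), "f1")
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- grab(if (mcc_den == 0) structure(0, flagged = TRUE)
              else (tp * tn - fp * fn) / mcc_den, "mcc")
  jaccard <- grab(safe_ratio(tp, tp + fp + fn), "jaccard")
  po <- accuracy
  pe <- (as.numeric(tp + fp) * (tp + fn) + as.numeric(fp + tn) * (fn + tn)) / n^2
  kappa <- grab(if (pe == 1) structure(0, flagged = TRUE) else (po - pe) / (1 - pe),
                "kappa")
  structure(list(accuracy = accuracy, recall = recall, precision = precision,
                 f1 = f1, mcc = mcc, error_rate = 1 - accuracy,
                 jaccard = jaccard, kappa = kappa, po = po, pe = pe),
            zero_division = flagged,
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  v <- unlist(x[c("accuracy", "recall", "precision", "f1", "mcc",
                  "error_rate", "jaccard", "kappa")])
  print(round(v, digits))
  invisible(x)
}

#' Reconstruct the integer confusion matrix behind printed accuracy and recall
#'
#' On a cohort of `n_pos` positives and `n_neg` negatives the accuracy and
#' recall determine the confusion matrix uniquely:
#' `tp = recall * n_pos` and `tp + tn = accuracy * (n_pos + n_neg)` must both
#' be integers (within `tol`).
#'
#' @param accuracy,recall Printed rates on the 0-1 scale.
#' @param n_pos,n_neg Class sizes.
#' @param tol Allowed distance from an integer (default 1e-3, covering
#'   truncated 4-decimal percentages).
#' @return A `confusion_matrix`.
#' @examples
#' invert_metrics(0.914285, 0.90, 20, 50)
#' @export
invert_metrics <- function(accuracy, recall, n_pos, n_neg, tol = 1e-3) {
  n <- n_pos + n_neg
  tp_raw <- recall * n_pos
  correct_raw <- accuracy * n
  if (abs(tp_raw - round(tp_raw)) > tol * n_pos ||
      abs(correct_raw - round(correct_raw)) > tol * n) {
    stop_microdiab("accuracy/recall do not correspond to integer cell counts",
                   "microdiab_inversion_error")
  }
  tp <- round(tp_raw)
  tn <- round(correct_raw) - tp
  fn <- n_pos - tp
  fp <- n_neg - tn
  if (min(tp, tn, fn, fp) < 0) {
    stop_microdiab("inverted confusion matrix has a negative cell",
                   "microdiab_inversion_error")
  }
  confusion_cells(tp, fn, fp, tn)
}

#' Pipeline specification for k-fold evaluation
#'
#' @param reduction A [reduction_config], or `NULL` to classify the gene-level
#'   matrix directly.
#' @param selection A [pso_config] or [hs_config], or `NULL` for the
#'   no-feature-selection regime.
#' @param kind Classifier kind (see [fit_classifier()]).
#' @param params Classifier parameters.
#' @param targets A [target_map].
#' @param log_transform Passed to [standardize()].
#' @return A list of class `pipeline_spec`.
#' @export
pipeline_spec <- function(reduction = reduction_config(), selection = NULL,
                          kind = "svm_rbf", params = list(),
                          targets = target_map(), log_transform = TRUE) {
  structure(list(reduction = reduction, selection = selection, kind = kind,
                 params = params, targets = targets,
                 log_transform = log_transform),
            class = "pipeline_spec")
}

select_with <- function(f, selection) {
  if (inherits(selection, "pso_config")) pso_select(f, selection)
  else if (inherits(selection, "hs_config")) hs_select(f, selection)
  else stop_microdiab("selection must be a pso_config or hs_config",
                      "microdiab_config_error")
}

# Train on one fold: fit reducer/selector/classifier on training samples only,
# return out-of-fold predictions.
fit_fold <- function(xs, train, test, spec, seed) {
  xtr <- expression_matrix(xs$values[, train, drop = FALSE],
                           xs$gene_ids, xs$sample_ids[train], xs$labels[train])
  xte <- expression_matrix(xs$values[, test, drop = FALSE],
                           xs$gene_ids, xs$sample_ids[test], xs$labels[test])
  if (!is.null(spec$reduction)) {
    cfg <- spec$reduction
    cfg$seed <- seed
    red <- fit_reducer(xtr, cfg)
    ftr <- predict(red, xtr)
    fte <- predict(red, xte)
  } else {
    ftr <- feature_matrix(xtr$values, xtr$gene_ids, xtr$labels, "genes")
    fte <- feature_matrix(xte$values, xte$gene_ids, xte$labels, "genes")
  }
  if (!is.null(spec$selection)) {
    sel_cfg <- spec$selection
    sel_cfg$seed <- seed
    ftr <- select_with(ftr, sel_cfg)
    idx <- attr(ftr, "selected_index")
    fte <- feature_matrix(fte$values[idx, , drop = FALSE],
                          fte$feature_ids[idx], fte$labels, ftr$method)
  }
  model <- fit_classifier(ftr, kind = spec$kind, params = spec$params,
                          targets = spec$targets, seed = seed)
  list(pred = predict(model, fte), truth = fte$labels)
}

#' Stratified k-fold evaluation of a classification pipeline
#'
#' Splits samples into `k` stratified folds (seeded); for each fold the
#' reduction statistics, feature selection and classifier are fitted on the
#' training samples only and applied to the held-out fold. Metrics are
#' computed from the pooled out-of-fold confusion matrix by default
#' (macro averaging over per-fold reports is available).
#'
#' @param x An [expression_matrix] of raw positive intensities (or already
#'   standardized data with `spec$log_transform = FALSE` and
#'   `standardized = TRUE`).
#' @param spec A [pipeline_spec].
#' @param k Number of folds (default 10). Each class needs at least `k`
#'   samples; otherwise stratification is relaxed with a warning.
#' @param seed Integer seed controlling folds and every stochastic stage.
#' @param aggregate `"pooled"` (default) or `"macro"`.
#' @param standardized Set `TRUE` when `x` is already standardized.
#' @return List of class `kfold_result` with `report` (a `metrics_report`),
#'   `confusion`, per-fold reports, fold assignment, predictions and truth.
#' @export
kfold_evaluate <- function(x, spec = pipeline_spec(), k = 10L, seed = 1L,
                           aggregate = c("pooled", "macro"),
                           standardized = FALSE) {
  stopifnot(inherits(x, "expression_matrix"), inherits(spec, "pipeline_spec"))
  aggregate <- match.arg(aggregate)
  k <- check_count(k, "k", 2L)
  n <- ncol(x$values)
  if (k > n) stop_microdiab("k exceeds the number of samples", "microdiab_config_error")
  if (min(sum(x$labels == 1L), sum(x$labels == 0L)) < k) {
    warning("fewer samples than folds in a class; stratification relaxed")
  }
  xs <- if (standardized) x else standardize(x, log_transform = spec$log_transform)
  fold <- withr::with_seed(seed, stratified_folds(x$labels, k))
  preds <- integer(n); truth <- x$labels
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    res <- fit_fold(xs, train, test, spec, seed = seed + f)
    preds[test] <- res$pred
    fold_reports[[f]] <- metrics(confusion(res$truth, res$pred))
  }
  cm <- confusion(truth, preds)
  report <- if (aggregate == "pooled") {
    metrics(cm)
  } else {
    avg <- Reduce(`+`, lapply(fold_reports, function(r) unlist(unclass(r)))) / k
    structure(as.list(avg), class = "metrics_report")
  }
  structure(list(report = report, confusion = cm, fold_reports = fold_reports,
                 fold = fold, predictions = preds, truth = truth,
                 k = k, seed = seed, aggregate = aggregate),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s aggregation)\n", x$k, x$aggregate))
  print(x$report)
  invisible(x)
}
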