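# Expression-matrix container and delimited-text I/O.

#' Expression matrix with sample labels
#'
#' Container for a genes x samples intensity matrix with a binary class label
#' per sample (1 = diabetic, the positive class; 0 = non-diabetic).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of row identifiers (default `g1, g2, ...`).
#' @param sample_ids Character vector of column identifiers.
#' @param labels Integer/numeric vector of 0/1 class labels, one per sample.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels`.
#' @examples
#' x <- expression_matrix(matrix(1:6, 3, 2), labels = c(1, 0))
#' dim(x$values)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids %||% paste0("g", seq_len(nrow(values))))
  sample_ids <- as.character(sample_ids %||% paste0("s", seq_len(ncol(values))))
  if (is.null(labels)) {
    stop_microdiab("`labels` are required (1 = diabetic, 0 = non-diabetic)",
                   "microdiab_label_error")
  }
  labels <- as.integer(labels)
  if (length(gene_ids) != nrow(values)) {
    stop_microdiab("length(gene_ids) must equal nrow(values)", "microdiab_format_error")
  }
  if (length(sample_ids) != ncol(values) || length(labels) != ncol(values)) {
    stop_microdiab("sample_ids and labels must have one entry per column",
                   "microdiab_format_error")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_microdiab(sprintf("missing value at gene %s, sample %s",
                           gene_ids[bad[1L]], sample_ids[bad[2L]]),
                   "microdiab_parse_error")
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_microdiab("labels must be 0/1", "microdiab_label_error")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d diabetic, %d non-diabetic)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

label_tokens <- c("diabetic" = 1L, "non-diabetic" = 0L, "nondiabetic" = 0L,
                  "1" = 1L, "0" = 0L)

parse_labels <- function(tokens, sample_ids) {
  lab <- label_tokens[tolower(trimws(as.character(tokens)))]
  if (anyNA(lab)) {
    bad <- tokens[is.na(lab)][1L]
    stop_microdiab(sprintf("unknown label token '%s' (expected diabetic/non-diabetic or 1/0)", bad),
                   "microdiab_label_error")
  }
  unname(lab)
}

#' Read an expression matrix and its labels from delimited text
#'
#' The expression file holds genes as rows: a header row of sample ids, a first
#' column of gene ids, numeric intensities elsewhere. Labels come from a
#' two-column sidecar file (`sample_id`, `label`) whose label tokens are
#' `diabetic`/`non-diabetic` (case-insensitive) or `1`/`0`; labels are aligned
#' to the sample order of the expression file.
#'
#' @param path Path to the expression table.
#' @param labels_path Path to the two-column label table.
#' @param sep Field delimiter for both files (default tab).
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, labels_path, sep = "\t") {
  if (!file.exists(path)) {
    stop_microdiab(sprintf("expression file not found: %s", path), "microdiab_format_error")
  }
  if (!file.exists(labels_path)) {
    stop_microdiab(sprintf("label file not found: %s", labels_path), "microdiab_format_error")
  }
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, colClasses = list(character = 1L),
                      data.table = FALSE, fill = FALSE),
    error = function(e) stop_microdiab(sprintf("ragged or malformed table: %s",
                                               conditionMessage(e)),
                                       "microdiab_format_error"))
  gene_ids <- as.character(dt[[1L]])
  sample_ids <- colnames(dt)[-1L]
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (is.character(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    if (anyNA(num) ) {
      bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
      stop_microdiab(sprintf("non-numeric cell at gene %s, sample %s",
                             gene_ids[bad[1L]], sample_ids[bad[2L]]),
                     "microdiab_parse_error")
    }
    vals <- num
  }
  storage.mode(vals) <- "double"
  lab_dt <- data.table::fread(labels_path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(lab_dt) < 2L) {
    stop_microdiab("label file must have columns sample_id, label", "microdiab_format_error")
  }
  idx <- match(sample_ids, as.character(lab_dt[[1L]]))
  if (anyNA(idx)) {
    stop_microdiab(sprintf("no label for sample %s", sample_ids[which(is.na(idx))[1L]]),
                   "microdiab_label_error")
  }
  labels <- parse_labels(lab_dt[[2L]][idx], sample_ids)
  expression_matrix(vals, gene_ids, sample_ids, labels)
}

#' Write an expression matrix and its labels to delimited text
#'
#' Inverse of [read_expression()]; values round-trip to full double precision.
#'
#' @param x An [expression_matrix].
#' @param path Output path for the expression table.
#' @param labels_path Output path for the label table.
#' @param sep Field delimiter (default tab).
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, labels_path, sep = "\t") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", x$sample_ids)
  data.table::fwrite(df, path, sep = sep)
  lab <- data.frame(sample_id = x$sample_ids,
                    label = ifelse(x$labels == 1L, "diabetic", "non-diabetic"))
  data.table::fwrite(lab, labels_path, sep = sep)
  invisible(x)
}

#' Per-sample log10 standardization
#'
#' Each sample (column) is log10-transformed, then shifted and scaled so its
#' mean is 0 and its variance is 1. The population variance convention
#' (divide by n) is the default, since the target is literally "mean 0,
#' variance 1" for the column as a finite set of values; sample variance
#' (divide by n-1) is available behind `variance`.
#'
#' @param x An [expression_matrix] (or bare numeric matrix, samples in columns).
#' @param log_transform If `FALSE`, skip the log10 step (for data already on a
#'   log scale). The log step requires strictly positive intensities.
#' @param variance `"population"` (default) or `"sample"`.
#' @return Object of the same class with transformed values.
#' @examples
#' x <- expression_matrix(matrix(c(10, 100, 1000, 1, 2, 4), 3, 2), labels = c(1, 0))
#' standardize(x)$values
#' @export
standardize <- function(x, log_transform = TRUE, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  is_em <- inherits(x, "expression_matrix")
  v <- if (is_em) x$values else as.matrix(x)
  if (log_transform) {
    if (any(v <= 0)) {
      bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
      gid <- if (is_em) x$gene_ids[bad[1L]] else as.character(bad[1L])
      sid <- if (is_em) x$sample_ids[bad[2L]] else as.character(bad[2L])
      stop_microdiab(sprintf("non-positive intensity at gene %s, sample %s (log10 domain)",
                             gid, sid),
                     "microdiab_domain_error")
    }
    v <- log10(v)
  }
  n <- nrow(v)
  mu <- colMeans(v)
  centred <- sweep(v, 2L, mu)
  ss <- colSums(centred^2)
  denom <- if (variance == "population") n else n - 1L
  s <- sqrt(ss / denom)
  if (any(s == 0)) {
    sid <- if (is_em) x$sample_ids[which(s == 0)[1L]] else as.character(which(s == 0)[1L])
    stop_microdiab(sprintf("sample %s has zero variance after transform", sid),
                   "microdiab_degenerate_error")
  }
  out <- sweep(centred, 2L, s, "/")
  if (is_em) {
    x$values <- out
    dimnames(x$values) <- list(x$gene_ids, x$sample_ids)
    x
  } else {
    out
  }
}
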