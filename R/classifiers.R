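# Seven two-class classifiers sharing one interface: every model predicts a
# continuous score which a target map converts to class labels. Regression
# models are trained toward mapped class targets (non-diabetic 0.1, diabetic
# 0.85, separated by at least 0.5) and thresholded at the target midpoint;
# logistic regression thresholds its probability at 0.5; the mixture, softmax
# and SVM models label by the sign/arg-max of their class scores.

CLASSIFIER_KINDS <- c("nlr", "lr", "lor", "gmm", "bldc", "sdc", "svm_rbf")

#' Target map for score-to-class conversion
#'
#' @param t_nd Regression target for the non-diabetic class (default 0.1).
#' @param t_dia Regression target for the diabetic class (default 0.85).
#' @param threshold Decision cut for regression scores (default the midpoint,
#'   0.475). A score strictly above the threshold is labelled diabetic; a tie
#'   goes to the negative class.
#' @return A list of class `target_map`.
#' @export
target_map <- function(t_nd = 0.1, t_dia = 0.85, threshold = (t_nd + t_dia) / 2) {
  if (abs(t_dia - t_nd) < 0.5) {
    stop_microdiab("|t_dia - t_nd| must be >= 0.5", "microdiab_config_error")
  }
  if (!(t_nd < threshold && threshold < t_dia)) {
    stop_microdiab("threshold must lie between t_nd and t_dia", "microdiab_config_error")
  }
  structure(list(t_nd = t_nd, t_dia = t_dia, threshold = threshold),
            class = "target_map")
}

mapped_targets <- function(labels, targets) {
  ifelse(labels == 1L, targets$t_dia, targets$t_nd)
}

#' Mean squared error
#'
#' @param observed,target Numeric vectors of equal, positive length.
#' @return Mean of squared differences.
#' @export
mse <- function(observed, target) {
  if (length(observed) == 0L || length(observed) != length(target)) {
    stop_microdiab("observed and target must be non-empty and equal length",
                   "microdiab_length_error")
  }
  mean((observed - target)^2)
}

as_values <- function(f) {
  if (inherits(f, "feature_matrix")) f$values else as.matrix(f)
}

# Iterative-fit stopping rule shared by the regression-family models.
MSE_TOL <- 1e-12
MAX_ITER <- 2000L

#' Fit a diabetes classifier
#'
#' @param f A [feature_matrix] (or bare features x samples matrix plus
#'   `labels`) of training samples; both classes must have >= 2 samples.
#' @param kind One of `"nlr"` (non-linear regression fitted by
#'   Levenberg-Marquardt), `"lr"` (linear regression, minimum-norm least
#'   squares), `"lor"` (ridge-penalized logistic regression), `"gmm"`
#'   (per-class Gaussian mixtures fitted by EM), `"bldc"` (Bayesian linear
#'   discriminant; closed-form ridge posterior mean), `"sdc"` (softmax
#'   discriminant over distances to training samples), `"svm_rbf"` (RBF-kernel
#'   support vector machine).
#' @param params Method-specific parameters; see Details.
#' @param targets A [target_map].
#' @param labels 0/1 labels when `f` is a bare matrix.
#' @param seed Integer seed for the stochastic fits (gmm restarts).
#' @details Parameter defaults: `lor` uses shrinkage `tau = 1`;
#'   `gmm` uses `g = 2` components per class with 3 seeded EM restarts;
#'   `bldc` uses hyperparameters `alpha = 1`, `beta = 1`, bias penalty
#'   `eps = 1e-6`; `sdc` uses penalty `lambda = 1`; `svm_rbf` uses `C = 1`,
#'   `gamma = 100` (kernel `exp(-gamma * ||x - y||^2)`; pass `sigma` to use
#'   the `1/(2*sigma)^2` parameterization instead) and positive-class weight
#'   `class_weight_pos = 0.86` applied as a multiplier on `C`. Iterative fits
#'   stop when the training MSE reaches 1e-12 or after 2000 iterations.
#' @return An object of classes `c("diab_<kind>", "diab_classifier")` whose
#'   parameter record is plain numeric data (JSON-serializable via
#'   [save_model()]); scores are computed from the stored record.
#' @export
fit_classifier <- function(f, kind = CLASSIFIER_KINDS, params = list(),
                           targets = target_map(), labels = NULL, seed = 1L) {
  kind <- match.arg(kind)
  x <- as_values(f)
  labels <- as.integer(labels %||% f$labels)
  if (length(labels) != ncol(x)) {
    stop_microdiab("labels must have one entry per sample", "microdiab_label_error")
  }
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop_microdiab("each class needs >= 2 training samples", "microdiab_class_error")
  }
  if (any(!is.finite(x))) {
    stop_microdiab("non-finite feature values", "microdiab_domain_error")
  }
  fitter <- switch(kind, nlr = fit_nlr, lr = fit_lr, lor = fit_lor,
                   gmm = fit_gmm, bldc = fit_bldc, sdc = fit_sdc,
                   svm_rbf = fit_svm_rbf)
  m <- fitter(x, labels, params, targets, seed)
  m$kind <- kind
  m$targets <- targets
  m$n_features <- nrow(x)
  structure(m, class = c(paste0("diab_", kind), "diab_classifier"))
}

# --- non-linear regression: sigmoid link scaled to [t_nd, t_dia], fitted by
# Levenberg-Marquardt with adaptive damping ------------------------------------
fit_nlr <- function(x, labels, params, targets, seed) {
  y <- mapped_targets(labels, targets)
  p <- nrow(x); n <- ncol(x)
  span <- targets$t_dia - targets$t_nd
  theta <- numeric(p + 1L)
  design <- rbind(1, x)
  tau <- params$tau %||% 1e-2
  max_iter <- params$max_iter %||% MAX_ITER
  predict_eta <- function(th) drop(crossprod(design, th))
  score_of <- function(th) targets$t_nd + span * stats::plogis(predict_eta(th))
  s <- score_of(theta)
  rss <- sum((y - s)^2)
  trace <- rss / n
  for (it in seq_len(max_iter)) {
    sig <- (s - targets$t_nd) / span
    J <- t(design) * (span * sig * (1 - sig)) # n x (p+1)
    g <- crossprod(J, y - s)
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (try in 1:8) {
      delta <- tryCatch(solve(JtJ + tau * diag(p + 1L), g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        s_cand <- score_of(cand)
        rss_cand <- sum((y - s_cand)^2)
        if (is.finite(rss_cand) && rss_cand < rss) {
          theta <- cand; s <- s_cand
          improvement <- rss - rss_cand
          rss <- rss_cand
          tau <- tau / 10
          accepted <- TRUE
          break
        }
      }
      tau <- tau * 10
    }
    if (!accepted) break
    trace <- c(trace, rss / n)
    if (rss / n <= MSE_TOL || improvement / max(rss, 1e-300) < 1e-12) break
  }
  list(parameters = list(theta = theta, tau = tau,
                         t_nd = targets$t_nd, t_dia = targets$t_dia),
       training_mse_trace = trace)
}

# --- linear regression onto mapped targets (minimum-norm least squares) -------
fit_lr <- function(x, labels, params, targets, seed) {
  y <- mapped_targets(labels, targets)
  design <- t(rbind(1, x)) # n x (p+1)
  sv <- svd(design)
  tol <- max(dim(design)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  if (!any(keep)) {
    stop_microdiab("singular design in linear regression", "microdiab_conditioning_error")
  }
  theta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  fittedv <- drop(design %*% theta)
  list(parameters = list(theta = drop(theta)),
       training_mse_trace = mse(fittedv, y))
}

# --- logistic regression with ridge shrinkage (IRLS on the penalized
# log-likelihood; penalty 1/(2 tau^2) ||coef||^2, intercept unpenalized) -------
fit_lor <- function(x, labels, params, targets, seed) {
  tau <- params$tau %||% 1
  design <- t(rbind(1, x)) # n x (p+1)
  p1 <- ncol(design)
  pen <- c(0, rep(1 / tau^2, p1 - 1L))
  beta <- numeric(p1)
  trace <- numeric(0)
  for (it in seq_len(params$max_iter %||% 100L)) {
    eta <- drop(design %*% beta)
    pi_hat <- stats::plogis(eta)
    W <- pmax(pi_hat * (1 - pi_hat), 1e-10)
    H <- crossprod(design, design * W) + diag(pen)
    g <- crossprod(design, labels - pi_hat) - pen * beta
    delta <- tryCatch(solve(H, g), error = function(e)
      stop_microdiab("singular system in logistic regression",
                     "microdiab_conditioning_error"))
    beta <- beta + drop(delta)
    trace <- c(trace, mse(stats::plogis(drop(design %*% beta)), labels))
    if (sqrt(sum(delta^2)) < 1e-10 || trace[length(trace)] <= MSE_TOL) break
  }
  list(parameters = list(upsilon = beta, tau = tau),
       training_mse_trace = trace)
}

# --- per-class Gaussian mixtures (EM via mclust, diagonal fallback) -----------
variance_floor <- function(S, floor = 1e-8) {
  d <- diag(S)
  if (any(d < floor)) {
    diag(S) <- pmax(d, floor)
    attr(S, "floored") <- TRUE
  }
  S
}

fit_gmm_class <- function(data, g, model, seed) {
  # data: n_c x p
  fit <- withr::with_seed(seed, tryCatch(
    suppressWarnings(mclust::Mclust(data, G = g, modelNames = model,
                                    verbose = FALSE)),
    error = function(e) NULL))
  if (is.null(fit) && g > 1L) {
    return(fit_gmm_class(data, 1L, model, seed))
  }
  if (is.null(fit)) { # single diagonal Gaussian fallback
    mu <- colMeans(data)
    v <- pmax(apply(data, 2L, var), 1e-8)
    return(list(weights = 1, means = list(mu), covs = list(diag(v, length(v)))))
  }
  G <- fit$G
  means <- lapply(seq_len(G), function(j) fit$parameters$mean[, j])
  sig <- fit$parameters$variance$sigma
  floored <- FALSE
  covs <- lapply(seq_len(G), function(j) {
    S <- variance_floor(as.matrix(sig[, , j]))
    if (isTRUE(attr(S, "floored"))) floored <<- TRUE
    attr(S, "floored") <- NULL
    S
  })
  if (floored) warning("degenerate mixture covariance regularized with a variance floor")
  list(weights = as.numeric(fit$parameters$pro) %||% 1, means = means, covs = covs)
}

fit_gmm <- function(x, labels, params, targets, seed) {
  g <- params$g %||% 2L
  p <- nrow(x)
  comps <- list()
  for (cl in c("0", "1")) {
    data <- t(x[, labels == as.integer(cl), drop = FALSE])
    model <- params$model %||% (if (p < nrow(data)) "VVV" else "VVI")
    gc <- min(g, nrow(data) - 1L)
    comps[[cl]] <- fit_gmm_class(data, max(gc, 1L), model, seed)
    comps[[cl]]$weights <- comps[[cl]]$weights / sum(comps[[cl]]$weights)
  }
  pars <- list(class0 = comps[["0"]], class1 = comps[["1"]],
               prior1 = mean(labels == 1L))
  m <- list(parameters = pars)
  m$training_mse_trace <- NA_real_ # filled after scoring below
  m
}

log_mvnorm <- function(v, mu, S) {
  # v: p x n matrix of points (columns)
  p <- length(mu)
  ch <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-6, p)))
  z <- backsolve(ch, v - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 2L, max)
  mx + log(colSums(exp(sweep(M, 2L, mx))))
}

gmm_class_logdens <- function(comp, v) {
  L <- vapply(seq_along(comp$weights), function(j) {
    log(comp$weights[j]) + log_mvnorm(v, comp$means[[j]], comp$covs[[j]])
  }, numeric(ncol(v)))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  logsumexp_rows(t(L))
}

# --- Bayesian linear discriminant: closed-form ridge posterior ----------------
fit_bldc <- function(x, labels, params, targets, seed) {
  alpha <- params$alpha %||% 1
  beta <- params$beta %||% 1
  eps <- params$eps %||% 1e-6
  a <- mapped_targets(labels, targets)
  B <- rbind(x, 1) # (l+1) x n, bias row last
  l1 <- nrow(B)
  Hp <- diag(c(rep(alpha, l1 - 1L), eps), l1)
  A <- beta * tcrossprod(B) + Hp
  upsilon <- beta * solve(A, B %*% a)
  X <- solve(A)
  fittedv <- drop(crossprod(B, upsilon))
  list(parameters = list(upsilon = drop(upsilon), alpha = alpha, beta = beta,
                         eps = eps),
       posterior_cov = X,
       training_mse_trace = mse(fittedv, a))
}

# --- softmax discriminant over distances to stored training samples -----------
fit_sdc <- function(x, labels, params, targets, seed) {
  lambda <- params$lambda %||% 1
  list(parameters = list(lambda = lambda,
                         Z0 = x[, labels == 0L, drop = FALSE],
                         Z1 = x[, labels == 1L, drop = FALSE]),
       training_mse_trace = NA_real_)
}

sdc_class_score <- function(Z, v, lambda) {
  # log sum_j exp(-lambda ||v - z_j||^2), column-wise over v, stable
  d2 <- outer(colSums(v^2), colSums(Z^2), "+") - 2 * crossprod(v, Z) # n x m
  E <- -lambda * d2
  mx <- apply(E, 1L, max)
  mx + log(rowSums(exp(E - mx)))
}

# --- RBF-kernel SVM (dual fit via e1071; scoring from stored duals) -----------
fit_svm_rbf <- function(x, labels, params, targets, seed) {
  C <- params$C %||% 1
  gamma <- if (!is.null(params$sigma)) 1 / (2 * params$sigma)^2 else params$gamma %||% 100
  cwp <- params$class_weight_pos %||% 0.86
  center <- rowMeans(x)
  scale_ <- apply(x, 1L, sd)
  scale_[scale_ == 0] <- 1
  xs <- (x - center) / scale_
  y <- factor(ifelse(labels == 1L, "pos", "neg"), levels = c("pos", "neg"))
  fit <- tryCatch(
    e1071::svm(x = t(xs), y = y, scale = FALSE, kernel = "radial",
               gamma = gamma, cost = C,
               class.weights = c(pos = cwp, neg = 1)),
    error = function(e) stop_microdiab(paste("SVM solver failed:", conditionMessage(e)),
                                       "microdiab_solver_error"))
  sv <- t(fit$SV) # p x nSV
  coefs <- drop(fit$coefs)
  rho <- fit$rho
  # normalize decision orientation: positive decision value = diabetic
  dec <- svm_decision(sv, coefs, rho, gamma, xs)
  orient <- suppressWarnings(cor(dec, labels))
  if (is.finite(orient) && orient < 0) {
    coefs <- -coefs
    rho <- -rho
  }
  list(parameters = list(support_vectors = sv, dual_coefs = coefs, rho = rho,
                         gamma = gamma, C = C, class_weight_pos = cwp,
                         center = center, scale = scale_),
       training_mse_trace = NA_real_)
}

svm_decision <- function(sv, coefs, rho, gamma, v) {
  d2 <- outer(colSums(v^2), colSums(sv^2), "+") - 2 * crossprod(v, sv)
  drop(exp(-gamma * pmax(d2, 0)) %*% coefs) - rho
}

#' Predict continuous scores from a fitted classifier
#'
#' Regression-family scores live near the target interval; logistic, mixture
#' and softmax scores are probabilities of the diabetic class in \[0, 1\]; SVM
#' scores are signed decision values.
#'
#' @param m A fitted `diab_classifier`.
#' @param f A [feature_matrix] or features x samples matrix with the training
#'   feature dimensionality.
#' @return Numeric vector, one score per sample.
#' @export
predict_score <- function(m, f) {
  stopifnot(inherits(m, "diab_classifier"))
  v <- as_values(f)
  if (nrow(v) != m$n_features) {
    stop_microdiab(sprintf("feature dimension %d does not match training dimension %d",
                           nrow(v), m$n_features),
                   "microdiab_shape_error")
  }
  p <- m$parameters
  out <- switch(m$kind,
    nlr = p$t_nd + (p$t_dia - p$t_nd) *
      stats::plogis(drop(crossprod(rbind(1, v), p$theta))),
    lr = drop(crossprod(rbind(1, v), p$theta)),
    lor = stats::plogis(drop(crossprod(rbind(1, v), p$upsilon))),
    bldc = drop(crossprod(rbind(v, 1), p$upsilon)),
    gmm = {
      l1 <- gmm_class_logdens(p$class1, v) + log(p$prior1)
      l0 <- gmm_class_logdens(p$class0, v) + log(1 - p$prior1)
      1 / (1 + exp(l0 - l1))
    },
    sdc = {
      s1 <- sdc_class_score(p$Z1, v, p$lambda)
      s0 <- sdc_class_score(p$Z0, v, p$lambda)
      1 / (1 + exp(s0 - s1))
    },
    svm_rbf = svm_decision(p$support_vectors, p$dual_coefs, p$rho, p$gamma,
                           (v - p$center) / p$scale))
  if (any(!is.finite(out))) {
    stop_microdiab("non-finite prediction score", "microdiab_domain_error")
  }
  unname(out)
}

#' Convert scores to class labels
#'
#' Regression-family models (`nlr`, `lr`, `bldc`) label diabetic when the
#' score strictly exceeds the target-map threshold; logistic, mixture and
#' softmax scores are cut at 0.5; SVM decision values at 0. A score exactly at
#' the cut goes to the negative class.
#'
#' @param scores Numeric score vector from [predict_score()].
#' @param m The fitted `diab_classifier` the scores came from.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(scores, m) {
  stopifnot(inherits(m, "diab_classifier"))
  cut <- switch(m$kind,
                nlr = , lr = , bldc = m$targets$threshold,
                lor = , gmm = , sdc = 0.5,
                svm_rbf = 0)
  as.integer(scores > cut)
}

#' @export
predict.diab_classifier <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- predict_score(object, newdata)
  if (type == "score") s else classify(s, object)
}

#' @export
print.diab_classifier <- function(x, ...) {
  cat(sprintf("diab_classifier [%s]: %d features, targets (%.2f, %.2f)\n",
              x$kind, x$n_features, x$targets$t_nd, x$targets$t_dia))
  invisible(x)
}

#' @export
summary.diab_classifier <- function(object, ...) {
  cat(sprintf("Kind: %s\nFeatures: %d\nTargets: non-diabetic %.3f, diabetic %.3f, threshold %.3f\n",
              object$kind, object$n_features, object$targets$t_nd,
              object$targets$t_dia, object$targets$threshold))
  tr <- object$training_mse_trace
  if (length(tr) && all(is.finite(tr))) {
    cat(sprintf("Training MSE: %.3g after %d iteration(s)\n", tail(tr, 1L), length(tr)))
  }
  invisible(object)
}

# --- plain-text model persistence --------------------------------------------

serialize_component <- function(x) {
  if (is.matrix(x)) list(.matrix = TRUE, dim = dim(x), data = as.numeric(x))
  else if (is.list(x)) lapply(x, serialize_component)
  else x
}

deserialize_component <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) matrix(as.numeric(unlist(x$data)), x$dim[1L], x$dim[2L])
  else if (is.list(x)) lapply(x, deserialize_component)
  else x
}

#' Save a fitted classifier as JSON text
#'
#' The stored record (kind, parameter record, target map, feature count) is
#' sufficient to reproduce predictions exactly; [load_model()] is the inverse.
#'
#' @param m A fitted `diab_classifier`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "diab_classifier"))
  obj <- list(kind = m$kind,
              parameters = serialize_component(m$parameters),
              targets = unclass(m$targets),
              n_features = m$n_features,
              training_mse_trace = m$training_mse_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `diab_classifier`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  m <- list(kind = obj$kind,
            parameters = deserialize_component(obj$parameters),
            targets = do.call(target_map, as.list(obj$targets)),
            n_features = obj$n_features,
            training_mse_trace = as.numeric(unlist(obj$training_mse_trace)))
  structure(m, class = c(paste0("diab_", obj$kind), "diab_classifier"))
}
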