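toy_features <- function(n_features = 4, n_pos = 6, n_neg = 8, effect = 3,
                         seed = 1) {
  planted_features(n_features, n_features, n_pos, n_neg, effect, seed)
}

test_that("target map enforces the separation constraint", {
  tm <- target_map()
  expect_equal(c(tm$t_nd, tm$t_dia, tm$threshold), c(0.1, 0.85, 0.475))
  expect_error(target_map(0.3, 0.7), class = "microdiab_config_error")
  expect_error(target_map(threshold = 0.05), class = "microdiab_config_error")
})

test_that("logistic regression separates a separable toy at the 0.5 cut", {
  f <- feature_matrix(matrix(c(-2, -1.5, 1.7, 2.2), 1), labels = c(0, 0, 1, 1))
  m <- fit_classifier(f, "lor")
  s <- predict_score(m, f)
  expect_true(all(s[3:4] > 0.5) && all(s[1:2] < 0.5))
  expect_identical(classify(s, m), c(0L, 0L, 1L, 1L))
})

test_that("linear regression recovers exact coefficients on noiseless targets", {
  withr::with_seed(31, {
    X <- matrix(rnorm(5 * 40), 5, 40)
    theta <- c(0.2, rnorm(5))
    y <- drop(crossprod(rbind(1, X), theta))
  })
  labels <- as.integer(y > stats::median(y))
  f <- feature_matrix(X, labels = labels)
  m <- fit_classifier(f, "lr")
  # refit against the synthetic response by pushing it through mapped targets:
  # instead check the normal-equation property directly on the stored fit
  fitted_scores <- predict_score(m, f)
  tgt <- ifelse(labels == 1L, 0.85, 0.1)
  theta_ref <- qr.solve(t(rbind(1, X)), tgt)
  expect_equal(m$parameters$theta, theta_ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fitted_scores, drop(crossprod(rbind(1, X), theta_ref)),
               tolerance = 1e-8)
})

test_that("nonlinear regression training MSE trace is non-increasing", {
  f <- toy_features(3, 8, 10, effect = 2, seed = 5)
  m <- fit_classifier(f, "nlr")
  expect_true(all(diff(m$training_mse_trace) <= 1e-12))
  expect_gte(mean(predict(m, f) == f$labels), 0.9)
})

test_that("bayesian discriminant equals the independent ridge solve", {
  for (seed in 1:25) {
    f <- toy_features(5, 4, 4, effect = 1, seed = seed)
    m <- fit_classifier(f, "bldc", params = list(alpha = 2, beta = 3, eps = 1e-6))
    B <- rbind(f$values, 1)
    a <- ifelse(f$labels == 1L, 0.85, 0.1)
    Hp <- diag(c(rep(2, 5), 1e-6))
    ups_ref <- 3 * solve(3 * B %*% t(B) + Hp) %*% B %*% a
    expect_equal(m$parameters$upsilon, drop(ups_ref), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # posterior covariance is symmetric positive definite
    X <- m$posterior_cov
    expect_equal(X, t(X), tolerance = 1e-12)
    expect_true(all(eigen(X, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("softmax discriminant favours the class containing the test sample", {
  f <- toy_features(3, 5, 6, effect = 4, seed = 9)
  m <- fit_classifier(f, "sdc")
  # a test sample equal to a stored diabetic training sample: its squared
  # distance term is zero, so the diabetic class attains the maximal score
  v <- f$values[, which(f$labels == 1L)[1], drop = FALSE]
  expect_gt(predict_score(m, v), 0.5)
  v0 <- f$values[, which(f$labels == 0L)[1], drop = FALSE]
  expect_lt(predict_score(m, v0), 0.5)
})

test_that("gaussian mixture density at a class mean matches the closed form", {
  withr::with_seed(41, {
    x1 <- matrix(rnorm(2 * 60, mean = 2), 2)
    x0 <- matrix(rnorm(2 * 60, mean = -2), 2)
  })
  f <- feature_matrix(cbind(x1, x0), labels = rep(c(1L, 0L), each = 60))
  m <- fit_classifier(f, "gmm", params = list(g = 1, model = "VVV"))
  p <- m$parameters$class1
  mu <- p$means[[1]]; S <- p$covs[[1]]
  dens_hand <- 1 / ((2 * pi)^(2 / 2) * sqrt(det(S))) # density at the mean itself
  log_dens <- microdiab:::gmm_class_logdens(p, matrix(mu, ncol = 1))
  expect_equal(exp(log_dens), dens_hand, tolerance = 1e-9)
  expect_equal(sum(p$weights), 1)
})

test_that("one-component mixtures reproduce the quadratic-discriminant oracle", {
  withr::with_seed(43, {
    x1 <- matrix(rnorm(2 * 100, mean = 1.2), 2)
    x0 <- matrix(rnorm(2 * 100, mean = -0.4, sd = 1.6), 2)
    test_pts <- matrix(rnorm(2 * 200, sd = 2), 2)
  })
  f <- feature_matrix(cbind(x1, x0), labels = rep(c(1L, 0L), each = 100))
  m <- fit_classifier(f, "gmm", params = list(g = 1, model = "VVV"))
  pred <- classify(predict_score(m, test_pts), m)
  # independent QDA: per-class MLE Gaussian log-densities plus log priors
  qda_log <- function(X, pts) {
    mu <- rowMeans(X)
    S <- tcrossprod(X - mu) / ncol(X)
    ct <- pts - mu
    -0.5 * colSums(ct * solve(S, ct)) - 0.5 * log(det(S)) - log(2 * pi)
  }
  d1 <- qda_log(x1, test_pts) + log(0.5)
  d0 <- qda_log(x0, test_pts) + log(0.5)
  expect_identical(pred, as.integer(d1 > d0))
})

test_that("svm duals are feasible and the decision matches a reference solver", {
  f <- toy_features(2, 10, 12, effect = 3, seed = 13)
  m <- fit_classifier(f, "svm_rbf",
                      params = list(gamma = 0.5, C = 2, class_weight_pos = 1))
  p <- m$parameters
  expect_lt(abs(sum(p$dual_coefs)), 1e-6) # sum alpha_i y_i = 0
  expect_true(all(abs(p$dual_coefs) <= 2 + 1e-8))
  scores <- predict_score(m, f)
  skip_if_not_installed("kernlab")
  xs <- t((f$values - p$center) / p$scale)
  ref <- kernlab::ksvm(xs, factor(f$labels), kernel = "rbfdot",
                       kpar = list(sigma = 0.5), C = 2, scaled = FALSE)
  ref_pred <- as.integer(as.character(kernlab::predict(ref, xs)))
  expect_gte(mean(classify(scores, m) == ref_pred), 0.95)
})

test_that("rbf kernel of a point with itself is one and tiny gamma collapses decisions", {
  sv <- matrix(c(0.3, -0.2), 2, 1)
  expect_equal(microdiab:::svm_decision(sv, 1, 0, 5, sv), 1)
  f <- toy_features(3, 6, 14, effect = 1, seed = 15)
  m <- fit_classifier(f, "svm_rbf", params = list(gamma = 1e-9, class_weight_pos = 1))
  pred <- classify(predict_score(m, f), m)
  expect_identical(length(unique(pred)), 1L) # majority-style constant decision
})

test_that("score-to-label conversion follows the target map and tie rule", {
  f <- toy_features(2, 4, 4, effect = 2, seed = 17)
  m_reg <- fit_classifier(f, "lr")
  expect_identical(classify(c(0.1, 0.85), m_reg), c(0L, 1L))
  expect_identical(classify(0.475, m_reg), 0L) # tie goes negative
  m_lor <- fit_classifier(f, "lor")
  expect_identical(classify(c(0.51, 0.5, 0.49), m_lor), c(1L, 0L, 0L))
})

test_that("models survive a JSON save/load round trip with identical predictions", {
  f <- toy_features(4, 6, 8, effect = 2, seed = 19)
  newdata <- planted_features(4, 4, 3, 3, effect = 2, seed = 20)
  dir <- withr::local_tempdir()
  for (kind in c("nlr", "lr", "lor", "gmm", "bldc", "sdc", "svm_rbf")) {
    m <- fit_classifier(f, kind, seed = 2,
                        params = if (kind == "svm_rbf") list(gamma = 0.5) else list())
    path <- file.path(dir, paste0(kind, ".json"))
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict_score(m2, newdata), predict_score(m, newdata),
                 tolerance = 1e-12, info = kind)
  }
})

test_that("shape and class preconditions are enforced", {
  f <- toy_features(4, 6, 8)
  m <- fit_classifier(f, "lr")
  expect_error(predict_score(m, matrix(0, 3, 2)), class = "microdiab_shape_error")
  one_class <- feature_matrix(matrix(rnorm(12), 3), labels = rep(1L, 4))
  expect_error(fit_classifier(one_class, "lr"), class = "microdiab_class_error")
})
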