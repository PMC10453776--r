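# Wrapper feature selection: particle swarm optimization and harmony search
# over a continuous score vector in [0,1]^n_features; the k_select largest
# components define the selected subset. The wrapper objective is stratified
# 5-fold training accuracy of a nearest-centroid classifier on the subset
# (a filter objective, the sum of per-feature |t| scores, is also available).

#' PSO configuration for feature selection
#'
#' @param n_particles Swarm size (default 20).
#' @param iterations Number of velocity/position updates (default 25).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 1.5).
#' @param w_max,w_min Inertia-weight bounds of the linear schedule
#'   `w(k) = w_max - (w_max - w_min) * k / k_max` (defaults 0.9 and 0.4).
#' @param k_select Number of features to retain (default 287).
#' @param seed Integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 20L, iterations = 25L, c1 = 1.5, c2 = 1.5,
                       w_max = 0.9, w_min = 0.4, k_select = 287L, seed = 1L) {
  if (w_max < w_min || w_min <= 0) {
    stop_microdiab("need w_max >= w_min > 0", "microdiab_config_error")
  }
  structure(list(n_particles = check_count(n_particles, "n_particles", 2L),
                 iterations = check_count(iterations, "iterations"),
                 c1 = check_scalar(c1, "c1", 0), c2 = check_scalar(c2, "c2", 0),
                 w_max = w_max, w_min = w_min,
                 k_select = check_count(k_select, "k_select"),
                 seed = check_count(seed, "seed", 0L)),
            class = "pso_config")
}

#' Harmony-search configuration for feature selection
#'
#' @param memory_size Number of stored harmonies (default 20).
#' @param consider_rate Probability of drawing each variable from memory
#'   (default 0.9).
#' @param adjust_rate Probability of pitch-adjusting a memory-drawn variable
#'   (default 0.3).
#' @param bandwidth Half-width of the uniform pitch adjustment (default 0.1).
#' @param iterations Number of improvisations (default 300).
#' @param k_select Number of features to retain (default 287).
#' @param lower,upper Per-variable bounds (defaults 0 and 1).
#' @param seed Integer seed.
#' @return A list of class `hs_config`.
#' @export
hs_config <- function(memory_size = 20L, consider_rate = 0.9, adjust_rate = 0.3,
                      bandwidth = 0.1, iterations = 300L, k_select = 287L,
                      lower = 0, upper = 1, seed = 1L) {
  structure(list(memory_size = check_count(memory_size, "memory_size", 2L),
                 consider_rate = check_scalar(consider_rate, "consider_rate", 0, 1, strict = TRUE),
                 adjust_rate = check_scalar(adjust_rate, "adjust_rate", 0, 1, strict = TRUE),
                 bandwidth = check_scalar(bandwidth, "bandwidth", 0),
                 iterations = check_count(iterations, "iterations"),
                 k_select = check_count(k_select, "k_select"),
                 lower = lower, upper = upper,
                 seed = check_count(seed, "seed", 0L)),
            class = "hs_config")
}

#' Initialize a particle swarm state
#'
#' @param positions `n_particles x dim` matrix of initial positions.
#' @param velocities Matrix of the same shape (default zero).
#' @param fitness Batch fitness function (positions matrix -> numeric vector),
#'   used to score the initial swarm.
#' @return A list of class `swarm_state` with positions, velocities, per-particle
#'   bests, the global best and the iteration counter.
#' @export
swarm_state <- function(positions, velocities = NULL, fitness) {
  positions <- as.matrix(positions)
  velocities <- velocities %||% matrix(0, nrow(positions), ncol(positions))
  fit <- fitness(positions)
  if (any(!is.finite(fit))) {
    stop_microdiab("non-finite fitness in initial swarm", "microdiab_optimization_error")
  }
  g <- which.max(fit)
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 pbest = positions, pbest_fitness = fit,
                 gbest = positions[g, ], gbest_fitness = fit[g],
                 iteration = 0L),
            class = "swarm_state")
}

#' One particle-swarm update step
#'
#' Velocities are updated with the linearly scheduled inertia weight plus the
#' cognitive pull toward each particle's best and the social pull toward the
#' global best (fresh uniform draws in \[0,1\] per particle and dimension);
#' positions advance by the new velocity; personal and global bests are
#' replaced when the new fitness is better (maximization), so the global best
#' never decreases.
#'
#' @param state A `swarm_state`.
#' @param cfg A [pso_config] (its `iterations` sets the inertia schedule).
#' @param fitness Batch fitness function (matrix of positions -> vector).
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, cfg, fitness) {
  stopifnot(inherits(state, "swarm_state"))
  P <- nrow(state$positions); D <- ncol(state$positions)
  k <- state$iteration
  w <- cfg$w_max - (cfg$w_max - cfg$w_min) * k / cfg$iterations
  r1 <- matrix(runif(P * D), P, D)
  r2 <- matrix(runif(P * D), P, D)
  gmat <- matrix(state$gbest, P, D, byrow = TRUE)
  state$velocities <- w * state$velocities +
    cfg$c1 * r1 * (state$pbest - state$positions) +
    cfg$c2 * r2 * (gmat - state$positions)
  state$positions <- state$positions + state$velocities
  fit <- fitness(state$positions)
  if (any(!is.finite(fit))) {
    stop_microdiab("non-finite fitness during PSO", "microdiab_optimization_error")
  }
  better <- fit > state$pbest_fitness
  state$pbest[better, ] <- state$positions[better, , drop = FALSE]
  state$pbest_fitness[better] <- fit[better]
  g <- which.max(state$pbest_fitness)
  if (state$pbest_fitness[g] > state$gbest_fitness) {
    state$gbest <- state$pbest[g, ]
    state$gbest_fitness <- state$pbest_fitness[g]
  }
  state$iteration <- k + 1L
  state
}

# Stratified fold ids (1..k) per sample, round-robin within each shuffled class.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Nearest-centroid accuracy under fixed stratified folds for a feature subset.
nc_cv_accuracy <- function(values, labels, fold) {
  correct <- 0L
  for (f in unique(fold)) {
    test <- fold == f
    tr <- values[, !test, drop = FALSE]
    ltr <- labels[!test]
    c1 <- rowMeans(tr[, ltr == 1L, drop = FALSE])
    c0 <- rowMeans(tr[, ltr == 0L, drop = FALSE])
    te <- values[, test, drop = FALSE]
    d1 <- colSums((te - c1)^2)
    d0 <- colSums((te - c0)^2)
    pred <- as.integer(d1 < d0)
    correct <- correct + sum(pred == labels[test])
  }
  correct / length(labels)
}

# Batch subset fitness from continuous score rows: top-k components -> subset.
make_subset_fitness <- function(values, labels, k_select, fold,
                                objective = c("wrapper", "filter")) {
  objective <- match.arg(objective)
  t_scores <- row_abs_t(values, labels)
  function(positions) {
    apply(positions, 1L, function(p) {
      sel <- order(p, decreasing = TRUE)[seq_len(k_select)]
      if (objective == "wrapper") {
        nc_cv_accuracy(values[sel, , drop = FALSE], labels, fold)
      } else {
        sum(t_scores[sel])
      }
    })
  }
}

# Warm-start score vector: rank of per-feature |t| mapped into [0,1].
t_warm_start <- function(values, labels) {
  rank(row_abs_t(values, labels), ties.method = "first") / nrow(values)
}

finish_selection <- function(f, scores, k_select, method) {
  sel <- sort(order(scores, decreasing = TRUE)[seq_len(k_select)])
  tt <- class_ttest(f)
  report <- data.frame(feature_id = f$feature_ids, score = scores,
                       selected = seq_len(nrow(f$values)) %in% sel,
                       p_value = tt$p_values, stringsAsFactors = FALSE)
  out <- feature_matrix(f$values[sel, , drop = FALSE],
                        feature_ids = f$feature_ids[sel],
                        labels = f$labels,
                        method = paste(f$method, method, sep = "+"))
  attr(out, "report") <- report
  attr(out, "selected_index") <- sel
  out
}

#' Select features by particle swarm optimization
#'
#' Each particle is a continuous score vector over all features; its
#' `k_select` largest components define the candidate subset, scored by the
#' wrapper objective (stratified 5-fold nearest-centroid training accuracy).
#' One particle is warm-started from the per-feature |t|-score ranking. The
#' subset of the global best after `cfg$iterations` steps is returned.
#'
#' @param f A [feature_matrix] of training samples with both classes present.
#' @param cfg A [pso_config].
#' @param objective `"wrapper"` (default) or `"filter"` (sum of |t| scores).
#' @return A [feature_matrix] with exactly `k_select` rows; the per-feature
#'   selection report is in `attr(, "report")` and the best-fitness trace in
#'   `attr(, "trace")`.
#' @export
pso_select <- function(f, cfg = pso_config(), objective = "wrapper") {
  stopifnot(inherits(f, "feature_matrix"))
  D <- nrow(f$values)
  if (cfg$k_select > D) {
    stop_microdiab("k_select exceeds the number of features", "microdiab_config_error")
  }
  if (length(unique(f$labels)) < 2L) {
    stop_microdiab("selection needs both classes", "microdiab_class_error")
  }
  withr::with_seed(cfg$seed, {
    fold <- stratified_folds(f$labels, 5L)
    fitness <- make_subset_fitness(f$values, f$labels, cfg$k_select, fold, objective)
    X <- matrix(runif(cfg$n_particles * D), cfg$n_particles, D)
    X[1L, ] <- t_warm_start(f$values, f$labels)
    V <- matrix(runif(cfg$n_particles * D, -0.1, 0.1), cfg$n_particles, D)
    state <- swarm_state(X, V, fitness)
    trace <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      state <- pso_step(state, cfg, fitness)
      trace[it] <- state$gbest_fitness
    }
  })
  out <- finish_selection(f, state$gbest, cfg$k_select, "pso")
  attr(out, "trace") <- trace
  out
}

#' Harmony-search optimization of a scalar objective (minimization)
#'
#' Memory of `memory_size` harmonies; each improvisation draws every variable
#' from memory with probability `consider_rate` (pitch-adjusted within
#' `bandwidth` with probability `adjust_rate`) and uniformly at random within
#' bounds otherwise; the new harmony replaces the worst stored one only when
#' its objective is lower.
#'
#' @param objective Function from a parameter vector to a scalar to minimize.
#' @param dim Number of decision variables.
#' @param cfg An [hs_config].
#' @param init Optional matrix of initial harmonies (rows).
#' @return List with `best`, `best_fitness`, `trace` (best per iteration,
#'   non-increasing) and `worst_trace` (worst stored, non-increasing).
#' @export
hs_optimize <- function(objective, dim, cfg = hs_config(), init = NULL) {
  M <- cfg$memory_size
  HM <- matrix(runif(M * dim, cfg$lower, cfg$upper), M, dim)
  if (!is.null(init)) {
    ni <- min(nrow(init), M)
    HM[seq_len(ni), ] <- init[seq_len(ni), , drop = FALSE]
  }
  fit <- apply(HM, 1L, objective)
  if (any(!is.finite(fit))) {
    stop_microdiab("non-finite objective in initial harmony memory",
                   "microdiab_optimization_error")
  }
  trace <- worst_trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    new <- numeric(dim)
    from_mem <- runif(dim) < cfg$consider_rate
    rows <- sample.int(M, dim, replace = TRUE)
    new[from_mem] <- HM[cbind(rows[from_mem], which(from_mem))]
    adjust <- from_mem & (runif(dim) < cfg$adjust_rate)
    new[adjust] <- new[adjust] + runif(sum(adjust), -cfg$bandwidth, cfg$bandwidth)
    new[!from_mem] <- runif(sum(!from_mem), cfg$lower, cfg$upper)
    new <- clip_box(new, cfg$lower, cfg$upper)
    fnew <- objective(new)
    if (!is.finite(fnew)) {
      stop_microdiab("non-finite objective during harmony search",
                     "microdiab_optimization_error")
    }
    worst <- which.max(fit)
    if (fnew < fit[worst]) {
      HM[worst, ] <- new
      fit[worst] <- fnew
    }
    trace[it] <- min(fit)
    worst_trace[it] <- max(fit)
  }
  best <- which.min(fit)
  list(best = HM[best, ], best_fitness = fit[best],
       trace = trace, worst_trace = worst_trace)
}

#' Select features by harmony search
#'
#' Same encoding and wrapper objective as [pso_select()] (harmony search
#' minimizes the negated accuracy); one initial harmony is warm-started from
#' the |t|-score ranking.
#'
#' @inheritParams pso_select
#' @param cfg An [hs_config].
#' @return A [feature_matrix] with exactly `k_select` rows, with the selection
#'   report in `attr(, "report")` and traces in `attr(, "trace")` /
#'   `attr(, "worst_trace")`.
#' @export
hs_select <- function(f, cfg = hs_config(), objective = "wrapper") {
  stopifnot(inherits(f, "feature_matrix"))
  D <- nrow(f$values)
  if (cfg$k_select > D) {
    stop_microdiab("k_select exceeds the number of features", "microdiab_config_error")
  }
  if (length(unique(f$labels)) < 2L) {
    stop_microdiab("selection needs both classes", "microdiab_class_error")
  }
  withr::with_seed(cfg$seed, {
    fold <- stratified_folds(f$labels, 5L)
    fitness <- make_subset_fitness(f$values, f$labels, cfg$k_select, fold, objective)
    obj <- function(p) -fitness(matrix(p, 1L))
    warm <- matrix(t_warm_start(f$values, f$labels), 1L)
    res <- hs_optimize(obj, D, cfg, init = warm)
  })
  out <- finish_selection(f, res$best, cfg$k_select, "hs")
  attr(out, "trace") <- -res$trace
  attr(out, "worst_trace") <- res$worst_trace
  out
}

#' Per-feature and pooled Welch t-tests between classes
#'
#' Two-sided Welch (unequal-variance) t-test of each feature between the
#' diabetic and non-diabetic samples, plus a pooled summary: the same test
#' applied to the per-sample mean over all features. Features with no variance
#' in either class report p = 1 when the class means agree and p = 0 when they
#' differ.
#'
#' @param f A [feature_matrix] with at least two samples per class.
#' @param alpha Significance level for the `significant` flags (default 0.05).
#' @return List with `p_values` (per feature), `t_values`, `significant`,
#'   `pooled_p`, `pooled_t` and `alpha`.
#' @export
class_ttest <- function(f, alpha = 0.05) {
  stopifnot(inherits(f, "feature_matrix"))
  pos <- f$labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 2L) {
    stop_microdiab("each class needs >= 2 samples for the t-test",
                   "microdiab_class_error")
  }
  welch <- function(M) {
    m1 <- rowMeans(M[, pos, drop = FALSE]); m0 <- rowMeans(M[, !pos, drop = FALSE])
    v1 <- rowSums((M[, pos, drop = FALSE] - m1)^2) / (n1 - 1L)
    v0 <- rowSums((M[, !pos, drop = FALSE] - m0)^2) / (n0 - 1L)
    se2 <- v1 / n1 + v0 / n0
    t <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
    p <- 2 * pt(-abs(t), df)
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(m1[degenerate] == m0[degenerate], 1, 0)
    t[degenerate] <- ifelse(m1[degenerate] == m0[degenerate], 0, Inf)
    list(t = t, p = p)
  }
  per <- welch(f$values)
  per$p <- unname(per$p); per$t <- unname(per$t)
  pooled <- welch(matrix(colMeans(f$values), 1L))
  list(p_values = per$p, t_values = per$t, significant = per$p < alpha,
       pooled_p = pooled$p[1L], pooled_t = pooled$t[1L], alpha = alpha)
}
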