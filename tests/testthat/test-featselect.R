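test_that("degenerate PSO coefficients reduce the update to pure inertia", {
  fitness <- function(X) -rowSums(X^2)
  X0 <- matrix(c(1, 2, -1, 0.5, 0, -2), 3, 2)
  V0 <- matrix(0.25, 3, 2)
  cfg <- pso_config(n_particles = 3, iterations = 10, c1 = 0, c2 = 0,
                    w_max = 1, w_min = 1, k_select = 1)
  state <- swarm_state(X0, V0, fitness)
  s1 <- pso_step(state, cfg, fitness)
  expect_equal(s1$velocities, V0)
  expect_equal(s1$positions, X0 + V0)
})

test_that("the inertia weight follows the linear schedule between its bounds", {
  fitness <- function(X) rep(0, nrow(X))
  cfg <- pso_config(n_particles = 2, iterations = 4, c1 = 0, c2 = 0,
                    w_max = 0.9, w_min = 0.4, k_select = 1)
  V0 <- matrix(1, 2, 2)
  state <- swarm_state(matrix(0, 2, 2), V0, fitness)
  sched <- cfg$w_max - (cfg$w_max - cfg$w_min) * (0:4) / cfg$iterations
  expect_equal(sched[1], 0.9)
  expect_equal(sched[5], 0.4)
  w_prod <- 1
  for (k in 1:4) {
    state <- pso_step(state, cfg, fitness)
    w_prod <- w_prod * sched[k]
    expect_equal(state$velocities[1, 1], w_prod, tolerance = 1e-12)
  }
})

test_that("one PSO step equals a hand-stepped trace of the update equations", {
  quad <- function(X) -rowSums((X - 2)^2)
  cfg <- pso_config(n_particles = 3, iterations = 5, c1 = 1.5, c2 = 2,
                    w_max = 0.9, w_min = 0.4, k_select = 1)
  X0 <- matrix(c(0, 1, 3, -1, 2, 4), 3, 2)
  V0 <- matrix(0.1, 3, 2)
  stepped <- withr::with_seed(42, {
    st <- swarm_state(X0, V0, quad)
    pso_step(st, cfg, quad)
  })
  manual <- withr::with_seed(42, {
    fit0 <- quad(X0)
    g <- X0[which.max(fit0), ]
    r1 <- matrix(runif(6), 3, 2)
    r2 <- matrix(runif(6), 3, 2)
    V1 <- 0.9 * V0 + 1.5 * r1 * (X0 - X0) + 2 * r2 * (matrix(g, 3, 2, byrow = TRUE) - X0)
    X1 <- X0 + V1
    fit1 <- quad(X1)
    pbest <- X0; pbf <- fit0
    imp <- fit1 > pbf
    pbest[imp, ] <- X1[imp, ]; pbf[imp] <- fit1[imp]
    list(V = V1, X = X1, pbf = pbf,
         gbest = pbest[which.max(pbf), ], gbf = max(pbf))
  })
  expect_equal(stepped$velocities, manual$V)
  expect_equal(stepped$positions, manual$X)
  expect_equal(stepped$pbest_fitness, manual$pbf)
  expect_equal(stepped$gbest, manual$gbest, ignore_attr = TRUE)
  expect_equal(stepped$gbest_fitness, manual$gbf)
})

test_that("gbest fitness is monotone and non-finite fitness is rejected", {
  f <- planted_features(30, 5, 8, 10, effect = 2, seed = 2)
  sel <- pso_select(f, pso_config(n_particles = 8, iterations = 10,
                                  k_select = 5, seed = 3))
  expect_monotone_nondecreasing(attr(sel, "trace"))
  bad <- function(X) rep(NaN, nrow(X))
  expect_error(swarm_state(matrix(0, 2, 2), fitness = bad),
               class = "microdiab_optimization_error")
})

test_that("both selectors find the planted optimum confirmed by exhaustive search", {
  f <- planted_features(20, 5, 10, 14, effect = 5, seed = 7)
  fold <- withr::with_seed(1, microdiab:::stratified_folds(f$labels, 5L))
  subset_fit <- function(sel) {
    microdiab:::nc_cv_accuracy(f$values[sel, , drop = FALSE], f$labels, fold)
  }
  combos <- utils::combn(20, 5)
  fits <- apply(combos, 2, subset_fit)
  expect_equal(subset_fit(1:5), max(fits)) # planted subset attains the optimum

  psel <- pso_select(f, pso_config(n_particles = 10, iterations = 10,
                                   k_select = 5, seed = 5))
  expect_identical(attr(psel, "selected_index"), 1:5)
  expect_identical(nrow(psel$values), 5L)

  hsel <- hs_select(f, hs_config(iterations = 120, k_select = 5, seed = 5))
  expect_identical(attr(hsel, "selected_index"), 1:5)
  expect_monotone_nondecreasing(attr(hsel, "trace"))
  expect_true(all(diff(attr(hsel, "worst_trace")) <= 1e-12))
})

test_that("selection is deterministic and subset cardinality is exact", {
  f <- planted_features(40, 8, 8, 12, effect = 3, seed = 11)
  cfg <- pso_config(n_particles = 6, iterations = 6, k_select = 12, seed = 17)
  s1 <- pso_select(f, cfg); s2 <- pso_select(f, cfg)
  expect_identical(s1$values, s2$values)
  expect_identical(nrow(s1$values), 12L)
  expect_true(all(s1$feature_ids %in% f$feature_ids))
  h1 <- hs_select(f, hs_config(iterations = 60, k_select = 12, seed = 17))
  h2 <- hs_select(f, hs_config(iterations = 60, k_select = 12, seed = 17))
  expect_identical(h1$values, h2$values)
  expect_identical(nrow(h1$values), 12L)
  expect_error(pso_select(f, pso_config(k_select = 41)),
               class = "microdiab_config_error")
})

test_that("a saturated consider rate confines harmonies to memory", {
  init <- matrix(1, 6, 4)
  res <- withr::with_seed(3, hs_optimize(function(p) sum((p - 1)^2), dim = 4,
    hs_config(memory_size = 6, consider_rate = 1 - 1e-12, adjust_rate = 1e-12,
              bandwidth = 0, iterations = 40, k_select = 1, seed = 3),
    init = init))
  expect_equal(res$best, rep(1, 4))
  expect_equal(res$best_fitness, 0)
  expect_error(hs_config(consider_rate = 1), class = "microdiab_config_error")
})

test_that("selectors recover most planted features across seeds", {
  recovery <- function(selector) {
    mean(vapply(1:20, function(seed) {
      f <- planted_features(100, 10, 10, 20, effect = 3, seed = seed)
      sel <- selector(f, seed)
      mean(attr(sel, "selected_index") %in% 1:10)
    }, numeric(1)))
  }
  pso_rec <- recovery(function(f, seed) {
    pso_select(f, pso_config(n_particles = 10, iterations = 8, k_select = 10,
                             seed = seed))
  })
  hs_rec <- recovery(function(f, seed) {
    hs_select(f, hs_config(iterations = 100, k_select = 10, seed = seed))
  })
  expect_gte(pso_rec, 0.8)
  expect_gte(hs_rec, 0.8)
})

test_that("welch t-tests are calibrated under the null and powered under signal", {
  null_f <- planted_features(2000, 0, 15, 15, effect = 0, seed = 23)
  tt <- class_ttest(null_f)
  expect_lt(abs(mean(tt$p_values < 0.05) - 0.05), 0.02)
  # per-feature p-values agree with the reference implementation
  ref <- sapply(1:10, function(i) {
    t.test(null_f$values[i, null_f$labels == 1], null_f$values[i, null_f$labels == 0])$p.value
  })
  expect_equal(tt$p_values[1:10], ref, tolerance = 1e-10)

  strong <- planted_features(50, 50, 10, 12, effect = 5, seed = 29)
  expect_lt(class_ttest(strong)$pooled_p, 1e-6)

  const <- feature_matrix(matrix(2, 4, 8), labels = rep(c(1, 0), each = 4))
  expect_equal(class_ttest(const)$p_values, rep(1, 4))
  single <- feature_matrix(matrix(rnorm(20), 4), labels = rep(1L, 5))
  expect_error(class_ttest(single), class = "microdiab_class_error")
})
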