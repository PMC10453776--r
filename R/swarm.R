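# Firefly and Cuckoo population optimizers over a box, plus the Mantegna
# Levy-flight step sampler. Both optimizers maximize a batch fitness
# f(positions) -> numeric vector and keep a monotone best-fitness trace.

#' Swarm parameters for the Firefly and Cuckoo optimizers
#'
#' @param population Number of fireflies / host nests (>= 2).
#' @param iterations Number of generations.
#' @param beta0 Attractiveness at distance 0 (> 0).
#' @param absorption Light-absorption coefficient of the attractiveness decay
#'   `beta0 * exp(-absorption * r^2)`.
#' @param rand_scale Scale of the uniform random kick drawn in \[-1, +1\].
#' @param levy_exponent Tail exponent of the Levy step-length law (default 0.2,
#'   a heavy tail with infinite mean and variance).
#' @param step_size Multiplier on the Levy step (default 1).
#' @param abandon_prob Fraction of worst nests re-initialized each generation,
#'   in (0, 1) (default 0.25).
#' @return A list of class `swarm_params`.
#' @export
swarm_params <- function(population = 8L, iterations = 10L, beta0 = 1,
                         absorption = 1, rand_scale = 0.2, levy_exponent = 0.2,
                         step_size = 1, abandon_prob = 0.25) {
  population <- check_count(population, "population", min = 2L)
  iterations <- check_count(iterations, "iterations")
  beta0 <- check_scalar(beta0, "beta0")
  if (beta0 <= 0) stop_microdiab("beta0 must be > 0", "microdiab_config_error")
  abandon_prob <- check_scalar(abandon_prob, "abandon_prob", 0, 1, strict = TRUE)
  structure(list(population = population, iterations = iterations,
                 beta0 = beta0, absorption = check_scalar(absorption, "absorption", 0),
                 rand_scale = check_scalar(rand_scale, "rand_scale", 0),
                 levy_exponent = check_scalar(levy_exponent, "levy_exponent", 0.01, 1.99),
                 step_size = check_scalar(step_size, "step_size", 0),
                 abandon_prob = abandon_prob),
            class = "swarm_params")
}

#' Firefly attractiveness at distance r
#'
#' `beta0 * exp(-absorption * r^2)`: equals `beta0` at `r = 0` and decays
#' monotonically with distance when `absorption > 0`.
#'
#' @param beta0 Brightness at distance zero (> 0).
#' @param absorption Light-absorption coefficient (>= 0).
#' @param r Non-negative distance (vectorized).
#' @return Attractiveness value(s).
#' @examples
#' firefly_attractiveness(1, 1, 1) # exp(-1)
#' @export
firefly_attractiveness <- function(beta0, absorption, r) {
  if (beta0 <= 0) stop_microdiab("beta0 must be > 0", "microdiab_domain_error")
  if (absorption < 0) stop_microdiab("absorption must be >= 0", "microdiab_domain_error")
  if (any(r < 0)) stop_microdiab("distance r must be >= 0", "microdiab_domain_error")
  beta0 * exp(-absorption * r^2)
}

#' Levy-flight steps by the Mantegna algorithm
#'
#' Draws `n` symmetric heavy-tailed steps `u / |v|^(1/exponent)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna scale `sigma_u`
#' chosen so the step-length survival function decays as a power law with the
#' requested tail exponent.
#'
#' @param n Number of draws.
#' @param exponent Tail exponent in (0, 2).
#' @param step_size Multiplier applied to every step (default 1).
#' @return Numeric vector of `n` steps.
#' @export
levy_steps <- function(n, exponent = 0.2, step_size = 1) {
  n <- check_count(n, "n")
  b <- check_scalar(exponent, "exponent", 0.01, 1.99)
  sigma_u <- (gamma(1 + b) * sin(pi * b / 2) /
                (gamma((1 + b) / 2) * b * 2^((b - 1) / 2)))^(1 / b)
  u <- rnorm(n, sd = sigma_u)
  v <- rnorm(n)
  step_size * u / abs(v)^(1 / b)
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Shared optimizer result: list(best, best_fitness, trace).
check_finite_fitness <- function(fit) {
  if (any(!is.finite(fit))) {
    stop_microdiab("non-finite fitness during swarm optimization",
                   "microdiab_optimization_error")
  }
  fit
}

#' Firefly optimization of a batch fitness over a box
#'
#' Fireflies move toward every brighter firefly with distance-attenuated
#' attractiveness plus a uniform random kick in \[-1, +1\] scaled by
#' `rand_scale`. Maximizes `fitness`.
#'
#' @param fitness Function taking a `population x dim` matrix of positions and
#'   returning one fitness value per row.
#' @param dim Dimension of the search space.
#' @param params A [swarm_params].
#' @param lower,upper Box bounds (scalars, default -1 and 1).
#' @return List with `best` (position), `best_fitness`, and `trace` (best
#'   fitness per generation, non-decreasing).
#' @export
firefly_optimize <- function(fitness, dim, params = swarm_params(),
                             lower = -1, upper = 1) {
  P <- params$population
  X <- matrix(runif(P * dim, lower, upper), P, dim)
  fit <- check_finite_fitness(fitness(X))
  best_i <- which.max(fit)
  best <- X[best_i, ]
  best_fit <- fit[best_i]
  trace <- numeric(params$iterations)
  for (it in seq_len(params$iterations)) {
    for (i in seq_len(P)) {
      brighter <- which(fit > fit[i])
      for (k in brighter) {
        r <- sqrt(sum((X[i, ] - X[k, ])^2))
        beta <- firefly_attractiveness(params$beta0, params$absorption, r)
        X[i, ] <- X[i, ] + beta * (X[k, ] - X[i, ]) +
          params$rand_scale * runif(dim, -1, 1)
      }
      if (length(brighter) == 0L) { # brightest firefly wanders randomly
        X[i, ] <- X[i, ] + params$rand_scale * runif(dim, -1, 1)
      }
      X[i, ] <- clip_box(X[i, ], lower, upper)
    }
    fit <- check_finite_fitness(fitness(X))
    if (max(fit) > best_fit) {
      best_i <- which.max(fit)
      best <- X[best_i, ]
      best_fit <- fit[best_i]
    }
    trace[it] <- best_fit
  }
  list(best = best, best_fitness = best_fit, trace = trace)
}

#' Cuckoo-search optimization of a batch fitness over a box
#'
#' New candidate eggs are generated from each nest by Levy-flight steps toward
#' the current best nest; a candidate replaces a randomly chosen nest when
#' fitter, and the worst `abandon_prob` fraction of nests is re-initialized
#' each generation. Maximizes `fitness`.
#'
#' @inheritParams firefly_optimize
#' @return List with `best`, `best_fitness`, and non-decreasing `trace`.
#' @export
cuckoo_optimize <- function(fitness, dim, params = swarm_params(),
                            lower = -1, upper = 1) {
  P <- params$population
  X <- matrix(runif(P * dim, lower, upper), P, dim)
  fit <- check_finite_fitness(fitness(X))
  best_i <- which.max(fit)
  best <- X[best_i, ]
  best_fit <- fit[best_i]
  trace <- numeric(params$iterations)
  n_abandon <- max(0L, floor(params$abandon_prob * P))
  for (it in seq_len(params$iterations)) {
    steps <- matrix(levy_steps(P * dim, params$levy_exponent, params$step_size),
                    P, dim)
    # step toward the best nest, scaled by the distance from it
    cand <- clip_box(X + 0.01 * steps * (X - matrix(best, P, dim, byrow = TRUE)),
                     lower, upper)
    cand_fit <- check_finite_fitness(fitness(cand))
    target <- sample.int(P, P, replace = TRUE)
    improve <- cand_fit > fit[target]
    if (any(improve)) {
      X[target[improve], ] <- cand[improve, , drop = FALSE]
      fit[target[improve]] <- cand_fit[improve]
    }
    if (n_abandon > 0L) {
      worst <- order(fit)[seq_len(n_abandon)]
      keep_best <- worst != which.max(fit)
      worst <- worst[keep_best]
      if (length(worst)) {
        X[worst, ] <- matrix(runif(length(worst) * dim, lower, upper),
                             length(worst), dim)
        fit[worst] <- check_finite_fitness(fitness(X[worst, , drop = FALSE]))
      }
    }
    if (max(fit) > best_fit) {
      best_i <- which.max(fit)
      best <- X[best_i, ]
      best_fit <- fit[best_i]
    }
    trace[it] <- best_fit
  }
  list(best = best, best_fitness = best_fit, trace = trace)
}
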