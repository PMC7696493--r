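test_that("velocity update follows the inertia + attraction rule", {
  # inertia-only limit
  expect_equal(update_velocity(v = c(1, -2), x = c(0, 0), pbest = c(5, 5),
                               gbest = c(9, 9), w = 1, c1 = 0, c2 = 0,
                               r1 = c(1, 1), r2 = c(1, 1)), c(1, -2))
  # converged fixed point
  expect_equal(update_velocity(0, 3, 3, 3, w = 0.9, c1 = 1.5, c2 = 1.7,
                               r1 = 0.4, r2 = 0.8), 0)
  # direct evaluation: 0.5*2 + 1*1*4 + 0 = 5
  expect_equal(update_velocity(v = 2, x = 0, pbest = 4, gbest = 0, w = 0.5,
                               c1 = 1, c2 = 0, r1 = 1, r2 = 0.3), 5.0)
  # clamp
  expect_equal(update_velocity(2, 0, 4, 0, 0.5, 1, 0, 1, 0, v_max = 3), 3)
})

test_that("position update adds velocity and clamps to the box", {
  expect_equal(update_position(c(1, 1), c(0, 0)), c(1, 1))
  expect_equal(update_position(1, 2, upper = 2.5), 2.5)
  expect_equal(update_position(c(1, 1), c(0.5, -0.5)), c(1.5, 0.5))
  expect_equal(update_position(0, -9, lower = -1), -1)
})

test_that("adaptive inertia reproduces the piecewise rule and its bounds", {
  expect_equal(adaptive_inertia(0.9, 0.2, 0.5), 0.9)            # above average
  expect_equal(adaptive_inertia(0.2, 0.2, 0.5, invert = FALSE), 0.4)  # at minimum
  expect_equal(adaptive_inertia(0.5, 0.2, 0.5, invert = FALSE), 0.9)  # branch continuity
  expect_equal(adaptive_inertia(0.35, 0.2, 0.5, invert = FALSE),
               (0.9 - 0.4) * 0.15 / 0.3 + 0.4)
  # degenerate swarm
  expect_equal(adaptive_inertia(0.3, 0.3, 0.3, invert = FALSE), 0.4)
  # always within [w_min, w_max], both senses
  set.seed(1)
  for (invert in c(TRUE, FALSE)) {
    k <- runif(100)
    w <- adaptive_inertia(k, min(k), mean(k), invert = invert)
    expect_true(all(w >= 0.4 - 1e-12 & w <= 0.9 + 1e-12))
  }
  # the two senses mirror each other
  expect_equal(adaptive_inertia(0.35, 0.2, 0.5, invert = TRUE),
               0.9 + 0.4 - adaptive_inertia(0.35, 0.2, 0.5, invert = FALSE))
})

test_that("the swarm bookkeeping is monotone, reproducible and bounded", {
  sphere <- function(p) -sum(p^2)
  r1 <- pso_optimize(sphere, c(-5, -5), c(5, 5),
                     pso_config(n_particles = 10, max_iter = 40, seed = 21))
  expect_false(is.unsorted(r1$trace))
  r2 <- pso_optimize(sphere, c(-5, -5), c(5, 5),
                     pso_config(n_particles = 10, max_iter = 40, seed = 21))
  expect_identical(r1, r2)

  # a single sweep returns the best initial particle
  r3 <- pso_optimize(sphere, c(-5, -5), c(5, 5),
                     pso_config(n_particles = 10, max_iter = 1, seed = 22))
  expect_length(r3$trace, 1)
  expect_identical(r3$value, r3$trace[1])
  r4 <- pso_optimize(sphere, c(-5, -5), c(5, 5),
                     pso_config(n_particles = 10, max_iter = 5, seed = 22))
  expect_identical(r4$trace[1], r3$value)

  expect_error(pso_optimize(sphere, c(0, 0), c(-1, 1), pso_config()),
               "infeasible")
})

test_that("CV fitness of the tree is a mean of fold accuracies in [0, 1]", {
  ds <- toy_clusters(n_per_class = 15)
  spec <- fitness_spec(ds, folds = 5, fold_seed = 3)
  h <- cv_fitness(c(log10(10), log10(1)), spec)
  expect_identical(h, 1)      # separable clusters classify perfectly
  h2 <- cv_fitness(c(-2, -3), spec)   # tiny C and gamma: weak model
  expect_gte(h2, 0)
  expect_lte(h2, 1)
  expect_error(fitness_spec(toy_clusters(n_per_class = 4), folds = 10),
               "at least")
})

test_that("PSO tuning matches good fixed parameters on separable data", {
  ds <- toy_clusters(n_per_class = 12)
  tuned <- tune_tree_pso(ds, folds = 4,
                         swarm = pso_config(n_particles = 6, max_iter = 8,
                                            seed = 5),
                         fold_seed = 5)
  expect_gte(tuned$fitness, 0.9)
  expect_false(is.unsorted(tuned$trace))
  fit <- train_tree(ds, C = tuned$C, gamma = tuned$gamma)
  expect_gte(mean(predict_tree(fit, ds$x) == ds$y), 0.95)
})
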