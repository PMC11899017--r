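test_that("velocity update reduces to its analytic limits", {
  cfg <- swarm_config(velocity_clamp = 10)
  p <- list(position = c(0.5, 0.5), velocity = c(0.1, -0.1),
            pbest_position = c(0.7, 0.3))
  # inertia-only limit
  cfg0 <- swarm_config(cognitive = 0, social = 0, velocity_clamp = 10)
  expect_equal(update_velocity(p, c(0.6, 0.4), cfg0, inertia = 1),
               p$velocity)
  # particle sitting at both bests: pure inertia regardless of c1/c2
  q <- list(position = c(0.4, 0.4), velocity = c(0.05, 0.02),
            pbest_position = c(0.4, 0.4))
  expect_equal(update_velocity(q, c(0.4, 0.4), cfg, inertia = 0.7),
               0.7 * q$velocity)
  # scalar hand evaluation
  s <- list(position = 0.5, velocity = 0.1, pbest_position = 0.7)
  cfg15 <- swarm_config(cognitive = 1.5, social = 1.5, velocity_clamp = 10)
  v <- update_velocity(s, 0.6, cfg15, inertia = 0.7, r1 = 0.5, r2 = 0.2)
  expect_equal(v, 0.07 + 0.15 + 0.03)
  expect_error(update_velocity(s, c(0.6, 0.7), cfg15), "dimension mismatch")
})

test_that("velocity is clamped elementwise", {
  cfg <- swarm_config(velocity_clamp = 0.2)
  p <- list(position = c(0, 1), velocity = c(0, 0),
            pbest_position = c(1, 0))
  v <- update_velocity(p, c(1, 0), cfg, inertia = 0.9, r1 = 1, r2 = 1)
  expect_true(all(abs(v) <= 0.2))
})

test_that("position update clips to [0,1] and zeroes clipped velocity", {
  p <- list(position = c(0.5, 0.95, 0.2), velocity = c(0.2, 0.2, 0))
  out <- update_position(p)
  expect_equal(out$position, c(0.7, 1.0, 0.2))
  expect_equal(out$velocity, c(0.2, 0, 0))
})

test_that("swarm improves on the sphere target with nonincreasing history", {
  layout <- build_layout(search_space_config(max_macro_layers = 1,
                                             fc_slots = 0))
  res <- pso_run(swarm_config(population_size = 10, iterations = 30,
                              seed = 5, stop_threshold = -1),
                 layout, sphere_fitness)
  expect_true(all(diff(res$history) <= 0))
  expect_lt(res$best_fitness, res$history[1])
})

test_that("constant fitness keeps gbest fixed while particles still move", {
  layout <- build_layout(search_space_config(max_macro_layers = 1,
                                             fc_slots = 0))
  positions <- list()
  fit <- function(g) { positions[[length(positions) + 1]] <<- g; 0.5 }
  res <- pso_run(swarm_config(population_size = 4, iterations = 5, seed = 2,
                              stop_threshold = -1), layout, fit)
  expect_equal(res$best_fitness, 0.5)
  expect_true(all(res$history == 0.5))
  first_iter <- do.call(rbind, positions[1:4])
  last_iter <- do.call(rbind, positions[17:20])
  expect_false(isTRUE(all.equal(first_iter, last_iter)))
})

test_that("early stop, determinism, and the evaluation budget audit hold", {
  layout <- build_layout(search_space_config(max_macro_layers = 1,
                                             fc_slots = 0))
  # threshold 1.0 is met by the first evaluation -> exactly one iteration
  res <- pso_run(swarm_config(population_size = 3, iterations = 50, seed = 1,
                              stop_threshold = 1.0), layout, sphere_fitness)
  expect_length(res$history, 1)
  # identical seed -> identical trajectory
  r1 <- pso_run(swarm_config(population_size = 5, iterations = 10, seed = 9,
                             stop_threshold = -1), layout, sphere_fitness)
  r2 <- pso_run(swarm_config(population_size = 5, iterations = 10, seed = 9,
                             stop_threshold = -1), layout, sphere_fitness)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_genome, r2$best_genome)
  # 5 x 40 and 10 x 20 both consume 200 evaluations
  a <- pso_run(swarm_config(population_size = 5, iterations = 40, seed = 3,
                            stop_threshold = -1), layout, sphere_fitness)
  b <- pso_run(swarm_config(population_size = 10, iterations = 20, seed = 3,
                            stop_threshold = -1), layout, sphere_fitness)
  expect_equal(a$evaluations, 200)
  expect_equal(b$evaluations, 200)
})

test_that("positions stay inside the unit hypercube throughout a run", {
  layout <- build_layout(search_space_config(max_macro_layers = 2,
                                             fc_slots = 1))
  seen <- list()
  fit <- function(g) { seen[[length(seen) + 1]] <<- g; sphere_fitness(g) }
  pso_run(swarm_config(population_size = 6, iterations = 15, seed = 4,
                       stop_threshold = -1), layout, fit)
  all_pos <- unlist(seen)
  expect_true(all(all_pos >= 0 & all_pos <= 1))
})

test_that("a failing fitness evaluation is demoted to worst case, not fatal", {
  layout <- build_layout(search_space_config(max_macro_layers = 1,
                                             fc_slots = 0))
  calls <- 0
  fit <- function(g) {
    calls <<- calls + 1
    if (calls == 2) stop("boom")
    sphere_fitness(g)
  }
  expect_warning(
    res <- pso_run(swarm_config(population_size = 3, iterations = 2,
                                seed = 8, stop_threshold = -1), layout, fit),
    "assigned 1.0")
  expect_lte(res$best_fitness, 1)
})
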