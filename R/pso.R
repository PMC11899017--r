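# Particle swarm engine over genomes in the unit hypercube.
#
# Velocity update: v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x), with
# r1, r2 ~ U(0,1) drawn per particle per iteration (scalars by default, one
# per coordinate behind a flag), followed by elementwise clamping to
# +/- velocity_clamp. Position update: x' = x + v', clipped into [0, 1];
# a clipped coordinate has its velocity component zeroed so the swarm does
# not pile up against the bounds. Fitness is minimized.

#' Swarm configuration
#'
#' @param population_size Number of particles (>= 2).
#' @param iterations Number of swarm iterations (>= 1); every iteration
#'   evaluates all particles, so the total evaluation budget is
#'   `population_size * iterations` (e.g. 5 x 40 and 10 x 20 both spend
#'   200 trainings).
#' @param inertia Length-2 vector `c(start, end)`: the inertia weight is
#'   decayed linearly from start to end over the run. A single value keeps
#'   it constant.
#' @param cognitive,social Acceleration coefficients c1 and c2.
#' @param velocity_clamp Elementwise velocity bound (fraction of the unit
#'   range).
#' @param stop_threshold Fitness value at or below which the search halts
#'   early.
#' @param seed Integer seed controlling initialization and all r1/r2 draws.
#' @param per_coordinate_r Draw r1/r2 per coordinate instead of per
#'   particle.
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(population_size = 5, iterations = 40,
                         inertia = c(0.9, 0.4), cognitive = 1.49445,
                         social = 1.49445, velocity_clamp = 0.2,
                         stop_threshold = 0, seed = 1,
                         per_coordinate_r = FALSE) {
  stopifnot(population_size >= 2, iterations >= 1, velocity_clamp > 0)
  if (length(inertia) == 1) inertia <- c(inertia, inertia)
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 velocity_clamp = velocity_clamp,
                 stop_threshold = stop_threshold, seed = as.integer(seed),
                 per_coordinate_r = per_coordinate_r),
            class = "swarm_config")
}

.inertia_at <- function(config, iter) {
  if (config$iterations <= 1) return(config$inertia[1])
  config$inertia[1] + (config$inertia[2] - config$inertia[1]) *
    (iter - 1) / (config$iterations - 1)
}

#' Velocity update for one particle
#'
#' @param particle List with `position`, `velocity`, `pbest_position`.
#' @param gbest Global best position (same length).
#' @param config A [swarm_config()].
#' @param inertia Inertia weight for this iteration (defaults to the
#'   config's starting value).
#' @param r1,r2 Random factors in `[0, 1]`; drawn from the current RNG when
#'   `NULL`.
#' @return New velocity vector, clamped to `+/- velocity_clamp`.
#' @export
update_velocity <- function(particle, gbest, config,
                            inertia = config$inertia[1],
                            r1 = NULL, r2 = NULL) {
  x <- particle$position
  if (length(gbest) != length(x) ||
      length(particle$velocity) != length(x) ||
      length(particle$pbest_position) != length(x))
    stop("dimension mismatch in velocity update", call. = FALSE)
  n <- if (config$per_coordinate_r) length(x) else 1
  if (is.null(r1)) r1 <- runif(n)
  if (is.null(r2)) r2 <- runif(n)
  v <- inertia * particle$velocity +
    config$cognitive * r1 * (particle$pbest_position - x) +
    config$social * r2 * (gbest - x)
  pmin(pmax(v, -config$velocity_clamp), config$velocity_clamp)
}

#' Position update for one particle
#'
#' Adds the velocity to the position, clips into `[0, 1]`, and zeroes the
#' velocity component of every clipped coordinate.
#'
#' @param particle List with `position` and (already updated) `velocity`.
#' @return The particle with new `position` and `velocity`.
#' @export
update_position <- function(particle) {
  raw <- particle$position + particle$velocity
  clipped <- pmin(pmax(raw, 0), 1)
  particle$velocity[raw != clipped] <- 0
  particle$position <- clipped
  particle
}

.init_swarm <- function(config, layout) {
  particles <- lapply(seq_len(config$population_size), function(i) {
    pos <- random_genome(layout)
    list(position = pos,
         velocity = runif(layout$D, -config$velocity_clamp,
                          config$velocity_clamp),
         pbest_position = pos, pbest_fitness = Inf)
  })
  structure(list(particles = particles, gbest_position = NULL,
                 gbest_fitness = Inf, history = numeric(0), iter = 0,
                 evaluations = 0, config = config, layout = layout),
            class = "swarm_state")
}

#' One swarm iteration
#'
#' Evaluates every particle with `fitness_fn`, updates personal bests on
#' strict improvement (ties keep the earlier candidate), updates the global
#' best, then updates velocities and positions, and appends the global best
#' fitness to the history. A fitness call that errors is assigned the
#' worst-case fitness 1 and logged as a warning.
#'
#' @param state A `swarm_state` from [pso_run()]'s initializer.
#' @param fitness_fn Function genome -> fitness (minimized).
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, fitness_fn) {
  config <- state$config
  state$iter <- state$iter + 1
  w <- .inertia_at(config, state$iter)
  for (i in seq_along(state$particles)) {
    p <- state$particles[[i]]
    fit <- tryCatch(fitness_fn(p$position), error = function(e) {
      warning("fitness evaluation failed (assigned 1.0): ",
              conditionMessage(e), call. = FALSE)
      1.0
    })
    state$evaluations <- state$evaluations + 1
    if (fit < p$pbest_fitness) {
      p$pbest_fitness <- fit
      p$pbest_position <- p$position
    }
    if (fit < state$gbest_fitness) {
      state$gbest_fitness <- fit
      state$gbest_position <- p$position
    }
    state$particles[[i]] <- p
  }
  for (i in seq_along(state$particles)) {
    p <- state$particles[[i]]
    p$velocity <- update_velocity(p, state$gbest_position, config, w)
    state$particles[[i]] <- update_position(p)
  }
  state$history <- c(state$history, state$gbest_fitness)
  state
}

#' Run the particle swarm search
#'
#' Initializes `population_size` particles uniformly in `[0, 1]^D`,
#' iterates [pso_step()] until the iteration budget is exhausted or the
#' global best fitness reaches `stop_threshold`, and returns the best-ever
#' genome with the per-iteration convergence history. Fully reproducible
#' under the config seed.
#'
#' @param config A [swarm_config()].
#' @param layout A [build_layout()] result.
#' @param fitness_fn Function genome -> fitness in `[0, 1]` (minimized).
#' @param verbose Print a per-iteration line (iteration, gbest fitness,
#'   evaluations used).
#' @return List: `best_genome`, `best_fitness`, `history` (one entry per
#'   executed iteration), `evaluations`, `state`.
#' @export
pso_run <- function(config, layout, fitness_fn, verbose = FALSE) {
  local_seed(config$seed, {
    state <- .init_swarm(config, layout)
    for (it in seq_len(config$iterations)) {
      state <- pso_step(state, fitness_fn)
      if (verbose)
        message(sprintf("iter %3d  gbest %.4f  evals %d", it,
                        state$gbest_fitness, state$evaluations))
      if (state$gbest_fitness <= config$stop_threshold) break
    }
    list(best_genome = state$gbest_position,
         best_fitness = state$gbest_fitness,
         history = state$history, evaluations = state$evaluations,
         state = state)
  })
}

#' Write a convergence history as CSV
#'
#' @param history Numeric vector of per-iteration global best fitness.
#' @param path Output CSV path (columns `iteration`, `gbest_fitness`).
#' @export
write_convergence_csv <- function(history, path) {
  write.csv(data.frame(iteration = seq_along(history),
                       gbest_fitness = history),
            path, row.names = FALSE)
}
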