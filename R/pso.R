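# Particle swarm optimizer with per-particle adaptive inertia and a k-fold
# cross-validation fitness for tuning (C, gamma) of the SVM tree. The
# optimizer maximizes; fitness traces record the global best per iteration.
#
# Velocity update: V <- w V + c1 r1 (pbest - x) + c2 r2 (gbest - x), with
# r1, r2 i.i.d. uniform(0,1) per dimension. Inertia w is adapted per
# particle from its fitness K relative to the swarm's minimum and mean
# fitness this iteration: below-average particles interpolate between w_min
# (at K = K_min) and w_max (at K = K_avg); above-average particles get
# w_max. That piecewise form comes from the minimization literature, where
# "below average" means better than average; since this optimizer maximizes,
# the default applies the rule in that classical sense (good particles get
# the small inertia for fine search, `invert_inertia = TRUE`), and
# `invert_inertia = FALSE` applies the printed form literally to the
# maximized fitness, which hands good particles the large inertia and
# measurably slows final convergence.

#' Swarm configuration
#'
#' Defaults follow the study settings: population 20, 200 iterations, local
#' acceleration 1.5, global acceleration 1.7; inertia bounds 0.9/0.4 are the
#' conventional choice. The velocity clamp defaults to half the search range
#' per dimension.
#'
#' @param n_particles swarm size (>= 2)
#' @param max_iter maximum fitness-evaluation sweeps (the first sweep
#'   evaluates the initial swarm)
#' @param c1 local (personal-best) acceleration constant
#' @param c2 global acceleration constant
#' @param w_max,w_min inertia bounds (w_min <= w_max)
#' @param v_max velocity clamp per dimension (`NULL`: 0.5 x range)
#' @param seed integer RNG seed; fixes the whole trajectory
#' @param stall_iter,stall_tol early stop: quit after `stall_iter`
#'   iterations without a global-best improvement exceeding `stall_tol`
#'   (`stall_iter = Inf` disables)
#' @param invert_inertia `TRUE` (default): apply the adaptive-inertia rule
#'   in its classical minimization sense, so better-than-average particles
#'   get the small inertia for fine search; `FALSE`: apply the piecewise
#'   rule literally to the maximized fitness (high fitness -> high inertia)
#' @return object of class `pso_config`
#' @export
pso_config <- function(n_particles = 20, max_iter = 200, c1 = 1.5, c2 = 1.7,
                       w_max = 0.9, w_min = 0.4, v_max = NULL, seed = 1L,
                       stall_iter = 30, stall_tol = 1e-6,
                       invert_inertia = TRUE) {
  if (n_particles < 2) stop_config("swarm size must be >= 2")
  if (w_min > w_max) stop_config("w_min must be <= w_max")
  if (c1 < 0 || c2 < 0) stop_config("acceleration constants must be >= 0")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 w_max = w_max, w_min = w_min, v_max = v_max,
                 seed = seed, stall_iter = stall_iter, stall_tol = stall_tol,
                 invert_inertia = isTRUE(invert_inertia)),
            class = "pso_config")
}

#' Adaptive inertia weight
#'
#' Piecewise rule on a particle's fitness `K` relative to the swarm minimum
#' `K_min` and mean `K_avg`: for `K <= K_avg`, `w = (w_max - w_min) * (K -
#' K_min) / (K_avg - K_min) + w_min`; for `K > K_avg`, `w = w_max`. The two
#' branches are continuous at `K = K_avg`. Degenerate swarms with `K_avg ==
#' K_min` get `w_min`.
#'
#' @param k_fit particle fitness (vectorized)
#' @param k_min,k_avg swarm minimum and mean fitness this iteration
#' @param w_max,w_min inertia bounds
#' @param invert mirror the rule (`w -> w_max + w_min - w`)
#' @return inertia weight(s) in `[w_min, w_max]`
#' @export
adaptive_inertia <- function(k_fit, k_min, k_avg, w_max = 0.9, w_min = 0.4,
                             invert = FALSE) {
  if (k_min > k_avg) stop("k_min must be <= k_avg")
  w <- if (k_avg == k_min) rep(w_min, length(k_fit)) else
    pmin((w_max - w_min) * (k_fit - k_min) / (k_avg - k_min) + w_min, w_max)
  w[k_fit > k_avg] <- w_max
  if (invert) w <- w_max + w_min - w
  w
}

#' Velocity update
#'
#' `V' = w V + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, clamped elementwise
#' to `[-v_max, v_max]`. `r1`, `r2` are supplied so the update is a pure
#' function; [pso_optimize()] draws them i.i.d. uniform(0,1) per dimension.
#'
#' @param v,x,pbest,gbest velocity, position, personal best, global best
#' @param w inertia weight
#' @param c1,c2 acceleration constants
#' @param r1,r2 uniform(0,1) draws, one per dimension
#' @param v_max velocity clamp (may be `Inf`)
#' @return updated velocity
#' @export
update_velocity <- function(v, x, pbest, gbest, w, c1, c2, r1, r2,
                            v_max = Inf) {
  vn <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  pmin(pmax(vn, -v_max), v_max)
}

#' Position update
#'
#' `x' = x + V`, clamped to the box `[lower, upper]`.
#'
#' @param x position
#' @param v velocity
#' @param lower,upper per-dimension bounds
#' @return updated position
#' @export
update_position <- function(x, v, lower = -Inf, upper = Inf) {
  pmin(pmax(x + v, lower), upper)
}

#' Particle swarm optimization (maximization)
#'
#' Runs the swarm until `max_iter` sweeps or until the global best has not
#' improved by more than `stall_tol` for `stall_iter` consecutive
#' iterations. Fitness ties are broken by lower particle index, and with a
#' fixed seed the whole trajectory is reproducible bit-for-bit.
#'
#' @param fn objective to maximize: `fn(position) -> scalar`
#' @param lower,upper per-dimension box bounds
#' @param config a [pso_config()]
#' @return list with `par` (best position), `value` (best fitness), `trace`
#'   (global-best fitness per iteration, non-decreasing) and `iterations`
#' @export
pso_optimize <- function(fn, lower, upper, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  d <- length(lower)
  if (length(upper) != d || any(upper < lower))
    stop_config("infeasible bounds")
  v_max <- if (is.null(config$v_max)) 0.5 * (upper - lower) else
    rep_len(config$v_max, d)
  np <- config$n_particles
  with_seed(config$seed, {
    x <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)), np, d)
    v <- matrix(runif(np * d, rep(-v_max, each = np), rep(v_max, each = np)), np, d)
    fit <- apply(x, 1, fn)
    pbest <- x
    pbest_fit <- fit
    g <- which.max(fit)                      # ties -> lowest index
    gbest <- x[g, ]
    gbest_fit <- fit[g]
    trace <- numeric(config$max_iter)
    trace[1] <- gbest_fit
    stall <- 0L
    it <- 1L
    while (it < config$max_iter && stall < config$stall_iter) {
      it <- it + 1L
      k_min <- min(fit)
      k_avg <- mean(fit)
      w <- adaptive_inertia(fit, k_min, k_avg, config$w_max, config$w_min,
                            config$invert_inertia)
      r1 <- matrix(runif(np * d), np, d)
      r2 <- matrix(runif(np * d), np, d)
      for (p in seq_len(np)) {
        v[p, ] <- update_velocity(v[p, ], x[p, ], pbest[p, ], gbest,
                                  w[p], config$c1, config$c2,
                                  r1[p, ], r2[p, ], v_max)
        x[p, ] <- update_position(x[p, ], v[p, ], lower, upper)
      }
      fit <- apply(x, 1, fn)
      better <- fit > pbest_fit
      pbest[better, ] <- x[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      g <- which.max(pbest_fit)
      improvement <- pbest_fit[g] - gbest_fit
      if (improvement > 0) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      stall <- if (improvement > config$stall_tol) 0L else stall + 1L
      trace[it] <- gbest_fit
    }
    list(par = gbest, value = gbest_fit, trace = trace[seq_len(it)],
         iterations = it)
  })
}

#' Cross-validation fitness specification
#'
#' Precomputes a stratified K-fold assignment (deterministic under
#' `fold_seed`) over a labeled dataset, for use as the PSO fitness. Each
#' fold's accuracy is `P_lr / (P_lr + P_lw)` (correct over correct plus
#' wrong); the fitness is the mean over folds.
#'
#' @param ds a [labeled_dataset()]
#' @param folds fold count K (default 10)
#' @param kind kernel kind for the tree nodes
#' @param fold_seed seed for the fold shuffle
#' @return object of class `fitness_spec`
#' @export
fitness_spec <- function(ds, folds = 10, kind = "rbf", fold_seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  counts <- tabulate(ds$y, 4)
  if (any(counts < folds))
    stop("every class needs at least ", folds, " samples for ", folds,
         "-fold CV (counts: ", paste(counts, collapse = ", "), ")")
  fold <- integer(length(ds$y))
  with_seed(fold_seed, for (cl in 1:4) {
    idx <- sample(which(ds$y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  })
  structure(list(ds = ds, folds = folds, kind = kind, fold = fold),
            class = "fitness_spec")
}

#' K-fold CV fitness of a (C, gamma) position
#'
#' Position is in log10 coordinates `(log10 C, log10 gamma)`. The binary
#' tree is trained with the shared pair on K-1 folds and scored on the held
#' fold; the fitness H is the mean fold accuracy, in [0, 1].
#'
#' @param position numeric length-2, `(log10 C, log10 gamma)`
#' @param spec a [fitness_spec()]
#' @return fitness H in [0, 1]
#' @export
cv_fitness <- function(position, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  C <- 10^position[1]
  gamma <- 10^position[2]
  ds <- spec$ds
  acc <- vapply(seq_len(spec$folds), function(l) {
    tr <- spec$fold != l
    fitted <- train_tree(labeled_dataset(ds$x[tr, , drop = FALSE], ds$y[tr]),
                         C = C, gamma = gamma, kind = spec$kind)
    mean(predict_tree(fitted, ds$x[!tr, , drop = FALSE]) == ds$y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Tune the SVM tree's (C, gamma) by PSO
#'
#' Searches `C` in [1e-2, 1e2] and `gamma` in [1e-3, 1e1] (log10
#' coordinates) maximizing the K-fold CV accuracy of the binary tree with
#' one shared pair across the three nodes; `per_node = TRUE` instead runs
#' one search per node's own binary subproblem.
#'
#' @param ds training [labeled_dataset()]
#' @param folds CV fold count
#' @param kind kernel kind
#' @param swarm a [pso_config()]
#' @param lower,upper log10 search bounds, `(log10 C, log10 gamma)`
#' @param fold_seed seed for the fold shuffle
#' @param per_node tune each tree node separately
#' @return list with `C`, `gamma` (length 1 or 3), `fitness`, `trace`
#' @export
tune_tree_pso <- function(ds, folds = 10, kind = "rbf",
                          swarm = pso_config(), lower = c(-2, -3),
                          upper = c(2, 1), fold_seed = 1L, per_node = FALSE) {
  spec <- fitness_spec(ds, folds, kind, fold_seed)
  if (!per_node) {
    res <- pso_optimize(function(p) cv_fitness(p, spec), lower, upper, swarm)
    return(list(C = 10^res$par[1], gamma = 10^res$par[2],
                fitness = res$value, trace = res$trace))
  }
  # per-node mode: each node is its own binary CV problem on the rows it sees
  node_rows <- list(seq_along(ds$y), which(ds$y != 1L), which(ds$y %in% 3:4))
  node_pos <- c(1L, 2L, 3L)
  Cs <- gammas <- fits <- numeric(3)
  traces <- vector("list", 3)
  for (k in 1:3) {
    rows <- node_rows[[k]]
    yk <- ifelse(ds$y[rows] == node_pos[k], 1L, -1L)
    fold <- integer(length(rows))
    with_seed(fold_seed + k, for (cl in c(-1L, 1L)) {
      idx <- sample(which(yk == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    })
    xk <- ds$x[rows, , drop = FALSE]
    fn <- function(p) {
      mean(vapply(seq_len(folds), function(l) {
        tr <- fold != l
        m <- train_binary(xk[tr, , drop = FALSE], yk[tr], C = 10^p[1],
                          kernel = kernel_spec(kind, 10^p[2]))
        mean(predict_binary(m, xk[!tr, , drop = FALSE])$class == yk[!tr])
      }, numeric(1)))
    }
    res <- pso_optimize(fn, lower, upper, swarm)
    Cs[k] <- 10^res$par[1]; gammas[k] <- 10^res$par[2]
    fits[k] <- res$value; traces[[k]] <- res$trace
  }
  list(C = Cs, gamma = gammas, fitness = fits, trace = traces)
}
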