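# Metaheuristic search of the SVM hyperparameters (c, g): real-coded
# genetic algorithm, inertia-weight particle swarm, and the canonical grey
# wolf optimizer, all maximising a cross-validated classification accuracy
# (or any user fitness) over a bounded 2-D box, optionally on log scale.

#' Hyperparameter search space
#'
#' @param c_bounds,g_bounds `(low, high)` bounds for the SVM penalty `c` and
#'   RBF kernel parameter `g`; must be positive when `log_scale = TRUE`
#'   (general real boxes are allowed on linear scale, e.g. for benchmark
#'   fitness functions).
#' @param log_scale search on log10 scale (default TRUE: both parameters act
#'   multiplicatively).
#' @return object of class `search_space`.
#' @export
search_space <- function(c_bounds = c(0.01, 100), g_bounds = c(0.01, 100),
                         log_scale = TRUE) {
  stopifnot(length(c_bounds) == 2, length(g_bounds) == 2,
            c_bounds[1] < c_bounds[2], g_bounds[1] < g_bounds[2])
  if (isTRUE(log_scale))
    stopifnot(c_bounds[1] > 0, g_bounds[1] > 0)
  structure(list(c_bounds = as.numeric(c_bounds),
                 g_bounds = as.numeric(g_bounds),
                 log_scale = isTRUE(log_scale)),
            class = "search_space")
}

# internal coordinates: the box actually searched (log10 if log_scale)
space_box <- function(space) {
  if (space$log_scale)
    rbind(log10(space$c_bounds), log10(space$g_bounds))
  else rbind(space$c_bounds, space$g_bounds)
}

space_decode <- function(space, xy) {
  if (space$log_scale) 10^xy else xy
}

clip_box <- function(X, box) {
  X[, 1] <- pmin(pmax(X[, 1], box[1, 1]), box[1, 2])
  X[, 2] <- pmin(pmax(X[, 2], box[2, 1]), box[2, 2])
  X
}

make_run <- function(algorithm, space, best_xy, best_fit, trace, evals, seed) {
  cg <- space_decode(space, best_xy)
  structure(list(algorithm = algorithm, best_c = cg[1], best_g = cg[2],
                 best_fitness = best_fit, trace = trace,
                 evaluations = evals, seed = seed, space = space),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("<optimizer_run> %s: best c=%.4f g=%.4f fitness=%.4f (%d evals)\n",
              x$algorithm, x$best_c, x$best_g, x$best_fitness, x$evaluations))
  invisible(x)
}

# evaluate fitness on decoded coordinates, one row at a time
eval_fitness <- function(fitness, space, X) {
  apply(X, 1, function(xy) {
    cg <- space_decode(space, xy)
    fitness(cg[1], cg[2])
  })
}

#' Cross-validated SVM fitness
#'
#' Mean stratified k-fold accuracy of an RBF soft-margin SVM at penalty `c`
#' and kernel parameter `g` (kernel \eqn{\exp(-g \|x-y\|^2)}).
#' Standardisation is fit on each training fold and applied to its held-out
#' fold.  Deterministic under `seed` (which fixes the folds).
#'
#' @param train a [feature_table()].
#' @param c,g positive SVM hyperparameters.
#' @param k_folds folds (>= 2); every class needs at least `k_folds` samples.
#' @param seed fold-assignment seed.
#' @return accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(train, c, g, k_folds = 5, seed = 1L) {
  stopifnot(c > 0, g > 0, k_folds >= 2)
  tab <- base::table(train$cultivar)
  if (any(tab < k_folds))
    stopf("class '%s' has %d samples, fewer than k_folds = %d",
          names(tab)[which.min(tab)], min(tab), k_folds)
  X <- feature_matrix(train)
  y <- factor(train$cultivar)
  folds <- stratified_folds(y, k_folds, seed)
  correct <- 0L
  for (fold in seq_len(k_folds)) {
    te <- folds == fold
    mu <- colMeans(X[!te, , drop = FALSE])
    sg <- apply(X[!te, , drop = FALSE], 2, stats::sd)
    sg[sg < 1e-12] <- 1
    Ztr <- sweep(sweep(X[!te, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(Ztr, y[!te], type = "C-classification",
                      kernel = "radial", cost = c, gamma = g, scale = FALSE)
    correct <- correct + sum(stats::predict(fit, Zte) == y[te])
  }
  correct / length(y)
}

#' Build a (c, g) fitness closure over a training table
#'
#' Convenience wrapper binding [cv_fitness()] to a fixed table, fold count
#' and seed, the form the optimizers consume.
#'
#' @inheritParams cv_fitness
#' @return `function(c, g) -> accuracy`.
#' @export
svm_fitness <- function(train, k_folds = 5, seed = 1L) {
  force(train); force(k_folds); force(seed)
  function(c, g) cv_fitness(train, c, g, k_folds = k_folds, seed = seed)
}

#' Genetic-algorithm search of (c, g)
#'
#' Real-coded GA: tournament selection (size 2), arithmetic crossover
#' (probability 0.8), Gaussian mutation (probability 0.1 per gene, sd 10% of
#' the range) and elitism of one.  Maximises `fitness`.
#'
#' @param fitness `function(c, g) -> real` to maximise.
#' @param space a [search_space()].
#' @param pop population size (>= 4... `pop >= 1` accepted for degenerate runs).
#' @param gens generations (>= 1).
#' @param seed RNG seed.
#' @param p_crossover,p_mutation operator rates.
#' @return an `optimizer_run` (best-ever point; `trace` is the running best
#'   fitness per generation, non-decreasing by elitism).
#' @export
ga_optimize <- function(fitness, space, pop = 20, gens = 50, seed = 1L,
                        p_crossover = 0.8, p_mutation = 0.1) {
  stopifnot(inherits(space, "search_space"), pop >= 1, gens >= 1)
  box <- space_box(space)
  rng <- local_rng(seed)
  span <- box[, 2] - box[, 1]
  X <- cbind(box[1, 1] + rng$runif(pop) * span[1],
             box[2, 1] + rng$runif(pop) * span[2])
  f <- eval_fitness(fitness, space, X)
  evals <- pop
  best_i <- which.max(f)
  best_xy <- X[best_i, ]; best_f <- f[best_i]
  trace <- numeric(gens)
  for (gen in seq_len(gens)) {
    # tournament selection
    parents <- matrix(0, pop, 2)
    for (i in seq_len(pop)) {
      cand <- rng$sample_int(pop, size = min(2L, pop), replace = TRUE)
      parents[i, ] <- X[cand[which.max(f[cand])], ]
    }
    # arithmetic crossover on consecutive pairs
    child <- parents
    if (pop >= 2) for (i in seq(1, pop - 1, by = 2)) {
      if (rng$runif(1) < p_crossover) {
        a <- rng$runif(1)
        child[i, ] <- a * parents[i, ] + (1 - a) * parents[i + 1, ]
        child[i + 1, ] <- (1 - a) * parents[i, ] + a * parents[i + 1, ]
      }
    }
    # Gaussian mutation
    mut <- matrix(rng$runif(pop * 2) < p_mutation, pop, 2)
    noise <- matrix(rng$rnorm(pop * 2), pop, 2) *
      matrix(0.1 * span, pop, 2, byrow = TRUE)
    child[mut] <- child[mut] + noise[mut]
    child <- clip_box(child, box)
    # elitism: keep the best-ever point in slot 1
    child[1, ] <- best_xy
    fc <- f
    fc[1] <- best_f
    recompute <- seq_len(pop)[-1]
    if (length(recompute)) {
      fc[recompute] <- eval_fitness(fitness, space,
                                    child[recompute, , drop = FALSE])
      evals <- evals + length(recompute)
    }
    X <- child; f <- fc
    if (max(f) > best_f) { best_f <- max(f); best_xy <- X[which.max(f), ] }
    trace[gen] <- best_f
  }
  make_run("GA", space, best_xy, best_f, trace, evals, seed)
}

#' Particle-swarm search of (c, g)
#'
#' Inertia-weight PSO: w decreases linearly 0.9 to 0.4, cognitive and social
#' coefficients c1 = c2 = 2, velocity clamped to 20% of the range per axis,
#' positions clipped to the box.  Maximises `fitness`.
#'
#' @inheritParams ga_optimize
#' @param particles swarm size (>= 2).
#' @param iters iterations (>= 1).
#' @return an `optimizer_run` (global best; `trace` non-decreasing).
#' @export
pso_optimize <- function(fitness, space, particles = 20, iters = 50, seed = 1L) {
  stopifnot(inherits(space, "search_space"), particles >= 2, iters >= 1)
  box <- space_box(space)
  rng <- local_rng(seed)
  span <- box[, 2] - box[, 1]
  vmax <- 0.2 * span
  X <- cbind(box[1, 1] + rng$runif(particles) * span[1],
             box[2, 1] + rng$runif(particles) * span[2])
  V <- cbind((rng$runif(particles) - 0.5) * vmax[1],
             (rng$runif(particles) - 0.5) * vmax[2])
  f <- eval_fitness(fitness, space, X)
  evals <- particles
  Pbest <- X; fP <- f
  gi <- which.max(fP)
  gbest <- Pbest[gi, ]; fg <- fP[gi]
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    w <- 0.9 - (0.9 - 0.4) * (it - 1) / max(1, iters - 1)
    r1 <- matrix(rng$runif(particles * 2), particles, 2)
    r2 <- matrix(rng$runif(particles * 2), particles, 2)
    V <- w * V + 2 * r1 * (Pbest - X) +
      2 * r2 * (matrix(gbest, particles, 2, byrow = TRUE) - X)
    V[, 1] <- pmin(pmax(V[, 1], -vmax[1]), vmax[1])
    V[, 2] <- pmin(pmax(V[, 2], -vmax[2]), vmax[2])
    X <- clip_box(X + V, box)
    f <- eval_fitness(fitness, space, X)
    evals <- evals + particles
    up <- f > fP
    Pbest[up, ] <- X[up, ]; fP[up] <- f[up]
    gi <- which.max(fP)
    if (fP[gi] > fg) { fg <- fP[gi]; gbest <- Pbest[gi, ] }
    trace[it] <- fg
  }
  make_run("PSO", space, gbest, fg, trace, evals, seed)
}

#' Grey-wolf search of (c, g)
#'
#' Canonical GWO: the three best wolves (alpha, beta, delta) steer the pack;
#' the control scalar `a` decreases linearly 2 to 0; per wolf and leader,
#' `A = 2 a r1 - a`, `C = 2 r2`, `D = |C X_leader - X|`, and the candidate is
#' the mean of the three leader-driven positions `X_leader - A D`, clipped to
#' the box.  Maximises `fitness`; returns the alpha.
#'
#' @inheritParams ga_optimize
#' @param wolves pack size (>= 3).
#' @param iters iterations (>= 1).
#' @return an `optimizer_run` (`trace` = alpha fitness, non-decreasing).
#' @export
gwo_optimize <- function(fitness, space, wolves = 20, iters = 50, seed = 1L) {
  stopifnot(inherits(space, "search_space"), wolves >= 3, iters >= 1)
  box <- space_box(space)
  rng <- local_rng(seed)
  span <- box[, 2] - box[, 1]
  X <- cbind(box[1, 1] + rng$runif(wolves) * span[1],
             box[2, 1] + rng$runif(wolves) * span[2])
  f <- eval_fitness(fitness, space, X)
  evals <- wolves
  ord <- order(f, decreasing = TRUE)
  alpha <- X[ord[1], ]; beta <- X[ord[2], ]; delta <- X[ord[3], ]
  fa <- f[ord[1]]; fb <- f[ord[2]]; fd <- f[ord[3]]
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    a <- 2 - 2 * (it - 1) / max(1, iters - 1)
    Xn <- X
    for (i in seq_len(wolves)) {
      cand <- c(0, 0)
      for (Lx in list(alpha, beta, delta)) {
        A <- 2 * a * rng$runif(2) - a
        C <- 2 * rng$runif(2)
        D <- abs(C * Lx - X[i, ])
        cand <- cand + (Lx - A * D)
      }
      Xn[i, ] <- cand / 3
    }
    X <- clip_box(Xn, box)
    f <- eval_fitness(fitness, space, X)
    evals <- evals + wolves
    # re-rank the hierarchy over the stored leaders plus the new pack, so
    # the alpha (and its cached fitness) can never worsen
    allX <- rbind(alpha, beta, delta, X)
    allf <- c(fa, fb, fd, f)
    ord <- order(allf, decreasing = TRUE)
    alpha <- allX[ord[1], ]; beta <- allX[ord[2], ]; delta <- allX[ord[3], ]
    fa <- allf[ord[1]]; fb <- allf[ord[2]]; fd <- allf[ord[3]]
    trace[it] <- fa
  }
  make_run("GWO", space, alpha, fa, trace, evals, seed)
}

#' Exhaustive log-grid search of (c, g)
#'
#' Reference oracle: evaluates `fitness` on an `n x n` grid spanning the
#' space (log-spaced when the space is log scale) and returns the best cell.
#'
#' @inheritParams ga_optimize
#' @param n grid side.
#' @return an `optimizer_run` with `algorithm = "grid"`.
#' @export
grid_search <- function(fitness, space, n = 50) {
  box <- space_box(space)
  cs <- seq(box[1, 1], box[1, 2], length.out = n)
  gs <- seq(box[2, 1], box[2, 2], length.out = n)
  X <- as.matrix(expand.grid(cs, gs))
  f <- eval_fitness(fitness, space, X)
  i <- which.max(f)
  make_run("grid", space, X[i, ], f[i], trace = max(f), evals = n * n,
           seed = NA_integer_)
}
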