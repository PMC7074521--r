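#' Population metaheuristics over mixed search spaces
#'
#' Four optimizers share one interface: `objective` maps a named list of
#' dimension values to a finite fitness (lower is better), `space` is a
#' [search_space()], and every optimizer is fully reproducible given
#' `seed`. Each returns a list with `best` (a list of `values` and
#' `fitness`) and `trace` (an `"optimizer_trace"` whose best-so-far
#' fitness sequence is non-increasing).
#'
#' \describe{
#'   \item{`pso_optimize()`}{global-best particle swarm on continuous
#'     random-key encodings of the dimensions, with inertia `w` and
#'     cognitive/social coefficients `c1`, `c2`.}
#'   \item{`aco_optimize()`}{archive-based continuous ant colony
#'     (ACOR-style): a rank-weighted solution archive plays the role of
#'     the pheromone trail; integer dimensions are sampled from
#'     Gaussians centered on archive members, categorical dimensions
#'     from rank-weighted category frequencies.}
#'   \item{`hs_optimize()`}{harmony search: each new harmony takes every
#'     dimension from memory with probability `hmcr`, pitch-adjusts it
#'     with probability `par` (plus/minus up to `bandwidth` for
#'     integers, a neighboring category for categoricals), otherwise
#'     samples it at random; the new harmony replaces the worst member
#'     when better.}
#'   \item{`ca_optimize()`}{cultural algorithm: a population evolves
#'     under a belief space holding situational knowledge (best-so-far
#'     individual) and normative knowledge (per-dimension promising
#'     ranges / category sets from the top `acceptance_fraction` of the
#'     population); offspring are drawn from the belief space or mutated
#'     from parents, and the best of parents plus offspring survive.}
#' }
#'
#' @param objective function(values) -> finite real, lower is better.
#' @param space a [search_space()].
#' @param n_iters iteration count.
#' @param seed RNG seed.
#' @name optimizers
NULL

# sample() without the scalar-x surprise
resample <- function(x, ...) x[sample.int(length(x), ...)]

#' @rdname optimizers
#' @param n_particles swarm size (default 30).
#' @param w,c1,c2 inertia and acceleration coefficients (defaults 0.72,
#'   1.49, 1.49).
#' @export
pso_optimize <- function(objective, space, n_particles = 30, n_iters = 50,
                         seed = 1, w = 0.72, c1 = 1.49, c2 = 1.49) {
  d <- length(space)
  with_seed(seed, {
    pos <- matrix(runif(n_particles * d), n_particles, d)
    vel <- matrix(runif(n_particles * d, -0.1, 0.1), n_particles, d)
    fit <- apply(pos, 1, function(k) safe_eval(objective, decode_keys(space, k)))
    pbest <- pos; pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    trace <- new_trace(seed)
    trace$n_evaluations <- n_particles
    for (it in seq_len(n_iters)) {
      r1 <- matrix(runif(n_particles * d), n_particles, d)
      r2 <- matrix(runif(n_particles * d), n_particles, d)
      vel <- w * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -0.25), 0.25)
      pos <- pos + vel
      # reflect at the key bounds
      pos <- ifelse(pos < 0, -pos, ifelse(pos > 1, 2 - pos, pos))
      pos <- pmin(pmax(pos, 0), 1)
      fit <- apply(pos, 1, function(k) safe_eval(objective, decode_keys(space, k)))
      trace$n_evaluations <- trace$n_evaluations + n_particles
      better <- fit < pbest_fit
      pbest[better, ] <- pos[better, ]
      pbest_fit[better] <- fit[better]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trace$iteration <- c(trace$iteration, it)
      trace$best_fitness <- c(trace$best_fitness, gbest_fit)
    }
    list(best = list(values = decode_keys(space, gbest),
                     fitness = gbest_fit),
         trace = trace)
  })
}

#' @rdname optimizers
#' @param n_ants new solutions per iteration (default 30).
#' @param archive_size solution archive size (default 30).
#' @param q locality of the rank weighting (default 0.1).
#' @param xi width multiplier of the sampling Gaussians (default 0.85).
#' @export
aco_optimize <- function(objective, space, n_ants = 30, archive_size = 30,
                         n_iters = 50, seed = 1, q = 0.1, xi = 0.85) {
  d <- length(space)
  with_seed(seed, {
    archive <- lapply(seq_len(archive_size), function(i) random_values(space))
    fit <- vapply(archive, function(v) safe_eval(objective, v), numeric(1))
    ord <- order(fit)
    archive <- archive[ord]; fit <- fit[ord]
    trace <- new_trace(seed)
    trace$n_evaluations <- archive_size
    ranks <- seq_len(archive_size)
    wts <- exp(-(ranks - 1)^2 / (2 * q^2 * archive_size^2))
    wts <- wts / sum(wts)
    for (it in seq_len(n_iters)) {
      newcomers <- lapply(seq_len(n_ants), function(a) {
        guide <- sample.int(archive_size, 1, prob = wts)
        vals <- vector("list", d); names(vals) <- names(space)
        for (dd in seq_len(d)) {
          dm <- space[[dd]]
          if (dm$kind == "integer") {
            center <- archive[[guide]][[dd]]
            spread <- xi * mean(abs(vapply(archive,
              function(s) s[[dd]], numeric(1)) - center))
            spread <- max(spread, 0.5)
            v <- round(rnorm(1, center, spread))
            vals[[dd]] <- min(max(v, dm$lo), dm$hi)
          } else {
            # rank-weighted category frequencies with a uniform floor
            lev <- dm$levels
            freq <- vapply(lev, function(lv) {
              sum(wts[vapply(archive, function(s) s[[dd]] == lv,
                             logical(1))])
            }, numeric(1))
            prob <- freq + 0.1 / length(lev)
            vals[[dd]] <- resample(lev, 1, prob = prob)
          }
        }
        vals
      })
      new_fit <- vapply(newcomers, function(v) safe_eval(objective, v),
                        numeric(1))
      trace$n_evaluations <- trace$n_evaluations + n_ants
      all_sol <- c(archive, newcomers)
      all_fit <- c(fit, new_fit)
      keep <- order(all_fit)[seq_len(archive_size)]
      archive <- all_sol[keep]; fit <- all_fit[keep]
      trace$iteration <- c(trace$iteration, it)
      trace$best_fitness <- c(trace$best_fitness, fit[1])
    }
    list(best = list(values = archive[[1]], fitness = fit[1]),
         trace = trace)
  })
}

#' @rdname optimizers
#' @param harmony_memory_size memory size (default 30).
#' @param hmcr memory-consideration rate (default 0.9).
#' @param par pitch-adjustment rate (default 0.3).
#' @param bandwidth maximum integer pitch step (default 2).
#' @export
hs_optimize <- function(objective, space, harmony_memory_size = 30,
                        n_iters = 500, seed = 1, hmcr = 0.9, par = 0.3,
                        bandwidth = 2) {
  d <- length(space)
  with_seed(seed, {
    memory <- lapply(seq_len(harmony_memory_size),
                     function(i) random_values(space))
    fit <- vapply(memory, function(v) safe_eval(objective, v), numeric(1))
    trace <- new_trace(seed)
    trace$n_evaluations <- harmony_memory_size
    for (it in seq_len(n_iters)) {
      vals <- vector("list", d); names(vals) <- names(space)
      for (dd in seq_len(d)) {
        dm <- space[[dd]]
        if (runif(1) < hmcr) {
          v <- memory[[sample.int(harmony_memory_size, 1)]][[dd]]
          if (runif(1) < par) {
            if (dm$kind == "integer") {
              v <- v + sample(c(-1, 1), 1) * sample.int(bandwidth, 1)
              v <- min(max(v, dm$lo), dm$hi)
            } else {
              k <- match(v, dm$levels)
              k <- 1 + (k - 1 + sample(c(-1, 1), 1)) %% length(dm$levels)
              v <- dm$levels[k]
            }
          }
          vals[[dd]] <- v
        } else {
          vals[[dd]] <- random_values(space)[[dd]]
        }
      }
      f <- safe_eval(objective, vals)
      trace$n_evaluations <- trace$n_evaluations + 1L
      worst <- which.max(fit)
      if (f < fit[worst]) {
        memory[[worst]] <- vals
        fit[worst] <- f
      }
      trace$iteration <- c(trace$iteration, it)
      trace$best_fitness <- c(trace$best_fitness, min(fit))
    }
    b <- which.min(fit)
    list(best = list(values = memory[[b]], fitness = fit[b]),
         trace = trace)
  })
}

#' @rdname optimizers
#' @param pop_size population size (default 30).
#' @param acceptance_fraction fraction of the population whose knowledge
#'   updates the belief space (default 0.2).
#' @export
ca_optimize <- function(objective, space, pop_size = 30, n_iters = 50,
                        seed = 1, acceptance_fraction = 0.2) {
  d <- length(space)
  with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) random_values(space))
    fit <- vapply(pop, function(v) safe_eval(objective, v), numeric(1))
    trace <- new_trace(seed)
    trace$n_evaluations <- pop_size
    belief <- update_belief(NULL, pop, fit, space, acceptance_fraction)
    for (it in seq_len(n_iters)) {
      offspring <- lapply(seq_len(pop_size), function(i) {
        parent <- pop[[sample.int(pop_size, 1)]]
        influence_variation(parent, belief, space)
      })
      off_fit <- vapply(offspring, function(v) safe_eval(objective, v),
                        numeric(1))
      trace$n_evaluations <- trace$n_evaluations + pop_size
      all_pop <- c(pop, offspring)
      all_fit <- c(fit, off_fit)
      keep <- order(all_fit)[seq_len(pop_size)]
      pop <- all_pop[keep]; fit <- all_fit[keep]
      belief <- update_belief(belief, pop, fit, space, acceptance_fraction)
      trace$iteration <- c(trace$iteration, it)
      trace$best_fitness <- c(trace$best_fitness, fit[1])
    }
    list(best = list(values = pop[[1]], fitness = fit[1]),
         trace = trace, belief = belief)
  })
}

# Belief space: situational = best individual ever; normative =
# per-dimension ranges (integers) / category sets (categoricals) spanned
# by the accepted elite.
update_belief <- function(belief, pop, fit, space, acceptance_fraction) {
  n_acc <- max(1, round(length(pop) * acceptance_fraction))
  elite <- pop[order(fit)[seq_len(n_acc)]]
  best <- pop[[which.min(fit)]]
  situational <- if (is.null(belief) || min(fit) <= belief$situational_fit) {
    list(values = best, fit = min(fit))
  } else {
    list(values = belief$situational, fit = belief$situational_fit)
  }
  normative <- lapply(seq_along(space), function(dd) {
    dm <- space[[dd]]
    ev <- lapply(elite, function(e) e[[dd]])
    if (dm$kind == "integer") {
      v <- c(unlist(ev), situational$values[[dd]])
      list(lo = min(v), hi = max(v))
    } else {
      list(levels = unique(c(unlist(ev),
                             situational$values[[dd]])))
    }
  })
  names(normative) <- names(space)
  list(situational = situational$values,
       situational_fit = situational$fit,
       normative = normative)
}

# Variation biased by the belief space: per dimension, inherit the
# situational value, sample the normative range, or mutate the parent.
influence_variation <- function(parent, belief, space) {
  out <- parent
  for (dd in seq_along(space)) {
    dm <- space[[dd]]
    u <- runif(1)
    if (u < 0.2) {
      out[[dd]] <- belief$situational[[dd]]
    } else if (u < 0.6) {
      nm <- belief$normative[[dd]]
      out[[dd]] <- if (dm$kind == "integer") {
        resample(seq.int(nm$lo, nm$hi), 1)
      } else {
        resample(nm$levels, 1)
      }
    } else if (u < 0.9) {
      out[[dd]] <- if (dm$kind == "integer") {
        min(max(parent[[dd]] + sample(c(-2, -1, 1, 2), 1), dm$lo), dm$hi)
      } else if (runif(1) < 0.5) {
        resample(dm$levels, 1)
      } else {
        parent[[dd]]
      }
    } # else: inherit the parent value unchanged
  }
  out
}
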