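# Real-coded genetic algorithm used for the MPC input optimization and
# for steady-state parameter estimation: tournament selection, blend
# (BLX-alpha) crossover, Gaussian mutation, elitism.

#' Minimize a function over a box with a real-coded genetic algorithm
#'
#' @param fn objective; receives a `pop_size x d` matrix of candidates and
#'   must return a numeric vector of objective values (lower is better).
#' @param lower,upper numeric bounds of length `d`.
#' @param pop_size population size.
#' @param generations number of generations.
#' @param seed optional integer seed (set once at entry).
#' @param elite number of elites copied unchanged each generation.
#' @param p_cross,p_mut crossover and per-gene mutation probabilities.
#' @param mut_sd mutation standard deviation as a fraction of each gene's
#'   range; annealed linearly to a third of its initial value.
#' @param tol stop early when the best objective improves by less than
#'   `tol` over 15 consecutive generations.
#' @param init optional matrix of initial candidates (rows), clamped to
#'   the box; the remainder of the population is drawn uniformly.
#' @return List with `par` (best candidate), `value` (its objective) and
#'   `trace`, a tibble `(generation, best)` of the best-so-far objective.
#' @export
ga_optimize <- function(fn, lower, upper, pop_size = 40, generations = 30,
                        seed = NULL, elite = 2, p_cross = 0.9, p_mut = 0.15,
                        mut_sd = 0.1, tol = 1e-8, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), pop_size >= 4)
  rng <- upper - lower
  pop <- matrix(stats::runif(pop_size * d), pop_size, d)
  pop <- sweep(sweep(pop, 2, rng, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d, byrow = TRUE)
    k <- min(nrow(init), pop_size)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  fit <- fn(pop)
  best_i <- which.min(fit)
  best <- list(par = pop[best_i, ], value = fit[best_i])
  trace <- numeric(generations + 1)
  trace[1] <- best$value
  stall <- 0L
  for (g in seq_len(generations)) {
    ord <- order(fit)
    new_pop <- matrix(NA_real_, pop_size, d)
    n_elite <- min(elite, pop_size)
    new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    sdg <- mut_sd * (1 - (2 / 3) * (g - 1) / max(1, generations - 1))
    for (i in seq(n_elite + 1, pop_size)) {
      p1 <- pop[tournament(fit, 3), ]
      p2 <- pop[tournament(fit, 3), ]
      child <- if (stats::runif(1) < p_cross) blx(p1, p2, 0.5) else p1
      mut <- stats::runif(d) < p_mut
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = sdg * rng[mut])
      }
      new_pop[i, ] <- pmin(pmax(child, lower), upper)
    }
    pop <- new_pop
    fit <- fn(pop)
    gi <- which.min(fit)
    improve <- best$value - fit[gi]
    if (fit[gi] < best$value) best <- list(par = pop[gi, ], value = fit[gi])
    trace[g + 1] <- best$value
    stall <- if (is.finite(improve) && improve > tol) 0L else stall + 1L
    if (stall >= 15L && g > generations / 2) {
      trace <- trace[seq_len(g + 1)]
      break
    }
  }
  list(par = best$par, value = best$value,
       trace = tibble::tibble(generation = seq_along(trace) - 1,
                              best = cummin(trace)))
}

tournament <- function(fit, k) {
  idx <- sample.int(length(fit), k)
  idx[which.min(fit[idx])]
}

blx <- function(p1, p2, alpha) {
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  span <- hi - lo
  stats::runif(length(p1), lo - alpha * span, hi + alpha * span)
}
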