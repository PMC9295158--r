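#' Right-hand side of the toggle switch ODE model
#'
#' Time derivatives of the six model states: the two mRNAs and proteins of
#' the mutually repressing LacI/TetR pair, plus the intracellular inducers
#' exchanged across the cell membrane. Transcription of each gene is
#' repressed by the opposing protein, whose effective level is reduced by
#' its inducer (aTc sequesters TetR, IPTG sequesters LacI), both through
#' decreasing Hill functions.
#'
#' Membrane exchange of each inducer is linear in the concentration
#' difference, with the influx rate constant applying when the external
#' concentration exceeds the internal one and the efflux rate constant
#' otherwise.
#'
#' @param state named numeric state vector, see [toggle_state()].
#' @param aTc_ext external aTc (ng/mL).
#' @param IPTG_ext external IPTG (mM).
#' @param params a [toggle_params()] object.
#' @return Named numeric vector of the six time derivatives (per minute).
#' @examples
#' p <- toggle_params()
#' toggle_rhs(toggle_state(), aTc_ext = 0, IPTG_ext = 0, p)
#' @export
toggle_rhs <- function(state, aTc_ext, IPTG_ext, params) {
  p <- params
  # adaptive integrators may probe marginally negative trial states;
  # evaluate the kinetics at the clamped values
  mL <- state[[1]]; mT <- state[[2]]
  L <- max(state[[3]], 0); Tt <- max(state[[4]], 0)
  aTc <- max(state[[5]], 0); IPTG <- max(state[[6]], 0)
  wa <- hill(aTc,  p$thetaaTc,  p$etaaTc)
  wi <- hill(IPTG, p$thetaIPTG, p$etaIPTG)
  dmL <- p$kLm0 + p$kLm * hill(Tt * wa, p$thetaTetR, p$etaTetR) - p$gLm * mL
  dmT <- p$kTm0 + p$kTm * hill(L * wi, p$thetaLacI, p$etaLacI) - p$gTm * mT
  dL  <- p$kLp * mL - p$gLp * L
  dT  <- p$kTp * mT - p$gTp * Tt
  ka <- if (aTc_ext >= aTc) p$kaTcin else p$kaTcout
  ki <- if (IPTG_ext >= IPTG) p$kIPTGin else p$kIPTGout
  daTc  <- ka * (aTc_ext - aTc)
  dIPTG <- ki * (IPTG_ext - IPTG)
  stats::setNames(c(dmL, dmT, dL, dT, daTc, dIPTG), STATE_NAMES)
}

# RHS of the 4-state biochemical subsystem with inducers held at fixed
# (equilibrium) levels; used by the continuation and steady-state code.
toggle_rhs4 <- function(x, aTc, IPTG, params) {
  p <- params
  wa <- hill(aTc,  p$thetaaTc,  p$etaaTc)
  wi <- hill(IPTG, p$thetaIPTG, p$etaIPTG)
  c(p$kLm0 + p$kLm * hill(max(x[4], 0) * wa, p$thetaTetR, p$etaTetR) -
      p$gLm * x[1],
    p$kTm0 + p$kTm * hill(max(x[3], 0) * wi, p$thetaLacI, p$etaLacI) -
      p$gTm * x[2],
    p$kLp * x[1] - p$gLp * x[3],
    p$kTp * x[2] - p$gTp * x[4])
}

# Analytic Jacobian of the 4-state subsystem (inducers fixed).
toggle_jac4 <- function(x, aTc, IPTG, params) {
  p <- params
  wa <- hill(aTc,  p$thetaaTc,  p$etaaTc)
  wi <- hill(IPTG, p$thetaIPTG, p$etaIPTG)
  J <- matrix(0, 4, 4)
  J[1, 1] <- -p$gLm
  J[1, 4] <- p$kLm * hill_prime(x[4] * wa, p$thetaTetR, p$etaTetR) * wa
  J[2, 2] <- -p$gTm
  J[2, 3] <- p$kTm * hill_prime(x[3] * wi, p$thetaLacI, p$etaLacI) * wi
  J[3, 1] <- p$kLp; J[3, 3] <- -p$gLp
  J[4, 2] <- p$kTp; J[4, 4] <- -p$gTp
  J
}

# d(RHS4)/d(IPTG) at fixed state: IPTG enters only the mRNA_TetR equation.
toggle_dfdp4 <- function(x, aTc, IPTG, params) {
  p <- params
  wi <- hill(IPTG, p$thetaIPTG, p$etaIPTG)
  dwi <- hill_prime(IPTG, p$thetaIPTG, p$etaIPTG)
  c(0,
    p$kTm * hill_prime(x[3] * wi, p$thetaLacI, p$etaLacI) * x[3] * dwi,
    0, 0)
}

#' Jacobian of the toggle switch vector field
#'
#' Analytic 6x6 Jacobian of [toggle_rhs()] with respect to the state, at
#' fixed external inducer levels. The membrane-exchange terms are piecewise
#' linear in the inducer states; the rate constant on the side of the
#' current exchange direction is used (influx when external >= internal).
#'
#' @inheritParams toggle_rhs
#' @return 6x6 numeric matrix with rows/columns in canonical state order.
#' @export
toggle_jacobian <- function(state, aTc_ext, IPTG_ext, params) {
  p <- params
  J <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  x4 <- state[1:4]
  aTc <- state[[5]]; IPTG <- state[[6]]
  J[1:4, 1:4] <- toggle_jac4(x4, aTc, IPTG, params)
  wa <- hill(aTc,  p$thetaaTc,  p$etaaTc)
  wi <- hill(IPTG, p$thetaIPTG, p$etaIPTG)
  # repression strength depends on the internal inducers
  J[1, 5] <- p$kLm * hill_prime(x4[4] * wa, p$thetaTetR, p$etaTetR) *
    x4[4] * hill_prime(aTc, p$thetaaTc, p$etaaTc)
  J[2, 6] <- p$kTm * hill_prime(x4[3] * wi, p$thetaLacI, p$etaLacI) *
    x4[3] * hill_prime(IPTG, p$thetaIPTG, p$etaIPTG)
  J[5, 5] <- -(if (aTc_ext >= aTc) p$kaTcin else p$kaTcout)
  J[6, 6] <- -(if (IPTG_ext >= IPTG) p$kIPTGin else p$kIPTGout)
  J
}

# Central finite-difference Jacobian, used as an independent cross-check.
fd_jacobian <- function(state, aTc_ext, IPTG_ext, params, h = 1e-5) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(state[[j]]))
    xp <- state; xp[j] <- xp[j] + hj
    xm <- state; xm[j] <- max(0, xm[j] - hj)
    J[, j] <- (toggle_rhs(xp, aTc_ext, IPTG_ext, params) -
                 toggle_rhs(xm, aTc_ext, IPTG_ext, params)) / (xp[j] - xm[j])
  }
  dimnames(J) <- list(STATE_NAMES, STATE_NAMES)
  J
}

as_trajectory <- function(times, states, aTc_ext, IPTG_ext) {
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- STATE_NAMES
  out <- tibble::add_column(out, time_min = times, .before = 1)
  out$aTc_ext <- aTc_ext
  out$IPTG_ext <- IPTG_ext
  class(out) <- c("toggle_trajectory", class(out))
  out
}

# Normalize an input schedule: either scalars (constant inputs) or a data
# frame with columns time_min, aTc_ext, IPTG_ext (piecewise constant from
# each time onward, 5-min granularity by convention).
input_at <- function(schedule, t) {
  if (is.data.frame(schedule)) {
    i <- findInterval(t + 1e-9, schedule$time_min)
    i <- max(i, 1L)
    c(aTc = schedule$aTc_ext[i], IPTG = schedule$IPTG_ext[i])
  } else {
    c(aTc = schedule[["aTc_ext"]], IPTG = schedule[["IPTG_ext"]])
  }
}

#' Simulate the deterministic toggle switch
#'
#' Integrates the six-state ODE model with adaptive step control between
#' samples, returning states on a uniform sampling grid (default every
#' 5 min, the realistic imaging/actuation interval for a microfluidics
#' experiment).
#'
#' @param params a [toggle_params()] object.
#' @param inputs either `c(aTc_ext = , IPTG_ext = )` for constant inputs,
#'   or a data frame `time_min, aTc_ext, IPTG_ext` interpreted as a
#'   piecewise-constant schedule.
#' @param x0 initial state, see [toggle_state()].
#' @param t_end simulation end time (min).
#' @param sample_period sampling period (min), default 5.
#' @param rtol,atol integration tolerances passed to [deSolve::ode()].
#' @return A `toggle_trajectory` tibble with columns `time_min`, the six
#'   states, `aTc_ext` and `IPTG_ext`.
#' @examples
#' p <- toggle_params()
#' tr <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0),
#'                           toggle_state(), t_end = 50)
#' tail(tr)
#' @export
simulate_toggle_ode <- function(params, inputs, x0, t_end, sample_period = 5,
                                rtol = 1e-8, atol = 1e-8) {
  stopifnot(t_end > 0, sample_period > 0)
  grid <- seq(0, t_end, by = sample_period)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  if (is.data.frame(inputs)) {
    # integrate piece by piece so input switches land exactly on boundaries
    switch_t <- sort(unique(c(inputs$time_min, grid)))
    switch_t <- switch_t[switch_t <= t_end]
    if (switch_t[1] > 0) switch_t <- c(0, switch_t)
    states <- matrix(NA_real_, length(switch_t), 6)
    urec <- matrix(NA_real_, length(switch_t), 2)
    states[1, ] <- x0
    urec[1, ] <- input_at(inputs, 0)
    x <- x0
    for (i in seq_len(length(switch_t) - 1)) {
      u <- input_at(inputs, switch_t[i])
      x <- ode_piece(x, switch_t[i], switch_t[i + 1], u[1], u[2], params,
                     rtol, atol)
      states[i + 1, ] <- x
      urec[i + 1, ] <- u
    }
    keep <- switch_t %in% grid
    as_trajectory(switch_t[keep], states[keep, , drop = FALSE],
                  urec[keep, 1], urec[keep, 2])
  } else {
    u <- input_at(inputs, 0)
    f <- function(t, y, parms) list(toggle_rhs(y, u[1], u[2], params))
    sol <- deSolve::ode(y = as.numeric(x0), times = grid, func = f,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed near t = ", max(sol[, 1]), " min",
           call. = FALSE)
    }
    as_trajectory(sol[, 1], pmax(sol[, -1, drop = FALSE], 0), u[1], u[2])
  }
}

# integrate one constant-input piece, returning the final state
ode_piece <- function(x, t0, t1, aTc_ext, IPTG_ext, params,
                      rtol = 1e-8, atol = 1e-8) {
  f <- function(t, y, parms) list(toggle_rhs(y, aTc_ext, IPTG_ext, params))
  sol <- deSolve::ode(y = as.numeric(x), times = c(t0, t1), func = f,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed near t = ", sol[nrow(sol), 1], " min",
         call. = FALSE)
  }
  pmax(sol[nrow(sol), -1], 0)
}

# Stoichiometry of the 8 pseudoreactions acting on the four biochemical
# states (rows: mRNA_LacI, mRNA_TetR, LacI, TetR). Column order matches
# propensities(): transcription (x2), translation (x2), mRNA degradation
# (x2), protein degradation (x2).
toggle_stoichiometry <- function() {
  S <- matrix(0, 4, 8,
              dimnames = list(STATE_NAMES[1:4],
                              c("tx_LacI", "tx_TetR", "tl_LacI", "tl_TetR",
                                "deg_mLacI", "deg_mTetR",
                                "deg_LacI", "deg_TetR")))
  S["mRNA_LacI", "tx_LacI"] <- 1
  S["mRNA_TetR", "tx_TetR"] <- 1
  S["LacI", "tl_LacI"] <- 1
  S["TetR", "tl_TetR"] <- 1
  S["mRNA_LacI", "deg_mLacI"] <- -1
  S["mRNA_TetR", "deg_mTetR"] <- -1
  S["LacI", "deg_LacI"] <- -1
  S["TetR", "deg_TetR"] <- -1
  S
}

#' Propensity functions of the toggle switch pseudoreactions
#'
#' Rates of the eight pseudoreactions (transcription, translation,
#' degradation/dilution of each mRNA and protein) underlying the chemical
#' Langevin model. By construction `S %*% propensities(...)` with
#' `S = toggle_stoichiometry()` equals the first four components of
#' [toggle_rhs()].
#'
#' @inheritParams toggle_rhs
#' @return Named nonnegative numeric vector of length 8.
#' @export
propensities <- function(state, aTc_ext, IPTG_ext, params) {
  if (any(state < 0)) stop("negative state in propensities()", call. = FALSE)
  p <- params
  wa <- hill(state[[5]], p$thetaaTc,  p$etaaTc)
  wi <- hill(state[[6]], p$thetaIPTG, p$etaIPTG)
  c(tx_LacI  = p$kLm0 + p$kLm * hill(state[[4]] * wa, p$thetaTetR, p$etaTetR),
    tx_TetR  = p$kTm0 + p$kTm * hill(state[[3]] * wi, p$thetaLacI, p$etaLacI),
    tl_LacI  = p$kLp * state[[1]],
    tl_TetR  = p$kTp * state[[2]],
    deg_mLacI = p$gLm * state[[1]],
    deg_mTetR = p$gTm * state[[2]],
    deg_LacI = p$gLp * state[[3]],
    deg_TetR = p$gTp * state[[4]])
}

#' Simulate the stochastic (chemical Langevin) toggle switch
#'
#' Euler--Maruyama integration of the chemical Langevin equation
#' `dX = S a(X) dt + S diag(sqrt(a(X))) dW` for the four biochemical
#' species, with eight independent Wiener increments (one per
#' pseudoreaction). The inducer states carry no pseudoreactions and are
#' propagated deterministically by the membrane-exchange kinetics. States
#' are clamped at zero from below after each step.
#'
#' @inheritParams simulate_toggle_ode
#' @param dt Euler--Maruyama step (min), default 0.1; must divide the
#'   sampling period.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param noise_scale multiplier on the diffusion term (1 = chemical
#'   Langevin; 0 recovers the fixed-step deterministic Euler scheme).
#' @return A `toggle_trajectory` tibble sampled every `sample_period`
#'   minutes, with an attribute `n_clamped` counting negative excursions
#'   clamped to zero.
#' @examples
#' p <- toggle_params()
#' tr <- simulate_toggle_sde(p, c(aTc_ext = 25, IPTG_ext = 0),
#'                           toggle_state(TetR = 500), t_end = 30, seed = 1)
#' @export
simulate_toggle_sde <- function(params, inputs, x0, t_end, dt = 0.1,
                                sample_period = 5, seed = NULL,
                                noise_scale = 1) {
  stopifnot(dt > 0, dt <= sample_period)
  nsub <- round(sample_period / dt)
  if (abs(nsub * dt - sample_period) > 1e-9) {
    stop("dt must divide the sampling period", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  S <- toggle_stoichiometry()
  p <- params
  nsamp <- floor(t_end / sample_period)
  times <- seq(0, nsamp * sample_period, by = sample_period)
  states <- matrix(NA_real_, nsamp + 1, 6)
  urec <- matrix(NA_real_, nsamp + 1, 2)
  x <- as.numeric(x0)
  states[1, ] <- x
  urec[1, ] <- input_at(inputs, 0)
  n_clamped <- 0L
  for (k in seq_len(nsamp)) {
    u <- input_at(inputs, times[k])
    x <- em_steps(x, u[1], u[2], params, dt, nsub, noise_scale)
    n_clamped <- n_clamped + attr(x, "n_clamped")
    states[k + 1, ] <- x
    urec[k + 1, ] <- u
  }
  out <- as_trajectory(times, states, urec[, 1], urec[, 2])
  attr(out, "n_clamped") <- n_clamped
  if (n_clamped > t_end / dt) {
    warning("many negative excursions clamped; consider a smaller dt",
            call. = FALSE)
  }
  out
}

# `nsub` Euler--Maruyama steps of length dt under held inputs, consuming
# the current RNG stream; shared by simulate_toggle_sde() and the CBC
# loop so both plants are the same discretization.
em_steps <- function(x, aTc_ext, IPTG_ext, params, dt, nsub,
                     noise_scale = 1) {
  p <- params
  S <- toggle_stoichiometry()
  sq_dt <- sqrt(dt)
  n_clamped <- 0L
  for (s in seq_len(nsub)) {
    a <- propensities(x, aTc_ext, IPTG_ext, p)
    dW <- stats::rnorm(8L, sd = sq_dt)
    x4 <- x[1:4] + (S %*% a) * dt + noise_scale * (S %*% (sqrt(a) * dW))
    if (any(x4 < 0)) {
      n_clamped <- n_clamped + sum(x4 < 0)
      x4 <- pmax(x4, 0)
    }
    ka <- if (aTc_ext >= x[5]) p$kaTcin else p$kaTcout
    ki <- if (IPTG_ext >= x[6]) p$kIPTGin else p$kIPTGout
    x <- c(x4, x[5] + ka * (aTc_ext - x[5]) * dt,
           x[6] + ki * (IPTG_ext - x[6]) * dt)
  }
  attr(x, "n_clamped") <- n_clamped
  x
}

#' Locate a steady state of the toggle switch
#'
#' Damped Newton iteration on the four-state biochemical subsystem with the
#' internal inducers pinned to the external concentrations (membrane
#' exchange vanishes at equilibrium, so internal = external at every steady
#' state).
#'
#' @param params a [toggle_params()] object.
#' @param aTc_ext,IPTG_ext external inducer concentrations (ng/mL, mM).
#' @param guess starting state; see [toggle_state()]. Only the four
#'   biochemical components are used. In the bistable window, low- and
#'   high-TetR guesses converge to the two different stable equilibria.
#' @param tol residual norm tolerance (default 1e-9).
#' @param max_iter Newton iteration cap.
#' @return Named 6-vector: the equilibrium state (internal inducers equal
#'   to the external ones), with attribute `residual`.
#' @export
steady_state <- function(params, aTc_ext, IPTG_ext, guess,
                         tol = 1e-9, max_iter = 200) {
  stopifnot(aTc_ext >= 0, IPTG_ext >= 0)
  x <- pmax(as.numeric(guess)[1:4], 1e-6)
  f <- toggle_rhs4(x, aTc_ext, IPTG_ext, params)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(f^2)) < tol) break
    J <- toggle_jac4(x, aTc_ext, IPTG_ext, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular Jacobian in steady_state(); try a different guess",
           call. = FALSE)
    }
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn <- toggle_rhs4(xn, aTc_ext, IPTG_ext, params)
      if (sqrt(sum(fn^2)) < sqrt(sum(f^2)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
  }
  if (sqrt(sum(f^2)) >= tol) {
    stop("steady_state() did not converge (residual ",
         format(sqrt(sum(f^2))), "); try a different guess", call. = FALSE)
  }
  out <- stats::setNames(c(x, aTc_ext, IPTG_ext), STATE_NAMES)
  attr(out, "residual") <- sqrt(sum(f^2))
  out
}

# All equilibrium TetR values at a given IPTG, by exhaustive bracketing of
# the scalar steady-state map TetR -> G(TetR). Independent of the
# continuation code; used as a root-count/branch oracle.
#
# At equilibrium the 4-state system reduces to a scalar fixed-point
# problem: given TetR, LacI follows from the LacI-arm steady state, and
# TetR follows back from the TetR arm. Equilibria are roots of
# G(TetR) - TetR.
equilibria_at <- function(params, aTc_ext, IPTG_ext, n_grid = 2000) {
  p <- params
  wa <- hill(aTc_ext, p$thetaaTc, p$etaaTc)
  wi <- hill(IPTG_ext, p$thetaIPTG, p$etaIPTG)
  Gmap <- function(Tt) {
    mL <- (p$kLm0 + p$kLm * hill(Tt * wa, p$thetaTetR, p$etaTetR)) / p$gLm
    L <- p$kLp * mL / p$gLp
    mT <- (p$kTm0 + p$kTm * hill(L * wi, p$thetaLacI, p$etaLacI)) / p$gTm
    p$kTp * mT / p$gTp
  }
  Tmax <- p$kTp * (p$kTm0 + p$kTm) / (p$gTm * p$gTp)
  grid <- seq(0, Tmax * 1.05, length.out = n_grid)
  g <- vapply(grid, Gmap, numeric(1)) - grid
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (g[i] == 0) roots <- c(roots, grid[i])
    if (g[i] * g[i + 1] < 0) {
      r <- stats::uniroot(function(Tt) Gmap(Tt) - Tt, c(grid[i], grid[i + 1]),
                          tol = 1e-12)$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(roots))
  # assemble the full states
  lapply(roots, function(Tt) {
    mL <- (p$kLm0 + p$kLm * hill(Tt * wa, p$thetaTetR, p$etaTetR)) / p$gLm
    L <- p$kLp * mL / p$gLp
    mT <- p$gTp * Tt / p$kTp
    stats::setNames(c(mL, mT, L, Tt, aTc_ext, IPTG_ext), STATE_NAMES)
  })
}
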