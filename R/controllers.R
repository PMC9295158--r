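# The two stabilizing control laws used inside control-based
# continuation: a proportional controller (gain selected by linearized
# closed-loop eigenvalue analysis) and an MPC stack (LTI identification
# -> Kalman predictor -> constrained genetic-algorithm optimization).

#' Proportional controller configuration
#'
#' @param Kp proportional gain (mM of IPTG per a.u. of TetR error).
#' @param input_bounds admissible IPTG range (mM), default [0, 1].
#' @return List of class `p_controller`.
#' @export
p_controller <- function(Kp = 0.0016, input_bounds = c(0, 1)) {
  stopifnot(Kp > 0, length(input_bounds) == 2,
            input_bounds[1] < input_bounds[2])
  structure(list(Kp = Kp, input_bounds = input_bounds),
            class = "p_controller")
}

#' Proportional control law
#'
#' `u = clamp(Kp * (x_ref - y_TetR), input_bounds)`: the IPTG input is
#' proportional to the control error (reference minus measured TetR),
#' clamped to the admissible input range.
#'
#' @param x_ref control reference (a.u. of TetR).
#' @param y_TetR measured TetR (a.u.).
#' @param cfg a [p_controller()].
#' @return IPTG concentration to apply (mM).
#' @examples
#' p_control(1800, 1100, p_controller(Kp = 0.0016))
#' @export
p_control <- function(x_ref, y_TetR, cfg = p_controller()) {
  stopifnot(is.finite(x_ref), is.finite(y_TetR))
  u <- cfg$Kp * (x_ref - y_TetR)
  min(max(u, cfg$input_bounds[1]), cfg$input_bounds[2])
}

# Bisection for the smallest gain whose closed-loop spectrum lies in the
# open left half plane; `max_re_fun(Kp)` returns the leading eigenvalue
# real part. Result rounded to 3 significant figures (still stabilizing).
minimal_stabilizing_gain <- function(max_re_fun, lower = 1e-8, upper = 10) {
  if (max_re_fun(lower) < 0) return(signif(lower, 3))
  hi <- lower
  repeat {
    hi <- hi * 2
    if (hi > upper) stop("no stabilizing gain found below ", upper,
                         call. = FALSE)
    if (max_re_fun(hi) < 0) break
  }
  lo <- hi / 2
  while ((hi - lo) / hi > 1e-6) {
    mid <- (lo + hi) / 2
    if (max_re_fun(mid) < 0) hi <- mid else lo <- mid
  }
  kp <- signif(hi, 3)
  if (max_re_fun(kp) >= 0) kp <- signif(hi * 1.001, 3)
  kp
}

#' Minimal stabilizing proportional gain at an unstable equilibrium
#'
#' Linearizes the six-state plant around the equilibrium, closes the IPTG
#' channel through the proportional law (the external IPTG becomes
#' `-Kp` times the TetR deviation, entering through the membrane influx
#' kinetics), and bisects on the gain until the leading closed-loop
#' eigenvalue crosses the imaginary axis. Returns the smallest
#' stabilizing gain to three significant figures.
#'
#' @param params a [toggle_params()] object.
#' @param unstable_point equilibrium state (named 6-vector or the four
#'   biochemical components) classified unstable.
#' @param aTc_ext,IPTG_ext external inducers at the equilibrium.
#' @param upper upper limit of the gain search.
#' @return Minimal stabilizing `Kp` (mM per a.u.).
#' @export
tune_kp <- function(params, unstable_point, aTc_ext = 25, IPTG_ext = NULL,
                    upper = 10) {
  x <- as.numeric(unstable_point)
  if (length(x) >= 6 && is.null(IPTG_ext)) IPTG_ext <- x[6]
  stopifnot(!is.null(IPTG_ext))
  state <- stats::setNames(c(x[1:4], aTc_ext, IPTG_ext), STATE_NAMES)
  if (classify_stability(state, aTc_ext, IPTG_ext, params) != "unstable") {
    stop("tune_kp() expects an unstable equilibrium", call. = FALSE)
  }
  f <- function(Kp) {
    max(Re(eigen(closed_loop_jacobian(state, aTc_ext, IPTG_ext, params, Kp),
                 only.values = TRUE)$values))
  }
  minimal_stabilizing_gain(f, upper = upper)
}

# 6x6 Jacobian of the P-controlled plant: the open-loop Jacobian with the
# external IPTG channel closed through u = Kp (ref - TetR). The influx
# rate constant is used for the exchange linearization (the controller
# raises the external level above the internal one when TetR falls).
closed_loop_jacobian <- function(state, aTc_ext, IPTG_ext, params, Kp) {
  J <- toggle_jacobian(state, aTc_ext, IPTG_ext, params)
  J[6, 6] <- -params$kIPTGin
  J[6, 4] <- J[6, 4] - params$kIPTGin * Kp
  J
}

#' Generate pulse-response data for system identification
#'
#' Excites the stochastic toggle switch with randomly generated
#' piecewise-constant pulses of aTc and IPTG (random durations and
#' amplitudes) and records the LacI/TetR outputs every 5 min, emulating
#' the identification experiments run before MPC deployment.
#'
#' @param params a [toggle_params()] object.
#' @param pulse_spec list with elements `t_end` (min, default 2400),
#'   `dur_range` (pulse duration range in min, default c(60, 240),
#'   rounded to the 5-min grid), `IPTG_range` (mM, default c(0, 1)) and
#'   `aTc_range` (ng/mL, default c(0, 50)).
#' @param seed integer seed (pulse schedule and process noise).
#' @param x0 initial state; default the unforced (IPTG = 0, aTc = 25)
#'   equilibrium.
#' @param plant `"sde"` (default) or `"ode"`.
#' @return Tibble of class `id_dataset` with columns `time_min`,
#'   `aTc_ext`, `IPTG_ext`, `LacI`, `TetR`; the pulse schedule and seed
#'   are attached as attributes.
#' @export
generate_id_data <- function(params, pulse_spec = list(), seed = 1,
                             x0 = NULL, plant = c("sde", "ode")) {
  plant <- match.arg(plant)
  spec <- utils::modifyList(list(t_end = 2400, dur_range = c(60, 240),
                                 IPTG_range = c(0, 1), aTc_range = c(0, 50)),
                            pulse_spec)
  stopifnot(spec$IPTG_range[1] >= 0, spec$aTc_range[1] >= 0)
  set.seed(seed)
  sched <- list(); t <- 0
  while (t < spec$t_end) {
    dur <- 5 * round(stats::runif(1, spec$dur_range[1],
                                  spec$dur_range[2]) / 5)
    dur <- max(dur, 5)
    sched[[length(sched) + 1]] <- data.frame(
      time_min = t,
      aTc_ext = stats::runif(1, spec$aTc_range[1], spec$aTc_range[2]),
      IPTG_ext = stats::runif(1, spec$IPTG_range[1], spec$IPTG_range[2]))
    t <- t + dur
  }
  schedule <- do.call(rbind, sched)
  if (is.null(x0)) {
    x0 <- steady_state(params, 25, 0,
                       toggle_state(mRNA_LacI = 50, mRNA_TetR = 1,
                                    LacI = 3000, TetR = 60))
  }
  tr <- if (plant == "sde") {
    simulate_toggle_sde(params, schedule, x0, t_end = spec$t_end)
  } else {
    simulate_toggle_ode(params, schedule, x0, t_end = spec$t_end)
  }
  out <- tibble::tibble(time_min = tr$time_min, aTc_ext = tr$aTc_ext,
                        IPTG_ext = tr$IPTG_ext, LacI = tr$LacI,
                        TetR = tr$TetR)
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  class(out) <- c("id_dataset", class(out))
  out
}

#' Identify an innovation-form LTI model from pulse data
#'
#' Least-squares prediction-error fit of a multivariable ARX predictor of
#' the LacI/TetR outputs on the aTc/IPTG inputs, realized in block
#' observer form as a discrete-time innovation model
#' `x(k+1) = Ad x + Bd u + Kd e`, `y = Cd x + e` with `D = 0` (no direct
#' feedthrough), working in deviations from the training means. The
#' continuous-time matrices `A`, `B`, `C`, `K` are recovered through the
#' matrix logarithm of `Ad`. Training fit percentages of the one-interval
#' Kalman predictor are attached.
#'
#' @param train an `id_dataset` from [generate_id_data()].
#' @param order state dimension `n` (even; `n/2` output lags), default 4.
#' @return Object of class `lti_model`: discrete matrices `Ad`, `Bd`,
#'   `Cd`, `Kd`, sampling period `Ts`, offsets `u0`, `y0`, continuous
#'   `A`, `B`, `C`, `D`, `K` (NULL if the matrix logarithm is not real),
#'   and `fit` (training fit percentages).
#' @export
identify_lti <- function(train, order = 4) {
  stopifnot(order >= 2, order %% 2 == 0)
  p_lag <- order / 2
  Y <- as.matrix(train[, c("LacI", "TetR")])
  U <- as.matrix(train[, c("aTc_ext", "IPTG_ext")])
  N <- nrow(Y)
  if (N <= 10 * order) {
    stop("identification dataset too short for the requested order",
         call. = FALSE)
  }
  y0 <- colMeans(Y); u0 <- colMeans(U)
  Yd <- sweep(Y, 2, y0); Ud <- sweep(U, 2, u0)
  idx <- (p_lag + 1):N
  # lagged outputs and inputs plus an intercept absorbing the residual
  # constant that centering leaves for non-stationary records
  Phi <- do.call(cbind, c(
    lapply(seq_len(p_lag), function(i) Yd[idx - i, , drop = FALSE]),
    lapply(seq_len(p_lag), function(i) Ud[idx - i, , drop = FALSE]),
    list(rep(1, length(idx)))))
  qrP <- qr(Phi)
  if (qrP$rank < ncol(Phi)) {
    stop("rank-deficient identification data; use richer pulses",
         call. = FALSE)
  }
  Th <- t(qr.coef(qrP, Yd[idx, , drop = FALSE]))   # 2 x (4 p_lag + 1)
  Ai <- lapply(seq_len(p_lag), function(i)
    unname(Th[, (2 * i - 1):(2 * i)]))
  Bi <- lapply(seq_len(p_lag), function(i)
    unname(Th[, (2 * p_lag + 2 * i - 1):(2 * p_lag + 2 * i)]))
  cc <- unname(Th[, ncol(Th)])
  n <- order
  Ad <- matrix(0, n, n)
  for (i in seq_len(p_lag)) Ad[(2 * i - 1):(2 * i), 1:2] <- Ai[[i]]
  if (p_lag > 1) {
    Ad[1:(n - 2), 3:n] <- diag(n - 2)
  }
  Bd <- do.call(rbind, Bi)
  Kd <- do.call(rbind, Ai)
  Cd <- cbind(diag(2), matrix(0, 2, n - 2))
  Ts <- diff(train$time_min[1:2])
  cont <- tryCatch({
    Ac <- pracma::logm(Ad) / Ts
    if (max(abs(Im(Ac))) > 1e-8) stop("complex logarithm")
    Ac <- Re(Ac)
    Bc <- solve(Ad - diag(n), Ac %*% Bd)
    Kc <- solve(Ad - diag(n), Ac %*% Kd)
    list(A = Ac, B = Bc, C = Cd, D = matrix(0, 2, 2), K = Kc)
  }, error = function(e) list(A = NULL, B = NULL, C = Cd,
                              D = matrix(0, 2, 2), K = NULL))
  cd <- c(cc, rep(0, n - 2))   # affine term enters the output block
  model <- structure(
    c(list(Ad = Ad, Bd = Bd, Cd = Cd, Kd = Kd, cd = cd, Ts = Ts, y0 = y0,
           u0 = u0, order = n, n_lags = p_lag), cont),
    class = "lti_model")
  pred <- kalman_predict(model, U, Y)
  model$fit <- c(LacI = fit_percent(Y[, 1], pred$outputs$LacI),
                 TetR = fit_percent(Y[, 2], pred$outputs$TetR))
  model
}

#' Assemble an innovation-form LTI model from given matrices
#'
#' Mostly useful for tests and toy plants; [identify_lti()] builds the
#' model from data. Either the discrete matrices (`Ad`, `Bd`, `Kd`) or
#' the continuous ones (`A`, `B`, `K`, discretized by the matrix
#' exponential at `Ts`) must be supplied. `D` is identically zero.
#'
#' @param Ad,Bd,Cd,Kd discrete-time innovation-form matrices.
#' @param A,B,C,K continuous-time matrices (used when `Ad` is missing).
#' @param Ts sampling period (min).
#' @param y0,u0 output/input offsets (original units), default zero.
#' @return An `lti_model` object.
#' @export
lti_model <- function(Ad = NULL, Bd = NULL, Cd = NULL, Kd = NULL,
                      A = NULL, B = NULL, C = NULL, K = NULL,
                      Ts = 5, y0 = NULL, u0 = NULL) {
  if (is.null(Ad)) {
    stopifnot(!is.null(A), !is.null(B), !is.null(C))
    n <- nrow(A)
    if (is.null(K)) K <- matrix(0, n, nrow(C))
    Ad <- pracma::expm(A * Ts)
    M <- solve(A, Ad - diag(n))    # integral of expm(A t) over the period
    Bd <- M %*% B
    Kd <- M %*% K
    Cd <- C
  } else {
    stopifnot(!is.null(Bd), !is.null(Cd))
    n <- nrow(Ad)
    if (is.null(Kd)) Kd <- matrix(0, n, nrow(Cd))
  }
  ny <- nrow(Cd); nu <- ncol(Bd)
  if (is.null(y0)) y0 <- rep(0, ny)
  if (is.null(u0)) u0 <- rep(0, nu)
  structure(list(Ad = Ad, Bd = Bd, Cd = Cd, Kd = Kd, Ts = Ts,
                 y0 = y0, u0 = u0, order = nrow(Ad),
                 A = A, B = B, C = if (is.null(C)) Cd else C,
                 D = matrix(0, ny, ny), K = K),
            class = "lti_model")
}

#' @export
print.lti_model <- function(x, ...) {
  cat("<lti_model> order", x$order, " Ts =", x$Ts, "min, D = 0\n")
  if (!is.null(x$fit)) {
    cat("training fit %:", paste(names(x$fit),
                                 round(x$fit, 1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Model fit percentage
#'
#' `100 * (1 - ||y - y_hat|| / ||y - mean(y)||)` with Euclidean norms:
#' the percentage of the output variation reproduced by the model (100 =
#' perfect, 0 = no better than the mean, negative = worse).
#'
#' @param y measured output series.
#' @param y_hat model-predicted series of the same length.
#' @return Scalar percentage.
#' @export
fit_percent <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom == 0) stop("fit_percent() undefined for constant y",
                       call. = FALSE)
  100 * (1 - sqrt(sum((y - y_hat)^2)) / denom)
}

#' Kalman predictor of the identified innovation model
#'
#' Propagates the innovation-form predictor over each sampling interval:
#' the state estimate evolves with the applied inputs and is corrected by
#' the measured LacI/TetR through the Kalman gain
#' (`x(k+1) = Ad x + Bd (u - u0) + Kd (y - y0 - Cd x)`). With `y = NULL`
#' (or a zero gain) this reduces to open-loop simulation of the model.
#'
#' @param model an `lti_model`.
#' @param u input matrix (columns aTc, IPTG), one row per sample.
#' @param y measured output matrix (columns LacI, TetR) or `NULL`.
#' @param x0 initial predictor state (deviation coordinates). Defaults to
#'   zero, except for identified (block observer form) models with
#'   measurements available, where the state is initialized from the
#'   first sample under a constant-history assumption so the early
#'   predictions start at the measured output instead of the training
#'   mean.
#' @return List with `states` (matrix of predictor states, row k =
#'   estimate at sample k) and `outputs` (tibble `LacI`, `TetR` of
#'   predicted outputs in original units).
#' @export
kalman_predict <- function(model, u, y = NULL, x0 = NULL) {
  u <- as.matrix(u); N <- nrow(u)
  if (!is.null(y)) {
    y <- as.matrix(y)
    stopifnot(nrow(y) == N)
  }
  n <- model$order
  ny <- nrow(model$Cd)
  x <- if (!is.null(x0)) as.numeric(x0)
       else if (!is.null(y) && !is.null(model$n_lags)) {
         arx_initial_state(model, y[1, ], u[1, ])
       } else rep(0, n)
  X <- matrix(NA_real_, N, n)
  Yh <- matrix(NA_real_, N, ny)
  for (k in seq_len(N)) {
    X[k, ] <- x
    yh <- as.numeric(model$Cd %*% x)
    Yh[k, ] <- yh + model$y0
    innov <- if (is.null(y)) rep(0, ny) else (y[k, ] - model$y0 - yh)
    x <- as.numeric(model$Ad %*% x + model$Bd %*% (u[k, ] - model$u0) +
                      model$Kd %*% innov)
    if (!is.null(model$cd)) x <- x + model$cd
  }
  colnames(Yh) <- if (ny == 2) c("LacI", "TetR") else
    paste0("y", seq_len(ny))
  list(states = X, outputs = tibble::as_tibble(Yh))
}

# Block-observer predictor state consistent with a constant pre-history
# at the first measured sample: x_1 = yd1, and for deeper blocks
# x_j = sum_{i >= j} (A_i yd1 + B_i ud1) with A_i, B_i read off the
# stacked Kd/Bd blocks.
arx_initial_state <- function(model, y1, u1) {
  p_lag <- model$n_lags
  yd1 <- y1 - model$y0
  ud1 <- u1 - model$u0
  blocks <- lapply(seq_len(p_lag), function(i) {
    rows <- (2 * i - 1):(2 * i)
    as.numeric(model$Kd[rows, , drop = FALSE] %*% yd1 +
                 model$Bd[rows, , drop = FALSE] %*% ud1)
  })
  x <- numeric(model$order)
  x[1:2] <- yd1
  if (p_lag > 1) {
    for (j in 2:p_lag) {
      x[(2 * j - 1):(2 * j)] <- Reduce(`+`, blocks[j:p_lag])
    }
  }
  x
}

#' MPC configuration for control-based continuation
#'
#' @param model an `lti_model` used for prediction.
#' @param N prediction horizon in 5-min steps, default 12 (1 h).
#' @param gamma admissible relative band of the input around the previous
#'   steady-state value, default 0.3.
#' @param input_bounds admissible IPTG range (mM).
#' @param u_init band center for the first reference step (mM).
#' @param aTc_ext held-constant aTc level fed to the aTc input channel.
#' @param ga_pop,ga_gens genetic-algorithm budget per step.
#' @return List of class `mpc_controller`.
#' @export
mpc_controller <- function(model, N = 12, gamma = 0.3,
                           input_bounds = c(0, 1), u_init = 1,
                           aTc_ext = 25, ga_pop = 40, ga_gens = 30) {
  stopifnot(N >= 1, gamma > 0, gamma <= 1)
  structure(list(model = model, N = N, gamma = gamma,
                 input_bounds = input_bounds, u_init = u_init,
                 aTc_ext = aTc_ext, ga_pop = ga_pop, ga_gens = ga_gens),
            class = "mpc_controller")
}

#' One MPC step: optimal constant input over the horizon
#'
#' Minimizes the weighted quadratic tracking cost
#' `J = sum_{k=1..N} (N - k + 1) e(i+k)^2` over a candidate IPTG input
#' held constant across the horizon, with the TetR error predicted
#' through the identified LTI model from the current predictor state. The
#' feasible set is the input bounds intersected with the relative band
#' `[u (1 - gamma), u (1 + gamma)]` around the previous registered
#' steady-state input (or around `u_init` on the first reference step).
#' The minimization uses the seeded genetic algorithm, matching the
#' experiment protocol.
#'
#' @param cfg an [mpc_controller()].
#' @param x_hat current predictor state (deviation coordinates).
#' @param x_ref TetR reference (a.u.).
#' @param u_prev_ss previous steady-state input (mM).
#' @param first_step logical; center the band on `u_init` instead.
#' @return IPTG input to apply (mM).
#' @export
mpc_step <- function(cfg, x_hat, x_ref, u_prev_ss, first_step = FALSE) {
  m <- cfg$model
  center <- if (first_step) cfg$u_init else u_prev_ss
  lo <- max(cfg$input_bounds[1], center * (1 - cfg$gamma))
  hi <- min(cfg$input_bounds[2], center * (1 + cfg$gamma))
  if (lo > hi) {
    stop("empty feasible set: the gamma band lies outside the input bounds",
         call. = FALSE)
  }
  if (hi - lo < 1e-12) return(lo)
  # TetR prediction is affine in the (constant) candidate input u:
  # e_k = a_k + b_k (u - u0_IPTG); accumulate the quadratic coefficients.
  n <- m$order
  x <- as.numeric(x_hat)
  cvec <- rep(0, n)                 # sensitivity state wrt IPTG deviation
  da <- cfg$aTc_ext - m$u0[1]       # held-constant aTc deviation
  cd <- if (is.null(m$cd)) rep(0, n) else m$cd
  q0 <- 0; q1 <- 0; q2 <- 0
  for (k in seq_len(cfg$N)) {
    x <- as.numeric(m$Ad %*% x) + m$Bd[, 1] * da + cd
    cvec <- as.numeric(m$Ad %*% cvec) + m$Bd[, 2]
    a_k <- sum(m$Cd[2, ] * x) + m$y0[2] - x_ref
    b_k <- sum(m$Cd[2, ] * cvec)
    w <- cfg$N - k + 1
    q0 <- q0 + w * a_k^2
    q1 <- q1 + w * a_k * b_k
    q2 <- q2 + w * b_k^2
  }
  du0 <- m$u0[2]
  fn <- function(X) {
    du <- X[, 1] - du0
    q0 + 2 * q1 * du + q2 * du^2
  }
  res <- ga_optimize(fn, lo, hi, pop_size = cfg$ga_pop,
                     generations = cfg$ga_gens, mut_sd = 0.2)
  unname(res$par)
}
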