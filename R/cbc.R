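# The control-based continuation loop: step the reference, run the
# controlled plant, detect steady state, average the tail, record the
# (TetR_ss, IPTG_ss) pair -- plus the fold-normal-form testbed that
# embodies the noninvasiveness argument in closed form.

#' Configuration of a control-based continuation run
#'
#' @param references explicit vector of TetR references (a.u.), or `NULL`
#'   to use `make_reference_schedule(ref_start, ref_end, n_points)`.
#' @param ref_start,ref_end,n_points linear reference schedule (a.u.),
#'   descending by default: 30 points from 1800 down to 0.
#' @param sampling sampling/actuation period (min), default 5.
#' @param dwell_mode `"fixed"` (hold each reference a fixed time) or
#'   `"detect"` (advance once the steady-state detector fires).
#' @param dwell fixed dwell per reference (min), default 595 (9 h 55 min).
#' @param min_dwell minimum dwell before detection is consulted (min),
#'   default 180 (3 h).
#' @param window number of samples in the steady-state detection window,
#'   default 12.
#' @param slope_tol_error,slope_tol_control detection tolerances on the
#'   least-squares slope of the error and control windows (a.u./sample,
#'   mM/sample). Defaults 0.5 and 1e-4 for the deterministic plant; both
#'   are multiplied by `noise_slope_factor` for the SDE plant.
#' @param noise_slope_factor slope-tolerance inflation under process
#'   noise, default 5.
#' @param avg_window number of trailing samples averaged into each
#'   collected point, default 12 (the last hour).
#' @param plant `"ode"` or `"sde"`.
#' @param sde_dt Euler--Maruyama step for the SDE plant (min).
#' @param seed integer seed (SDE noise and any stochastic controller).
#' @param aTc_ext fixed external aTc (ng/mL), default 25.
#' @param x0 initial plant state; default the IPTG = 0 equilibrium.
#' @return List of class `cbc_config`.
#' @export
cbc_config <- function(references = NULL, ref_start = 1800, ref_end = 0,
                       n_points = 30, sampling = 5,
                       dwell_mode = c("fixed", "detect"), dwell = 595,
                       min_dwell = 180, window = 12,
                       slope_tol_error = 0.5, slope_tol_control = 1e-4,
                       noise_slope_factor = 5, avg_window = 12,
                       plant = c("ode", "sde"), sde_dt = 0.1, seed = NULL,
                       aTc_ext = 25, x0 = NULL) {
  dwell_mode <- match.arg(dwell_mode)
  plant <- match.arg(plant)
  if (is.null(references)) {
    references <- make_reference_schedule(ref_start, ref_end, n_points)
  }
  stopifnot(length(references) >= 2, sampling > 0,
            window * sampling <= dwell, avg_window * sampling <= dwell)
  structure(list(references = references, sampling = sampling,
                 dwell_mode = dwell_mode, dwell = dwell,
                 min_dwell = min_dwell, window = window,
                 slope_tol_error = slope_tol_error,
                 slope_tol_control = slope_tol_control,
                 noise_slope_factor = noise_slope_factor,
                 avg_window = avg_window, plant = plant, sde_dt = sde_dt,
                 seed = seed, aTc_ext = aTc_ext, x0 = x0),
            class = "cbc_config")
}

#' Linear schedule of control references
#'
#' @param start first reference (a.u.).
#' @param end last reference (a.u.).
#' @param n number of points (>= 2).
#' @return Numeric vector of `n` equally spaced references from `start`
#'   to `end` (descending when `start > end`).
#' @examples
#' make_reference_schedule(1800, 0, 30)
#' @export
make_reference_schedule <- function(start, end, n) {
  stopifnot(n >= 2)
  seq(start, end, length.out = n)
}

#' Steady-state detection from trailing signal windows
#'
#' Fits a least-squares line to the last `n` samples of the error signal
#' and of the control signal; the process is declared at steady state
#' when both slopes are below their tolerances in absolute value.
#'
#' @param error_window,control_window trailing samples of the control
#'   error (a.u.) and applied input (mM); at least `n` samples each.
#' @param tol_error,tol_control slope tolerances (a.u./sample,
#'   mM/sample).
#' @param n window length (samples), default 12.
#' @return List with `steady` (logical), `slope_error`, `slope_control`
#'   (per-sample least-squares slopes).
#' @export
detect_steady_state <- function(error_window, control_window,
                                tol_error = 0.5, tol_control = 1e-4,
                                n = 12) {
  if (length(error_window) < n || length(control_window) < n) {
    stop("detection windows shorter than the configured ", n, " samples",
         call. = FALSE)
  }
  se <- ols_slope(utils::tail(error_window, n))
  sc <- ols_slope(utils::tail(control_window, n))
  list(steady = abs(se) < tol_error && abs(sc) < tol_control,
       slope_error = se, slope_control = sc)
}

# least-squares slope of y against sample index 1..n
ols_slope <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Average a trajectory tail into one collected equilibrium point
#'
#' The steady-state values of every signal are the arithmetic means over
#' the last `avg_window` samples (default 12, i.e. the last hour at 5-min
#' sampling) of the closed-loop trajectory tail.
#'
#' @param tail_df trailing rows of the closed-loop trajectory, with the
#'   six state columns and `IPTG_applied`.
#' @param reference the reference the controller was tracking (a.u.).
#' @param avg_window number of samples to average.
#' @return One-row tibble with `reference`, `TetR_ss`, `IPTG_ss` and the
#'   averaged remaining states.
#' @export
collect_point <- function(tail_df, reference, avg_window = 12) {
  if (nrow(tail_df) < avg_window) {
    stop("trajectory tail shorter than the averaging window", call. = FALSE)
  }
  tl <- utils::tail(tail_df, avg_window)
  tibble::tibble(reference = reference,
                 TetR_ss = mean(tl$TetR),
                 IPTG_ss = mean(tl$IPTG_applied),
                 LacI_ss = mean(tl$LacI),
                 mRNA_LacI_ss = mean(tl$mRNA_LacI),
                 mRNA_TetR_ss = mean(tl$mRNA_TetR),
                 aTc_in_ss = mean(tl$aTc_in),
                 IPTG_in_ss = mean(tl$IPTG_in))
}

#' Run control-based continuation on the toggle switch
#'
#' For each reference in the schedule, the controller input is computed
#' from the latest measurement, held constant for one sampling period,
#' and applied to the plant; this repeats until the dwell elapses (fixed
#' mode) or the steady-state detector fires after the minimum dwell
#' (detect mode). The trailing samples are then averaged into one
#' collected point and the plant state carries over to the next
#' reference. With a settled, constant control signal the collected
#' (TetR_ss, IPTG_ss) pair is an equilibrium of the *uncontrolled* plant
#' at IPTG = IPTG_ss: the constant input is a pure shift of the
#' bifurcation parameter, which is what makes the controller
#' noninvasive.
#'
#' @param controller a [p_controller()] or [mpc_controller()].
#' @param cfg a [cbc_config()].
#' @param params a [toggle_params()] object.
#' @param verbose print one log line per collected point.
#' @return A `cbc_result`: tibble of collected points (columns
#'   `reference`, `TetR_ss`, `IPTG_ss`, averaged states, `dwell_min`,
#'   `converged`) with the full closed-loop trajectory, the controller,
#'   the config and `total_hours` as attributes.
#' @export
run_cbc <- function(controller, cfg = cbc_config(), params = toggle_params(),
                    verbose = FALSE) {
  stopifnot(inherits(cfg, "cbc_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  is_mpc <- inherits(controller, "mpc_controller")
  tol_e <- cfg$slope_tol_error
  tol_c <- cfg$slope_tol_control
  if (cfg$plant == "sde") {
    tol_e <- tol_e * cfg$noise_slope_factor
    tol_c <- tol_c * cfg$noise_slope_factor
  }
  x <- cfg$x0
  if (is.null(x)) {
    x <- steady_state(params, cfg$aTc_ext, 0,
                      toggle_state(mRNA_LacI = 50, mRNA_TetR = 1,
                                   LacI = 3000, TetR = 60))
  }
  x <- as.numeric(x)
  nsub <- if (cfg$plant == "sde") round(cfg$sampling / cfg$sde_dt) else NA
  x_hat <- if (is_mpc) rep(0, controller$model$order) else NULL
  u_prev_applied <- NULL
  u_prev_ss <- NA_real_
  points <- list()
  traj <- list()
  t_global <- 0
  for (ri in seq_along(cfg$references)) {
    ref <- cfg$references[ri]
    errs <- numeric(0); us <- numeric(0)
    rows <- list()
    k <- 0L
    dwell_used <- 0
    steady <- FALSE
    repeat {
      y <- x[4]                       # measured TetR
      if (is_mpc) {
        ym <- x[c(3, 4)]              # measured (LacI, TetR)
        if (!is.null(u_prev_applied)) {
          m <- controller$model
          innov <- ym - m$y0 - as.numeric(m$Cd %*% x_hat)
          x_hat <- as.numeric(m$Ad %*% x_hat +
                                m$Bd %*% (u_prev_applied - m$u0) +
                                m$Kd %*% innov)
          if (!is.null(m$cd)) x_hat <- x_hat + m$cd
        }
        u <- mpc_step(controller, x_hat, ref,
                      u_prev_ss, first_step = (ri == 1L))
      } else {
        u <- p_control(ref, y, controller)
      }
      rows[[k + 1L]] <- c(t_global, x, u, ref)
      errs <- c(errs, ref - y)
      us <- c(us, u)
      # advance the plant one sampling period under the held input
      if (cfg$plant == "ode") {
        x <- ode_piece(x, 0, cfg$sampling, cfg$aTc_ext, u, params)
      } else {
        x <- em_steps(x, cfg$aTc_ext, u, params, cfg$sde_dt, nsub)
      }
      if (is_mpc) u_prev_applied <- c(cfg$aTc_ext, u)
      k <- k + 1L
      t_global <- t_global + cfg$sampling
      dwell_used <- k * cfg$sampling
      if (cfg$dwell_mode == "fixed") {
        if (dwell_used >= cfg$dwell) break
      } else {
        if (dwell_used >= cfg$min_dwell && k >= cfg$window) {
          det <- detect_steady_state(errs, us, tol_e, tol_c, cfg$window)
          if (det$steady) { steady <- TRUE; break }
        }
        if (dwell_used >= cfg$dwell) break   # dwell cap also in detect mode
      }
    }
    tr <- as.data.frame(do.call(rbind, rows))
    names(tr) <- c("time_min", STATE_NAMES, "IPTG_applied", "reference")
    det_final <- detect_steady_state(errs, us, tol_e, tol_c,
                                     min(cfg$window, length(errs)))
    pt <- collect_point(tr, ref, cfg$avg_window)
    pt$dwell_min <- dwell_used
    pt$converged <- if (cfg$dwell_mode == "detect") steady else
      det_final$steady
    u_prev_ss <- pt$IPTG_ss
    points[[ri]] <- pt
    traj[[ri]] <- tr
    if (verbose) {
      message(sprintf(
        "ref %8.1f a.u. | dwell %4d min | converged %s | TetR_ss %8.2f IPTG_ss %.4f",
        ref, dwell_used, pt$converged, pt$TetR_ss, pt$IPTG_ss))
    }
  }
  pts <- dplyr::bind_rows(points)
  out <- pts
  class(out) <- c("cbc_result", class(out))
  attr(out, "trajectory") <- tibble::as_tibble(dplyr::bind_rows(traj))
  attr(out, "controller") <- controller
  attr(out, "config") <- cfg
  attr(out, "params") <- params
  attr(out, "total_hours") <- sum(pts$dwell_min) / 60
  out
}

#' @export
print.cbc_result <- function(x, ...) {
  cat("<cbc_result> ", nrow(x), " collected points, ",
      round(attr(x, "total_hours"), 1), " simulated hours (",
      class(attr(x, "controller"))[1], ", ",
      attr(x, "config")$plant, " plant)\n", sep = "")
  NextMethod()
}

#' Open-loop noninvasiveness check of collected CBC points
#'
#' Re-simulates the uncontrolled plant from each collected state with the
#' input frozen at the recorded IPTG_ss and reports the largest relative
#' TetR excursion over the horizon. Small excursions certify that the
#' collected pairs are genuine open-loop equilibria (the control merely
#' shifted the bifurcation parameter).
#'
#' @param result a `cbc_result` from [run_cbc()].
#' @param params the plant parameters used in the run.
#' @param horizon_min open-loop horizon (min), default 300 (5 h).
#' @return The points tibble with an added `max_rel_dev` column.
#' @export
check_noninvasive <- function(result, params = attr(result, "params"),
                              horizon_min = 300) {
  cfg <- attr(result, "config")
  devs <- vapply(seq_len(nrow(result)), function(i) {
    pt <- result[i, ]
    x0 <- c(pt$mRNA_LacI_ss, pt$mRNA_TetR_ss, pt$LacI_ss, pt$TetR_ss,
            pt$aTc_in_ss, pt$IPTG_in_ss)
    tr <- simulate_toggle_ode(params,
                              c(aTc_ext = cfg$aTc_ext, IPTG_ext = pt$IPTG_ss),
                              x0, t_end = horizon_min)
    max(abs(tr$TetR - pt$TetR_ss)) / max(pt$TetR_ss, 1e-9)
  }, numeric(1))
  out <- result
  out$max_rel_dev <- devs
  out
}

#' Control-based continuation on the fold normal form
#'
#' Runs the CBC loop on the scalar saddle-node normal form
#' `x' = mu + u - x^2` under proportional control `u = Kp (x_ref - x)`.
#' Because the control enters exactly like the bifurcation parameter, the
#' settled constant input is a pure parameter shift: every collected pair
#' satisfies `x_ss^2 = mu + u_ss`, i.e. the points lie on the open-loop
#' equilibrium curve at the shifted parameter `mu_tilde = mu + u_ss`.
#' With `Kp > 2 sqrt(mu)` the whole curve, including the unstable branch
#' `x < 0`, is stabilized.
#'
#' @param mu bifurcation parameter of the normal form.
#' @param Kp proportional gain.
#' @param references vector of references; default spans both branches.
#'   Note the controlled system only has equilibria for
#'   `x_ref > -(mu + Kp^2/4)/Kp` (the closed loop has its own fold);
#'   references beyond it diverge in finite time.
#' @param sampling sampling period (time units); the input is held
#'   constant over each period.
#' @param dt integrator step within a period.
#' @param dwell samples per reference before collection.
#' @param avg_window trailing samples averaged per point.
#' @return Tibble with one row per reference: `reference`, `x_ss`,
#'   `u_ss`, `mu_tilde` (`= mu + u_ss`) and `residual`
#'   (`x_ss^2 - mu_tilde`).
#' @examples
#' demo <- cbc_fold_demo(mu = 1, Kp = 3)
#' max(abs(demo$residual))
#' @export
cbc_fold_demo <- function(mu = 1, Kp = 3,
                          references = seq(1.4, -0.95, length.out = 15) *
                            sqrt(mu),
                          sampling = 0.5, dt = 0.01, dwell = 400,
                          avg_window = 12) {
  stopifnot(mu > 0, Kp > 0)
  x <- sqrt(mu)   # start on the stable branch
  out <- list()
  nsub <- round(sampling / dt)
  for (ref in references) {
    xs <- numeric(dwell); us <- numeric(dwell)
    for (k in seq_len(dwell)) {
      u <- Kp * (ref - x)
      for (s in seq_len(nsub)) {     # RK4 on the held-input dynamics
        f <- function(z) mu + u - z^2
        k1 <- f(x); k2 <- f(x + dt / 2 * k1)
        k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
        x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      xs[k] <- x; us[k] <- u
    }
    x_ss <- mean(utils::tail(xs, avg_window))
    u_ss <- mean(utils::tail(us, avg_window))
    out[[length(out) + 1]] <- tibble::tibble(
      reference = ref, x_ss = x_ss, u_ss = u_ss,
      mu_tilde = mu + u_ss, residual = x_ss^2 - (mu + u_ss))
  }
  dplyr::bind_rows(out)
}
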