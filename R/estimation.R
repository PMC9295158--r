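# Steady-state parameter estimation from measured equilibrium points
# (TetR_ss, IPTG_ss): analytic inversion of the equilibrium relation,
# nearest-point cost in normalized coordinates, genetic-algorithm fit,
# open-loop sweep baseline, and a bistability check on the fitted model.

# The 14 free parameters, in conventional order; degradation rates stay
# pinned to their nominal values during estimation.
THETA_NAMES <- c("kLm0", "kLm", "thetaaTc", "etaaTc", "thetaTetR", "etaTetR",
                 "kTm0", "kTm", "thetaIPTG", "etaIPTG", "thetaLacI",
                 "etaLacI", "kLp", "kTp")

#' Nominal values of the 14 estimated toggle parameters
#' @return Named numeric vector in the order used throughout estimation.
#' @export
theta_nominal <- function() {
  p <- toggle_params()
  vapply(THETA_NAMES, function(nm) p[[nm]], numeric(1))
}

#' Assemble a full parameter set from an estimated theta vector
#'
#' Degradation rates (and the membrane exchange rates, which do not affect
#' equilibria) are taken from `base`, everything else from `theta`.
#'
#' @param theta named vector over (a subset of) [theta_nominal()] names.
#' @param base a [toggle_params()] supplying the fixed parameters.
#' @return A [toggle_params()] object.
#' @export
theta_to_params <- function(theta, base = toggle_params()) {
  stopifnot(all(names(theta) %in% THETA_NAMES))
  do.call(toggle_params, as.list(theta))
}

# Analytic steady-state inverse IPTG(TetR) at fixed aTc; vectorized over
# TetR, NA where the inversion leaves the real positive domain.
iptg_at_tetr <- function(TetR, params, aTc_ext) {
  p <- params
  wa <- hill(aTc_ext, p$thetaaTc, p$etaaTc)
  mT <- p$gTp * TetR / p$kTp
  v <- (p$gTm * mT - p$kTm0) / p$kTm        # required repression level
  mL <- (p$kLm0 + p$kLm * hill(TetR * wa, p$thetaTetR, p$etaTetR)) / p$gLm
  L <- p$kLp * mL / p$gLp
  out <- rep(NA_real_, length(TetR))
  ok <- is.finite(v) & v > 0 & v < 1
  w <- rep(NA_real_, length(TetR))
  w[ok] <- p$thetaLacI * (1 / v[ok] - 1)^(1 / p$etaLacI)
  ok <- ok & w > 0 & L >= w
  out[ok] <- p$thetaIPTG * (L[ok] / w[ok] - 1)^(1 / p$etaIPTG)
  out
}

#' Invert the toggle equilibrium relation: IPTG required for a TetR level
#'
#' Solves the steady-state equations analytically for the external IPTG
#' concentration that places an equilibrium at the requested TetR level,
#' at fixed aTc. The chain is: TetR fixes its mRNA; the mRNA balance fixes
#' the required repression level of the LacI arm; inverting the Hill
#' function gives the required effective LacI; LacI itself follows from
#' its own steady state given TetR and aTc; a final Hill inversion yields
#' IPTG. Parameter sets for which any step leaves the real positive
#' domain (the requested repression is unreachable, or the available LacI
#' is below the required effective level) give `NA` -- such candidate
#' parameter sets are discarded during estimation rather than raising an
#' error.
#'
#' @param TetR target TetR level(s), a.u. (vectorized).
#' @param theta named vector of (a subset of) the 14 free parameters, see
#'   [theta_nominal()]; or a full [toggle_params()] object.
#' @param aTc_ext fixed external aTc (ng/mL), default 25.
#' @param base fixed parameters used with a partial `theta`.
#' @return Numeric vector of IPTG (mM), `NA` where invalid.
#' @examples
#' equilibrium_input(400, theta_nominal())
#' @export
equilibrium_input <- function(TetR, theta, aTc_ext = 25,
                              base = toggle_params()) {
  stopifnot(all(TetR > 0))
  params <- if (inherits(theta, "toggle_params")) theta
            else theta_to_params(theta, base)
  iptg_at_tetr(TetR, params, aTc_ext)
}

#' Predicted equilibrium curve of a candidate parameter set
#'
#' Evaluates [equilibrium_input()] on a TetR grid, drops invalid points,
#' and normalizes both coordinates so they are comparable in the
#' estimation cost: IPTG by the maximum applied input and TetR by the
#' normalization constant carried by the measured data (by default the
#' maximum measured TetR).
#'
#' @param theta candidate parameters (named vector or [toggle_params()]).
#' @param TetR_grid grid of TetR values covering the measured range.
#' @param aTc_ext fixed external aTc (ng/mL).
#' @param norm list with `TetR` and `IPTG` normalization constants.
#' @return Tibble `(TetR, IPTG, TetR_n, IPTG_n)` of valid grid points.
#' @export
predicted_curve <- function(theta, TetR_grid, aTc_ext = 25,
                            norm = list(TetR = 1200, IPTG = 1)) {
  iptg <- equilibrium_input(TetR_grid, theta, aTc_ext)
  ok <- is.finite(iptg) & iptg <= norm$IPTG * (1 + 1e-9)
  if (!any(ok)) stop("no admissible equilibria on the TetR grid",
                     call. = FALSE)
  tibble::tibble(TetR = TetR_grid[ok], IPTG = iptg[ok],
                 TetR_n = TetR_grid[ok] / norm$TetR,
                 IPTG_n = iptg[ok] / norm$IPTG)
}

#' Bundle measured steady-state points for estimation
#'
#' @param TetR_ss,IPTG_ss measured steady-state pairs (a.u., mM).
#' @param provenance data source label (`"cbc-p"`, `"cbc-mpc"`,
#'   `"sweep"`).
#' @param norm normalization constants; defaults to the maximum measured
#'   TetR and the maximum applied input (1 mM).
#' @return Tibble of class `measured_points` with normalized columns and
#'   the normalization in `attr(, "norm")`.
#' @export
measured_points <- function(TetR_ss, IPTG_ss, provenance = "cbc-p",
                            norm = NULL) {
  stopifnot(length(TetR_ss) == length(IPTG_ss), length(TetR_ss) > 0)
  if (is.null(norm)) {
    norm <- list(TetR = max(TetR_ss), IPTG = max(max(IPTG_ss), 1))
  }
  out <- tibble::tibble(TetR_ss = TetR_ss, IPTG_ss = IPTG_ss,
                        TetR_n = TetR_ss / norm$TetR,
                        IPTG_n = IPTG_ss / norm$IPTG,
                        provenance = provenance)
  attr(out, "norm") <- norm
  class(out) <- c("measured_points", class(out))
  out
}

#' Nearest-point estimation cost
#'
#' Sum over measured steady states of the squared Euclidean distance, in
#' normalized (TetR, IPTG) coordinates, to the nearest point of the
#' predicted equilibrium curve of `theta`. Candidate parameter sets whose
#' inversion is invalid over the whole grid receive a finite penalty
#' (4 per measured point, the scale of the largest possible squared
#' distance in normalized coordinates) so the optimizer can still rank
#' them out.
#'
#' @param theta candidate parameters.
#' @param measured a [measured_points()] tibble.
#' @param TetR_grid grid for [predicted_curve()]; default 400 points over
#'   the measured TetR range.
#' @param aTc_ext fixed external aTc.
#' @return Scalar cost (dimensionless).
#' @export
estimation_cost <- function(theta, measured, TetR_grid = NULL, aTc_ext = 25) {
  norm <- attr(measured, "norm")
  if (is.null(TetR_grid)) {
    TetR_grid <- seq(max(min(measured$TetR_ss) * 0.5, 1),
                     max(measured$TetR_ss) * 1.1, length.out = 400)
  }
  curve <- tryCatch(predicted_curve(theta, TetR_grid, aTc_ext, norm),
                    error = function(e) NULL)
  if (is.null(curve) || nrow(curve) == 0) return(4 * nrow(measured))
  d2 <- outer(measured$TetR_n, curve$TetR_n, "-")^2 +
    outer(measured$IPTG_n, curve$IPTG_n, "-")^2
  sum(apply(d2, 1, min))
}

#' Estimate toggle parameters from measured equilibrium points
#'
#' Seeded genetic-algorithm minimization of [estimation_cost()] over the
#' 14 free parameters. Rates and thresholds are searched in log10 space
#' within `bounds` (default a factor of 10 around nominal); Hill
#' coefficients are searched linearly in [1, 4].
#'
#' @param measured a [measured_points()] tibble.
#' @param bounds two-row matrix (lower, upper) with columns named as
#'   [theta_nominal()]; default `0.1x`--`10x` nominal, Hill coefficients
#'   `[1, 4]`.
#' @param pop_size,generations GA budget.
#' @param seed integer seed for reproducibility.
#' @param aTc_ext fixed external aTc.
#' @param TetR_grid grid passed to [estimation_cost()].
#' @return Object of class `theta_estimate`: list with `theta` (named
#'   vector), `params` (full [toggle_params()]), `cost`, `trace` (tibble
#'   of best cost per generation), `measured`, and the call settings.
#' @export
estimate_parameters <- function(measured, bounds = NULL, pop_size = 80,
                                generations = 80, seed = 1, aTc_ext = 25,
                                TetR_grid = NULL) {
  nom <- theta_nominal()
  is_eta <- grepl("^eta", THETA_NAMES)
  if (is.null(bounds)) {
    lower <- ifelse(is_eta, 1, nom * 0.1)
    upper <- ifelse(is_eta, 4, nom * 10)
    bounds <- rbind(lower, upper)
    colnames(bounds) <- THETA_NAMES
  }
  # genome: log10 for rates/thresholds, linear for Hill coefficients
  enc <- function(v) ifelse(is_eta, v, log10(v))
  dec <- function(g) ifelse(is_eta, g, 10^g)
  lo <- enc(bounds[1, THETA_NAMES]); hi <- enc(bounds[2, THETA_NAMES])
  if (is.null(TetR_grid)) {
    TetR_grid <- seq(max(min(measured$TetR_ss) * 0.5, 1),
                     max(measured$TetR_ss) * 1.1, length.out = 400)
  }
  fn <- function(X) {
    apply(X, 1, function(g) {
      th <- stats::setNames(dec(g), THETA_NAMES)
      estimation_cost(th, measured, TetR_grid, aTc_ext)
    })
  }
  res <- ga_optimize(fn, lo, hi, pop_size = pop_size,
                     generations = generations, seed = seed,
                     mut_sd = 0.08, tol = 1e-10)
  theta <- stats::setNames(dec(res$par), THETA_NAMES)
  structure(list(theta = theta, params = theta_to_params(theta),
                 cost = res$value, trace = res$trace, measured = measured,
                 seed = seed, aTc_ext = aTc_ext),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat("<theta_estimate> cost =", format(x$cost, digits = 4),
      " (", nrow(x$measured), " points, seed ", x$seed, ")\n", sep = "")
  print(round(x$theta, 5))
  invisible(x)
}

#' Open-loop parameter sweep baseline
#'
#' Records the open-loop steady state of the plant for each fixed IPTG
#' level, visiting the levels in ascending and/or descending order with
#' the state carried over between levels (exposing hysteresis inside the
#' bistable window). All collected points lie on stable branches; the
#' sweep cannot reach unstable equilibria because there is no feedback.
#'
#' @param params a [toggle_params()] object.
#' @param IPTG_levels input levels (mM) within [0, 1].
#' @param plant `"ode"` or `"sde"`.
#' @param directions subset of `c("ascending", "descending")`.
#' @param t_settle simulated time per level (min), default 3000 -- long
#'   enough to ride out the critical slowing down at levels just beyond
#'   a fold, where the vanished equilibrium leaves a slow transit
#'   corridor.
#' @param aTc_ext fixed external aTc.
#' @param seed seed for the SDE plant.
#' @param x0 initial state; default the IPTG = 0 equilibrium.
#' @return A [measured_points()] tibble with provenance `"sweep"` and a
#'   `direction` column; steady states are 12-sample averages.
#' @export
run_sweep <- function(params, IPTG_levels, plant = c("ode", "sde"),
                      directions = c("ascending", "descending"),
                      t_settle = 3000, aTc_ext = 25, seed = NULL, x0 = NULL) {
  plant <- match.arg(plant)
  stopifnot(all(IPTG_levels >= 0), all(IPTG_levels <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    x0 <- steady_state(params, aTc_ext, 0,
                       toggle_state(mRNA_LacI = 50, mRNA_TetR = 1,
                                    LacI = 3000, TetR = 60))
  }
  rows <- list()
  for (dir in directions) {
    lv <- sort(IPTG_levels, decreasing = (dir == "descending"))
    x <- as.numeric(x0)
    for (u in lv) {
      tr <- if (plant == "ode") {
        simulate_toggle_ode(params, c(aTc_ext = aTc_ext, IPTG_ext = u),
                            x, t_end = t_settle)
      } else {
        simulate_toggle_sde(params, c(aTc_ext = aTc_ext, IPTG_ext = u),
                            x, t_end = t_settle)
      }
      n <- nrow(tr)
      tail12 <- tr[seq(max(1, n - 11), n), ]
      x <- as.numeric(tr[n, STATE_NAMES])
      rows[[length(rows) + 1]] <- data.frame(
        TetR_ss = mean(tail12$TetR), IPTG_ss = u, direction = dir)
    }
  }
  df <- do.call(rbind, rows)
  out <- measured_points(df$TetR_ss, df$IPTG_ss, provenance = "sweep")
  out$direction <- df$direction
  out
}

#' Does a fitted parameter set yield a bistable toggle?
#'
#' Runs numerical continuation on the model assembled from `theta` (with
#' nominal degradation and exchange rates) and reports whether exactly two
#' fold points are found, i.e. whether the fitted model reproduces the
#' saddle-node pair that bounds the bistable window.
#'
#' @param theta named parameter vector, [toggle_params()], or a
#'   `theta_estimate`.
#' @param aTc_ext fixed external aTc.
#' @param IPTG_bounds continuation interval (mM).
#' @return Logical flag; continuation failure gives `FALSE` with a
#'   warning.
#' @export
check_bistability <- function(theta, aTc_ext = 25, IPTG_bounds = c(0, 1)) {
  params <- if (inherits(theta, "theta_estimate")) theta$params
            else if (inherits(theta, "toggle_params")) theta
            else theta_to_params(theta)
  bd <- tryCatch(
    suppressWarnings(continue_equilibria(params, aTc_ext, IPTG_bounds)),
    error = function(e) {
      warning("continuation failed for candidate parameters: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(bd)) return(FALSE)
  nrow(attr(bd, "folds")) == 2
}
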