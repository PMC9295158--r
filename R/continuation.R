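#' Numerical continuation of toggle switch equilibria
#'
#' Traces the equilibrium curve TetR vs IPTG at fixed aTc by
#' pseudo-arclength predictor--corrector continuation, following the full
#' S-shaped curve through both saddle-node (fold) points, including the
#' unstable branch. This is the model-based reference curve that
#' control-based continuation is compared against.
#'
#' Continuation runs on the four-state biochemical subsystem with the
#' internal inducers pinned to the external concentrations (exact at
#' equilibrium; it removes the neutral exchange directions). Arclength is
#' measured in scaled coordinates (mRNAs / 50, proteins / 1000 a.u., IPTG
#' / 0.25 mM) so that predictor steps are balanced across variables.
#'
#' @param params a [toggle_params()] object.
#' @param aTc_ext fixed external aTc (ng/mL), default 25.
#' @param IPTG_bounds continuation interval for IPTG (mM), within [0, 1].
#' @param step0 initial arclength step (scaled units).
#' @param step_min,step_max adaptive step limits; the step is halved on
#'   corrector failure and grown on easy convergence.
#' @param max_points safety cap on the number of points.
#' @param guess starting state for the first equilibrium (at
#'   `IPTG_bounds[1]`); defaults to a low-TetR state.
#' @return A `toggle_bifurcation` tibble with columns `IPTG`, the four
#'   biochemical states, `stability` (`"stable"`/`"unstable"`),
#'   `eig_max_re` (leading eigenvalue real part, 1/min) and `arclength`.
#'   Fold points are in `attr(, "folds")`, a tibble `(IPTG, TetR)`.
#' @examples
#' \donttest{
#' bd <- continue_equilibria(toggle_params())
#' attr(bd, "folds")
#' }
#' @export
continue_equilibria <- function(params, aTc_ext = 25, IPTG_bounds = c(0, 1),
                                step0 = 0.01, step_min = 1e-5, step_max = 0.05,
                                max_points = 4000, guess = NULL) {
  stopifnot(IPTG_bounds[1] >= 0, IPTG_bounds[2] <= 1,
            IPTG_bounds[1] < IPTG_bounds[2])
  scale <- c(50, 50, 1000, 1000, 0.25)  # (mL, mT, LacI, TetR, IPTG)
  if (is.null(guess)) {
    roots <- equilibria_at(params, aTc_ext, IPTG_bounds[1])
    if (!length(roots)) {
      stop("no starting equilibrium found at IPTG = ", IPTG_bounds[1],
           call. = FALSE)
    }
    guess <- roots[[1]]   # lowest-TetR equilibrium
  }
  x0 <- steady_state(params, aTc_ext, IPTG_bounds[1], guess)
  z <- c(x0[1:4], IPTG_bounds[1]) / scale

  resid <- function(z) toggle_rhs4(z[1:4] * scale[1:4], aTc_ext,
                                   z[5] * scale[5], params)
  jac_aug <- function(z) {
    x <- z[1:4] * scale[1:4]; pI <- z[5] * scale[5]
    cbind(toggle_jac4(x, aTc_ext, pI, params) *
            rep(scale[1:4], each = 4),
          toggle_dfdp4(x, aTc_ext, pI, params) * scale[5])
  }
  tangent <- function(z, prev = NULL) {
    A <- jac_aug(z)                      # 4 x 5
    t <- qr.Q(qr(t(A)), complete = TRUE)[, 5]
    t <- t / sqrt(sum(t^2))
    if (!is.null(prev) && sum(t * prev) < 0) t <- -t
    if (is.null(prev) && t[5] < 0) t <- -t  # start toward increasing IPTG
    t
  }
  correct <- function(z_pred, t, max_iter = 12, tol = 1e-10) {
    z <- z_pred
    for (it in seq_len(max_iter)) {
      f <- resid(z)
      g <- c(f, sum(t * (z - z_pred)))
      if (sqrt(sum(g^2)) < tol) return(z)
      Jg <- rbind(jac_aug(z), t)
      dz <- tryCatch(solve(Jg, -g), error = function(e) NULL)
      if (is.null(dz)) return(NULL)
      z <- z + dz
      if (any(!is.finite(z))) return(NULL)
    }
    if (sqrt(sum(c(resid(z), sum(t * (z - z_pred)))^2)) < 1e-8) z else NULL
  }

  pts <- list()
  tans <- list()
  record <- function(z, s) {
    x <- z[1:4] * scale[1:4]
    ev <- eigen(toggle_jac4(x, aTc_ext, z[5] * scale[5], params),
                only.values = TRUE)$values
    list(IPTG = z[5] * scale[5], mRNA_LacI = x[1], mRNA_TetR = x[2],
         LacI = x[3], TetR = x[4], eig_max_re = max(Re(ev)), arclength = s)
  }
  s <- 0
  t_prev <- tangent(z)
  pts[[1]] <- record(z, s)
  tans[[1]] <- t_prev
  ds <- step0
  warned <- FALSE
  for (k in seq_len(max_points)) {
    t_cur <- tangent(z, t_prev)
    z_new <- NULL
    repeat {
      z_new <- correct(z + ds * t_cur, t_cur)
      ok <- !is.null(z_new) && all(z_new[1:4] > -1e-9) &&
        z_new[5] * scale[5] >= IPTG_bounds[1] - 0.02 &&
        z_new[5] * scale[5] <= IPTG_bounds[2] + 0.02
      if (ok) break
      ds <- ds / 2
      if (ds < step_min) break
    }
    if (is.null(z_new) || ds < step_min) {
      warning("continuation stalled at arclength ", format(s),
              "; returning partial diagram", call. = FALSE)
      warned <- TRUE
      break
    }
    s <- s + ds
    z <- z_new
    t_prev <- t_cur
    pts[[length(pts) + 1]] <- record(z, s)
    tans[[length(tans) + 1]] <- t_cur
    ds <- min(ds * 1.3, step_max)
    # stop once the curve leaves the window heading outward
    p_now <- z[5] * scale[5]
    if ((p_now >= IPTG_bounds[2] && t_cur[5] > 0) ||
        (p_now <= IPTG_bounds[1] && t_cur[5] < 0)) break
  }
  bd <- tibble::as_tibble(do.call(rbind, lapply(pts, function(q)
    as.data.frame(q))))
  bd$stability <- ifelse(bd$eig_max_re < 0, "stable", "unstable")
  marginal <- abs(bd$eig_max_re) <= 1e-9
  if (any(marginal)) bd$stability[marginal] <- "marginal"
  bd <- bd[, c("IPTG", "mRNA_LacI", "mRNA_TetR", "LacI", "TetR",
               "stability", "eig_max_re", "arclength")]
  class(bd) <- c("toggle_bifurcation", class(bd))
  attr(bd, "tangents") <- do.call(rbind, tans)
  attr(bd, "scale") <- scale
  attr(bd, "aTc_ext") <- aTc_ext
  attr(bd, "params") <- params
  attr(bd, "partial") <- warned
  attr(bd, "folds") <- detect_folds(bd)
  bd
}

#' Locate saddle-node (fold) points on a bifurcation diagram
#'
#' Folds are detected where the continuation tangent's IPTG component
#' changes sign between consecutive points. When the diagram carries its
#' model parameters (as diagrams from [continue_equilibria()] do), each
#' fold is refined by bisection on the sign of dIPTG/dTetR of the analytic
#' steady-state inverse (the curve IPTG(TetR) is single valued, so a fold
#' is an interior extremum of it) until the fold IPTG moves by less than
#' `tol`. Otherwise the vertex of a parabola through the bracketing points
#' is used.
#'
#' @param diagram a `toggle_bifurcation` from [continue_equilibria()], or
#'   any tibble with `IPTG` and `TetR` columns ordered along the curve (in
#'   that case the secant direction replaces the stored tangent).
#' @param tol bisection tolerance on IPTG (mM).
#' @return Tibble with columns `IPTG`, `TetR`, one row per fold, ordered
#'   along the curve (possibly zero rows).
#' @export
detect_folds <- function(diagram, tol = 1e-5) {
  if (nrow(diagram) < 3) return(tibble::tibble(IPTG = numeric(0),
                                               TetR = numeric(0)))
  tans <- attr(diagram, "tangents")
  dirs <- if (!is.null(tans)) tans[, 5] else c(diff(diagram$IPTG), NA)
  dirs <- dirs[seq_len(nrow(diagram) - 1)]
  nz <- which(abs(dirs) > 0)
  flips <- nz[which(dirs[nz[-length(nz)]] * dirs[nz[-1]] < 0)]
  if (!length(flips)) return(tibble::tibble(IPTG = numeric(0),
                                            TetR = numeric(0)))
  params <- attr(diagram, "params")
  aTc <- attr(diagram, "aTc_ext")
  out <- lapply(flips, function(i) {
    idx <- max(i - 1, 1):min(i + 2, nrow(diagram))
    seg <- diagram[idx, ]
    refine_fold(seg, tol, params, aTc)
  })
  tibble::as_tibble(do.call(rbind, out))
}

# Refine one fold from curve points bracketing it. With model parameters,
# bisection on the central-difference slope of the analytic inverse
# IPTG(TetR); otherwise the vertex of a least-squares parabola.
refine_fold <- function(seg, tol, params = NULL, aTc = NULL) {
  x <- seg$TetR; y <- seg$IPTG
  if (!is.null(params)) {
    iv <- function(Tt) iptg_at_tetr(Tt, params, aTc)
    slope <- function(Tt) {
      h <- max(1e-4, 1e-7 * abs(Tt))
      (iv(Tt + h) - iv(Tt - h)) / (2 * h)
    }
    lo <- min(x); hi <- max(x)
    slo <- slope(lo); shi <- slope(hi)
    if (is.finite(slo) && is.finite(shi) && slo * shi < 0) {
      repeat {
        mid <- (lo + hi) / 2
        sm <- slope(mid)
        if (!is.finite(sm)) break
        if (sm * slo < 0) hi <- mid else { lo <- mid; slo <- sm }
        if (abs(iv(hi) - iv(lo)) < tol || hi - lo < 1e-9 * max(1, hi)) break
      }
      Tv <- (lo + hi) / 2
      Iv <- iv(Tv)
      if (is.finite(Iv)) {
        return(data.frame(IPTG = unname(Iv), TetR = unname(Tv)))
      }
    }
  }
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  Tv <- -co[2] / (2 * co[3])
  Iv <- co[1] + co[2] * Tv + co[3] * Tv^2
  data.frame(IPTG = unname(Iv), TetR = unname(Tv))
}

#' Classify the stability of an equilibrium point
#'
#' Stable iff every eigenvalue of the open-loop Jacobian (four-state
#' biochemical subsystem, inducers at their equilibrium values) has
#' negative real part. Eigenvalues within 1e-9 of the imaginary axis are
#' flagged `"marginal"`.
#'
#' @param state equilibrium state (named 6-vector or the four biochemical
#'   components).
#' @param aTc_ext,IPTG_ext external inducers at the equilibrium.
#' @param params a [toggle_params()] object.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
classify_stability <- function(state, aTc_ext, IPTG_ext, params) {
  ev <- eigen(toggle_jac4(as.numeric(state)[1:4], aTc_ext, IPTG_ext, params),
              only.values = TRUE)$values
  stability_from_eigen(max(Re(ev)))
}

stability_from_eigen <- function(max_re, tol = 1e-9) {
  if (abs(max_re) <= tol) "marginal" else if (max_re < 0) "stable"
  else "unstable"
}

# TetR values of all diagram branches crossing a given IPTG: segmentwise
# linear interpolation along the ordered curve, then (when the diagram
# carries its parameters) a Newton polish of each crossing so the value
# is an equilibrium at exactly that IPTG rather than a chord point.
branches_at <- function(diagram, IPTG) {
  x <- diagram$IPTG; y <- diagram$TetR
  params <- attr(diagram, "params")
  aTc <- attr(diagram, "aTc_ext")
  hits <- numeric(0)
  for (i in seq_len(length(x) - 1)) {
    if ((x[i] - IPTG) * (x[i + 1] - IPTG) <= 0 && x[i] != x[i + 1]) {
      w <- (IPTG - x[i]) / (x[i + 1] - x[i])
      Tt <- y[i] + w * (y[i + 1] - y[i])
      if (!is.null(params)) {
        g <- (1 - w) * unlist(diagram[i, c("mRNA_LacI", "mRNA_TetR",
                                           "LacI", "TetR")]) +
          w * unlist(diagram[i + 1, c("mRNA_LacI", "mRNA_TetR",
                                      "LacI", "TetR")])
        Tt <- tryCatch(
          steady_state(params, aTc, IPTG, c(g, aTc, IPTG))[["TetR"]],
          error = function(e) Tt)
      }
      hits <- c(hits, Tt)
    }
  }
  # collapse duplicates from points landing exactly on the grid value
  if (length(hits) > 1) {
    hits <- sort(hits)
    keep <- c(TRUE, diff(hits) > 1e-6 * pmax(1, hits[-1]))
    hits <- hits[keep]
  }
  hits
}

#' @export
print.toggle_bifurcation <- function(x, ...) {
  folds <- attr(x, "folds")
  cat("<toggle_bifurcation> ", nrow(x), " equilibrium points, ",
      nrow(folds), " fold(s)\n", sep = "")
  if (nrow(folds)) {
    cat("folds (IPTG mM, TetR a.u.):\n")
    print(as.data.frame(folds), row.names = FALSE)
  }
  NextMethod()
}
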