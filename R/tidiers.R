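# broom-style tidiers for the fitted/derived objects.

#' Tidy a bifurcation diagram
#'
#' @param x a `toggle_bifurcation`.
#' @param ... unused.
#' @return A plain tibble of equilibrium points.
#' @export
tidy.toggle_bifurcation <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("IPTG", "mRNA_LacI", "mRNA_TetR", "LacI",
                                 "TetR", "stability", "eig_max_re",
                                 "arclength")])
}

#' @rdname tidy.toggle_bifurcation
#' @export
glance.toggle_bifurcation <- function(x, ...) {
  folds <- attr(x, "folds")
  tibble::tibble(n_points = nrow(x),
                 n_folds = nrow(folds),
                 bistable = nrow(folds) == 2,
                 IPTG_fold_lo = if (nrow(folds)) min(folds$IPTG) else NA_real_,
                 IPTG_fold_hi = if (nrow(folds)) max(folds$IPTG) else NA_real_,
                 aTc_ext = attr(x, "aTc_ext"))
}

#' Tidy a control-based continuation result
#'
#' @param x a `cbc_result`.
#' @param ... unused.
#' @return Collected points as a plain tibble.
#' @export
tidy.cbc_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.cbc_result
#' @export
glance.cbc_result <- function(x, ...) {
  tibble::tibble(n_points = nrow(x),
                 n_converged = sum(x$converged),
                 total_hours = attr(x, "total_hours"),
                 controller = class(attr(x, "controller"))[1],
                 plant = attr(x, "config")$plant,
                 IPTG_min = min(x$IPTG_ss), IPTG_max = max(x$IPTG_ss))
}

#' Tidy a parameter estimate
#'
#' @param x a `theta_estimate`.
#' @param ... unused.
#' @return Tibble with `parameter`, `estimate`, `nominal` and the
#'   relative deviation from nominal.
#' @export
tidy.theta_estimate <- function(x, ...) {
  nom <- theta_nominal()[names(x$theta)]
  tibble::tibble(parameter = names(x$theta),
                 estimate = unname(x$theta),
                 nominal = unname(nom),
                 rel_deviation = unname(x$theta / nom - 1))
}

#' @rdname tidy.theta_estimate
#' @export
glance.theta_estimate <- function(x, ...) {
  tibble::tibble(cost = x$cost,
                 n_points = nrow(x$measured),
                 seed = x$seed,
                 generations = max(x$trace$generation))
}

#' Tidy an identified LTI model
#'
#' @param x an `lti_model`.
#' @param ... unused.
#' @return Long tibble of matrix entries (discrete-time innovation form).
#' @export
tidy.lti_model <- function(x, ...) {
  one <- function(M, nm) {
    idx <- expand.grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
    tibble::tibble(matrix = nm, row = idx$row, col = idx$col,
                   value = M[cbind(idx$row, idx$col)])
  }
  dplyr::bind_rows(one(x$Ad, "Ad"), one(x$Bd, "Bd"),
                   one(x$Cd, "Cd"), one(x$Kd, "Kd"))
}

#' @rdname tidy.lti_model
#' @export
glance.lti_model <- function(x, ...) {
  tibble::tibble(order = x$order, Ts = x$Ts,
                 fit_LacI = if (!is.null(x$fit)) x$fit[["LacI"]] else NA_real_,
                 fit_TetR = if (!is.null(x$fit)) x$fit[["TetR"]] else NA_real_,
                 continuous = !is.null(x$A))
}
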