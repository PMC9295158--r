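# ggplot2 views of the main result types.

#' Plot a bifurcation diagram
#'
#' TetR against IPTG with the unstable branch dashed and the saddle-node
#' (fold) points marked.
#'
#' @param object a `toggle_bifurcation`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.toggle_bifurcation <- function(object, ...) {
  folds <- attr(object, "folds")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$IPTG, y = .data$TetR)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$stability,
                                    group = 1)) +
    ggplot2::geom_point(data = folds, shape = 8, size = 3,
                        colour = "firebrick") +
    ggplot2::scale_linetype_manual(
      values = c(stable = "solid", unstable = "dashed",
                 marginal = "dotted")) +
    ggplot2::labs(x = "IPTG (mM)", y = "TetR (a.u.)",
                  linetype = NULL,
                  title = "Toggle switch equilibrium curve",
                  subtitle = "* saddle-node (fold) points") +
    ggplot2::theme_minimal()
}

#' Plot collected CBC points over the reference diagram
#'
#' @param object a `cbc_result`.
#' @param diagram optional `toggle_bifurcation` to underlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cbc_result <- function(object, diagram = NULL, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$IPTG_ss,
                                            y = .data$TetR_ss))
  if (!is.null(diagram)) {
    g <- g + ggplot2::geom_path(
      data = diagram,
      ggplot2::aes(x = .data$IPTG, y = .data$TetR,
                   linetype = .data$stability, group = 1),
      colour = "grey50")
  }
  g +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged),
                        colour = "steelblue", size = 2) +
    ggplot2::scale_linetype_manual(
      values = c(stable = "solid", unstable = "dashed",
                 marginal = "dotted")) +
    ggplot2::labs(x = "IPTG (mM)", y = "TetR (a.u.)",
                  title = "Equilibria collected by control-based continuation") +
    ggplot2::theme_minimal()
}

#' Plot a simulated toggle switch trajectory
#'
#' @param object a `toggle_trajectory`.
#' @param vars state columns to show.
#' @param ... unused.
#' @return A ggplot object, one facet per variable.
#' @export
autoplot.toggle_trajectory <- function(object,
                                       vars = c("LacI", "TetR", "IPTG_in"),
                                       ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_min", vars)],
    -"time_min", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min / 60,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost trace of a parameter estimate
#'
#' @param object a `theta_estimate`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.theta_estimate <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$generation,
                                             y = .data$best)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best cost",
                  title = "Genetic-algorithm cost trace") +
    ggplot2::theme_minimal()
}
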