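# Configuration loading and result serialization: YAML run configs,
# CSV/JSON exports with a file manifest, round-trip safe.

run_config_defaults <- function() {
  list(
    params = list(),                 # toggle_params() overrides
    plant = "ode",
    controller = "p",                # "p" or "mpc"
    p = list(Kp = 0.0016, input_bounds = c(0, 1)),
    mpc = list(N = 12, gamma = 0.3, input_bounds = c(0, 1), u_init = 1,
               ga_pop = 40, ga_gens = 30, order = 4),
    cbc = list(ref_start = 1800, ref_end = 0, n_points = 30, sampling = 5,
               dwell_mode = "fixed", dwell = 595, min_dwell = 180,
               window = 12, slope_tol_error = 0.5, slope_tol_control = 1e-4,
               noise_slope_factor = 5, avg_window = 12, sde_dt = 0.1,
               aTc_ext = 25),
    estimation = list(pop_size = 80, generations = 80),
    seed = 1,
    out_dir = "cbc-out"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills defaults (nominal parameters,
#' aTc = 25 ng/mL, 5-min sampling, the default controller gains) and
#' rejects unknown keys so typos fail loudly.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return Named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- run_config_defaults()
  check_keys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0(prefix, bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(u)) {
      if (is.list(d[[nm]]) && is.list(u[[nm]]) && nm != "params") {
        check_keys(u[[nm]], d[[nm]], paste0(prefix, nm, "."))
      }
    }
  }
  check_keys(user, defs)
  cfg <- utils::modifyList(defs, user)
  if (!cfg$controller %in% c("p", "mpc")) {
    stop("config key controller must be \"p\" or \"mpc\"", call. = FALSE)
  }
  if (!cfg$plant %in% c("ode", "sde")) {
    stop("config key plant must be \"ode\" or \"sde\"", call. = FALSE)
  }
  if (cfg$p$Kp <= 0) stop("config key p.Kp must be positive", call. = FALSE)
  if (cfg$mpc$gamma <= 0 || cfg$mpc$gamma > 1) {
    stop("config key mpc.gamma must be in (0, 1]", call. = FALSE)
  }
  do.call(toggle_params, cfg$params)   # validates parameter overrides
  structure(cfg, class = "run_config")
}

#' Write analysis results to a directory
#'
#' Serializes a result object (`cbc_result`, `toggle_bifurcation`,
#' `theta_estimate`, `toggle_trajectory` or `lti_model`) under
#' deterministic file names, together with a JSON summary carrying the
#' seed and a hash of the configuration, and returns the manifest of
#' files written.
#'
#' @param result the object to write.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; defaults to the result class.
#' @return Character vector of files written (invisibly).
#' @export
write_results <- function(result, dir, stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  UseMethod("write_results")
}

#' @export
write_results.cbc_result <- function(result, dir, stem = "cbc") {
  pts_file <- file.path(dir, paste0(stem, "_points.csv"))
  utils::write.csv(as.data.frame(result), pts_file, row.names = FALSE)
  tr_file <- file.path(dir, paste0(stem, "_trajectory.csv"))
  utils::write.csv(as.data.frame(attr(result, "trajectory")), tr_file,
                   row.names = FALSE)
  cfg <- attr(result, "config")
  sm_file <- file.path(dir, paste0(stem, "_summary.json"))
  jsonlite::write_json(
    list(total_simulated_hours = attr(result, "total_hours"),
         n_points = nrow(result),
         n_converged = sum(result$converged),
         controller = class(attr(result, "controller"))[1],
         plant = cfg$plant,
         seed = cfg$seed,
         config_hash = config_hash(cfg)),
    sm_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest(dir, stem, c(pts_file, tr_file, sm_file))
}

#' @export
write_results.toggle_bifurcation <- function(result, dir, stem = "diagram") {
  dg_file <- file.path(dir, paste0(stem, "_curve.csv"))
  utils::write.csv(
    as.data.frame(result[, c("IPTG", "mRNA_LacI", "mRNA_TetR", "LacI",
                             "TetR", "stability")]),
    dg_file, row.names = FALSE)
  fd_file <- file.path(dir, paste0(stem, "_folds.json"))
  folds <- attr(result, "folds")
  jsonlite::write_json(
    list(n_folds = nrow(folds),
         folds = as.data.frame(folds),
         aTc_ext = attr(result, "aTc_ext")),
    fd_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest(dir, stem, c(dg_file, fd_file))
}

#' @export
write_results.theta_estimate <- function(result, dir, stem = "estimate") {
  th_file <- file.path(dir, paste0(stem, "_theta.csv"))
  utils::write.csv(
    data.frame(parameter = names(result$theta), value = result$theta,
               nominal = theta_nominal()[names(result$theta)]),
    th_file, row.names = FALSE)
  tr_file <- file.path(dir, paste0(stem, "_trace.csv"))
  utils::write.csv(as.data.frame(result$trace), tr_file, row.names = FALSE)
  sm_file <- file.path(dir, paste0(stem, "_summary.json"))
  jsonlite::write_json(
    list(cost = result$cost, seed = result$seed,
         n_points = nrow(result$measured)),
    sm_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest(dir, stem, c(th_file, tr_file, sm_file))
}

#' @export
write_results.toggle_trajectory <- function(result, dir, stem = "trajectory") {
  f <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(as.data.frame(result), f, row.names = FALSE)
  manifest(dir, stem, f)
}

#' @export
write_results.lti_model <- function(result, dir, stem = "lti_model") {
  f <- file.path(dir, paste0(stem, ".json"))
  write_lti_json(result, f)
  manifest(dir, stem, f)
}

manifest <- function(dir, stem, files) {
  mf <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(list(files = basename(c(files, mf))), mf,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(c(files, mf))
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))),
             collapse = "\n")
  # small rolling hash; stable across sessions, no extra dependency
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 1e9
}

#' Serialize / read an identified LTI model as JSON
#'
#' Matrices are stored row-major with explicit dimensions.
#'
#' @param model an `lti_model`.
#' @param path JSON file path.
#' @return `write_lti_json` returns `path` invisibly; `read_lti_json`
#'   returns the reconstructed `lti_model`.
#' @export
write_lti_json <- function(model, path) {
  mat <- function(M) list(dim = dim(M), data = as.numeric(t(M)))
  obj <- list(order = model$order, Ts = model$Ts,
              n_lags = model$n_lags,
              y0 = model$y0, u0 = model$u0, cd = model$cd,
              Ad = mat(model$Ad), Bd = mat(model$Bd),
              Cd = mat(model$Cd), Kd = mat(model$Kd),
              fit = model$fit)
  if (!is.null(model$A)) {
    obj <- c(obj, list(A = mat(model$A), B = mat(model$B),
                       C = mat(model$C), K = mat(model$K)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lti_json
#' @export
read_lti_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unmat <- function(m) matrix(m$data, m$dim[1], m$dim[2], byrow = TRUE)
  model <- structure(
    list(Ad = unmat(obj$Ad), Bd = unmat(obj$Bd), Cd = unmat(obj$Cd),
         Kd = unmat(obj$Kd), cd = obj$cd, Ts = obj$Ts, y0 = obj$y0,
         u0 = obj$u0, order = obj$order, n_lags = obj$n_lags,
         A = if (!is.null(obj$A)) unmat(obj$A),
         B = if (!is.null(obj$B)) unmat(obj$B),
         C = if (!is.null(obj$C)) unmat(obj$C),
         D = matrix(0, nrow(unmat(obj$Cd)), nrow(unmat(obj$Cd))),
         K = if (!is.null(obj$K)) unmat(obj$K),
         fit = obj$fit),
    class = "lti_model")
  model
}
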