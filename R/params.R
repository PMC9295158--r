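#' Kinetic parameters of the inducible toggle switch
#'
#' Returns the full parameter set of the Hill-type toggle switch model
#' (two mutually repressing genes, LacI and TetR, with the inducers IPTG
#' and aTc antagonizing repression, plus inducer membrane-exchange rates).
#' Defaults are the nominal calibration of the inducible LacI/TetR circuit;
#' any subset can be overridden by name.
#'
#' Units: mRNA and proteins in arbitrary units (a.u.), aTc in ng/mL,
#' IPTG in mM, all rates per minute. Hill thresholds are in the units of
#' their ligand; Hill coefficients are dimensionless.
#'
#' @param ... named overrides of individual parameters, e.g. `kTm = 1.0`.
#' @return A named list of class `toggle_params` with 22 strictly positive
#'   entries: transcription leakage (`kLm0`, `kTm0`) and rates (`kLm`,
#'   `kTm`), translation rates (`kLp`, `kTp`), mRNA and protein degradation
#'   rates (`gLm`, `gTm`, `gLp`, `gTp`), Hill thresholds/coefficients
#'   (`thetaLacI`, `etaLacI`, `thetaIPTG`, `etaIPTG`, `thetaTetR`,
#'   `etaTetR`, `thetaaTc`, `etaaTc`) and membrane exchange rates
#'   (`kIPTGin`, `kIPTGout`, `kaTcin`, `kaTcout`).
#' @examples
#' p <- toggle_params()
#' p$kTm
#' toggle_params(etaLacI = 2.5)$etaLacI
#' @export
toggle_params <- function(...) {
  p <- list(
    kLm0 = 3.20e-2, kTm0 = 1.19e-1,
    kLm  = 8.30,    kTm  = 2.06,
    kLp  = 9.726e-1, kTp = 1.170,
    gLm  = 1.386e-1, gTm = 1.386e-1,
    gLp  = 1.65e-2,  gTp = 1.65e-2,
    thetaLacI = 31.94,   etaLacI = 2.00,
    thetaIPTG = 9.06e-2, etaIPTG = 2.00,
    thetaTetR = 30.00,   etaTetR = 2.00,
    thetaaTc  = 11.65,   etaaTc  = 2.00,
    kIPTGin = 2.75e-2, kIPTGout = 1.11e-1,
    kaTcin  = 1.62e-1, kaTcout  = 2.00e-2
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown toggle parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all toggle parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(p, class = "toggle_params")
}

#' @export
print.toggle_params <- function(x, ...) {
  cat("<toggle_params> (", length(x), " kinetic constants)\n", sep = "")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Decreasing Hill function
#'
#' `h(x, theta, eta) = 1 / (1 + (x / theta)^eta)`: the fraction of
#' unrepressed promoter activity at repressor (or ligand) level `x`, with
#' half-occupancy threshold `theta` and cooperativity `eta`. Strictly
#' decreasing in `x`, equal to 1 at `x = 0` and 1/2 at `x = theta`.
#'
#' @param x nonnegative ligand/repressor level (vectorized).
#' @param theta positive threshold, in the units of `x`.
#' @param eta positive Hill coefficient.
#' @return Values in (0, 1].
#' @examples
#' hill(0, 30, 2)    # 1: no repression
#' hill(30, 30, 2)   # 0.5: half occupancy at the threshold
#' @export
hill <- function(x, theta, eta) {
  if (any(x < 0) || any(theta <= 0) || any(eta <= 0)) {
    stop("hill() requires x >= 0, theta > 0, eta > 0", call. = FALSE)
  }
  1 / (1 + (x / theta)^eta)
}

# derivative of hill() w.r.t. x; finite at x = 0 for eta >= 1
hill_prime <- function(x, theta, eta) {
  r <- (x / theta)^eta
  -(eta / theta) * (x / theta)^(eta - 1) / (1 + r)^2
}

# Canonical state ordering used everywhere in the package.
STATE_NAMES <- c("mRNA_LacI", "mRNA_TetR", "LacI", "TetR", "aTc_in", "IPTG_in")

#' Construct a toggle switch state vector
#'
#' @param mRNA_LacI,mRNA_TetR mRNA abundances (a.u.).
#' @param LacI,TetR protein abundances (a.u.).
#' @param aTc_in intracellular aTc (ng/mL).
#' @param IPTG_in intracellular IPTG (mM).
#' @return Named numeric vector in the canonical ordering
#'   `(mRNA_LacI, mRNA_TetR, LacI, TetR, aTc_in, IPTG_in)`.
#' @export
toggle_state <- function(mRNA_LacI = 0, mRNA_TetR = 0, LacI = 0, TetR = 0,
                         aTc_in = 0, IPTG_in = 0) {
  x <- c(mRNA_LacI = mRNA_LacI, mRNA_TetR = mRNA_TetR, LacI = LacI,
         TetR = TetR, aTc_in = aTc_in, IPTG_in = IPTG_in)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("all state components must be finite and nonnegative", call. = FALSE)
  }
  x
}
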