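#' Kinetic parameters of the TF-A autoregulation model
#'
#' Bundles the four rate constants of the transcription-factor activator
#' (TF-A) positive-feedback model. The TF-A monomer activates its own
#' transcription through homodimer binding to responsive elements, giving a
#' Hill-type production term of order 2, and is degraded linearly.
#'
#' @param k_f maximal transcription rate (1/min).
#' @param K_d dissociation constant of the dimer from its responsive
#'   element; enters the denominator of the Hill term un-squared.
#' @param k_d first-order degradation rate of the monomer (1/min).
#' @param R_bas basal synthesis rate (nM/min).
#'
#' @return An object of class `tfa_params`.
#' @examples
#' tfa_params(6, 10, 1, 0.4)
#' @export
tfa_params <- function(k_f, K_d, k_d, R_bas) {
  vals <- c(k_f = k_f, K_d = K_d, k_d = k_d, R_bas = R_bas)
  if (!all(is.finite(vals))) stop("all TF-A parameters must be finite")
  if (any(vals <= 0)) {
    stop("all TF-A parameters must be strictly positive, got: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  structure(as.list(vals), class = "tfa_params")
}

#' @export
print.tfa_params <- function(x, ...) {
  cat("TF-A model parameters\n")
  cat(sprintf("  k_f   = %g 1/min   (maximal transcription rate)\n", x$k_f))
  cat(sprintf("  K_d   = %g         (dissociation constant)\n", x$K_d))
  cat(sprintf("  k_d   = %g 1/min   (degradation rate)\n", x$k_d))
  cat(sprintf("  R_bas = %g nM/min  (basal synthesis rate)\n", x$R_bas))
  invisible(x)
}

as_tfa_params <- function(x) {
  if (inherits(x, "tfa_params")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    return(tfa_params(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  stop("cannot interpret 'params' as TF-A model parameters")
}

#' Drift (deterministic rate of change) of the TF-A concentration
#'
#' Evaluates f(x) = k_f x^2 / (x^2 + K_d) - k_d x + R_bas, the right-hand
#' side of the deterministic TF-A model. Negative arguments are permitted
#' because jump trajectories can overshoot into the exterior; the formula is
#' evaluated as written.
#'
#' @param x numeric vector of concentrations (nM).
#' @param params a [tfa_params()] object.
#' @return numeric vector of rates (nM/min).
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' tfa_drift(0, p)    # = R_bas
#' tfa_drift(0.62685, p)  # ~ 0: the low stable state
#' @export
tfa_drift <- function(x, params) {
  params <- as_tfa_params(params)
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  params$k_f * x^2 / (x^2 + params$K_d) - params$k_d * x + params$R_bas
}

#' Potential energy of the TF-A model
#'
#' The potential V with V'(x) = -f(x), normalised so that V(0) = 0.
#' The drift then reads dx/dt = -V'(x); the bistable regime corresponds to a
#' double-well V. Computed by adaptive quadrature of -f from 0, which keeps
#' the code generic in the parameters.
#'
#' @inheritParams tfa_drift
#' @return numeric vector of potential values (arbitrary units).
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' tfa_potential(c(0.62685, 1.48971, 4.28343), p)
#' @export
tfa_potential <- function(x, params) {
  params <- as_tfa_params(params)
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    -stats::integrate(tfa_drift, 0, xi, params = params,
                      rel.tol = 1e-10, abs.tol = 1e-12,
                      subdivisions = 500L)$value
  }, numeric(1))
}

# central-difference derivative of the drift
drift_prime <- function(x, params, h = 1e-6) {
  (tfa_drift(x + h, params) - tfa_drift(x - h, params)) / (2 * h)
}

#' Locate the equilibria of the TF-A model
#'
#' Finds all roots of the drift on `[0, search_max]` by sign-change
#' bracketing on a fine grid followed by bisection, and classifies the model
#' as bistable when three roots are present. The cubic structure of
#' x^2 f(x) admits at most three positive roots; a root count of exactly two
#' indicates a tangency (saddle-node) at the resolution of the tolerance and
#' raises an error.
#'
#' @param params a [tfa_params()] object.
#' @param search_max upper end of the root search interval (nM); the default
#'   10 covers all parameter sets of interest.
#' @return An object of class `tfa_equilibria`: a list with `roots` (sorted
#'   ascending), `stability` (character vector), `bistable` flag, and for the
#'   bistable case the named states `x_minus`, `x_u`, `x_plus`.
#' @examples
#' eq <- find_equilibria(tfa_params(6, 10, 1, 0.4))
#' eq$roots   # 0.62685 1.48971 4.28343
#' @export
find_equilibria <- function(params, search_max = 10) {
  params <- as_tfa_params(params)
  if (!is.numeric(search_max) || search_max <= 0) {
    stop("'search_max' must be positive")
  }
  grid <- seq(0, search_max, length.out = 4001L)
  fv <- tfa_drift(grid, params)
  roots <- numeric(0)
  # exact zeros on the grid
  hit <- which(fv == 0)
  roots <- c(roots, grid[hit])
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    lo <- grid[i]; hi <- grid[i + 1L]
    # bisection to bracket width 1e-12, report midpoint
    flo <- tfa_drift(lo, params)
    while (hi - lo > 1e-12) {
      mid <- (lo + hi) / 2
      fm <- tfa_drift(mid, params)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0) stop("no equilibria found on [0, search_max]")
  if (length(roots) == 2) {
    stop("two roots found: tangency (saddle-node) at tolerance; ",
         "perturb parameters")
  }
  if (length(roots) > 3) stop("more than three roots: inconsistent model")
  stab <- ifelse(drift_prime(roots, params) < 0, "stable", "unstable")
  out <- list(roots = roots, stability = stab,
              bistable = length(roots) == 3L, params = params)
  if (out$bistable) {
    out$x_minus <- roots[1]; out$x_u <- roots[2]; out$x_plus <- roots[3]
  }
  class(out) <- "tfa_equilibria"
  out
}

#' @export
print.tfa_equilibria <- function(x, ...) {
  cat(if (x$bistable) "Bistable" else "Monostable",
      "TF-A system with equilibria:\n")
  fp <- drift_prime(x$roots, x$params)
  for (i in seq_along(x$roots)) {
    cat(sprintf("  x = %.5f   f'(x) = %+.4f   %s\n",
                x$roots[i], fp[i], x$stability[i]))
  }
  invisible(x)
}

#' Stability of an equilibrium point
#'
#' Classifies an equilibrium of the TF-A drift as stable or unstable from
#' the sign of the central-difference derivative f'(x).
#'
#' @param params a [tfa_params()] object.
#' @param x a single equilibrium concentration (|f(x)| must be below 1e-6).
#' @return `"stable"` if f'(x) < 0, else `"unstable"`.
#' @export
classify_stability <- function(params, x) {
  params <- as_tfa_params(params)
  if (length(x) != 1L) stop("'x' must be a single value")
  if (abs(tfa_drift(x, params)) > 1e-6) {
    stop("x is not an equilibrium: |f(x)| > 1e-6")
  }
  if (drift_prime(x, params) < 0) "stable" else "unstable"
}
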