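#' Noise specification: Gaussian and alpha-stable Levy intensities
#'
#' The stochastic TF-A model perturbs the basal synthesis rate with two
#' independent additive noises: a Brownian motion of intensity `sigma` and a
#' symmetric alpha-stable pure-jump Levy motion of intensity `epsilon` with
#' stability index `alpha`. The relative contribution factor (RCF)
#' lambda = epsilon / sigma summarises their balance; under the constrained
#' budget sigma + epsilon = 1 the pair is determined by lambda alone.
#'
#' @param sigma Gaussian noise intensity, >= 0.
#' @param epsilon Levy noise intensity, >= 0.
#' @param alpha stability index in (0, 2]; `alpha = 2` is Gaussian (no
#'   jumps). Small alpha means rare large jumps; alpha near 2 means frequent
#'   small jumps.
#' @param constrained if `TRUE`, require sigma + epsilon = 1 with
#'   sigma in (0, 1] (the fixed-total-intensity convention used in
#'   RCF sweeps).
#' @return An object of class `noise_spec` with fields `sigma`, `epsilon`,
#'   `alpha` and the derived `lambda_rcf` (`Inf` when `sigma = 0`).
#' @examples
#' noise_spec(0.5, 0.5, alpha = 1.5)
#' noise_spec(0, 1, alpha = 0.5)        # pure jump noise
#' @export
noise_spec <- function(sigma, epsilon, alpha, constrained = FALSE) {
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.finite(epsilon) || epsilon < 0) stop("'epsilon' must be >= 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2) {
    stop("'alpha' must lie in (0, 2]")
  }
  if (constrained) {
    if (abs(sigma + epsilon - 1) > 1e-10) {
      stop("sigma + epsilon must equal 1 in constrained mode")
    }
    if (sigma <= 0) stop("constrained mode requires sigma in (0, 1]")
  }
  structure(list(sigma = sigma, epsilon = epsilon, alpha = alpha,
                 lambda_rcf = if (sigma > 0) epsilon / sigma else Inf),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "noise_spec: sigma = %g, epsilon = %g, alpha = %g (RCF lambda = %g)\n",
    x$sigma, x$epsilon, x$alpha, x$lambda_rcf))
  invisible(x)
}

#' Noise intensities from the relative contribution factor
#'
#' Under the fixed total intensity sigma + epsilon = 1, the RCF
#' lambda = epsilon / sigma determines both intensities:
#' sigma = 1 / (1 + lambda), epsilon = lambda / (1 + lambda).
#'
#' @param lambda_rcf nonnegative finite ratio of Levy to Gaussian intensity.
#' @return A named numeric vector `c(sigma = , epsilon = )`.
#' @examples
#' intensities_from_rcf(1)   # equal split
#' intensities_from_rcf(3)   # (0.25, 0.75)
#' @export
intensities_from_rcf <- function(lambda_rcf) {
  if (!is.numeric(lambda_rcf) || length(lambda_rcf) != 1L ||
      !is.finite(lambda_rcf) || lambda_rcf < 0) {
    stop("'lambda_rcf' must be a single finite value >= 0")
  }
  c(sigma = 1 / (1 + lambda_rcf), epsilon = lambda_rcf / (1 + lambda_rcf))
}

#' Constrained noise specification from the RCF
#'
#' Convenience wrapper: builds a constrained [noise_spec()] (with
#' sigma + epsilon = 1) from the relative contribution factor.
#'
#' @inheritParams intensities_from_rcf
#' @param alpha stability index in (0, 2].
#' @return A `noise_spec` object.
#' @export
rcf_setting <- function(lambda_rcf, alpha) {
  se <- intensities_from_rcf(lambda_rcf)
  noise_spec(se[["sigma"]], se[["epsilon"]], alpha, constrained = TRUE)
}
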