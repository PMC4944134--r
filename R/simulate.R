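#' Simulate one trajectory of the stochastic TF-A model
#'
#' Euler-Maruyama integration of the jump-diffusion
#' dX = f(X) dt + sigma dB_t + epsilon dL_t^alpha, where f is the TF-A
#' drift, B a standard Brownian motion and L a standard symmetric
#' alpha-stable Levy motion. The discrete update is
#' X_{n+1} = X_n + f(X_n) dt + sigma sqrt(dt) G_n + epsilon dt^{1/alpha} S_n
#' with G_n standard Gaussian and S_n standard symmetric alpha-stable; the
#' dt^{1/alpha} scaling follows from the self-similarity of the stable
#' motion. Both noise streams are drawn from the current RNG stream in a
#' fixed order (all Gaussian increments first, then all stable increments),
#' so a run is exactly reproducible from its seed.
#'
#' Negative excursions are allowed (jumps can overshoot the origin); the
#' drift is evaluated as written. If the state overflows to a non-finite
#' value after a huge jump the path is truncated and flagged.
#'
#' @param params a [tfa_params()] object.
#' @param noise a [noise_spec()] object.
#' @param x0 initial concentration (nM).
#' @param dt time step (min).
#' @param t_max time horizon (min).
#' @param seed optional integer seed (calls [set.seed()]).
#' @return A data.frame of class `tfa_trajectory` with columns `t`, `x`,
#'   and attributes `dt`, `seed`, `truncated`.
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' path <- simulate_path(p, noise_spec(0.05, 0, 2), x0 = 1.3,
#'                       dt = 1e-2, t_max = 20, seed = 1)
#' tail(path, 1)  # near the low stable state 0.62685
#' @export
simulate_path <- function(params, noise, x0, dt = 1e-3, t_max = 10,
                          seed = NULL) {
  params <- as_tfa_params(params)
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.finite(t_max) || t_max < dt) stop("'t_max' must be >= dt")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(t_max / dt)
  g <- if (noise$sigma > 0) stats::rnorm(n) else numeric(n)
  s <- if (noise$epsilon > 0) rstable_standard(n, noise$alpha) else numeric(n)
  x <- numeric(n + 1L)
  x[1] <- x0
  truncated <- FALSE
  sg <- noise$sigma * sqrt(dt)
  sl <- noise$epsilon * dt^(1 / noise$alpha)
  for (i in seq_len(n)) {
    xi <- x[i] + tfa_drift(x[i], params) * dt + sg * g[i] + sl * s[i]
    if (!is.finite(xi)) {
      x <- x[seq_len(i)]
      truncated <- TRUE
      warning("path truncated at step ", i, ": non-finite state")
      break
    }
    x[i + 1L] <- xi
  }
  out <- data.frame(t = dt * (seq_along(x) - 1L), x = x)
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  attr(out, "truncated") <- truncated
  class(out) <- c("tfa_trajectory", "data.frame")
  out
}

#' Monte Carlo ensemble of first exits from a domain
#'
#' Simulates `n_paths` Euler-Maruyama trajectories started at `x0` and
#' records, for each, the first time step at which the state lies outside
#' the open domain `D`, together with the state at that step (jump
#' overshoot is preserved: the recorded exit state is the post-jump
#' position, with no boundary interpolation). Paths that have not exited by
#' the step cap are flagged as censored; if no explicit `t_max` is given the
#' horizon is doubled adaptively until censoring drops below 5% or a hard
#' cap of 1e6 steps is reached.
#'
#' All paths are advanced synchronously; at each step the Gaussian
#' increments of the active paths are drawn first, then the stable
#' increments, so the ensemble is reproducible from
#' `(seed, dt, n_paths)`.
#'
#' @inheritParams simulate_path
#' @param domain a [domain1d()] open set D containing `x0`.
#' @param n_paths number of trajectories.
#' @param t_max optional fixed horizon (min); `NULL` (default) uses the
#'   adaptive doubling rule.
#' @return An object of class `exit_ensemble`: a list with `exit_times`,
#'   `exit_states`, `censored` (logical), `n_censored`, `x0`, `domain`,
#'   `dt`, `seed`.
#' @export
mc_first_exit <- function(params, noise, domain, x0, n_paths = 1e4,
                          dt = 1e-3, t_max = NULL, seed = NULL) {
  params <- as_tfa_params(params)
  stopifnot(inherits(noise, "noise_spec"))
  domain <- as_domain1d(domain)
  if (!is.null(seed)) set.seed(seed)
  n_paths <- as.integer(n_paths)
  if (!in_domain(x0, domain)) {
    # already outside: immediate exit at time 0 for every path
    return(structure(list(exit_times = rep(0, n_paths),
                          exit_states = rep(x0, n_paths),
                          censored = rep(FALSE, n_paths), n_censored = 0L,
                          x0 = x0, domain = domain, dt = dt, seed = seed,
                          n_paths = n_paths),
                     class = "exit_ensemble"))
  }
  hard_cap <- 1e6
  cap <- if (is.null(t_max)) 1e4 else max(1, floor(t_max / dt))
  adaptive <- is.null(t_max)

  x <- rep(x0, n_paths)
  ids <- seq_len(n_paths)
  exit_step <- rep(NA_integer_, n_paths)
  exit_state <- rep(NA_real_, n_paths)
  sg <- noise$sigma * sqrt(dt)
  sl <- noise$epsilon * dt^(1 / noise$alpha)
  use_g <- noise$sigma > 0
  use_s <- noise$epsilon > 0

  step <- 0L
  while (length(ids) > 0) {
    if (step >= cap) {
      frac <- length(ids) / n_paths
      if (adaptive && frac >= 0.05 && cap < hard_cap) {
        cap <- min(2 * cap, hard_cap)
      } else break
    }
    step <- step + 1L
    m <- length(x)
    dx <- tfa_drift(x, params) * dt
    if (use_g) dx <- dx + sg * stats::rnorm(m)
    if (use_s) dx <- dx + sl * rstable_standard(m, noise$alpha)
    x <- x + dx
    bad <- !is.finite(x)
    if (any(bad)) {
      # overflow from a huge jump: treat as an exit far outside the domain
      x[bad] <- sign(dx[bad]) * .Machine$double.xmax
    }
    out <- !in_domain(x, domain)
    if (any(out)) {
      exit_step[ids[out]] <- step
      exit_state[ids[out]] <- x[out]
      ids <- ids[!out]
      x <- x[!out]
    }
  }
  censored <- is.na(exit_step)
  exit_step[censored] <- step
  exit_state[censored] <- x
  n_cens <- sum(censored)
  if (n_cens / n_paths > 0.05) {
    warning(sprintf(
      "%.1f%% of paths censored at t = %g: MFET estimate biased low",
      100 * n_cens / n_paths, step * dt))
  }
  structure(list(exit_times = exit_step * dt, exit_states = exit_state,
                 censored = censored, n_censored = n_cens,
                 x0 = x0, domain = domain, dt = dt, seed = seed,
                 n_paths = n_paths),
            class = "exit_ensemble")
}

#' @export
print.exit_ensemble <- function(x, ...) {
  cat(sprintf(
    "exit_ensemble: %d paths from x0 = %g, dt = %g, %d censored\n",
    x$n_paths, x$x0, x$dt, x$n_censored))
  cat(sprintf("  mean exit time %.4g, mean exit state %.4g\n",
              mean(x$exit_times), mean(x$exit_states)))
  invisible(x)
}

new_mc_estimate <- function(value, std_error, n) {
  structure(list(value = value, std_error = std_error, n = n),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC estimate: %.6g (SE %.3g, n = %d)\n",
              x$value, x$std_error, x$n))
  invisible(x)
}

#' Monte Carlo mean first exit time
#'
#' Sample mean of the first-exit times of an ensemble, with its standard
#' error. Censored paths contribute their censoring time, which biases the
#' mean low; a warning is issued if any are present.
#'
#' @param ens an [mc_first_exit()] ensemble.
#' @return An `mc_estimate` with fields `value`, `std_error`, `n`.
#' @export
mc_mfet <- function(ens) {
  stopifnot(inherits(ens, "exit_ensemble"))
  n <- length(ens$exit_times)
  if (n == 0) stop("empty ensemble")
  if (ens$n_censored > 0) {
    warning("ensemble contains censored paths: MFET biased low")
  }
  se <- if (n > 1) stats::sd(ens$exit_times) / sqrt(n) else 0
  new_mc_estimate(mean(ens$exit_times), se, n)
}

#' Monte Carlo first escape probability
#'
#' Proportion of paths whose first-exit state lands in the target set
#' (closed-set semantics), with a binomial standard error. Censored paths
#' never exited and count as non-escapes.
#'
#' @param ens an [mc_first_exit()] ensemble.
#' @param target target set E in the complement of the ensemble's domain
#'   (a [domain1d()], a `c(a, b)` pair, or a matrix of intervals; `Inf`
#'   endpoints allowed).
#' @return An `mc_estimate`; `value` lies in [0, 1].
#' @export
mc_fep <- function(ens, target) {
  stopifnot(inherits(ens, "exit_ensemble"))
  target <- as_target(target)
  check_target_exterior(target, ens$domain)
  hit <- rep(FALSE, length(ens$exit_states))
  for (i in seq_len(nrow(target))) {
    hit <- hit | (ens$exit_states >= target[i, 1] &
                  ens$exit_states <= target[i, 2])
  }
  hit[ens$censored] <- FALSE
  n <- length(hit)
  p <- mean(hit)
  new_mc_estimate(p, sqrt(p * (1 - p) / n), n)
}
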