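#' @title Nonlocal finite-difference solver for exit problems
#' @description Internal machinery shared by [solve_mfet()] and
#'   [solve_fep()]: a uniform grid per domain interval, and a dense
#'   discretisation of the jump-diffusion generator
#'   A u = f u' + (sigma^2/2) u'' +
#'         eps^alpha C_alpha PV int (u(x+y) - u(x)) |y|^{-1-alpha} dy,
#'   with the principal-value integral split into (i) a midpoint-rule sum
#'   over interior nodes, (ii) an effective-diffusion correction for the
#'   singular cell |y| < h, and (iii) analytic integrals of the jump kernel
#'   over the entire exterior (prescribed-value load plus escaping tail
#'   mass). Because the exterior is integrated exactly, the generator
#'   annihilates constants to rounding error and non-adjacent targets need
#'   no artificial truncation.
#' @name nonlocal-solver
#' @keywords internal
NULL

#' Normalising constant of the symmetric alpha-stable jump measure
#'
#' C_alpha = alpha * Gamma((1+alpha)/2) /
#'           (2^(1-alpha) * sqrt(pi) * Gamma(1 - alpha/2)),
#' the constant in the jump measure nu(dy) = C_alpha |y|^(-1-alpha) dy of
#' the standard symmetric alpha-stable motion. C_1 = 1/pi (Cauchy).
#'
#' @param alpha stability index in (0, 2).
#' @return positive scalar.
#' @export
stable_c_alpha <- function(alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 2) {
    stop("'alpha' must lie in (0, 2) for the jump measure")
  }
  alpha * gamma((1 + alpha) / 2) /
    (2^(1 - alpha) * sqrt(pi) * gamma(1 - alpha / 2))
}

# uniform grid with J cells on each domain interval; interior nodes only
make_grid <- function(domain, J) {
  domain <- as_domain1d(domain)
  J <- as.integer(J)
  if (J < 17L) stop("J too coarse: need at least 16 interior nodes per interval")
  xs <- list(); hs <- numeric(0); iv <- integer(0)
  for (i in seq_len(nrow(domain))) {
    a <- domain[i, 1]; b <- domain[i, 2]
    h <- (b - a) / J
    xs[[i]] <- a + h * seq_len(J - 1L)
    hs <- c(hs, rep(h, J - 1L))
    iv <- c(iv, rep(i, J - 1L))
  }
  list(x = unlist(xs), h = hs, interval = iv, domain = domain, J = J)
}

# analytic integral of |y - x|^(-1-alpha) over a single exterior interval
# (c, d) not containing x; d may be Inf, c may be -Inf
kernel_mass_interval <- function(x, c, d, alpha) {
  if (d <= x) {            # entirely left of x
    lo <- x - d; hi <- if (is.infinite(c)) Inf else x - c
  } else {                 # entirely right of x
    lo <- c - x; hi <- if (is.infinite(d)) Inf else d - x
  }
  if (lo <= 0) stop("exterior interval touches the node")
  upper <- if (is.infinite(hi)) 0 else hi^(-alpha)
  (lo^(-alpha) - upper) / alpha
}

# complement of the domain as a matrix of intervals, with +-Inf tails
exterior_intervals <- function(domain) {
  domain <- as_domain1d(domain)
  n <- nrow(domain)
  lo <- c(-Inf, domain[, 2])
  hi <- c(domain[, 1], Inf)
  keep <- lo < hi
  cbind(a = lo[keep], b = hi[keep])
}

#' Assemble the discrete generator of the jump-diffusion
#'
#' Builds the dense linear system representing the generator A on the
#' interior nodes of a grid, together with the affine load carrying the
#' prescribed exterior values, so that for a field v with the given
#' exterior condition, (A v)(x_j) = (matrix %*% v_interior + load)_j.
#'
#' The Gaussian part uses central differences; the nonlocal part uses a
#' midpoint-rule principal-value sum over interior nodes, an
#' effective-diffusion correction C_alpha h^(2-alpha)/(2-alpha) u'' for the
#' singular cell, and exact integrals of the jump kernel over every exterior
#' interval (both the tail mass leaving the window and the load from
#' nonzero prescribed values). `alpha = 2` (or `epsilon = 0`) assembles a
#' pure advection-diffusion operator with effective variance
#' sigma^2 + 2 epsilon^2.
#'
#' @param grid a grid as built internally by the solvers; alternatively pass
#'   a [domain1d()] and `J` to have one built.
#' @param params a [tfa_params()] object.
#' @param noise a [noise_spec()] object.
#' @param exterior an [exterior_condition()].
#' @param J cells per domain interval when `grid` is a domain (default 400).
#' @return An object of class `generator_matrix`: list with `matrix`,
#'   `load`, `tail_mass`, and the grid.
#' @export
assemble_generator <- function(grid, params, noise, exterior, J = 400) {
  params <- as_tfa_params(params)
  stopifnot(inherits(noise, "noise_spec"), inherits(exterior, "exterior_condition"))
  if (!is.list(grid) || is.null(grid$x)) grid <- make_grid(grid, J)
  x <- grid$x; h <- grid$h; n <- length(x)
  domain <- grid$domain
  fdrift <- tfa_drift(x, params)

  nonlocal <- noise$epsilon > 0 && noise$alpha < 2
  # alpha = 2 stable increments are Gaussian with variance 2 per unit scale
  sigma2 <- noise$sigma^2 +
    if (noise$epsilon > 0 && noise$alpha == 2) 2 * noise$epsilon^2 else 0

  M <- matrix(0, n, n)
  load <- numeric(n)
  tail_mass <- numeric(n)

  # boundary values seen by the local stencils at interval endpoints
  bval <- function(xb) exterior_value_at(exterior, xb)

  # local part: advection + diffusion + singular-cell correction
  add_local_stencil <- function(coef_m1, coef_0, coef_p1) {
    # coefs are per-node vectors for the (j-1, j, j+1) stencil
    for (j in seq_len(n)) {
      iv <- grid$interval[j]
      a <- domain[iv, 1]; b <- domain[iv, 2]
      M[j, j] <<- M[j, j] + coef_0[j]
      left_is_boundary <- j == 1L || grid$interval[j - 1L] != iv
      right_is_boundary <- j == n || grid$interval[j + 1L] != iv
      if (left_is_boundary) {
        load[j] <<- load[j] + coef_m1[j] * bval(a)
      } else M[j, j - 1L] <<- M[j, j - 1L] + coef_m1[j]
      if (right_is_boundary) {
        load[j] <<- load[j] + coef_p1[j] * bval(b)
      } else M[j, j + 1L] <<- M[j, j + 1L] + coef_p1[j]
    }
  }

  alpha <- noise$alpha
  w <- if (nonlocal) noise$epsilon^alpha * stable_c_alpha(alpha) else 0
  dif <- sigma2 / 2 / h^2
  # singular-cell |y| < h of the jump integral as effective diffusion
  corr <- if (nonlocal) w * h^(-alpha) / (2 - alpha) else 0

  # advection: central differences where the local diffusive coupling
  # keeps the stencil sign-stable, first-order upwind otherwise (pure-jump
  # runs with small alpha are advection-dominated near the boundaries)
  central <- abs(fdrift) / (2 * h) <= dif + corr
  adv_m1 <- ifelse(central, -fdrift / (2 * h),
                   ifelse(fdrift < 0, -fdrift / h, 0))
  adv_p1 <- ifelse(central, fdrift / (2 * h),
                   ifelse(fdrift > 0, fdrift / h, 0))
  adv_0 <- ifelse(central, 0, -abs(fdrift) / h)
  add_local_stencil(adv_m1 + dif + corr, adv_0 - 2 * (dif + corr),
                    adv_p1 + dif + corr)

  if (nonlocal) {

    # principal-value trapezoid sum over interior nodes (|y| >= h): the two
    # same-interval neighbours sit on the edge of the singular cell and
    # carry half weight, so their cells do not overlap the correction region
    d <- abs(outer(x, x, "-"))
    K <- w * matrix(rep(h, each = n), n, n) / d^(1 + alpha)  # K[j,k] ~ h_k
    diag(K) <- 0
    same <- outer(grid$interval, grid$interval, "==")
    adj <- same & abs(d - matrix(h, n, n)) < 1e-12 * matrix(h, n, n)
    K[adj] <- K[adj] / 2
    M <- M + K
    diag(M) <- diag(M) - rowSums(K)

    # exact exterior integrals: escaping mass and prescribed-value load
    ext <- exterior_intervals(domain)
    for (j in seq_len(n)) {
      mass_j <- 0
      for (i in seq_len(nrow(ext))) {
        mass_j <- mass_j + kernel_mass_interval(x[j], ext[i, 1], ext[i, 2], alpha)
      }
      tail_mass[j] <- mass_j
      M[j, j] <- M[j, j] - w * mass_j
      if (exterior$kind == "constant" && exterior$value != 0) {
        load[j] <- load[j] + w * exterior$value * mass_j
      } else if (exterior$kind == "indicator") {
        for (i in seq_len(nrow(exterior$target))) {
          load[j] <- load[j] +
            w * kernel_mass_interval(x[j], exterior$target[i, 1],
                                     exterior$target[i, 2], alpha)
        }
      }
    }
  }

  structure(list(matrix = M, load = load, tail_mass = tail_mass,
                 grid = grid, params = params, noise = noise,
                 exterior = exterior),
            class = "generator_matrix")
}

#' Apply an assembled generator to a nodal field
#'
#' Evaluates (A v)(x_j) for interior nodal values `v` under the generator's
#' exterior condition. Useful for residual checks, e.g. that A annihilates
#' the constant field 1 when the exterior value is 1.
#'
#' @param gen a [assemble_generator()] object.
#' @param v numeric vector of interior nodal values.
#' @return numeric vector of generator values at the interior nodes.
#' @export
apply_generator <- function(gen, v) {
  stopifnot(inherits(gen, "generator_matrix"))
  as.numeric(gen$matrix %*% v + gen$load)
}

new_field_solution <- function(grid, values_int, kind, exterior, noise,
                               params, clip = FALSE) {
  domain <- grid$domain
  raw_range <- range(values_int)
  if (clip) values_int <- pmin(pmax(values_int, 0), 1)
  # store per-interval arrays including the boundary nodes, whose values
  # come from the exterior condition, so interpolation and plotting see the
  # full profile
  xs <- numeric(0); vs <- numeric(0); iv <- integer(0)
  for (i in seq_len(nrow(domain))) {
    sel <- grid$interval == i
    a <- domain[i, 1]; b <- domain[i, 2]
    va <- exterior_value_at(exterior, a)
    vb <- exterior_value_at(exterior, b)
    xs <- c(xs, a, grid$x[sel], b)
    vs <- c(vs, va, values_int[sel], vb)
    iv <- c(iv, rep(i, sum(sel) + 2L))
  }
  structure(list(x = xs, values = vs, interval = iv, kind = kind,
                 domain = domain, J = grid$J, noise = noise,
                 params = params, raw_range = raw_range),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution (%s) on ", x$kind))
  cat(paste(sprintf("(%g, %g)", x$domain[, 1], x$domain[, 2]),
            collapse = " U "))
  cat(sprintf(", J = %d\n  range [%.4g, %.4g], max at x = %.4g\n",
              x$J, min(x$values), max(x$values),
              x$x[which.max(x$values)]))
  invisible(x)
}

#' Evaluate a field solution at arbitrary points
#'
#' Linear interpolation of a nodal MFET or FEP field within its solve
#' domain. Points outside every domain interval return `NA`.
#'
#' @param sol a [solve_mfet()] / [solve_fep()] result.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of interpolated values.
#' @export
field_eval <- function(sol, x) {
  stopifnot(inherits(sol, "field_solution"))
  out <- rep(NA_real_, length(x))
  for (i in seq_len(nrow(sol$domain))) {
    sel <- x >= sol$domain[i, 1] & x <= sol$domain[i, 2]
    if (any(sel)) {
      nod <- sol$interval == i
      out[sel] <- stats::approx(sol$x[nod], sol$values[nod],
                                xout = x[sel])$y
    }
  }
  out
}

#' Mean first exit time by the nonlocal solver
#'
#' Solves A u = -1 on the interior of `domain` with u = 0 on the whole
#' exterior (the nonlocal Dirichlet condition), where A is the
#' jump-diffusion generator. u(x) is the expected time (min) for the
#' process started at x to first leave the domain.
#'
#' @param domain the open set D, a [domain1d()] or `c(a, b)`.
#' @param params a [tfa_params()] object.
#' @param noise a [noise_spec()] object with `sigma^2 + epsilon^alpha > 0`.
#' @param J grid cells per domain interval (default 400).
#' @return A `field_solution` of kind `"mfet"`; evaluate with
#'   [field_eval()].
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' u <- solve_mfet(c(0, 1.48971), p, noise_spec(0.5, 0, 2), J = 100)
#' field_eval(u, 0.62685)
#' @export
solve_mfet <- function(domain, params, noise, J = 400) {
  domain <- as_domain1d(domain)
  ext <- exterior_condition("zero")
  gen <- assemble_generator(make_grid(domain, J), params, noise, ext)
  u <- tryCatch(solve(gen$matrix, -1 - gen$load),
                error = function(e) stop("singular generator system: ",
                                         conditionMessage(e)))
  new_field_solution(gen$grid, u, "mfet", ext, gen$noise, gen$params)
}

#' First escape probability by the nonlocal solver
#'
#' Solves A p = 0 on the interior of `domain` with the Balayage-Dirichlet
#' exterior condition p = 1 on the target set E and p = 0 on the rest of
#' the complement. p(x) is the probability that the process started at x
#' lands in E at its first exit from the domain. Semi-infinite targets
#' (e.g. E = [x_u, Inf)) are handled by exact tail integration; a target
#' sharing a boundary with the domain also feeds the diffusive stencil
#' through the boundary value p = 1 there.
#'
#' @inheritParams solve_mfet
#' @param target the target set E in the complement of `domain` (pair,
#'   matrix of intervals, or [domain1d()]; `Inf` endpoints allowed).
#' @return A `field_solution` of kind `"fep"` with values clipped to
#'   [0, 1]; the pre-clip range is kept in `$raw_range`.
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' fep <- solve_fep(c(0, 1.48971), c(1.48971, Inf), p,
#'                  noise_spec(0.5, 0.5, 1.5), J = 100)
#' field_eval(fep, 0.62685)
#' @export
solve_fep <- function(domain, target, params, noise, J = 400) {
  domain <- as_domain1d(domain)
  target <- as_target(target)
  check_target_exterior(target, domain)
  ext <- exterior_condition("indicator", target = target)
  gen <- assemble_generator(make_grid(domain, J), params, noise, ext)
  p <- tryCatch(solve(gen$matrix, -gen$load),
                error = function(e) stop("singular generator system: ",
                                         conditionMessage(e)))
  if (min(p) < -1e-8 || max(p) > 1 + 1e-8) {
    warning(sprintf("FEP exceeds [0,1] beyond tolerance: [%.3g, %.3g]",
                    min(p), max(p)))
  }
  new_field_solution(gen$grid, p, "fep", ext, gen$noise, gen$params,
                     clip = TRUE)
}

#' Closed-form Brownian mean first exit time (oracle)
#'
#' For the pure-diffusion case dX = f(X) dt + sigma dB on a single interval
#' (a, b) with absorption at both ends, the MFET solves
#' (sigma^2/2) u'' + f u' = -1, u(a) = u(b) = 0, whose solution is obtained
#' from the scale density psi(t) = exp(-(2/sigma^2) int_a^t f). This
#' quadrature evaluation is independent of the finite-difference solver and
#' serves as its oracle.
#'
#' @param params a [tfa_params()] object (drift f).
#' @param sigma Gaussian intensity > 0.
#' @param domain single interval `c(a, b)`.
#' @param x evaluation point(s) in (a, b).
#' @return MFET value(s) in minutes.
#' @export
brownian_mfet_closed_form <- function(params, sigma, domain, x) {
  params <- as_tfa_params(params)
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  domain <- as_domain1d(domain)
  if (nrow(domain) != 1L) stop("closed form needs a single interval")
  a <- domain[1, 1]; b <- domain[1, 2]
  q <- 2 / sigma^2
  intf <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(tfa_drift, a, ti, params = params,
                       rel.tol = 1e-10, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  psi <- function(t) exp(-q * intf(t))
  inv_psi <- function(t) exp(q * intf(t))
  Phi <- function(t) {  # int_a^t 1/psi
    vapply(t, function(ti) {
      stats::integrate(inv_psi, a, ti, rel.tol = 1e-10, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  S <- function(t) {    # int_a^t psi
    vapply(t, function(ti) {
      stats::integrate(psi, a, ti, rel.tol = 1e-10, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  psiPhi <- function(t) psi(t) * Phi(t)
  int_psiPhi <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(psiPhi, a, ti, rel.tol = 1e-9, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  C <- q * int_psiPhi(b) / S(b)
  unname(C * S(x) - q * int_psiPhi(x))
}

#' Closed-form Brownian escape probability (oracle)
#'
#' Scale-function ratio for the probability that the diffusion
#' dX = f dt + sigma dB started at x in (a, b) exits through b before a:
#' p(x) = int_a^x psi / int_a^b psi with
#' psi(t) = exp(-(2/sigma^2) int_a^t f).
#'
#' @inheritParams brownian_mfet_closed_form
#' @return probability value(s) in [0, 1].
#' @export
brownian_fep_closed_form <- function(params, sigma, domain, x) {
  params <- as_tfa_params(params)
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  domain <- as_domain1d(domain)
  if (nrow(domain) != 1L) stop("closed form needs a single interval")
  a <- domain[1, 1]; b <- domain[1, 2]
  q <- 2 / sigma^2
  intf <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(tfa_drift, a, ti, params = params,
                       rel.tol = 1e-10, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  psi <- function(t) exp(-q * intf(t))
  S <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(psi, a, ti, rel.tol = 1e-10, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  unname(S(x) / S(b))
}

#' Solve with grid refinement until self-convergence
#'
#' Repeatedly doubles the grid resolution and compares successive solutions
#' at the coarse nodes until the maximum relative change drops below `tol`.
#'
#' @inheritParams solve_mfet
#' @param target optional target set; when given, [solve_fep()] is refined,
#'   otherwise [solve_mfet()].
#' @param tol relative tolerance on the maximum nodal change (default
#'   1e-3); `Inf` returns the first solve unchanged.
#' @param J_init starting resolution (default 100).
#' @param J_max refinement cap (default 6400); exceeding it is an error.
#' @return The finest `field_solution`, with the convergence history in
#'   attribute `"convergence"` (data.frame of J and successive change).
#' @export
refine_until <- function(domain, params, noise, target = NULL, tol = 1e-3,
                         J_init = 100, J_max = 6400) {
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0) {
    stop("'tol' must be positive")
  }
  domain <- as_domain1d(domain)
  solve_at <- function(J) {
    if (is.null(target)) solve_mfet(domain, params, noise, J = J)
    else solve_fep(domain, target, params, noise, J = J)
  }
  J <- J_init
  sol <- solve_at(J)
  hist <- data.frame(J = J, change = NA_real_)
  if (is.infinite(tol)) {
    attr(sol, "convergence") <- hist
    return(sol)
  }
  repeat {
    if (2 * J > J_max) {
      stop(sprintf(
        "no convergence by J = %d (last relative change %.3g > tol %.3g)",
        J, hist$change[nrow(hist)], tol))
    }
    J <- 2L * J
    sol2 <- solve_at(J)
    # coarse interior nodes are a subset of the fine grid; compare there
    xc <- sol$x
    change <- max(abs(field_eval(sol2, xc) - sol$values)) /
      max(abs(sol2$values))
    hist <- rbind(hist, data.frame(J = J, change = change))
    sol <- sol2
    if (change < tol) break
  }
  attr(sol, "convergence") <- hist
  sol
}
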