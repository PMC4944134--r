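#' @title Escape experiments: RCF sweeps and the stochastic basin
#' @name escape-analysis
#' @keywords internal
NULL

# normalise a list of noise settings: numeric vector of RCF lambdas,
# list of (sigma, epsilon) pairs, or list of noise_spec objects
as_noise_settings <- function(settings, alpha) {
  if (is.numeric(settings)) {
    return(lapply(settings, rcf_setting, alpha = alpha))
  }
  if (is.list(settings)) {
    return(lapply(settings, function(s) {
      if (inherits(s, "noise_spec")) s
      else if (is.numeric(s) && length(s) == 2L) {
        noise_spec(s[[1]], s[[2]], alpha)
      } else stop("cannot interpret noise setting")
    }))
  }
  stop("'settings' must be RCF values, (sigma, epsilon) pairs, ",
       "or noise_spec objects")
}

sweep_row <- function(x0_list, ns, quantity, scenario, values) {
  data.frame(x0 = x0_list, alpha = ns$alpha, sigma = ns$sigma,
             epsilon = ns$epsilon, lambda = ns$lambda_rcf,
             scenario = scenario, quantity = quantity, value = values)
}

#' Sweep the mean first exit time over noise settings
#'
#' Solves the MFET equation once per noise setting and tabulates the
#' interpolated values at the requested initial concentrations — the
#' numerical experiment behind MFET-versus-RCF curves.
#'
#' @param x0_list initial concentrations inside `domain`.
#' @param alpha stability index used when `settings` are plain RCF values
#'   or `(sigma, epsilon)` pairs.
#' @param settings numeric vector of RCF lambda values (converted to
#'   constrained sigma/epsilon pairs with `sigma + epsilon = 1`), a list of
#'   `c(sigma, epsilon)` pairs, or a list of [noise_spec()] objects.
#' @param domain the exit domain D.
#' @param params a [tfa_params()] object.
#' @param J grid resolution per interval.
#' @return A data.frame (`sweep_table`) with columns `x0`, `alpha`,
#'   `sigma`, `epsilon`, `lambda`, `scenario`, `quantity`, `value`, sorted
#'   by (x0, lambda).
#' @examples
#' p <- tfa_params(6, 10, 1, 0.4)
#' sweep_mfet(c(0.3, 0.62685), alpha = 0.5, settings = c(1, 4),
#'            domain = c(0, 1.48971), params = p, J = 50)
#' @export
sweep_mfet <- function(x0_list, alpha, settings, domain, params, J = 400) {
  domain <- as_domain1d(domain)
  if (!all(in_domain(x0_list, domain))) {
    stop("all 'x0_list' points must lie inside the domain")
  }
  specs <- as_noise_settings(settings, alpha)
  rows <- lapply(specs, function(ns) {
    sol <- solve_mfet(domain, params, ns, J = J)
    sweep_row(x0_list, ns, "mfet", NA_integer_, field_eval(sol, x0_list))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$x0, out$lambda), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Sweep the first escape probability over noise settings
#'
#' Solves the FEP equation once per noise setting, for an adjacent
#' (scenario 1) or non-adjacent (scenario 2) target set, and tabulates the
#' interpolated values at the requested initial concentrations.
#'
#' @inheritParams sweep_mfet
#' @param target the target set E (in the complement of `domain`).
#' @param scenario 1 if E is adjacent to D (shares a boundary), 2 if E is
#'   separated from D by a gap (reachable only by jumps); checked against
#'   the geometry.
#' @return A `sweep_table` data.frame as in [sweep_mfet()], with
#'   `quantity = "fep"` and the scenario recorded.
#' @export
sweep_fep <- function(x0_list, alpha, settings, domain, target, scenario,
                      params, J = 400) {
  domain <- as_domain1d(domain)
  target <- as_target(target)
  check_target_exterior(target, domain)
  if (!all(in_domain(x0_list, domain))) {
    stop("all 'x0_list' points must lie inside the domain")
  }
  scenario <- as.integer(scenario)
  if (!scenario %in% c(1L, 2L)) stop("'scenario' must be 1 or 2")
  gap <- min(vapply(seq_len(nrow(target)), function(i) {
    min(abs(c(outer(target[i, ], as.numeric(domain), "-"))))
  }, numeric(1)))
  if (scenario == 2L && gap == 0) {
    stop("scenario 2 requires a target non-adjacent to the domain")
  }
  specs <- as_noise_settings(settings, alpha)
  rows <- lapply(specs, function(ns) {
    sol <- solve_fep(domain, target, params, ns, J = J)
    sweep_row(x0_list, ns, "fep", scenario, field_eval(sol, x0_list))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$x0, out$lambda), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}

# runs of consecutive TRUE values as (start, end) index pairs
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# superlevel set {v > thr} (or >= thr) of a piecewise-linear field on one
# interval's nodes, endpoints located by inverse linear interpolation.
# `keep` marks nodes allowed to anchor a component: runs made up solely of
# excluded nodes (e.g. a prescribed boundary value not attained by the
# solution nearby, as happens for jump processes at the target boundary)
# are dropped.
superlevel_intervals <- function(x, v, thr, strict = TRUE,
                                 keep = rep(TRUE, length(x))) {
  above <- if (strict) v > thr else v >= thr
  if (!any(above)) return(matrix(numeric(0), ncol = 2))
  runs <- true_runs(above)
  anchored <- vapply(seq_len(nrow(runs)), function(k)
    any(keep[runs[k, 1]:runs[k, 2]]), logical(1))
  runs <- runs[anchored, , drop = FALSE]
  if (nrow(runs) == 0) return(matrix(numeric(0), ncol = 2))
  out <- matrix(NA_real_, nrow(runs), 2)
  for (k in seq_len(nrow(runs))) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    lo <- if (i0 == 1L) x[1] else {
      x[i0 - 1L] + (thr - v[i0 - 1L]) / (v[i0] - v[i0 - 1L]) *
        (x[i0] - x[i0 - 1L])
    }
    hi <- if (i1 == length(x)) x[length(x)] else {
      x[i1] + (thr - v[i1]) / (v[i1 + 1L] - v[i1]) * (x[i1 + 1L] - x[i1])
    }
    out[k, ] <- c(lo, hi)
  }
  out
}

#' Extract the metastable core K from an MFET field
#'
#' K = {x : u(x) >= u_star} restricted to its connected component
#' containing the maximiser of u — the closed set of initial concentrations
#' whose expected residence time exceeds the threshold. Endpoints are
#' located by linear interpolation of u across the threshold (ties broken
#' toward the leftmost maximiser).
#'
#' @param u a `field_solution` of kind `"mfet"`.
#' @param u_star positive time threshold, at most `max(u)`.
#' @return numeric `c(a, b)`, the closed interval K (degenerate when
#'   `u_star = max(u)`), rounded to 4 decimals.
#' @export
extract_k <- function(u, u_star) {
  stopifnot(inherits(u, "field_solution"))
  if (u$kind != "mfet") stop("'u' must be an MFET field")
  if (!is.finite(u_star) || u_star <= 0) stop("'u_star' must be positive")
  umax <- max(u$values)
  if (u_star > umax) stop("empty K: u_star exceeds max(u)")
  imax <- which.max(u$values)   # which.max takes the leftmost maximiser
  iv <- u$interval[imax]
  sel <- u$interval == iv
  comps <- superlevel_intervals(u$x[sel], u$values[sel], u_star,
                                strict = FALSE)
  xmax <- u$x[imax]
  hit <- which(comps[, 1] <= xmax & comps[, 2] >= xmax)[1]
  round(comps[hit, ], 4)
}

#' Stochastic basin of attraction of the low-concentration state
#'
#' Quantifies basin stability under noise as the union of (i) the closed
#' core K where the mean residence time exceeds `u_star` and (ii) the set M
#' of outside points whose probability of entering K at first exit from the
#' return domain exceeds `p_star`. The size of the basin is the total
#' interval length |K| + |M|.
#'
#' The procedure: solve the MFET equation on the deterministic basin of the
#' low state (by default (0, x_u), computed from the model's equilibria);
#' threshold it to get K; solve the FEP equation on the two-interval return
#' domain `window \ K` with target K (indicator exterior condition;
#' everything outside the window carries value 0); threshold that solution
#' to get M.
#'
#' @param params a [tfa_params()] object.
#' @param noise a [noise_spec()] object.
#' @param window bounded search window B for the return set (default
#'   `c(0, 6)`).
#' @param u_star residence-time threshold defining K (min).
#' @param p_star return-probability threshold defining M, in (0, 1).
#' @param J grid resolution per interval.
#' @param basin deterministic basin interval on which the MFET is solved;
#'   `NULL` (default) uses (0, x_u) from [find_equilibria()].
#' @return An object of class `sba_result`: list with `K` (interval), `M`
#'   (matrix of intervals), `u_star`, `p_star`, `window`, `sba_size`, and
#'   the two field solutions `u` and `p`.
#' @export
stochastic_basin <- function(params, noise, window = c(0, 6), u_star,
                             p_star, J = 400, basin = NULL) {
  params <- as_tfa_params(params)
  stopifnot(inherits(noise, "noise_spec"))
  window <- as_domain1d(window)
  if (nrow(window) != 1L) stop("'window' must be a single bounded interval")
  if (!is.finite(p_star) || p_star <= 0 || p_star >= 1) {
    stop("'p_star' must lie in (0, 1)")
  }
  if (is.null(basin)) {
    eq <- find_equilibria(params)
    if (!eq$bistable) stop("model is not bistable: no basin to threshold")
    basin <- domain1d(0, eq$x_u)
  } else basin <- as_domain1d(basin)

  u <- solve_mfet(basin, params, noise, J = J)
  K <- extract_k(u, u_star)
  wa <- window[1, 1]; wb <- window[1, 2]
  if (K[1] <= wa || K[2] >= wb) {
    warning("K touches the window boundary; enlarge the window")
    K[1] <- max(K[1], wa + 1e-8); K[2] <- min(K[2], wb - 1e-8)
  }
  ret_domain <- domain1d(c(wa, K[1]), c(K[2], wb))
  p <- solve_fep(ret_domain, matrix(K, ncol = 2), params, noise, J = J)

  M <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(ret_domain))) {
    sel <- p$interval == i
    xi <- p$x[sel]
    interior <- xi > ret_domain[i, 1] & xi < ret_domain[i, 2]
    M <- rbind(M, superlevel_intervals(xi, p$values[sel], p_star,
                                       strict = TRUE, keep = interior))
  }
  M <- round(M, 4)
  m_size <- if (nrow(M)) sum(M[, 2] - M[, 1]) else 0
  structure(list(K = K, M = M, u_star = u_star, p_star = p_star,
                 window = window, k_size = K[2] - K[1], m_size = m_size,
                 sba_size = (K[2] - K[1]) + m_size,
                 u = u, p = p, noise = noise, params = params),
            class = "sba_result")
}

#' @export
print.sba_result <- function(x, ...) {
  cat("Stochastic basin of attraction\n")
  cat(sprintf("  K = [%.4f, %.4f]  (u* = %.4g, |K| = %.4f)\n",
              x$K[1], x$K[2], x$u_star, x$k_size))
  if (nrow(x$M)) {
    cat(sprintf("  M = %s  (p* = %.3g, |M| = %.4f)\n",
                paste(sprintf("[%.4f, %.4f]", x$M[, 1], x$M[, 2]),
                      collapse = " U "), x$p_star, x$m_size))
  } else {
    cat(sprintf("  M empty at p* = %.3g\n", x$p_star))
  }
  cat(sprintf("  SBA size |K| + |M| = %.4f\n", x$sba_size))
  invisible(x)
}
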