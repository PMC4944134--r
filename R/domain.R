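#' One-dimensional solve domain: a finite union of open intervals
#'
#' Constructs the open set on which exit-time and escape-probability
#' equations are solved. Nonlocal (jump-driven) problems prescribe values on
#' the whole complement of the domain, so the domain is stored as an ordered
#' union of disjoint finite open intervals.
#'
#' @param ... either a single numeric vector `c(a, b)`, a 2-column matrix
#'   with one interval per row, or several `c(a, b)` vectors.
#' @return An object of class `domain1d`: a 2-column matrix (`a`, `b`) with
#'   one ordered interval per row.
#' @examples
#' domain1d(0, 1.48971)
#' domain1d(c(0, 0.4387), c(0.9869, 6))   # two-interval return domain
#' @export
domain1d <- function(...) {
  args <- list(...)
  if (length(args) == 2L && all(lengths(args) == 1L)) {
    ints <- matrix(c(args[[1]], args[[2]]), ncol = 2)
  } else if (length(args) == 1L && is.matrix(args[[1]])) {
    ints <- args[[1]]
  } else if (length(args) == 1L && is.numeric(args[[1]]) &&
             length(args[[1]]) == 2L) {
    ints <- matrix(args[[1]], ncol = 2)
  } else {
    if (!all(vapply(args, function(v) is.numeric(v) && length(v) == 2L,
                    logical(1)))) {
      stop("intervals must be numeric pairs c(a, b)")
    }
    ints <- do.call(rbind, args)
  }
  ints <- matrix(as.numeric(ints), ncol = 2)
  if (nrow(ints) == 0) stop("domain must contain at least one interval")
  if (any(!is.finite(ints))) stop("interval endpoints must be finite")
  if (any(ints[, 1] >= ints[, 2])) stop("each interval needs a < b")
  ints <- ints[order(ints[, 1]), , drop = FALSE]
  if (nrow(ints) > 1 && any(ints[-1, 1] < ints[-nrow(ints), 2])) {
    stop("intervals must be disjoint")
  }
  colnames(ints) <- c("a", "b")
  structure(ints, class = c("domain1d", "matrix"))
}

as_domain1d <- function(x) {
  if (inherits(x, "domain1d")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(domain1d(x))
  if (is.matrix(x)) return(domain1d(x))
  if (is.list(x)) return(do.call(domain1d, x))
  stop("cannot interpret object as a domain1d")
}

#' @export
print.domain1d <- function(x, ...) {
  cat("domain1d:",
      paste(sprintf("(%g, %g)", x[, 1], x[, 2]), collapse = " U "), "\n")
  invisible(x)
}

#' Membership in an open domain
#'
#' @param x numeric vector of points.
#' @param domain a [domain1d()] object.
#' @return logical vector; `TRUE` where `x` lies strictly inside one of the
#'   domain's open intervals.
#' @export
in_domain <- function(x, domain) {
  domain <- as_domain1d(domain)
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(domain))) {
    out <- out | (x > domain[i, 1] & x < domain[i, 2])
  }
  out
}

domain_length <- function(domain) {
  domain <- as_domain1d(domain)
  sum(domain[, 2] - domain[, 1])
}

#' Exterior condition for a nonlocal exit problem
#'
#' Nonlocal generators see the whole complement of the solve domain, so the
#' boundary data of an exit problem is a function prescribed on all of the
#' exterior (a Balayage-Dirichlet condition): identically zero for the mean
#' first exit time, the indicator of a target set for an escape probability,
#' or a constant.
#'
#' @param kind one of `"zero"`, `"indicator"`, `"constant"`.
#' @param target for `kind = "indicator"`: a [domain1d()] giving the target
#'   set (interpreted as closed; may be unbounded via `Inf` endpoints, in
#'   which case pass a matrix with `Inf`).
#' @param value for `kind = "constant"`: the prescribed constant.
#' @return An object of class `exterior_condition`.
#' @export
exterior_condition <- function(kind = c("zero", "indicator", "constant"),
                               target = NULL, value = NULL) {
  kind <- match.arg(kind)
  if (kind == "indicator") {
    if (is.null(target)) stop("indicator condition needs a 'target'")
    target <- as_target(target)
  }
  if (kind == "constant") {
    if (is.null(value) || !is.finite(value)) {
      stop("constant condition needs a finite 'value'")
    }
  }
  structure(list(kind = kind, target = target, value = value),
            class = "exterior_condition")
}

# target sets may be unbounded ([x_u, Inf)); keep them as a plain interval
# matrix rather than a domain1d, which requires finite endpoints
as_target <- function(x) {
  if (inherits(x, "domain1d")) {
    m <- matrix(as.numeric(x), ncol = 2)
  } else if (is.numeric(x) && length(x) == 2L) {
    m <- matrix(x, ncol = 2)
  } else if (is.matrix(x)) {
    m <- matrix(as.numeric(x), ncol = 2)
  } else if (is.list(x)) {
    m <- do.call(rbind, x)
  } else {
    stop("cannot interpret target set")
  }
  if (any(is.na(m)) || any(m[, 1] >= m[, 2])) stop("invalid target intervals")
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("a", "b")
  m
}

# value of the exterior condition at a point (closed-set semantics for
# indicator targets, so a boundary shared with the target carries value 1)
exterior_value_at <- function(cond, x) {
  switch(cond$kind,
         zero = rep(0, length(x)),
         constant = rep(cond$value, length(x)),
         indicator = {
           out <- rep(0, length(x))
           for (i in seq_len(nrow(cond$target))) {
             out[x >= cond$target[i, 1] & x <= cond$target[i, 2]] <- 1
           }
           out
         })
}

# check that a target lies in the complement of the domain
check_target_exterior <- function(target, domain) {
  domain <- as_domain1d(domain)
  for (i in seq_len(nrow(target))) {
    for (j in seq_len(nrow(domain))) {
      lo <- max(target[i, 1], domain[j, 1])
      hi <- min(target[i, 2], domain[j, 2])
      if (lo < hi) stop("target set overlaps the solve domain")
    }
  }
  invisible(TRUE)
}
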