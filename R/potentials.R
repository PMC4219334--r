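#' Parametric potential shape functions
#'
#' The dimensionless shapes f(r) of the provided interaction potentials. All
#' are attraction wells of unit depth that decay to 0 at large r:
#' \describe{
#'   \item{step}{f(r) = -1 for r < 0, 0 otherwise.}
#'   \item{hernquist}{f(r) = -1/(r + 1) for r > 0, -(1 - r) otherwise.}
#'   \item{linear1}{f(r) = 0 for r > 1, -(1 - r) otherwise.}
#'   \item{linear2}{f(r) = 0 for r > 1, -1 for r < 0, -(1 - r) in between.}
#'   \item{plummer}{f(r) = -(r^2 + 1)^(-1/2) for r > 0, -1 otherwise.}
#' }
#' Adding a new shape is a single-entry change to the internal shape table.
#'
#' @param shape one of `"step"`, `"hernquist"`, `"linear1"`, `"linear2"`,
#'   `"plummer"`.
#' @param r dimensionless argument(s).
#' @return f(r), vectorized over `r`.
#' @examples
#' shape_value("step", -0.5)   # -1
#' shape_value("linear2", 2)   # 0
#' shape_value("plummer", 0)   # -1
#' @export
shape_value <- function(shape, r) {
  fun <- potential_shapes[[match.arg(shape, names(potential_shapes))]]
  fun(as.numeric(r))
}

potential_shapes <- list(
  step      = function(r) -1 * (r < 0),
  hernquist = function(r) {
    out <- -1 / (r + 1)
    neg <- r <= 0
    out[neg] <- r[neg] - 1
    out
  },
  linear1   = function(r) pmin(r, 1) - 1,
  linear2   = function(r) pmax(pmin(r, 1), 0) - 1,
  plummer   = function(r) {
    out <- -1 / sqrt(r * r + 1)
    out[r <= 0] <- -1
    out
  }
)

#' Names of the available parametric shapes
#' @return character vector of shape identifiers.
#' @export
potential_shape_names <- function() names(potential_shapes)

#' Construct a parametric interaction potential
#'
#' Potentials are parameterized as phi(d) = epsilon * f((d - t) / sigma) with
#' interaction strength epsilon (>= 0; 0 means no interaction), length scale
#' sigma (> 0, distance units) and hard core t (>= 0, distance units; objects
#' closer than t count as overlapping). For the step shape sigma is fixed at 1
#' and t is free — its fit is a context-corrected object-based colocalization
#' count; for all other shapes t is fixed at 0 and sigma is free.
#'
#' @param shape a shape name (see [shape_value()]).
#' @param epsilon interaction strength (>= 0).
#' @param sigma length scale (> 0); forced to 1 for the step shape.
#' @param t hard core distance (>= 0); forced to 0 for non-step shapes.
#' @return object of class `c("parametric_potential", "ia_potential")`.
#' @examples
#' pot <- potential("plummer", epsilon = 2, sigma = 10)
#' potential_value(pot, c(0, 10, 100))
#' @export
potential <- function(shape, epsilon, sigma = 1, t = 0) {
  shape <- match.arg(shape, names(potential_shapes))
  if (epsilon < 0) stop("epsilon must be nonnegative (attraction wells only)")
  if (sigma <= 0) stop("sigma must be positive")
  if (t < 0) stop("t must be nonnegative")
  if (shape == "step") sigma <- 1 else t <- 0
  structure(list(shape = shape, epsilon = epsilon, sigma = sigma, t = t),
            class = c("parametric_potential", "ia_potential"))
}

#' Construct a non-parametric piecewise-linear potential
#'
#' A weighted sum of linear (tent) kernels centered on P support points: the
#' potential interpolates the (position, weight) pairs linearly. Below the
#' first support point the first weight is extended as a constant; beyond the
#' last support point the potential is 0, and the last weight is anchored to 0
#' to remove the additive gauge freedom the partition function would absorb.
#' Weights may be negative (attraction) or positive (repulsion).
#'
#' @param positions strictly increasing support distances (P >= 3).
#' @param weights potential value at each support point; the last must be 0.
#' @param smoothness penalty factor lambda >= 0 on squared differences of
#'   adjacent weights (see [smoothness_penalty()]).
#' @return object of class `c("nonparametric_potential", "ia_potential")`.
#' @export
nonparametric_potential <- function(positions, weights, smoothness = 0) {
  positions <- as.numeric(positions)
  weights <- as.numeric(weights)
  if (length(positions) < 3L) stop("need at least 3 support points")
  if (length(weights) != length(positions)) stop("positions and weights differ in length")
  if (any(diff(positions) <= 0)) stop("support positions must be strictly increasing")
  if (smoothness < 0) stop("smoothness must be nonnegative")
  if (abs(weights[length(weights)]) > 1e-12) stop("last weight must be 0 (anchoring)")
  structure(list(positions = positions, weights = weights, smoothness = smoothness),
            class = c("nonparametric_potential", "ia_potential"))
}

#' Evaluate an interaction potential
#'
#' @param pot an `ia_potential`.
#' @param d nonnegative distance(s).
#' @return phi(d), vectorized over `d`.
#' @export
potential_value <- function(pot, d) UseMethod("potential_value")

#' @export
potential_value.parametric_potential <- function(pot, d) {
  pot$epsilon * shape_value(pot$shape, (as.numeric(d) - pot$t) / pot$sigma)
}

#' @export
potential_value.nonparametric_potential <- function(pot, d) {
  d <- as.numeric(d)
  p <- pot$positions
  w <- pot$weights
  out <- approx(p, w, xout = d, rule = 2L)$y  # rule 2: constant below first node
  out[d > p[length(p)]] <- 0                  # zero beyond the last node
  out
}

#' Smoothness penalty of a non-parametric potential
#'
#' lambda * sum of squared differences between adjacent support weights; added
#' to the fitting objective to regularize the estimate.
#'
#' @param pot a `nonparametric_potential`.
#' @return nonnegative penalty value.
#' @export
smoothness_penalty <- function(pot) {
  stopifnot(inherits(pot, "nonparametric_potential"))
  pot$smoothness * sum(diff(pot$weights)^2)
}

# Lower bound of phi over d >= 0: -epsilon for parametric wells; for the
# non-parametric potential, the smallest of the weights and the zero tail.
phi_min <- function(pot) {
  if (inherits(pot, "parametric_potential")) -pot$epsilon
  else min(c(pot$weights, 0))
}

#' @export
print.parametric_potential <- function(x, ...) {
  cat(sprintf("Potential: %s, epsilon = %.4g, sigma = %.4g, t = %.4g\n",
              x$shape, x$epsilon, x$sigma, x$t))
  invisible(x)
}

#' @export
print.nonparametric_potential <- function(x, ...) {
  cat(sprintf("Non-parametric potential: %d support points on [%g, %g], smoothness = %g\n",
              length(x$positions), min(x$positions), max(x$positions), x$smoothness))
  cat("  depth (min weight):", format(min(x$weights), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.ia_potential <- function(x, ..., from = 0, to = NULL, n = 400L) {
  if (is.null(to)) {
    to <- if (inherits(x, "parametric_potential")) x$t + 5 * x$sigma
    else max(x$positions)
  }
  d <- seq(from, to, length.out = n)
  plot(d, potential_value(x, d), type = "l", xlab = "distance d",
       ylab = expression(phi(d)), ...)
  invisible(x)
}
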