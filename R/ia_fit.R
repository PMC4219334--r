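#' Precompute the context distance distribution
#'
#' Grid-samples nearest-neighbor distances from a regular lattice to the
#' reference set and smooths them once on a fine master grid. The resulting
#' object can be passed to [ia_fit()] or [ia_test()] to avoid recomputing the
#' context when the reference set and region are unchanged (e.g. across Monte
#' Carlo replicates, where reusing the context is also variance-reducing).
#'
#' @param y reference point set.
#' @param region the shared analysis [region()].
#' @param spacing lattice spacing for context sampling, in coordinate units.
#'   0.5 pixels suffices for images without sub-pixel detection; refine until
#'   the context stops changing. This is the costliest step of the analysis.
#' @param bandwidth explicit KDE bandwidth for the context; overrides `wt`.
#' @param wt kernel weight for the context smoothing; a small weight on the
#'   (large) lattice sample gives a smooth context. See
#'   [weight_to_bandwidth()].
#' @return object of class `ia_context`.
#' @export
ia_context <- function(y, region, spacing = 0.5, bandwidth = NULL, wt = 0.001) {
  y <- point_set(as_coord_matrix(y), label = "Y")
  if (!all(region_contains(region, y))) stop("reference points outside the region")
  samples <- sample_context(y, region, spacing)
  h <- if (!is.null(bandwidth)) bandwidth else weight_to_bandwidth(wt, samples)
  lim <- max(samples) * 1.05 + 4 * h
  grid <- seq(0, lim, length.out = 4096L)
  master <- kde(samples, h, grid)
  structure(list(samples = samples, bandwidth = h, master = master,
                 q999 = quantile(samples, 0.999, names = FALSE),
                 y = y, region = region, spacing = spacing),
            class = "ia_context")
}

#' @export
print.ia_context <- function(x, ...) {
  cat(sprintf("Context: %s lattice samples (spacing %g), bandwidth %.4g\n",
              format(length(x$samples), big.mark = ","), x$spacing, x$bandwidth))
  invisible(x)
}

# Rebuild a context's smoothed master density with a different bandwidth,
# reusing the existing lattice samples (cheap: one KDE pass, no resampling).
context_with_bandwidth <- function(ctx, bandwidth) {
  lim <- max(ctx$samples) * 1.05 + 4 * bandwidth
  ctx$bandwidth <- bandwidth
  ctx$master <- kde(ctx$samples, bandwidth, seq(0, lim, length.out = 4096L))
  ctx
}

# Evaluate a context's smoothed density on an analysis support.
context_on_support <- function(ctx, support) {
  v <- approx(ctx$master$support, ctx$master$values, xout = support, rule = 2L)$y
  v[support > max(ctx$master$support)] <- 0
  density_estimate(support, v, ctx$bandwidth)
}

#' Fit a Gibbs nearest-neighbor interaction model
#'
#' The main fitting function: given a dependent point set `x` and a reference
#' set `y` sharing one region, it computes the observed NN distances, grid-
#' samples the context q(d), smooths both by kernel density estimation on a
#' shared support, and estimates the interaction potential phi(d) minimizing
#' the L2 difference between the observed density and the model density
#' q exp(-phi)/Z.
#'
#' The fitted strength epsilon is 0 for independent patterns (up to sampling
#' noise); sigma is the length scale of organization between the patterns, in
#' the units of the coordinates; the hard core t of the step shape plays the
#' role of the distance threshold of classical object-based colocalization.
#' Use [ia_test()] to assess whether a fitted interaction is significant.
#'
#' @param x dependent point set (matrix or [point_set()]).
#' @param y reference point set.
#' @param region shared [region()] for both sets; every point must lie inside.
#' @param potential a parametric shape name (see [shape_value()]) or
#'   `"nonparametric"`.
#' @param spacing context lattice spacing (ignored when `context` is given).
#' @param bandwidth KDE bandwidth for the observed distance distribution;
#'   default is Silverman's suggestion on the observed distances.
#' @param wt_p alternative weight-style smoothing for the observed
#'   distribution (see [weight_to_bandwidth()]); ignored when `bandwidth` is
#'   given.
#' @param bandwidth_q,wt_q context smoothing (see [ia_context()]).
#' @param support_points grid resolution of the shared evaluation support.
#' @param P,smoothness non-parametric potential controls (see
#'   [fit_nonparametric()]).
#' @param opts a [fit_options()] list.
#' @param context optional precomputed [ia_context()].
#' @return object of class `ia_fit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `simulate` methods.
#' @examples
#' reg <- region(c(0, 1, 0, 1))
#' y <- generate_reference(50, reg, seed = 1)
#' x <- generate_interacting(y, 200, potential("plummer", 2, 0.05), reg, seed = 2)
#' fit <- ia_fit(x, y, reg, potential = "plummer", spacing = 0.01)
#' coef(fit)
#' @export
ia_fit <- function(x, y, region, potential = "plummer", spacing = 0.5,
                   bandwidth = NULL, wt_p = NULL,
                   bandwidth_q = NULL, wt_q = 0.001,
                   support_points = 1000L, P = 11L, smoothness = 0.1,
                   opts = fit_options(), context = NULL) {
  cl <- match.call()
  x <- point_set(as_coord_matrix(x), label = "X")
  if (!all(region_contains(region, x))) stop("dependent points outside the region")
  if (is.null(context)) {
    context <- ia_context(y, region, spacing = spacing,
                          bandwidth = bandwidth_q, wt = wt_q)
  } else {
    stopifnot(inherits(context, "ia_context"))
  }
  d_obs <- nn_distances(x, context$y)
  support <- make_support(d_obs, context$samples, support_points)
  h_p <- if (!is.null(bandwidth)) bandwidth
  else if (!is.null(wt_p)) weight_to_bandwidth(wt_p, d_obs)
  else silverman_bandwidth(d_obs)
  p_hat <- kde(d_obs, h_p, support)
  q <- context_on_support(context, support)

  core <- if (identical(potential, "nonparametric")) {
    fit_nonparametric(p_hat, q, P = P, smoothness = smoothness, opts = opts)
  } else {
    fit_parametric(p_hat, q, shape = potential, opts = opts)
  }

  structure(list(potential = core$potential, residual = core$residual,
                 p_model = core$p_model, Z = core$Z, n_evals = core$n_evals,
                 seed = core$seed, p_hat = p_hat, q = q, distances = d_obs,
                 bandwidth_p = h_p, context = context, x = x,
                 n = nrow(x), m = nrow(context$y), opts = opts, call = cl),
            class = "ia_fit")
}

#' @export
print.ia_fit <- function(x, ...) {
  cat("Gibbs nearest-neighbor interaction fit\n")
  cat(sprintf("  N = %d points vs M = %d reference points\n", x$n, x$m))
  print(x$potential)
  cat(sprintf("  residual (L2) = %.4g\n", x$residual))
  invisible(x)
}

#' @rdname ia_fit
#' @param object an `ia_fit`.
#' @param ... unused.
#' @export
summary.ia_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ia_fit")
}

#' @export
print.summary.ia_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  partition function Z = %.6g\n", f$Z))
  cat(sprintf("  observed-density bandwidth = %.4g (Silverman suggestion %.4g)\n",
              f$bandwidth_p, silverman_bandwidth(f$distances)))
  cat(sprintf("  context: %s samples, bandwidth %.4g, spacing %g\n",
              format(length(f$context$samples), big.mark = ","),
              f$context$bandwidth, f$context$spacing))
  cat(sprintf("  objective evaluations: %d (seed %d)\n", f$n_evals, f$seed))
  invisible(x)
}

#' @export
coef.ia_fit <- function(object, ...) {
  pot <- object$potential
  if (inherits(pot, "parametric_potential")) {
    c(epsilon = pot$epsilon, sigma = pot$sigma, t = pot$t)
  } else {
    setNames(pot$weights, paste0("w", seq_along(pot$weights)))
  }
}

#' Predict from a fitted interaction model
#'
#' @param object an `ia_fit`.
#' @param newdata distances at which to evaluate; defaults to the fit support.
#' @param type `"density"` for the model NN-distance density p(d),
#'   `"potential"` for phi(d), `"context"` for q(d).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ia_fit <- function(object, newdata = NULL,
                           type = c("density", "potential", "context"), ...) {
  type <- match.arg(type)
  d <- if (is.null(newdata)) object$p_model$support else as.numeric(newdata)
  switch(type,
    density = approx(object$p_model$support, object$p_model$values,
                     xout = d, rule = 2L)$y,
    potential = potential_value(object$potential, d),
    context = approx(object$q$support, object$q$values, xout = d, rule = 2L)$y)
}

#' @export
fitted.ia_fit <- function(object, ...) object$p_model$values

#' @export
residuals.ia_fit <- function(object, ...) {
  object$p_hat$values - object$p_model$values
}

#' @export
plot.ia_fit <- function(x, which = c("densities", "potential"), ...) {
  which <- match.arg(which)
  if (which == "densities") {
    s <- x$p_hat$support
    ylim <- range(0, x$p_hat$values, x$q$values, x$p_model$values)
    plot(s, x$p_hat$values, type = "l", col = "blue", ylim = ylim,
         xlab = "NN distance d", ylab = "density", ...)
    lines(s, x$q$values, col = "red")
    lines(s, x$p_model$values, col = "darkgreen")
    legend("topright", c("observed", "context", "model fit"),
           col = c("blue", "red", "darkgreen"), lty = 1, bty = "n")
  } else {
    plot(x$potential, ...)
  }
  invisible(x)
}

#' Simulate point sets from a fitted interaction model
#'
#' Draws new dependent point sets of the original size from the fitted
#' potential, against the fit's reference set and region, by exact rejection
#' sampling of the Gibbs NN model.
#'
#' @param object an `ia_fit`.
#' @param nsim number of point sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `point_set`s (a single `point_set` if `nsim = 1`).
#' @export
simulate.ia_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ctx <- object$context
  sims <- with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      generate_interacting(ctx$y, object$n, object$potential, ctx$region,
                           seed = NULL)
    })
  })
  if (nsim == 1L) sims[[1L]] else sims
}
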