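#' Silverman's bandwidth suggestion
#'
#' The rule-of-thumb bandwidth h = 0.9 min(s, IQR/1.34) n^(-1/5), with s the
#' sample standard deviation. Used as the suggested smoothing for the observed
#' nearest-neighbor distance distribution.
#'
#' @param samples numeric vector with at least two distinct values.
#' @return a positive bandwidth in the units of `samples`.
#' @export
silverman_bandwidth <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L) stop("need at least two samples")
  s <- sd(samples)
  iqr <- unname(diff(quantile(samples, c(0.25, 0.75), names = FALSE)))
  h <- 0.9 * min(s, iqr / 1.34) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) stop("degenerate samples: all values identical")
  h
}

#' Map a kernel weight to a bandwidth
#'
#' Compatibility mapping for weight-style smoothing parameters: h = s (n w)^(-1/2)
#' with s the sample standard deviation and n the sample count. Larger weights
#' give smaller bandwidths, i.e. a more fine-grained, less smooth estimate; a
#' small weight on a large context sample (the default wt_q = 0.001) gives a
#' very smooth context. Passing a bandwidth directly is the recommended
#' interface; this mapping exists so weight-style configurations remain usable.
#'
#' @param weight positive smoothing weight.
#' @param samples numeric vector with at least two distinct values.
#' @return a positive bandwidth.
#' @export
weight_to_bandwidth <- function(weight, samples) {
  if (weight <= 0) stop("weight must be positive")
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L) stop("need at least two samples")
  s <- sd(samples)
  if (!is.finite(s) || s <= 0) stop("degenerate samples: all values identical")
  s * (n * weight)^(-1 / 2)
}

#' Shared evaluation support for distance densities
#'
#' A uniform grid from 0 to 1.05 times the larger of the observed maximum and
#' the 99.9th percentile of the context samples. All densities in the pipeline
#' (observed, context, model) are evaluated on this common grid so they are
#' directly comparable.
#'
#' @param observed observed NN distance samples.
#' @param context context distance samples.
#' @param n_points number of grid points (>= 50).
#' @return numeric vector: the ascending support grid, starting at 0.
#' @export
make_support <- function(observed, context, n_points = 1000L) {
  if (length(observed) == 0L || length(context) == 0L) stop("empty distance set")
  if (n_points < 50L) stop("n_points must be at least 50")
  hi <- max(max(observed), quantile(context, 0.999, names = FALSE)) * 1.05
  if (hi <= 0) hi <- 1
  seq(0, hi, length.out = n_points)
}

#' Kernel density estimate of a distance distribution
#'
#' Gaussian-kernel density estimate of nonnegative distance samples, with
#' boundary reflection at d = 0 (mass that would leak to negative distances is
#' folded back) and renormalization so the trapezoid integral over the support
#' equals 1.
#'
#' Small samples are evaluated exactly; large samples (> 5,000, e.g. the
#' lattice context) go through the FFT-binned estimator of [stats::density()]
#' before folding, which is visually and numerically indistinguishable at
#' context sample sizes.
#'
#' @param samples nonnegative distance samples.
#' @param bandwidth Gaussian kernel standard deviation (> 0).
#' @param support ascending evaluation grid; should cover
#'   `[0, max(samples) + 3 * bandwidth]`. A support that truncates more than
#'   the extreme 0.5 percent tail of the samples is an error; mass beyond the
#'   support is dropped by the renormalization.
#' @return object of class `density_estimate`: list with `support`, `values`,
#'   `bandwidth`.
#' @export
kde <- function(samples, bandwidth, support) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty samples")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (max(support) < quantile(samples, 0.995, names = FALSE)) {
    stop("support too short: must cover the sample range")
  }
  n <- length(samples)
  if (n > 5000L) {
    lim <- max(support) + 4 * bandwidth
    d <- density(samples, bw = bandwidth, from = -lim, to = lim, n = 8192L)
    f <- approx(d$x, d$y, xout = support, rule = 2L)$y +
      approx(d$x, d$y, xout = -support, rule = 2L)$y
  } else {
    # exact evaluation, chunked over the support to bound memory
    f <- numeric(length(support))
    chunk <- max(1L, floor(5e6 / n))
    for (i in seq(1L, length(support), by = chunk)) {
      j <- i:min(i + chunk - 1L, length(support))
      s <- support[j]
      f[j] <- (colSums(dnorm(outer(samples, s, "-"), sd = bandwidth)) +
                 colSums(dnorm(outer(samples, -s, "-"), sd = bandwidth))) / n
    }
  }
  density_estimate(support, f, bandwidth)
}

#' Construct (and normalize) a density estimate
#'
#' Internal constructor shared by the KDE and the model density: clamps tiny
#' negative values from numerical roundoff and renormalizes to unit trapezoid
#' integral on the support.
#'
#' @param support strictly increasing grid of distances.
#' @param values nonnegative density values at the support points.
#' @param bandwidth the bandwidth used, or NA for model densities.
#' @return object of class `density_estimate`.
#' @export
density_estimate <- function(support, values, bandwidth = NA_real_) {
  if (any(diff(support) <= 0)) stop("support must be strictly increasing")
  if (any(values < -1e-10)) stop("negative density values")
  values <- pmax(values, 0)
  z <- trapz(support, values)
  if (!is.finite(z) || z <= 0) stop("density does not integrate to a positive value")
  structure(list(support = support, values = values / z, bandwidth = bandwidth),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate on [%g, %g] (%d points), bandwidth %s\n",
              min(x$support), max(x$support), length(x$support),
              if (is.na(x$bandwidth)) "-" else format(x$bandwidth, digits = 4)))
  invisible(x)
}

#' @export
plot.density_estimate <- function(x, ...) {
  plot(x$support, x$values, type = "l", xlab = "distance d",
       ylab = "density", ...)
  invisible(x)
}
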