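# Shared fixtures and independent oracles, built in code at test time.

unit_square <- function() region(c(0, 1, 0, 1))

# All-pairs brute-force nearest-neighbor oracle (quadratic, small n only).
brute_force_nn <- function(x, y) {
  x <- unclass(x); y <- unclass(y)
  apply(x, 1L, function(p) {
    sqrt(min(colSums((t(y) - p)^2)))
  })
}

# Independent L2 objective via the R-level model route (used to cross-check
# the compiled fitting objective and as the grid-scan oracle).
grid_scan_min <- function(p_hat, q, shape, n = 50L) {
  box <- nngibbs:::param_box(shape, q$support)
  g1 <- seq(box$lo[1L], box$hi[1L], length.out = n)
  g2 <- seq(box$lo[2L], box$hi[2L], length.out = n)
  best <- Inf
  for (a in g1) {
    for (b in g2) {
      pot <- nngibbs:::theta_to_potential(shape, c(a, b))
      val <- l2_objective(p_hat, model_pdf(q, pot))
      if (val < best) best <- val
    }
  }
  best
}

# Trapezoid integral of a density estimate (independent of package internals).
trapz_int <- function(d) {
  n <- length(d$support)
  sum(diff(d$support) * (d$values[-1] + d$values[-n])) / 2
}

# Lightweight fit options used where many fits are run.
light_opts <- function(statistic = "epsilon") {
  fit_options(restarts = 1L, grid_n = 8L, maxit = 200L, tol = 1e-7,
              statistic = statistic)
}

# Blob-image fixture: 50 blobs with jittered sub-pixel centers on a grid,
# minimum separation well above 4 * radius.
blob_fixture <- function(n_side = 8, sep = 16, radius = 3, snr = 10,
                         seed = 123) {
  centers <- as.matrix(expand.grid(seq(10, by = sep, length.out = n_side),
                                   seq(10, by = sep, length.out = n_side)))
  set.seed(seed)
  centers <- centers + matrix(runif(length(centers), -0.45, 0.45), ncol = 2)
  keep <- sample(nrow(centers), 50)
  centers <- centers[keep, , drop = FALSE]
  size <- rep(10 + sep * n_side, 2)
  list(centers = centers,
       img = generate_blob_image(centers, radius, snr, size, seed = seed + 1))
}

match_detections <- function(det, truth, tol = 2) {
  d <- nn_distances(truth, det$points)
  back <- nn_distances(det$points, truth)
  list(recall = mean(d < tol), spurious = sum(back >= tol), errors = d[d < tol])
}

# A smooth context/observed density pair on a shared support, for unit tests
# that need valid densities without running the full pipeline.
toy_densities <- function(seed = 7L, n_obs = 400L, pot = NULL) {
  set.seed(seed)
  reg <- unit_square()
  y <- generate_reference(50L, reg, seed = seed)
  ctx <- sample_context(y, reg, spacing = 0.02)
  x <- if (is.null(pot)) generate_reference(n_obs, reg, seed = seed + 1L)
  else generate_interacting(y, n_obs, pot, reg, seed = seed + 1L)
  d <- nn_distances(x, y)
  s <- make_support(d, ctx, 400L)
  list(q = kde(ctx, weight_to_bandwidth(0.001, ctx), s),
       p_hat = kde(d, silverman_bandwidth(d), s),
       support = s, y = y, region = reg)
}
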