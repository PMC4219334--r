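test_that("model density reduces to the context when the strength is zero", {
  td <- toy_densities()
  for (sh in potential_shape_names()) {
    p <- model_pdf(td$q, potential(sh, epsilon = 0, sigma = 0.05, t = 0.02))
    expect_lt(max(abs(p$values - td$q$values)), 1e-12)
  }
})

test_that("a step potential rescales the density piecewise by exp(epsilon)", {
  td <- toy_densities()
  cpt <- 0.05
  p <- model_pdf(td$q, potential("step", epsilon = log(2), t = cpt))
  ratio <- p$values / td$q$values
  below <- td$support < cpt - 1e-9 & td$q$values > 1e-8
  above <- td$support > cpt + 1e-9 & td$q$values > 1e-8
  # p/q is piecewise constant with a 2:1 ratio between the two sides
  expect_lt(diff(range(ratio[below])), 1e-9)
  expect_lt(diff(range(ratio[above])), 1e-9)
  expect_equal(mean(ratio[below]) / mean(ratio[above]), 2, tolerance = 1e-9)
})

test_that("model densities are normalized and renormalization is idempotent", {
  td <- toy_densities()
  pot <- potential("hernquist", 1.5, sigma = 0.03)
  p <- model_pdf(td$q, pot)
  expect_equal(trapz_int(p), 1, tolerance = 1e-3)
  p2 <- density_estimate(p$support, p$values)
  expect_equal(p2$values, p$values, tolerance = 1e-12)
  expect_gt(attr(p, "Z"), 1)  # attraction inflates the unnormalized mass
})

test_that("l2 objective is a symmetric squared distance with exact arithmetic", {
  s <- c(0, 1, 2)
  a <- density_estimate(s, c(1, 1, 1))   # uniform on [0,2] -> 0.5 each
  b <- density_estimate(s, c(2, 1, 1))   # -> c(0.8, 0.4, 0.4)
  expect_equal(l2_objective(a, a), 0)
  expect_equal(l2_objective(a, b), l2_objective(b, a))
  expect_equal(l2_objective(a, b), sum((a$values - b$values)^2) * 1)
  expect_equal(l2_objective(a, b), (0.3^2 + 0.1^2 + 0.1^2))
  expect_error(l2_objective(a, density_estimate(c(0, 1.1, 2.2), c(1, 1, 1))),
               "support mismatch")
})

test_that("compiled objective agrees with the R-level model route", {
  td <- toy_densities()
  dd <- td$support[2] - td$support[1]
  for (sh in potential_shape_names()) {
    box <- nngibbs:::param_box(sh, td$support)
    set.seed(21)
    for (k in 1:5) {
      theta <- box$lo + runif(2) * (box$hi - box$lo)
      via_cpp <- nngibbs:::.ia_objective_cpp(theta, match(sh, potential_shape_names()) - 1L,
                                             sh == "step", td$support, td$q$values,
                                             td$p_hat$values, dd, box$lo, box$hi)
      pot <- nngibbs:::theta_to_potential(sh, theta)
      via_r <- l2_objective(td$p_hat, model_pdf(td$q, pot))
      expect_equal(via_cpp, via_r, tolerance = 1e-9, info = sh)
    }
  }
})

test_that("fitting inverts an exactly model-generated density", {
  td <- toy_densities(seed = 30)
  truth <- potential("plummer", 2, 0.04)
  p_hat <- model_pdf(td$q, truth)
  fit <- fit_parametric(p_hat, td$q, "plummer")
  expect_equal(fit$potential$epsilon, 2, tolerance = 0.01)
  expect_equal(fit$potential$sigma, 0.04, tolerance = 0.01)
  expect_lt(fit$residual, 1e-8)
  # the recorded residual is the objective recomputed from the potential
  expect_equal(fit$residual, l2_objective(p_hat, model_pdf(td$q, fit$potential)),
               tolerance = 1e-9)
})

test_that("fitting the context against itself finds no interaction", {
  td <- toy_densities(seed = 31)
  for (sh in potential_shape_names()) {
    fit <- fit_parametric(td$q, td$q, sh)
    expect_lte(fit$potential$epsilon, 1e-3)
  }
})

test_that("fitted residual never exceeds the 50x50 grid-scan minimum", {
  td1 <- toy_densities(seed = 32, pot = potential("plummer", 1.5, 0.05))
  td2 <- toy_densities(seed = 33)
  cases <- list(list(td = td1, shape = "plummer"),
                list(td = td1, shape = "step"),
                list(td = td2, shape = "hernquist"))
  for (cs in cases) {
    fit <- fit_parametric(cs$td$p_hat, cs$td$q, cs$shape)
    oracle <- grid_scan_min(cs$td$p_hat, cs$td$q, cs$shape)
    expect_lte(fit$residual, oracle + 1e-12, label = cs$shape)
  }
})

test_that("non-parametric fit is null on the context and flattens under heavy smoothing", {
  td <- toy_densities(seed = 34)
  fit0 <- fit_nonparametric(td$q, td$q, P = 8, smoothness = 0.01)
  expect_lt(max(abs(fit0$potential$weights)), 0.05)

  tda <- toy_densities(seed = 35, pot = potential("plummer", 2, 0.05))
  lo <- fit_nonparametric(tda$p_hat, tda$q, P = 10, smoothness = 1e-4)
  hi <- fit_nonparametric(tda$p_hat, tda$q, P = 10, smoothness = 1e3)
  expect_lt(sum(diff(hi$potential$weights)^2),
            sum(diff(lo$potential$weights)^2))
  expect_lt(max(abs(diff(hi$potential$weights))), 0.05)
})

test_that("non-parametric fit recovers a step-shaped well", {
  reg <- unit_square()
  y <- generate_reference(100, reg, seed = 40)
  truth <- potential("step", epsilon = 1, t = 0.06)
  x <- generate_interacting(y, 3000, truth, reg, seed = 41)
  d <- nn_distances(x, y)
  ctx <- sample_context(y, reg, 0.005)
  s <- make_support(d, ctx, 500)
  q <- kde(ctx, weight_to_bandwidth(0.001, ctx), s)
  p_hat <- kde(d, silverman_bandwidth(d), s)
  fit <- fit_nonparametric(p_hat, q, P = 13, smoothness = 1e-3)
  w <- fit$potential$weights
  pos <- fit$potential$positions
  inside <- pos < 0.75 * 0.06
  outside <- pos > 2 * 0.06
  expect_lt(max(abs(w[inside] - (-1))), 0.25)
  expect_lt(max(abs(w[outside])), 0.25)
})

test_that("strength estimated on independent data stays near zero", {
  # step-shape fit with matched observed/context bandwidths: the setting in
  # which spurious strength on null data is smallest (see the methods
  # vignette on bandwidth matching and the weak identifiability of epsilon
  # in the large-sigma limit of smooth shapes)
  reg <- unit_square()
  y <- generate_reference(100, reg, seed = 50)
  ctx <- ia_context(y, reg, spacing = 1 / 128, bandwidth = 0.02)
  eps_hat <- vapply(1:100, function(k) {
    x <- generate_reference(2000, reg, seed = 1000 + k)
    fit <- ia_fit(x, y, reg, potential = "step", context = ctx,
                  support_points = 256, bandwidth = 0.02, opts = light_opts())
    fit$potential$epsilon
  }, numeric(1))
  expect_gte(mean(eps_hat <= 0.1), 0.95)
})
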