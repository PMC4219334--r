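test_that("uniform reference generation is uniform, bounded and reproducible", {
  reg <- region(c(0, 10, 0, 5))
  one <- generate_reference(1, reg, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(nngibbs:::region_contains(reg, one))

  big <- generate_reference(1e4, unit_square(), seed = 2)
  expect_true(all(colMeans(big) > 0.48 & colMeans(big) < 0.52))

  expect_identical(unclass(generate_reference(50, reg, seed = 3)),
                   unclass(generate_reference(50, reg, seed = 3)))
  expect_error(generate_reference(0, reg), "at least 1")
})

test_that("zero-strength generation is indistinguishable from uniform placement", {
  reg <- unit_square()
  y <- generate_reference(80, reg, seed = 10)
  x <- generate_interacting(y, 2000, potential("plummer", 0, 0.05), reg, seed = 11)
  d_gen <- nn_distances(x, y)
  # independent oracle: NN distances of fresh uniform points
  u <- generate_reference(2000, reg, seed = 12)
  d_unif <- nn_distances(u, y)
  ks <- suppressWarnings(ks.test(d_gen, d_unif))
  expect_gt(ks$p.value, 0.01)
})

test_that("step-potential generation reweights the colocalized fraction as predicted", {
  reg <- unit_square()
  y <- generate_reference(80, reg, seed = 20)
  cpt <- 0.06
  n <- 4000
  x <- generate_interacting(y, n, potential("step", log(2), t = cpt), reg, seed = 21)
  frac <- mean(nn_distances(x, y) < cpt)
  # context probability of d < cpt from a large independent uniform sample
  u <- generate_reference(4e4, reg, seed = 22)
  a <- mean(nn_distances(u, y) < cpt)
  expected <- 2 * a / (2 * a + (1 - a))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se + 3 * sqrt(a * (1 - a) / 4e4))
})

test_that("generated distance distributions match the model density for every shape", {
  # oracle without any smoothing: under the model, the probability of a
  # distance bin is the exp(-phi)-reweighted context measure of that bin;
  # the context measure is taken directly from the lattice samples
  reg <- unit_square()
  y <- generate_reference(80, reg, seed = 30)
  ctx <- sample_context(y, reg, 0.005)
  bw <- 0.01
  breaks <- seq(0, max(ctx) + 2 * bw, by = bw)
  for (sh in potential_shape_names()) {
    pot <- if (sh == "step") potential(sh, 1.5, t = 0.05)
    else potential(sh, 1.5, sigma = 0.05)
    x <- generate_interacting(y, 2e4, pot, reg, seed = 31)
    d <- nn_distances(x, y)
    gen_dens <- hist(d, breaks = breaks, plot = FALSE)$density
    wts <- exp(-potential_value(pot, ctx))
    bin <- findInterval(ctx, breaks, rightmost.closed = TRUE)
    model_prob <- vapply(seq_len(length(breaks) - 1L),
                         function(b) sum(wts[bin == b]), numeric(1)) / sum(wts)
    model_dens <- model_prob / bw
    expect_lt(max(abs(gen_dens - model_dens)),
              0.05 * max(model_dens), label = sh)
  }
})

test_that("an over-deep potential aborts with an acceptance-rate diagnostic", {
  reg <- unit_square()
  y <- generate_reference(20, reg, seed = 40)
  # a 12-deep well confined to a sliver of the region: nearly every uniform
  # proposal lands where exp(-(phi - phi_min)) = exp(-12)
  pot <- nonparametric_potential(c(0, 5e-4, 1e-3), c(-12, -12, 0))
  expect_error(generate_interacting(y, 50, pot, reg, seed = 41),
               "acceptance rate")
})

test_that("blob images render noise, signal and reproduce under a seed", {
  pure_noise <- generate_blob_image(NULL, 3, 10, c(32, 32), seed = 1)
  expect_equal(dim(pure_noise), c(32L, 32L))
  expect_lt(abs(mean(pure_noise)), 0.01)
  expect_equal(sd(pure_noise), 0.1, tolerance = 0.1)

  again <- generate_blob_image(NULL, 3, 10, c(32, 32), seed = 1)
  expect_identical(pure_noise, again)

  clean <- generate_blob_image(rbind(c(10.5, 20.25)), 3, Inf, c(40, 40))
  # unit peak amplitude, sampled at the nearest pixel of a sub-pixel center
  expect_true(max(clean) > 0.9 && max(clean) <= 1)
  expect_error(generate_blob_image(rbind(c(50, 10)), 3, Inf, c(40, 40)),
               "inside the image")
})

test_that("a noise-free blob is recovered at sub-pixel accuracy end to end", {
  truth <- rbind(c(10.5, 20.25))
  img <- generate_blob_image(truth, 3, Inf, c(40, 40))
  det <- detect_spots(img, radius = 4, percentile = 5)
  expect_equal(nrow(det$points), 1L)
  expect_lt(sqrt(sum((det$points[1, ] - truth)^2)), 0.1)
})
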