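test_that("nn_distances handles identity and simple geometric cases", {
  set.seed(1)
  x <- point_set(matrix(runif(40), ncol = 2))
  expect_equal(nn_distances(x, x), rep(0, 20))

  expect_equal(nn_distances(rbind(c(0, 0)), rbind(c(3, 4), c(10, 10))), 5)

  expect_error(nn_distances(matrix(runif(6), ncol = 3),
                            matrix(runif(4), ncol = 2)),
               "dimension mismatch")
  expect_error(nn_distances(matrix(runif(4), ncol = 2),
                            matrix(numeric(0), ncol = 2)),
               "empty reference")
})

test_that("kd-tree distances agree exactly with the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    dim <- if (seed %% 2 == 0) 3L else 2L
    n <- sample(50:500, 1)
    m <- sample(50:500, 1)
    x <- matrix(runif(n * dim, -5, 20), ncol = dim)
    y <- matrix(runif(m * dim, -5, 20), ncol = dim)
    expect_equal(nn_distances(x, y), brute_force_nn(x, y), tolerance = 1e-12)
  }
})

test_that("lattice_points counts, anchoring and mask semantics", {
  reg <- unit_square()
  lat <- lattice_points(reg, 0.5)
  expect_equal(nrow(lat), 9L)
  expect_setequal(unique(lat[, 1]), c(0, 0.5, 1))

  # a 400-pixel image axis spans [0, 399]; spacing 0.5 gives 799 per axis
  big <- region(c(0, 399, 0, 399))
  ax <- seq(0, 399, by = 0.5)
  expect_length(ax, 799L)
  expect_equal(nrow(lattice_points(big, 0.5)), 799L^2)

  mask <- matrix(FALSE, 3, 3)
  mask[1:2, ] <- TRUE  # cells at x = 0, 0.5 admissible
  regm <- region(c(0, 1, 0, 1), mask = mask, cell_size = 0.5)
  latm <- lattice_points(regm, 0.5)
  expect_true(all(latm[, 1] <= 0.5))
  expect_equal(nrow(latm), 6L)

  expect_error(lattice_points(reg, 0), "positive")
  expect_error(lattice_points(reg, 1.5), "extent")
  expect_error(region(c(0, 1, 0, 1), mask = matrix(FALSE, 3, 3), cell_size = 0.5),
               "empty admissible")
})

test_that("sample_context distances and invariances", {
  reg <- unit_square()
  lat <- lattice_points(reg, 0.25)
  expect_equal(sample_context(lat, reg, 0.25), rep(0, nrow(lat)))

  set.seed(3)
  y <- matrix(runif(60), ncol = 2)
  d1 <- sample_context(y, reg, 0.1)
  d2 <- sample_context(y[sample(30), ], reg, 0.1)
  expect_equal(d1, d2)

  full_mask <- matrix(TRUE, 11, 11)
  regm <- region(c(0, 1, 0, 1), mask = full_mask, cell_size = 0.1)
  expect_equal(sample_context(y, regm, 0.1), d1)
})

test_that("context of a central point matches the analytic distance law", {
  # reference = center of the unit square; the context CDF must match the
  # distribution of distance-to-center of a uniform point, computed here by
  # fine numerical integration over the square
  reg <- unit_square()
  ctx <- sample_context(rbind(c(0.5, 0.5)), reg, 0.01)
  u <- seq(0.0005, 0.9995, by = 0.001)
  gg <- expand.grid(u, u)
  r_all <- sqrt((gg[, 1] - 0.5)^2 + (gg[, 2] - 0.5)^2)
  dd <- seq(0, sqrt(0.5), length.out = 200)
  cdf_true <- vapply(dd, function(d) mean(r_all <= d), numeric(1))
  cdf_emp <- vapply(dd, function(d) mean(ctx <= d), numeric(1))
  expect_lt(max(abs(cdf_true - cdf_emp)), 0.02)
})

test_that("context estimate converges under lattice refinement", {
  set.seed(9)
  y <- matrix(runif(40), ncol = 2)
  reg <- unit_square()
  ctxs <- lapply(c(0.04, 0.02, 0.01), function(sp) sample_context(y, reg, sp))
  s <- seq(0, max(unlist(ctxs)) + 0.05, length.out = 300)
  qs <- lapply(ctxs, function(ctx) kde(ctx, 0.01, s)$values)
  d12 <- max(abs(qs[[1]] - qs[[2]]))
  d23 <- max(abs(qs[[2]] - qs[[3]]))
  expect_lt(d23, d12)
})

test_that("point_set and region validate their invariants", {
  expect_error(point_set(matrix(numeric(0), ncol = 2)), "at least one")
  expect_error(point_set(matrix(1, 1, 4)), "2D or 3D")
  expect_error(region(c(1, 0, 0, 1)), "exceed")
  reg <- region(c(0, 10, 0, 5))
  expect_true(all(nngibbs:::region_contains(reg, rbind(c(0, 0), c(10, 5)))))
  expect_false(nngibbs:::region_contains(reg, rbind(c(11, 1))))
})
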