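test_that("kNN pseudotime map interpolates exactly in degenerate cases", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))
  map1 <- fit_pseudotime_map(coords, pseudotime = c(0, 0.5, 1), k = 1)
  expect_equal(predict(map1, rbind(c(1, 0))), 0.5)

  map2 <- fit_pseudotime_map(rbind(c(0, 0), c(2, 0)),
                             pseudotime = c(0, 1), k = 2)
  expect_equal(predict(map2, rbind(c(1, 0))), 0.5)

  expect_error(fit_pseudotime_map(coords, pseudotime = c(0, 0.5, 1), k = 9),
               "k")
})

test_that("map predictions on a linear manifold explain held-out pseudotime", {
  set.seed(1)
  x <- runif(200, 0, 10)
  coords <- cbind(x, rnorm(200, sd = 0.01))
  pt <- 0.1 * x
  train <- 1:150
  map <- fit_pseudotime_map(coords[train, ], pseudotime = pt[train], k = 5)
  pred <- predict(map, coords[-train, ])
  r2 <- 1 - sum((pred - pt[-train])^2) / sum((pt[-train] - mean(pt[-train]))^2)
  expect_gte(r2, 0.96)
  # predictions bounded by the reference pseudotime range (uniform weights)
  expect_true(all(pred >= min(pt[train]) & pred <= max(pt[train])))
})

test_that("delta pseudotime follows the velocity direction on a linear manifold", {
  set.seed(2)
  n <- 200
  x <- sort(runif(n, 0, 10))
  coords <- cbind(x, 0)
  pt <- x / 10
  map <- fit_pseudotime_map(coords, pseudotime = pt, k = 5)

  # with k = 1 the map is exact at reference points, so zero velocity
  # gives exactly zero change in pseudotime
  map1 <- fit_pseudotime_map(coords, pseudotime = pt, k = 1)
  zero <- delta_pseudotime(coords, matrix(0, n, 2), map1, pt)
  expect_equal(zero$delta_p, rep(0, n))

  fwd <- delta_pseudotime(coords, cbind(rep(0.5, n), 0), map, pt)
  interior <- x > 1 & x < 9
  expect_true(all(fwd$delta_p[interior] > 0))

  bwd <- delta_pseudotime(coords, cbind(rep(-0.5, n), 0), map, pt)
  expect_true(all(bwd$delta_p[interior] < 0))
})

test_that("lineage regression classification matches the worked example", {
  lr <- classify_lineage_regression(c(-2, 0, 2))
  expect_equal(lr$sd, 2)
  expect_equal(lr$threshold, -1)
  expect_equal(lr$mask, c(TRUE, FALSE, FALSE))
  expect_equal(lr$fraction, 1 / 3)

  expect_equal(classify_lineage_regression(c(0.1, 0.5, 2, 1))$fraction, 0)
  expect_warning(res <- classify_lineage_regression(rep(1, 5)), "constant")
  expect_equal(res$fraction, 0)
})

test_that("regressing fraction is invariant under affine pseudotime rescaling", {
  set.seed(3)
  dp <- rnorm(500)
  a <- classify_lineage_regression(dp)
  b <- classify_lineage_regression(dp * 37.5)
  expect_identical(a$mask, b$mask)
  expect_equal(a$fraction, b$fraction)
})

test_that("the regressing-frequency curve reports binwise fractions", {
  set.seed(4)
  pt <- runif(1000)
  dp <- rnorm(1000) - 2 * (pt > 0.5)   # more regression late
  lr <- classify_lineage_regression(dp, pseudotime = pt, n_bins = 10)
  cv <- lr$curve
  expect_equal(nrow(cv), 10)
  expect_true(all(cv$fraction >= 0 & cv$fraction <= 1, na.rm = TRUE))
  expect_gt(mean(cv$fraction[cv$bin_center > 0.5]),
            mean(cv$fraction[cv$bin_center < 0.5]))
})

test_that("phase points stand still in a zero field and translate in a uniform one", {
  set.seed(5)
  cells <- matrix(runif(100, -1, 1), 50, 2)
  zero <- simulate_phase_points(cells, matrix(0, 50, 2), n_points = 10,
                                n_steps = 50, velocity_scale = 1, seed = 1)
  expect_equal(zero$terminal, zero$init, ignore_attr = TRUE)

  unif <- simulate_phase_points(cells, cbind(rep(1, 50), 0), n_points = 10,
                                n_steps = 100, step_size = 0.01,
                                velocity_scale = 1, seed = 2)
  expect_equal(unif$terminal[, 1] - unif$init[, 1], rep(1, 10), tolerance = 1e-12)
  expect_equal(unif$terminal[, 2], unif$init[, 2], tolerance = 1e-12)
})

test_that("a linear inward field contracts phase points onto the origin", {
  g <- seq(-1, 1, length.out = 63)
  cells <- as.matrix(expand.grid(g, g))      # dense symmetric grid
  sim <- simulate_phase_points(cells, -cells, n_points = 50, n_steps = 5000,
                               step_size = 0.01, velocity_scale = 1, seed = 3)
  expect_lt(max(sqrt(rowSums(sim$terminal^2))), 1e-3)
})

test_that("phase simulations are bit-reproducible given a seed", {
  set.seed(7)
  cells <- matrix(rnorm(200), 100, 2)
  v <- matrix(rnorm(200, sd = 0.1), 100, 2)
  a <- simulate_phase_points(cells, v, n_points = 20, n_steps = 100,
                             noise_sd = 0.05, seed = 11)
  b <- simulate_phase_points(cells, v, n_points = 20, n_steps = 100,
                             noise_sd = 0.05, seed = 11)
  expect_identical(a$terminal, b$terminal)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("progression comparison is exact for identical and trivial fields", {
  set.seed(8)
  cells <- cbind(runif(200, 0, 10), rnorm(200, sd = 0.1))
  v <- cbind(rep(1, 200), 0)
  map <- fit_pseudotime_map(cells, pseudotime = cells[, 1] / 10, k = 5)
  init <- cells[1:30, ]
  a <- simulate_phase_points(cells, v, init = init, n_steps = 200,
                             step_size = 0.01, velocity_scale = 1, seed = 1)
  b <- simulate_phase_points(cells, v, init = init, n_steps = 200,
                             step_size = 0.01, velocity_scale = 1, seed = 2)
  cp <- compare_progression(a, b, map)
  expect_equal(cp$curves$mean_pt_a, cp$curves$mean_pt_b)
  expect_equal(cp$terminal_centroid_distance, 0, tolerance = 1e-12)

  z <- simulate_phase_points(cells, 0 * v, init = init, n_steps = 200,
                             step_size = 0.01, velocity_scale = 1, seed = 3)
  cpz <- compare_progression(a, z, map)
  expect_equal(cpz$curves$mean_pt_b, rep(cpz$curves$mean_pt_b[1], nrow(cpz$curves)))
})

test_that("a half-strength field lags early and converges to the same attractor", {
  # 1-D contraction toward x = 8: explicit-Euler oracle
  set.seed(9)
  n <- 400
  x <- runif(n, 0, 10)
  cells <- cbind(x, 0)
  v_full <- cbind(pmin(8 - x, 2), 0) / 2
  map <- fit_pseudotime_map(cells, pseudotime = x / 10, k = 5)
  init <- cells[x < 2, ][1:40, ]
  a <- simulate_phase_points(cells, v_full, init = init, n_steps = 1500,
                             step_size = 0.02, velocity_scale = 1, seed = 1)
  b <- simulate_phase_points(cells, v_full * 0.5, init = init, n_steps = 1500,
                             step_size = 0.02, velocity_scale = 1, seed = 2)
  cp <- compare_progression(a, b, map)
  early <- cp$curves[cp$curves$step > 0 & cp$curves$step <= 300, ]
  expect_true(all(early$mean_pt_a > early$mean_pt_b))
  expect_lt(cp$terminal_centroid_distance, 0.05)
})

test_that("velocity differences by direction match brute-force recomputation", {
  expect_error(velocity_difference_by_direction(matrix(1, 2, 4),
                                                rep(FALSE, 4)), "non-empty")
  vg <- rbind(g1 = c(1, 1, -1, -1), g2 = c(0, 0, 0, 0))
  res <- velocity_difference_by_direction(vg, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$difference[res$gene_id == "g1"], 2, ignore_attr = TRUE)
  expect_equal(res$rank[res$gene_id == "g1"], 1, ignore_attr = TRUE)

  set.seed(10)
  vg <- matrix(rnorm(300), 30, 10,
               dimnames = list(paste0("g", 1:30), NULL))
  mask <- c(rep(TRUE, 4), rep(FALSE, 6))
  res <- velocity_difference_by_direction(vg, mask)
  brute <- rowMeans(vg[, !mask]) - rowMeans(vg[, mask])
  expect_equal(res$difference[match(names(brute), res$gene_id)],
               unname(brute), tolerance = 1e-12)

  same <- velocity_difference_by_direction(cbind(vg, vg),
                                           rep(c(TRUE, FALSE), each = 10))
  expect_equal(max(abs(same$difference)), 0, tolerance = 1e-12)
})

test_that("primitive initialization samples the early activated region", {
  set.seed(11)
  coords <- cbind(runif(100, 0, 10), 0)
  pt <- coords[, 1] / 10
  act <- coords[, 1] > 3
  init <- primitive_init(coords, pt, act, n_points = 50, seed = 1)
  lim <- quantile(pt[act], 0.25)
  expect_true(all(init[, 1] / 10 <= lim))
  expect_error(primitive_init(coords, pt, rep(FALSE, 100)), "empty")
})
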