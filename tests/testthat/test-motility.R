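test_that("feature extraction matches hand computation on canonical tracks", {
  f <- extract_features(line_track(10), window_h = NULL)
  expect_equal(f$total_distance, 9)
  expect_equal(f$net_distance, 9)
  expect_equal(f$net_total_ratio, 1)
  expect_equal(f$linearity, 1)
  expect_equal(f$mean_speed, 1 / 6.5)
  expect_equal(f$mean_turn_angle_cos, 1)
  expect_equal(f$progressivity, 1)

  s <- extract_features(stationary_track(), window_h = NULL)
  expect_equal(s$total_distance, 0)
  expect_equal(s$mean_speed, 0)
  expect_equal(s$max_speed, 0)
  expect_equal(s$net_total_ratio, 0)
  expect_equal(s$linearity, 0)

  q <- extract_features(square_track(), window_h = NULL)
  expect_equal(q$net_distance, 0)
  expect_equal(q$total_distance, 4)
})

test_that("features are invariant to translation and rotation (except linearity)", {
  set.seed(9)
  steps <- matrix(rnorm(40), 20, 2)
  xy <- apply(steps, 2, cumsum)
  tr0 <- tibble::tibble(cell_id = "c", frame = 0:19, x_um = xy[, 1], y_um = xy[, 2])
  theta <- 0.7
  rot <- xy %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  tr1 <- tibble::tibble(cell_id = "c", frame = 0:19,
                        x_um = rot[, 1] + 100, y_um = rot[, 2] - 50)
  f0 <- extract_features(tr0, window_h = NULL)
  f1 <- extract_features(tr1, window_h = NULL)
  keep <- setdiff(names(f0), c("cell_id", "linearity"))
  expect_equal(as.numeric(f0[keep][1, ]), as.numeric(f1[keep][1, ]),
               tolerance = 1e-10)
})

test_that("tracks shorter than the window are excluded with a message", {
  long <- line_track(400, "long")   # 400 frames at 6.5 min ~ 43 h
  short <- line_track(5, "short")
  expect_message(f <- extract_features(dplyr::bind_rows(long, short)),
                 "excluded")
  expect_identical(f$cell_id, "long")
})

test_that("behavior clustering recovers separated states and orders by speed", {
  set.seed(4)
  slow <- simulate_tracks(n_cells = 40, duration_h = 40, p_on_start = 0,
                          p_on_end = 0, init_state = "immotile", seed = 1)$tracks
  fast <- simulate_tracks(n_cells = 40, duration_h = 40, p_on_start = 1,
                          p_on_end = 1, p_off = 0, init_state = "motile",
                          speed_mean = 4, group = "fast", seed = 2)$tracks
  f <- extract_features(dplyr::bind_rows(slow, fast))
  cl <- cluster_behavior(f, k = 2)
  truth <- ifelse(grepl("fast", cl$cell_id), 2, 1)
  expect_equal(cl$cluster, truth)   # cluster 1 = least motile by convention

  # every cell its own cluster at k = n
  cl_n <- cluster_behavior(f, k = nrow(f))
  expect_equal(length(unique(cl_n$cluster)), nrow(f))

  # duplicate rows get identical labels
  f2 <- dplyr::bind_rows(f, dplyr::mutate(f[1, ], cell_id = "dup"))
  cl2 <- cluster_behavior(f2, k = 3)
  expect_equal(cl2$cluster[cl2$cell_id == "dup"],
               cl2$cluster[cl2$cell_id == f$cell_id[1]])

  expect_error(cluster_behavior(f, k = 1), "k")
})

test_that("transition magnitude matches hand-computed mean-vector norms", {
  expect_equal(transition_magnitude(rbind(c(1, 0), c(-1, 0)))$magnitude, 0)
  expect_equal(transition_magnitude(matrix(1, 5, 2))$magnitude, sqrt(2))
  m <- transition_magnitude(rbind(c(2, 0), c(0, 2), c(2, 2), c(0, 0)))
  expect_equal(m$magnitude, sqrt(2))
  expect_true(m$ci_lo <= m$magnitude && m$magnitude <= m$ci_hi)
  expect_error(transition_magnitude(matrix(1, 1, 2)), "2 cells")
})

test_that("detailed-balanced transitions always cancel", {
  set.seed(5)
  for (i in 1:5) {
    v <- matrix(rnorm(20), 10, 2)
    paired <- rbind(v, -v)
    expect_equal(transition_magnitude(paired)$magnitude, 0, tolerance = 1e-12)
  }
})

test_that("state preference chi-squared matches the textbook 2x2 value", {
  cluster <- rep(c(1, 2, 1, 2), c(70, 30, 30, 70))
  age <- rep(c("young", "aged"), each = 100)
  res <- state_preference_test(cluster, age)
  expect_equal(res$statistic, 32)    # sum((O-E)^2/E) with E = 50
  expect_equal(res$df, 1)
  expect_equal(res$method, "chisq")

  flat <- state_preference_test(rep(1:2, 100), rep(c("a", "b"), each = 100))
  expect_lt(flat$statistic, 1e-10)
  expect_gt(flat$p_value, 0.99)
})

test_that("logistic adjustment for a covariate reports an age effect", {
  set.seed(6)
  n <- 400
  age <- rep(c("young", "aged"), each = n / 2)
  lrc <- sample(c("LRC", "nonLRC"), n, replace = TRUE)
  cluster <- ifelse(runif(n) < ifelse(age == "aged", 0.7, 0.3), 1, 2)
  res <- state_preference_test(cluster, age, covariate = lrc)
  expect_true(is.finite(res$age_coef))
  expect_lt(res$age_p_adjusted_for_covariate, 0.001)
})

test_that("permuted age labels give uniform-ish preference p-values", {
  set.seed(7)
  cluster <- sample(1:3, 300, replace = TRUE)
  ps <- replicate(40, {
    state_preference_test(cluster, sample(rep(c("a", "b"), each = 150)))$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("behavior space transitions respond to an activation ramp", {
  yo <- simulate_tracks(n_cells = 120, p_on_start = 0.01, p_on_end = 0.12,
                        p_off = 0.06, group = "young", seed = 11)$tracks
  bs <- behavior_space(yo)
  expect_equal(dim(bs$transitions), c(length(bs$cell_id), 2))
  mag <- transition_magnitude(bs, seed = 1)
  expect_gt(mag$magnitude, 0)
})
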