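test_that("DE filters exclude weak-effect and rarely detected genes", {
  set.seed(1)
  n <- 20
  a <- rbind(weak = rnorm(n, 0.10), rare = c(rexp(1), rep(0, n - 1)),
             strong = rnorm(n, 2))
  b <- rbind(weak = rnorm(n, 0.00), rare = c(rexp(1), rep(0, n - 1)),
             strong = rnorm(n, 0))
  a["weak", ] <- a["weak", ] - mean(a["weak", ]) + 0.10  # |lfc| exactly 0.10
  b["weak", ] <- b["weak", ] - mean(b["weak", ])
  res <- rank_sum_de(a, b)
  expect_false(res$tested[res$gene_id == "weak"])
  expect_false(res$tested[res$gene_id == "rare"])   # 5% detection
  expect_true(res$tested[res$gene_id == "strong"])
  # Bonferroni over genes actually tested
  m <- sum(res$tested)
  expect_equal(res$p_bonferroni, pmin(1, res$p_value * m))
})

test_that("fully separated 6 vs 6 groups give the exact rank-sum p-value", {
  a <- matrix(7:12, 1, 6, dimnames = list("g", NULL))
  b <- matrix(1:6, 1, 6, dimnames = list("g", NULL))
  res <- rank_sum_de(a, b)
  expect_equal(res$p_value, 2 / choose(12, 6))   # = 1/462 ~ 0.00216
  expect_equal(res$p_value, 0.00216, tolerance = 1e-2)
})

test_that("a constant tested gene is flagged with p = 1", {
  a <- matrix(5, 1, 10); b <- matrix(5, 1, 10)
  rownames(a) <- rownames(b) <- "g"
  res <- rank_sum_de(a, b, min_lfc = 0)
  expect_equal(res$flag, "constant")
  expect_equal(res$p_value, 1)
})

test_that("permuted-label null data yield no Bonferroni discoveries", {
  set.seed(2)
  hits <- replicate(5, {
    x <- matrix(rpois(400 * 60, 3), 400, 60)
    rownames(x) <- paste0("g", 1:400)
    lab <- sample(rep(c(TRUE, FALSE), 30))
    res <- rank_sum_de(log1p(x[, lab]), log1p(x[, !lab]))
    sum(res$p_bonferroni < 0.05, na.rm = TRUE)
  })
  expect_lte(sum(hits > 0), 1)
})

test_that("gene AUROC matches pairwise enumeration and the U identity", {
  expect_equal(gene_auroc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(gene_auroc(rep(3, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(gene_auroc(c(3, 2, 2, 1), c(1, 1, 0, 0)), 0.875)

  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    u <- wilcox.test(x[y == 1], x[y == 0], exact = FALSE)$statistic
    expect_equal(gene_auroc(x, y), unname(u) / (sum(y == 1) * sum(y == 0)))
  }
})

test_that("DM overdispersion scores deviations from the running median", {
  # genes on one exact CV^2 curve: constant relative noise pattern
  n_cells <- 24
  pattern <- as.numeric(scale(seq_len(n_cells)))   # mean 0, sd 1
  mus <- 2^seq(0, 6, length.out = 30)
  m <- t(sapply(mus, function(mu) mu + 0.3 * mu * pattern))  # CV^2 = 0.09
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  dm <- dm_overdispersion(m, window = 7)
  expect_equal(dm$dm, rep(0, 30), tolerance = 1e-10)

  # inflate one gene's variance 10x -> DM = log10(10) = 1, top rank
  m2 <- m
  m2[15, ] <- mus[15] + sqrt(10) * 0.3 * mus[15] * pattern
  dm2 <- dm_overdispersion(m2, window = 7)
  expect_equal(dm2$dm[15], 1, tolerance = 1e-10)
  expect_equal(which.max(dm2$dm), 15L)

  # low-mean genes are excluded
  m3 <- rbind(m, low = rep(0.05, n_cells) + 0.01 * pattern)
  dm3 <- dm_overdispersion(m3, window = 7)
  expect_true(is.na(dm3$dm[31]))

  expect_error(dm_overdispersion(m, window = 100), "window")
})

test_that("DM scores are invariant to gene order shuffling", {
  set.seed(4)
  m <- matrix(rpois(50 * 40, 8), 50, 40, dimnames = list(paste0("g", 1:50), NULL))
  perm <- sample(50)
  d1 <- dm_overdispersion(m, window = 9)
  d2 <- dm_overdispersion(m[perm, ], window = 9)
  expect_equal(d2$dm[match(d1$gene_id, d2$gene_id)], d1$dm)
})

test_that("the KL estimator is near zero on identical distributions", {
  set.seed(5)
  kl <- kl_divergence(matrix(rnorm(2000)), matrix(rnorm(2000)), seed = 1)
  expect_lt(abs(kl$kl), 0.1)
  expect_lt(abs(kl$accuracy - 0.5), 0.1)
  # prior-ratio correction for unequal sample sizes
  kl2 <- kl_divergence(matrix(rnorm(800)), matrix(rnorm(3200)), seed = 2)
  expect_lt(abs(kl2$kl), 0.1)
})

test_that("the KL estimator approximates the Gaussian closed form and is asymmetric", {
  set.seed(6)
  xa <- matrix(rnorm(4000, 1))
  xb <- matrix(rnorm(4000, 0))
  kl <- kl_divergence(xa, xb, seed = 3)
  expect_equal(kl$kl, 0.5, tolerance = 0.15)   # (mu1-mu2)^2/2 for unit variances

  # unequal variances: KL(N(0,1) || N(0,2)) = 0.0966 but reversed 0.1534;
  # quadratic features make the logistic density-ratio model well specified
  za <- rnorm(4000); zb <- rnorm(4000, sd = sqrt(2))
  feat <- function(z) cbind(z, z^2)
  k_ab <- kl_divergence(feat(za), feat(zb), seed = 4)$kl
  k_ba <- kl_divergence(feat(zb), feat(za), seed = 4)$kl
  expect_equal(k_ab, 0.0966, tolerance = 0.5)
  expect_equal(k_ba, 0.1534, tolerance = 0.5)
  expect_gt(k_ba - k_ab, 0.01)
  expect_gt(k_ab, -0.05)
  expect_gt(k_ba, -0.05)

  expect_warning(
    kl_divergence(cbind(rnorm(100), 1), cbind(rnorm(100), 1), seed = 5),
    "degenerate"
  )
})

test_that("incorporation Wald test matches the hand-computed odds ratio", {
  res <- incorporation_wald(c(30, 10), c("a", "b"), totals = c(100, 100))
  expect_equal(res$odds_ratio, 27 / 7, tolerance = 1e-10)
  se_hand <- sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90)
  expect_equal(res$se, se_hand, tolerance = 1e-6)
  expect_equal(res$wald_z, log(27 / 7) / se_hand, tolerance = 1e-6)

  eq <- incorporation_wald(c(20, 20), c("a", "b"), totals = c(100, 100))
  expect_equal(eq$odds_ratio, 1)
  expect_gt(eq$p_value, 0.9)

  # large-cohort incorporation-rate contrast: 21% vs 17%
  big <- incorporation_wald(round(c(0.21 * 10279, 0.17 * 13464)),
                            c("LRC", "nonLRC"), totals = c(10279, 13464))
  expect_lt(big$p_value, 0.001)
  expect_gt(big$odds_ratio, 1)
})

test_that("perfect separation falls back to corrected counts with a flag", {
  res <- incorporation_wald(c(10, 0), c("a", "b"), totals = c(10, 10))
  expect_equal(res$flag, "haldane_anscombe_correction")
  expect_true(is.finite(res$wald_z))
  # per-cell interface agrees with aggregated counts
  outcome <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  grp <- rep(c("a", "b"), each = 100)
  res2 <- incorporation_wald(outcome, grp)
  expect_equal(res2$odds_ratio, 27 / 7, tolerance = 1e-10)
})

test_that("rank-sum DE has power for unit log-mean shifts", {
  set.seed(7)
  n <- 200
  mu <- exp(runif(500, log(10), log(100)))
  counts <- matrix(rnbinom(500 * 2 * n, size = 10, mu = mu), 500, 2 * n)
  rownames(counts) <- paste0("g", 1:500)
  norm <- normalize_counts(counts, scale_total = 10000)
  spiked <- 1:50
  norm[spiked, 1:n] <- norm[spiked, 1:n] + 1    # 1-unit log-mean shift
  de <- rank_sum_de(norm[, 1:n], norm[, (n + 1):(2 * n)])
  power <- mean(de$p_bonferroni[spiked] < 0.05, na.rm = TRUE)
  expect_gte(power, 0.8)
})
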