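#' Rank-sum differential expression with fold-change and detection filters
#'
#' Genes are first filtered: the absolute difference of group mean
#' log-normalized expression must be at least `min_lfc`, and the gene must be
#' detected (value > 0) in at least `min_frac` of cells in at least one
#' group. Surviving genes are tested with a two-sided Wilcoxon rank-sum test
#' and Bonferroni-corrected over the number of genes actually tested.
#'
#' @param expr_a,expr_b genes x cells matrices of log-normalized expression
#'   for the two populations (same genes, same order; >= 3 cells each).
#' @param min_lfc minimum absolute log fold change (default 0.15; natural-log
#'   scale of the normalized values).
#' @param min_frac minimum detection fraction (default 0.10).
#' @return tibble with per-gene `log_fc`, `frac_a`, `frac_b`, `tested`,
#'   `statistic`, `p_value`, `p_bonferroni` (min(1, p * n_tested)), and
#'   `flag` ("constant" when a tested gene is constant across both groups,
#'   giving p = 1).
#' @export
rank_sum_de <- function(expr_a, expr_b, min_lfc = 0.15, min_frac = 0.10) {
  if (ncol(expr_a) < 3 || ncol(expr_b) < 3) abort("both groups need >= 3 cells")
  if (nrow(expr_a) != nrow(expr_b)) abort("gene sets must match")
  a <- as.matrix(expr_a); b <- as.matrix(expr_b)
  lfc <- rowMeans(a) - rowMeans(b)
  frac_a <- rowMeans(a > 0)
  frac_b <- rowMeans(b > 0)
  tested <- abs(lfc) >= min_lfc & pmax(frac_a, frac_b) >= min_frac
  m <- sum(tested)
  res <- tibble(
    gene_id = rownames(a) %||% paste0("gene", seq_len(nrow(a))),
    log_fc = lfc, frac_a = frac_a, frac_b = frac_b, tested = tested,
    statistic = NA_real_, p_value = NA_real_, flag = NA_character_
  )
  for (g in which(tested)) {
    xa <- a[g, ]; xb <- b[g, ]
    if (var(c(xa, xb)) == 0) {
      res$statistic[g] <- length(xa) * length(xb) / 2
      res$p_value[g] <- 1
      res$flag[g] <- "constant"
    } else {
      wt <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
      res$statistic[g] <- unname(wt$statistic)
      res$p_value[g] <- wt$p.value
    }
  }
  res$p_bonferroni <- pmin(1, res$p_value * m)
  res
}

#' Gene-wise area under the ROC curve
#'
#' AUROC of a binary threshold classifier on a single gene's expression,
#' computed through the rank-sum identity `AUROC = U / (n1 * n0)` with ties
#' contributing 1/2.
#'
#' @param expr numeric expression of one gene across cells, or a genes x
#'   cells matrix (one AUROC per row).
#' @param labels binary labels (positive class = larger expected expression
#'   scores AUROC > 0.5); both classes must be present.
#' @return numeric AUROC (vector for matrix input).
#' @export
gene_auroc <- function(expr, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) abort("both classes must be present")
  one <- function(x) {
    r <- rank(x)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (is.matrix(expr)) apply(expr, 1, one) else one(as.numeric(expr))
}

#' Difference-from-median overdispersion scores
#'
#' Orders genes by log10 mean expression and scores each gene's log10
#' squared coefficient of variation against the running median of log10 CV^2
#' over a window of genes with comparable mean: `DM = log10 CV^2 - running
#' median`. Genes with mean expression below `mean_min` are excluded (NA),
#' as technical noise dominates at very low means. The score is invariant to
#' the input gene order.
#'
#' @param expr genes x cells expression matrix.
#' @param mean_min mean-expression floor (default 0.1).
#' @param window running-median window in genes (default 50; shrunk
#'   symmetrically at the ends).
#' @return tibble with `gene_id`, `mean`, `cv2`, `dm` (NA for filtered
#'   genes), ordered as the input.
#' @export
dm_overdispersion <- function(expr, mean_min = 0.1, window = 50) {
  m <- as.matrix(expr)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu >= mean_min
  if (sum(keep) < window) abort("`window` exceeds the number of genes passing the mean filter")
  cv2 <- v / mu^2
  lcv <- log10(pmax(cv2, 1e-12))
  lmu <- log10(mu)
  dm <- rep(NA_real_, nrow(m))
  idx <- which(keep)
  ord <- idx[order(lmu[idx], lcv[idx])]
  half <- floor(window / 2)
  n <- length(ord)
  run_med <- vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    median(lcv[ord[w]])
  }, numeric(1))
  dm[ord] <- lcv[ord] - run_med
  tibble(gene_id = rownames(m) %||% paste0("gene", seq_len(nrow(m))),
         mean = mu, cv2 = cv2, dm = dm)
}

#' Classifier-based density-ratio Kullback-Leibler divergence
#'
#' Estimates KL(A || B) in nats between two samples by training a
#' probabilistic classifier to tell them apart, converting its class
#' probabilities to a density ratio `r(x) = [p(A|x) / (1 - p(A|x))] *
#' (n_B / n_A)` (the second factor removes the class-prior ratio), and
#' averaging `log r(x)` over held-out A points. The classifier is
#' cross-fitted: samples are split into `n_folds` folds and each point is
#' scored by a model that never saw it. Probabilities are clipped to
#' `[clip, 1 - clip]`.
#'
#' @param xa,xb samples from A and B: numeric matrices (points x features)
#'   or vectors; >= 50 points each.
#' @param n_folds cross-fitting folds (default 2).
#' @param clip probability clipping bound (default 1e-6).
#' @param classifier `"glm"` (logistic regression, default) or `"ridge"`
#'   (L2-regularized logistic via glmnet, for wide feature matrices).
#' @param seed fold-assignment seed.
#' @return A `kl_estimate` list: `kl` (nats), `accuracy` (held-out
#'   classification accuracy), `n_a`, `n_b`, `n_folds`, `seed`.
#' @export
kl_divergence <- function(xa, xb, n_folds = 2, clip = 1e-6,
                          classifier = c("glm", "ridge"), seed = 1) {
  classifier <- match.arg(classifier)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (nrow(xa) < 50 || nrow(xb) < 50) abort("both samples need >= 50 points")
  x <- rbind(xa, xb)
  keep <- apply(x, 2, function(col) var(col) > 1e-12)
  if (!all(keep)) {
    warn(sprintf("%d degenerate single-valued feature(s) dropped", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- c(rep(1L, nrow(xa)), rep(0L, nrow(xb)))
  n_a <- nrow(xa); n_b <- nrow(xb)
  set.seed(seed)
  fold <- c(sample(rep_len(seq_len(n_folds), n_a)),
            sample(rep_len(seq_len(n_folds), n_b)))
  p_hat <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    if (classifier == "glm") {
      dtr <- data.frame(y = y[tr], as.data.frame(x[tr, , drop = FALSE]))
      fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = dtr))
      p_hat[te] <- suppressWarnings(
        predict(fit, as.data.frame(x[te, , drop = FALSE]), type = "response"))
    } else {
      fit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                               family = "binomial", alpha = 0, nfolds = 5)
      p_hat[te] <- as.numeric(predict(fit, x[te, , drop = FALSE],
                                      s = "lambda.min", type = "response"))
    }
  }
  p_hat <- pmin(pmax(p_hat, clip), 1 - clip)
  log_r <- log(p_hat / (1 - p_hat)) + log(n_b / n_a)
  kl <- mean(log_r[y == 1])
  acc <- mean((p_hat > n_a / (n_a + n_b)) == (y == 1))
  structure(list(kl = kl, accuracy = acc, n_a = n_a, n_b = n_b,
                 n_folds = n_folds, seed = seed),
            class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("KL(A || B) = %.4f nats  (holdout accuracy %.3f; n = %d vs %d)\n",
              x$kl, x$accuracy, x$n_a, x$n_b))
  invisible(x)
}

#' Wald test for incorporation-rate differences
#'
#' Logistic regression of a per-cell binary outcome (e.g. EdU incorporation)
#' on a two-level group indicator, with the Wald test on the group
#' coefficient and the odds ratio. Accepts either per-cell vectors or
#' aggregated counts. Under perfect separation the Wald statistic is
#' unreliable; the estimate is then recomputed from Haldane-Anscombe
#' corrected counts (0.5 added to each cell of the 2x2 table) and flagged.
#'
#' @param outcome per-cell binary outcome (0/1 or logical); or, with
#'   `totals`, a length-2 vector of success counts per group.
#' @param group per-cell two-level group labels; or, with `totals`, the two
#'   group labels.
#' @param totals optional length-2 vector of group sizes, switching to
#'   aggregated input.
#' @return tibble with `odds_ratio`, `log_or`, `se`, `wald_z`, `p_value`,
#'   `rate_1`, `rate_2`, `flag`.
#' @export
incorporation_wald <- function(outcome, group, totals = NULL) {
  if (!is.null(totals)) {
    succ <- as.numeric(outcome)
    tot <- as.numeric(totals)
    labels <- if (length(group) == 2) as.character(group) else c("g1", "g2")
    tab <- cbind(succ, tot - succ)
  } else {
    y <- as.integer(as.logical(outcome))
    g <- factor(group)
    if (nlevels(g) != 2) abort("`group` must have exactly two levels")
    labels <- levels(g)
    tab <- rbind(c(sum(y[g == labels[1]]), sum(1 - y[g == labels[1]])),
                 c(sum(y[g == labels[2]]), sum(1 - y[g == labels[2]])))
  }
  if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
    abort("outcome has no variation")
  }
  flag <- NA_character_
  if (any(tab == 0)) {
    tab_c <- tab + 0.5
    flag <- "haldane_anscombe_correction"
  } else {
    tab_c <- tab
  }
  df <- data.frame(g = factor(labels, levels = labels))
  fit <- suppressWarnings(
    glm(cbind(tab_c[, 1], tab_c[, 2]) ~ g, family = binomial(), data = df)
  )  # corrected counts are deliberately non-integer
  # coefficient of the second level = log odds(level2) - log odds(level1);
  # report the first group's odds relative to the second
  beta <- -unname(coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit))[2]))
  z <- beta / se
  tibble(odds_ratio = exp(beta), log_or = unname(beta), se = unname(se),
         wald_z = unname(z), p_value = unname(2 * pnorm(-abs(z))),
         rate_1 = tab[1, 1] / sum(tab[1, ]),
         rate_2 = tab[2, 1] / sum(tab[2, ]),
         flag = flag)
}
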