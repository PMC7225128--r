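make_lcm <- function(n_genes = 20, n_cells = 30, seed = 1, extra_genes = NULL) {
  set.seed(seed)
  genes <- c(paste0("g", seq_len(n_genes)), extra_genes)
  s <- matrix(rpois(length(genes) * n_cells, 5), length(genes), n_cells,
              dimnames = list(genes, paste0("c", seq_len(n_cells))))
  u <- matrix(rpois(length(genes) * n_cells, 2), length(genes), n_cells,
              dimnames = dimnames(s))
  layered_counts(s, u)
}

test_that("qc_filter removes high-mito and high-complexity cells and blocklist genes", {
  x <- make_lcm(extra_genes = c("Gm42418", "AY036118"))
  md <- x$cell_metadata
  md$mito_fraction[1] <- 0.15       # strictly above 0.10 -> removed
  md$mito_fraction[2] <- 0.10       # at the threshold -> kept
  md$genes_detected[3] <- 6000      # above 5000 -> removed
  x$cell_metadata <- md
  out <- qc_filter(x)
  expect_equal(ncol(out$spliced), 28)
  expect_false("c1" %in% out$cell_metadata$cell_id)
  expect_true("c2" %in% out$cell_metadata$cell_id)
  expect_false(any(c("Gm42418", "AY036118") %in% rownames(out$spliced)))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$rule == "blocklist_genes"], 2)
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  x <- make_lcm()
  once <- qc_filter(x)
  twice <- qc_filter(once)
  expect_identical(once$spliced, twice$spliced)

  bad <- x
  bad$cell_metadata$mito_fraction <- 0.5
  expect_error(qc_filter(bad), "all cells removed")
})

test_that("depth normalization and log transform follow the stated arithmetic", {
  m <- matrix(c(10, 9990, 5, 5), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  norm <- normalize_counts(m, scale_total = 10000, log = TRUE)
  expect_equal(norm["a", "c1"], log1p(10))      # ~2.3979
  expect_equal(norm["a", "c1"], 2.3979, tolerance = 1e-4)
  expect_equal(normalize_counts(matrix(0, 1, 1), log = TRUE)[1, 1], 0)
})

test_that("PCA embedding is deterministic, orthonormal, and captures rank", {
  set.seed(42)
  base <- runif(40)
  expr <- outer(base, seq_len(60))            # exactly rank one
  rownames(expr) <- paste0("g", 1:40); colnames(expr) <- paste0("c", 1:60)
  e <- preprocess_embed(expr, scale_total = NULL, log = FALSE, d = 2)
  expect_lt(e$sdev[2] / e$sdev[1], 1e-8)
  expect_equal(unname(crossprod(e$loadings)), diag(2), tolerance = 1e-6)
  # reconstruction within rank-d truncation
  centered <- sweep(t(expr[e$genes, ]), 2, e$gene_means)
  recon <- e$coordinates %*% t(e$loadings)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-6)
  expect_error(preprocess_embed(expr, scale_total = NULL, log = FALSE, d = 50),
               "rank")
})

test_that("variance decomposition attributes signal to the right factors", {
  set.seed(1)
  n <- 2000
  a <- rep(c("x", "y"), each = n / 2)
  b <- rep(c("p", "q"), n / 2)                 # orthogonal balanced
  # one gene fully determined by a; one pure noise; one equal a+b effects
  expr <- rbind(det = as.numeric(a == "x"),
                noise = rnorm(n),
                both = as.numeric(a == "x") + as.numeric(b == "p"))
  ve <- variance_explained(expr, data.frame(a = a, b = b))
  pg <- attr(ve, "per_gene")
  expect_equal(pg["det", "a"], 1)
  expect_lt(pg["noise", "a"], 0.01)
  expect_equal(pg["both", "a"], 0.5, tolerance = 1e-10)
  expect_equal(pg["both", "b"], 0.5, tolerance = 1e-10)
  expect_true(all(pg >= 0 & pg <= 1, na.rm = TRUE))
})

test_that("variance fractions are invariant to gene scaling and flag aliasing", {
  set.seed(2)
  a <- rep(c("x", "y"), 50)
  expr <- rbind(g1 = as.numeric(a == "x") + rnorm(100, sd = 0.1))
  v1 <- variance_explained(expr, data.frame(a = a))
  v2 <- variance_explained(expr * 37, data.frame(a = a))
  expect_equal(v1$mean_fraction, v2$mean_fraction)

  expect_warning(
    ve <- variance_explained(expr, data.frame(a = a, b = a)),
    "aliased"
  )
  expect_true(is.na(attr(ve, "per_gene")["g1", "b"]))
})

test_that("rank pseudotime is oriented toward activated cells and bounded", {
  set.seed(3)
  expr <- rbind(g1 = c(rnorm(30, 2), rnorm(30, 8)),
                g2 = rnorm(60))
  colnames(expr) <- paste0("c", 1:60)
  e <- preprocess_embed(expr, scale_total = NULL, log = FALSE, d = 2)
  act <- c(rep(FALSE, 30), rep(TRUE, 30))
  e <- assign_pseudotime(e, activated = act)
  expect_true(all(e$pseudotime >= 0 & e$pseudotime <= 1))
  expect_gt(mean(e$pseudotime[act]), mean(e$pseudotime[!act]))
})

test_that("layered MTX round trip preserves counts and metadata", {
  x <- make_lcm(n_genes = 8, n_cells = 6)
  dir <- withr::local_tempdir()
  write_layered(x, dir)
  y <- read_layered(dir)
  expect_equal(unname(as.matrix(x$spliced)), unname(y$spliced))
  expect_equal(unname(as.matrix(x$unspliced)), unname(y$unspliced))
  expect_equal(x$cell_metadata$cell_id, as.character(y$cell_metadata$cell_id))
})
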