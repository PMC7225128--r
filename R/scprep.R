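#' Quality-control filtering of a layered count matrix
#'
#' Removes suspected dead cells (mitochondrial read fraction strictly greater
#' than `mito_max`), suspected doublets (genes detected strictly greater than
#' `genes_max`), and a small blocklist of rRNA-contaminated transcripts from
#' both layers.
#'
#' @param x a [layered_counts()] object.
#' @param mito_max maximum tolerated mitochondrial fraction (default 0.10;
#'   cells with a strictly greater fraction are removed).
#' @param genes_max maximum genes detected per cell (default 5000, strictly
#'   greater removed).
#' @param blocklist gene ids removed from both layers regardless of QC
#'   (default `Gm42418` and `AY036118`, which overlap an unannotated rRNA
#'   locus and can carry amplified rRNA counts).
#' @return The filtered `layered_counts` with a `qc_report` attribute tibble
#'   listing the number of cells/genes removed per rule.
#' @export
qc_filter <- function(x, mito_max = 0.10, genes_max = 5000,
                      blocklist = c("Gm42418", "AY036118")) {
  stopifnot(inherits(x, "layered_counts"))
  md <- x$cell_metadata
  drop_mito <- md$mito_fraction > mito_max
  drop_genes <- md$genes_detected > genes_max
  keep <- !(drop_mito | drop_genes)
  if (!any(keep)) abort("all cells removed by QC filtering")
  gene_keep <- !(rownames(x$spliced) %in% blocklist)
  out <- layered_counts(
    x$spliced[gene_keep, keep, drop = FALSE],
    x$unspliced[gene_keep, keep, drop = FALSE],
    md[keep, , drop = FALSE]
  )
  attr(out, "qc_report") <- tibble(
    rule = c("mito_fraction", "genes_detected", "blocklist_genes"),
    removed = c(sum(drop_mito), sum(drop_genes & !drop_mito), sum(!gene_keep))
  )
  out
}

#' Depth-normalize and optionally log-transform a count matrix
#'
#' Scales each cell to `scale_total` total counts and (by default) applies
#' `log1p`.
#'
#' @param counts genes x cells matrix.
#' @param scale_total target total per cell (default 10000); `NULL` skips
#'   depth scaling (for matrices that are already size-normalized).
#' @param log apply `log1p` after scaling?
#' @return genes x cells numeric matrix.
#' @export
normalize_counts <- function(counts, scale_total = 10000, log = TRUE) {
  x <- as.matrix(counts)
  if (!is.null(scale_total)) {
    tot <- colSums(x)
    tot[tot == 0] <- 1
    x <- sweep(x, 2, tot / scale_total, "/")
  }
  if (log) log1p(x) else x
}

#' Normalize, select variable genes, and embed with PCA
#'
#' The standard preprocessing chain: per-cell depth normalization to
#' `scale_total`, `log1p` transform (optional), selection of the `n_hvg` most
#' overdispersed genes by variance-to-mean ratio in the transformed space, and
#' centered PCA. Component signs are fixed by forcing the largest-magnitude
#' loading of each component positive, so the embedding is deterministic.
#'
#' @param x a [layered_counts()] object or a genes x cells matrix.
#' @param scale_total per-cell depth target (default 10000); `NULL` skips
#'   depth scaling, e.g. when `x` is the size-normalized spliced layer of a
#'   velocity fit.
#' @param n_hvg number of highly variable genes to keep (default all genes).
#' @param d number of principal components (default 2).
#' @param log log1p-transform after depth normalization? The stored
#'   transform (depth scaling + log) is re-applied by [project_embedding()],
#'   so new expression profiles project consistently.
#' @return An `embedding_state` list: `coordinates` (cells x d score matrix),
#'   `loadings` (genes x d, orthonormal columns), `gene_means` (centering
#'   vector), `genes` (HVG ids), `sdev` (component standard deviations),
#'   `scale_total`, `log`, and `pseudotime` (NULL until assigned).
#' @export
preprocess_embed <- function(x, scale_total = 10000, n_hvg = NULL, d = 2,
                             log = TRUE) {
  counts <- if (inherits(x, "layered_counts")) x$spliced else x
  norm <- normalize_counts(counts, scale_total, log)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  disp <- v / pmax(mu, 1e-12)
  if (is.null(n_hvg)) n_hvg <- nrow(norm)
  n_hvg <- min(n_hvg, nrow(norm))
  hvg <- rownames(norm)[order(disp, decreasing = TRUE)][seq_len(n_hvg)]
  m <- t(norm[hvg, , drop = FALSE])          # cells x genes
  if (d > min(dim(m))) abort("`d` exceeds the available rank")
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = d)
  flip <- apply(pc$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  structure(list(
    coordinates = coords, loadings = loadings,
    gene_means = pc$center, genes = hvg, sdev = pc$sdev[seq_len(d)],
    scale_total = scale_total, log = log,
    cell_ids = colnames(counts), pseudotime = NULL
  ), class = "embedding_state")
}

#' @export
print.embedding_state <- function(x, ...) {
  cat(sprintf("<embedding_state> %d cells x %d components (%d genes)\n",
              nrow(x$coordinates), ncol(x$coordinates), length(x$genes)))
  if (!is.null(x$pseudotime)) cat("pseudotime assigned\n")
  invisible(x)
}

#' Project expression through a fitted embedding
#'
#' Applies the embedding's stored transform (depth scaling and log, as
#' fitted) followed by centering and the loadings, so new profiles land in
#' the same coordinate system as the reference cells.
#'
#' @param e an `embedding_state`.
#' @param expr genes x cells matrix in the same raw space the embedding was
#'   fitted on; gene set may be a superset (the embedding's genes are
#'   selected by name).
#' @return cells x d coordinate matrix.
#' @export
project_embedding <- function(e, expr) {
  common <- intersect(e$genes, rownames(expr))
  if (!length(common)) abort("no genes shared between embedding and matrix")
  expr <- normalize_counts(expr, e$scale_total, e$log)
  m <- matrix(0, ncol(expr), length(e$genes),
              dimnames = list(colnames(expr), e$genes))
  m[, common] <- t(expr[common, , drop = FALSE])
  sweep(m, 2, e$gene_means, "-") %*% e$loadings
}

#' Assign pseudotime to an embedding
#'
#' Either stores externally computed per-cell values or derives a simple
#' fallback ordering along the first principal component, oriented so that
#' cells flagged as activated (when `activated` is given) sit at larger
#' pseudotime. The default `"rank"` scaling maps the PC1 order to a uniform
#' grid on \[0, 1\]; like graph-based pseudotiming, this makes the axis a
#' property of the cell ordering, so equal-width pseudotime bins stay
#' populated even when the embedding has density gaps between timepoint
#' clusters. `"linear"` min-max-scales PC1 instead.
#'
#' @param e an `embedding_state`.
#' @param values optional numeric per-cell pseudotime (same order as cells).
#' @param activated optional logical per-cell vector used to orient the PC1
#'   fallback.
#' @param scaling `"rank"` (default) or `"linear"` fallback scaling.
#' @return the embedding with `pseudotime` set (nonnegative).
#' @export
assign_pseudotime <- function(e, values = NULL, activated = NULL,
                              scaling = c("rank", "linear")) {
  stopifnot(inherits(e, "embedding_state"))
  scaling <- match.arg(scaling)
  if (is.null(values)) {
    pc1 <- e$coordinates[, 1]
    if (!is.null(activated) && mean(pc1[activated]) < mean(pc1[!activated])) {
      pc1 <- -pc1
    }
    values <- if (scaling == "rank") {
      (rank(pc1, ties.method = "average") - 1) / max(length(pc1) - 1, 1)
    } else {
      (pc1 - min(pc1)) / max(max(pc1) - min(pc1), 1e-12)
    }
  }
  if (any(values < 0)) abort("pseudotime must be nonnegative")
  if (length(values) != nrow(e$coordinates)) abort("length mismatch")
  e$pseudotime <- as.numeric(values)
  e
}

#' Per-factor fraction of expression variance explained
#'
#' For each gene, fits a linear model of expression on the supplied
#' categorical factors and partitions the total sum of squares with
#' sequential (type-I) sums of squares in the caller's factor order. Reports
#' each factor's fraction averaged over genes; per gene the factor fractions
#' plus the residual fraction sum to one. Aliased (confounded) factors get NA
#' with a warning.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param factors data frame of per-cell factors (each with >= 2 levels).
#' @return tibble with `factor`, `mean_fraction`, and the per-gene fractions
#'   in a `per_gene` attribute (genes x factors matrix, residual included).
#' @export
variance_explained <- function(expr, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  factors[] <- lapply(factors, function(f) factor(as.character(f)))
  if (any(vapply(factors, nlevels, 1L) < 2)) {
    abort("each factor needs at least 2 levels")
  }
  mm_formula <- stats::as.formula(paste("y ~", paste(names(factors), collapse = " + ")))
  n_fac <- ncol(factors)
  frac <- matrix(NA_real_, nrow(expr), n_fac + 1,
                 dimnames = list(rownames(expr), c(names(factors), "residual")))
  aliased_any <- FALSE
  env <- factors
  for (i in seq_len(nrow(expr))) {
    env$y <- as.numeric(expr[i, ])
    fit <- lm(mm_formula, data = env)
    if (any(is.na(coef(fit)))) aliased_any <- TRUE
    av <- suppressWarnings(stats::anova(fit))  # SS only; F-test warnings on perfect fits are irrelevant
    ss <- av[["Sum Sq"]]
    terms_here <- rownames(av)
    tot <- sum(ss)
    if (tot <= 0) { frac[i, "residual"] <- 1; next }
    for (k in seq_len(n_fac)) {
      j <- match(names(factors)[k], terms_here)
      frac[i, k] <- if (is.na(j)) NA_real_ else ss[j] / tot
    }
    frac[i, "residual"] <- ss[length(ss)] / tot
  }
  if (aliased_any) {
    warn("some factors are aliased (confounded); inseparable terms set to NA")
    # mark fully confounded factors: their sequential SS absorbs the shared
    # variance, the later one is aliased out of the model matrix entirely
  }
  out <- tibble(
    factor = colnames(frac),
    mean_fraction = colMeans(frac, na.rm = FALSE)
  )
  attr(out, "per_gene") <- frac
  out
}
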