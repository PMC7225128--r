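#' Steady-state estimation of per-gene degradation ratios
#'
#' For each gene, fits the least-squares slope through the origin of
#' unspliced on spliced abundance, restricted to cells in the top and bottom
#' `extreme_quantile` of that gene's (pooled) spliced expression. Cells near
#' the extremes of expression are assumed to sit at kinetic steady state,
#' where u = gamma * s (splicing-normalized units), so the slope estimates
#' the degradation-to-splicing ratio gamma. Slopes are clipped at zero.
#'
#' Layers are first size-normalized (each cell scaled to the median total of
#' its layer) and then smoothed by k-nearest-neighbor pooling: each cell's
#' profile is replaced by the mean over its `pool_k` nearest neighbors
#' (itself included) in a PCA of the log1p spliced layer. Pooling suppresses
#' the count noise that otherwise attenuates the slope.
#'
#' @param spliced,unspliced genes x cells count matrices.
#' @param extreme_quantile fraction of cells in each tail used for the fit
#'   (default 0.05).
#' @param pool_k pooling neighborhood size (default 30); `1` disables
#'   pooling.
#' @param pool_d PCA dimensionality for the pooling neighbor search; kept
#'   low because the neighbor search must run in signal-dominated
#'   directions for pooling to average out independent count noise.
#' @param min_cells minimum cells required (default 10).
#' @param anchors optional two-level per-cell factor marking cells near the
#'   trajectory's terminal neighborhoods (e.g. pseudotime extremes, or the
#'   experimental timepoints); cells in neither anchor are `NA`. Both anchor
#'   populations are assumed near kinetic equilibrium. When given, each
#'   gene whose anchor centroids separate in spliced abundance is fitted by
#'   the chord through the two centroids in (spliced, unspliced) space
#'   (slope `gamma_hat`, intercept `offset`), so its velocity
#'   `v = u - gamma_hat * s - offset` vanishes at both anchors by
#'   construction. Genes whose centroids coincide (flat or pulse-shaped
#'   profiles) keep the extreme-quantile slope - for a pulsed gene the
#'   spliced extremes sit at the pulse peak and floor, both transient
#'   equilibria - and get the offset that zeroes the mean anchor velocity.
#'   This is the variant to use when the field drives phase-point
#'   simulations that must come to rest at the terminal state.
#' @return A `velocity_fit` list with `gamma_hat` (nonnegative named
#'   per-gene vector) and `offset` (zero unless anchored), plus the
#'   size-normalized layers: `spliced_norm` / `unspliced_norm` (unpooled -
#'   what [compute_velocity()] evaluates per-cell velocities on) and
#'   `spliced_pool` / `unspliced_pool` (the kNN-pooled matrices the slope
#'   was fitted on). Fitting on pooled layers controls estimator bias;
#'   evaluating velocities on unpooled layers keeps each cell's velocity
#'   noise independent, so neighbor averaging (during phase-point
#'   simulation or curve binning) can cancel it, and preserves the
#'   mean-reverting component that makes observed equilibrium clusters
#'   attracting.
#' @export
fit_gamma <- function(spliced, unspliced, extreme_quantile = 0.05,
                      pool_k = 30, pool_d = 2, min_cells = 10,
                      anchors = NULL) {
  if (ncol(spliced) < min_cells) abort("need at least `min_cells` cells")
  if (min(spliced) < 0 || min(unspliced) < 0) abort("layers must be nonnegative")
  s_raw <- size_normalize(spliced)
  u_raw <- size_normalize(unspliced)
  if (pool_k > 1) {
    nb <- pooling_neighbors(s_raw, k = min(pool_k, ncol(s_raw)), d = pool_d)
    s <- pool_layer(s_raw, nb)
    u <- pool_layer(u_raw, nb)
  } else {
    s <- s_raw
    u <- u_raw
  }
  offset <- rep(0, nrow(s))
  quantile_slope <- function(g) {
    sg <- s[g, ]; ug <- u[g, ]
    if (all(sg == 0) && all(ug == 0)) {
      warn(sprintf("gene %s has all-zero layers; gamma set to 0",
                   rownames(s)[g] %||% g))
      return(0)
    }
    qs <- quantile(sg, c(extreme_quantile, 1 - extreme_quantile))
    idx <- sg <= qs[1] | sg >= qs[2]
    denom <- sum(sg[idx]^2)
    if (denom == 0) return(0)
    max(sum(ug[idx] * sg[idx]) / denom, 0)
  }
  if (is.null(anchors)) {
    gamma_hat <- vapply(seq_len(nrow(s)), quantile_slope, numeric(1))
  } else {
    a <- factor(anchors)
    if (nlevels(a) != 2) abort("`anchors` must have exactly two levels")
    g1 <- which(a == levels(a)[1])
    g2 <- which(a == levels(a)[2])
    if (!length(g1) || !length(g2)) abort("both anchor groups must be non-empty")
    gamma_hat <- numeric(nrow(s))
    for (g in seq_len(nrow(s))) {
      s1 <- mean(s[g, g1]); s2 <- mean(s[g, g2])
      u1 <- mean(u[g, g1]); u2 <- mean(u[g, g2])
      ds <- s2 - s1
      spread <- sd(s[g, ])
      # the chord is trustworthy only when the anchors span most of the
      # gene's dynamic range; pulse-shaped genes return to baseline at both
      # anchors (small ds, large range) and need the apex as second anchor
      rng <- diff(quantile(s[g, ], c(0.05, 0.95)))
      if (abs(ds) >= 0.5 * max(rng, 1e-9) && abs(ds) > 1e-9) {
        gamma_hat[g] <- max((u2 - u1) / ds, 0)
        offset[g] <- u1 - gamma_hat[g] * s1
      } else {
        # anchors coincide in spliced abundance (flat or pulse-shaped
        # gene): take the expression apex - the top extreme quantile of
        # pooled spliced, a transient equilibrium where ds/dt = 0 - as the
        # second anchor, with centroids on the unpooled layers so that
        # tail selection noise does not tilt the chord
        anc <- c(g1, g2)
        top <- which(s[g, ] >= quantile(s[g, ], 1 - extreme_quantile))
        sa <- mean(s_raw[g, anc]); ua <- mean(u_raw[g, anc])
        st <- mean(s_raw[g, top]); ut <- mean(u_raw[g, top])
        if (abs(st - sa) > 0.25 * max(spread, 1e-9)) {
          gamma_hat[g] <- max((ut - ua) / (st - sa), 0)
          offset[g] <- ua - gamma_hat[g] * sa
        } else {
          gamma_hat[g] <- quantile_slope(g)
          offset[g] <- mean(u[g, anc] - gamma_hat[g] * s[g, anc])
        }
      }
    }
  }
  names(gamma_hat) <- rownames(spliced)
  names(offset) <- rownames(spliced)
  structure(list(gamma_hat = gamma_hat, offset = offset,
                 spliced_norm = s_raw, unspliced_norm = u_raw,
                 spliced_pool = s, unspliced_pool = u,
                 extreme_quantile = extreme_quantile, pool_k = pool_k,
                 anchored = !is.null(anchors)),
            class = "velocity_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

size_normalize <- function(m) {
  m <- as.matrix(m)
  tot <- colSums(m)
  target <- median(tot[tot > 0])
  if (!is.finite(target) || target == 0) return(m)
  tot[tot == 0] <- target
  sweep(m, 2, tot / target, "/")
}

pooling_neighbors <- function(s, k, d) {
  x <- t(log1p(s))
  d <- max(1, min(d, nrow(x) - 1, ncol(x)))
  pc <- prcomp(x, center = TRUE, rank. = d)
  cpp_knn_brute(pc$x, pc$x, as.integer(k))
}

pool_layer <- function(m, nb) {
  n <- ncol(m)
  k <- ncol(nb)
  w <- Matrix::sparseMatrix(i = as.integer(t(nb)),
                            j = rep(seq_len(n), each = k),
                            x = 1 / k, dims = c(n, n))
  out <- as.matrix(m %*% w)
  dimnames(out) <- dimnames(m)
  out
}

#' Compute RNA velocity and extrapolated future expression
#'
#' Velocity is `v = u - gamma_hat * s` per cell and gene (minus the per-gene
#' `offset` for anchored fits); the extrapolated future spliced state is
#' `max(s + v * delta_t, 0)`.
#'
#' @param fit a `velocity_fit` from [fit_gamma()], or a list with
#'   `spliced_norm`, `unspliced_norm`, `gamma_hat` (and optionally `offset`).
#' @param delta_t extrapolation step (dimensionless, default 1).
#' @return The fit with `velocity_gene` (genes x cells) and `future_spliced`
#'   (genes x cells, clipped at 0) added, class `velocity_field`.
#' @export
compute_velocity <- function(fit, delta_t = 1) {
  s <- fit$spliced_norm; u <- fit$unspliced_norm
  if (min(s) < 0 || min(u) < 0) abort("layers must be nonnegative")
  v <- u - fit$gamma_hat * s
  if (!is.null(fit$offset)) v <- v - fit$offset
  fit$velocity_gene <- v
  fit$future_spliced <- pmax(s + v * delta_t, 0)
  fit$delta_t <- delta_t
  class(fit) <- c("velocity_field", class(fit))
  fit
}

#' Project RNA velocity into an embedding
#'
#' Projects the current and extrapolated future expression through the
#' embedding's stored transform (normalization, centering, loadings) and
#' returns the per-cell displacement divided by `delta_t`. The projection is
#' deterministic; genes present in the embedding but absent from the
#' velocity fit contribute zero displacement.
#'
#' @param field a `velocity_field` from [compute_velocity()].
#' @param e an `embedding_state` (see [preprocess_embed()]); its gene set
#'   must intersect the field's.
#' @param smooth_k optional neighborhood size for post-projection smoothing:
#'   each cell's embedded velocity is replaced by the mean over its
#'   `smooth_k` nearest cells in the embedding. Count noise in the layers
#'   survives projection as a frozen small-scale vector field; smoothing
#'   suppresses it, which matters when the field drives phase-point
#'   simulations that should come to rest where the systematic field
#'   vanishes. `NULL` (default) disables smoothing.
#' @param smooth_within optional per-cell grouping factor: smoothing
#'   neighborhoods are restricted to cells of the same group, so that
#'   group-specific field differences (e.g. slower kinetics in aged cells)
#'   are not blended away.
#' @return cells x d matrix of embedded velocities (rows match `e`'s cells).
#' @export
embed_velocity <- function(field, e, smooth_k = NULL, smooth_within = NULL) {
  common <- intersect(e$genes, rownames(field$spliced_norm))
  if (!length(common)) abort("no genes shared between velocity field and embedding")
  cur <- project_embedding(e, field$spliced_norm)
  fut <- project_embedding(e, field$future_spliced)
  v <- (fut - cur) / field$delta_t
  if (!is.null(smooth_k) && smooth_k > 1) {
    groups <- if (is.null(smooth_within)) rep(1L, nrow(v)) else as.integer(factor(smooth_within))
    out <- v
    for (g in unique(groups)) {
      idx <- which(groups == g)
      k <- as.integer(min(smooth_k, length(idx)))
      nb <- cpp_knn_query(e$coordinates[idx, , drop = FALSE],
                          e$coordinates[idx, , drop = FALSE], k)
      vg <- v[idx, , drop = FALSE]
      out[idx, ] <- t(vapply(seq_along(idx),
                             function(i) colMeans(vg[nb[i, ], , drop = FALSE]),
                             numeric(ncol(v))))
    }
    v <- out
  }
  v
}

#' Velocity magnitude binned along pseudotime
#'
#' Bins cells into equal-width pseudotime bins and computes, per bin, the
#' Euclidean norm of the mean velocity vector; a rolling mean over bins
#' smooths the curve. Bins with fewer than `min_cells` cells are reported
#' but masked from the rolling mean.
#'
#' @param velocity_embed cells x d matrix of embedded velocities.
#' @param pseudotime per-cell pseudotime (no missing values).
#' @param n_bins number of equal-width bins (>= 2, default 20).
#' @param rolling_window rolling-mean width in bins (odd; default 5).
#' @param min_cells minimum cells for an unmasked bin (default 10).
#' @param breaks optional explicit bin breaks (overrides `n_bins`); use to
#'   bin two groups on a common axis.
#' @return tibble with `bin`, `bin_center`, `n_cells`, `magnitude`,
#'   `magnitude_smooth` (NA on masked bins), `masked`.
#' @export
magnitude_by_pseudotime <- function(velocity_embed, pseudotime, n_bins = 20,
                                    rolling_window = 5, min_cells = 10,
                                    breaks = NULL) {
  if (anyNA(pseudotime)) abort("pseudotime must be assigned for all cells")
  if (is.null(breaks)) {
    if (n_bins < 2) abort("`n_bins` must be at least 2")
    breaks <- seq(min(pseudotime), max(pseudotime), length.out = n_bins + 1)
  }
  n_bins <- length(breaks) - 1
  bin <- cut(pseudotime, breaks, include.lowest = TRUE, labels = FALSE)
  v <- as.matrix(velocity_embed)
  mags <- vapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NA_real_)
    sqrt(sum(colMeans(v[idx, , drop = FALSE])^2))
  }, numeric(1))
  n_in <- vapply(seq_len(n_bins), function(b) sum(bin == b, na.rm = TRUE), 0)
  masked <- n_in < min_cells
  kept <- ifelse(masked, NA_real_, mags)
  half <- floor(rolling_window / 2)
  smooth <- vapply(seq_len(n_bins), function(b) {
    w <- max(1, b - half):min(n_bins, b + half)
    if (is.na(kept[b])) return(NA_real_)
    mean(kept[w], na.rm = TRUE)
  }, numeric(1))
  tibble(bin = seq_len(n_bins),
         bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
         n_cells = n_in, magnitude = mags,
         magnitude_smooth = smooth, masked = masked)
}
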