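#' Fit a k-nearest-neighbor regression map from embedding to pseudotime
#'
#' Predictions are the (optionally inverse-distance weighted) mean
#' pseudotime of the `k` nearest reference cells by Euclidean distance, with
#' ties broken by reference index order. With uniform weights, predictions
#' are bounded by the reference pseudotime range.
#'
#' @param e an `embedding_state` with pseudotime assigned (see
#'   [assign_pseudotime()]), or a cells x d coordinate matrix.
#' @param pseudotime per-cell reference pseudotime (taken from `e` when it is
#'   an embedding).
#' @param k neighbor count (1 <= k <= number of reference cells; default 5).
#' @param weighting `"uniform"` or `"inverse_distance"`.
#' @return A `pseudotime_map` object with a [predict()] method.
#' @export
fit_pseudotime_map <- function(e, pseudotime = NULL, k = 5,
                               weighting = c("uniform", "inverse_distance")) {
  weighting <- match.arg(weighting)
  coords <- if (inherits(e, "embedding_state")) e$coordinates else as.matrix(e)
  if (is.null(pseudotime) && inherits(e, "embedding_state")) {
    pseudotime <- e$pseudotime
  }
  if (is.null(pseudotime) || anyNA(pseudotime)) {
    abort("pseudotime must be present for all reference cells")
  }
  if (k < 1 || k > nrow(coords)) abort("`k` must lie in [1, n_reference]")
  structure(list(coords = unname(as.matrix(coords)),
                 pseudotime = as.numeric(pseudotime),
                 k = as.integer(k), weighting = weighting),
            class = "pseudotime_map")
}

#' @param object a `pseudotime_map`.
#' @param newdata query coordinates (cells x d matrix).
#' @param ... unused.
#' @rdname fit_pseudotime_map
#' @export
predict.pseudotime_map <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) != ncol(object$coords)) abort("query dimensionality mismatch")
  idx <- cpp_knn_query(object$coords, q, object$k)
  if (object$weighting == "uniform") {
    pt <- matrix(object$pseudotime[idx], nrow(q), object$k)
    rowMeans(pt)
  } else {
    vapply(seq_len(nrow(q)), function(i) {
      ref <- object$coords[idx[i, ], , drop = FALSE]
      d2 <- sqrt(rowSums((ref - matrix(q[i, ], object$k, ncol(q),
                                       byrow = TRUE))^2))
      if (any(d2 < 1e-12)) return(object$pseudotime[idx[i, which.min(d2)]])
      w <- 1 / d2
      sum(w * object$pseudotime[idx[i, ]]) / sum(w)
    }, numeric(1))
  }
}

#' Change in pseudotime inferred from RNA velocity
#'
#' For each cell, extrapolates its embedding position one velocity step into
#' the future, predicts the pseudotime of that future position with the
#' kNN regression map, and returns the difference from the observed
#' pseudotime: `delta_p = predict(x + v * delta_t) - p_observed`.
#'
#' @param coords cells x d embedding coordinates.
#' @param velocity_embed cells x d embedded velocities (see
#'   [embed_velocity()]).
#' @param map a `pseudotime_map` fitted in the same embedding convention.
#' @param observed per-cell observed pseudotime (NA gives per-cell NA with a
#'   warning).
#' @param delta_t extrapolation step (default 1).
#' @return tibble with `pseudotime`, `future_pseudotime`, `delta_p`.
#' @export
delta_pseudotime <- function(coords, velocity_embed, map, observed,
                             delta_t = 1) {
  coords <- as.matrix(coords)
  v <- as.matrix(velocity_embed)
  stopifnot(all(dim(coords) == dim(v)))
  if (anyNA(observed)) warn("missing observed pseudotime; returning NA for those cells")
  fut <- predict(map, coords + v * delta_t)
  tibble(pseudotime = as.numeric(observed),
         future_pseudotime = fut,
         delta_p = fut - as.numeric(observed))
}

#' Classify lineage-regressing cells from the delta-pseudotime distribution
#'
#' A cell is "regressing" along the trajectory when its change in pseudotime
#' falls more than `threshold_multiplier` sample standard deviations below
#' zero: `delta_p < -threshold_multiplier * sd(delta_p)`. The regressing
#' fraction is invariant to affine rescaling of pseudotime because the
#' threshold scales with the standard deviation.
#'
#' @param delta_p per-cell change in pseudotime (>= 2 values).
#' @param threshold_multiplier threshold in standard-deviation units
#'   (default 0.5).
#' @param pseudotime optional observed per-cell pseudotime; when given, a
#'   per-bin regressing-fraction curve is returned.
#' @param n_bins bins for the frequency curve (default 20).
#' @param smooth_sigma Gaussian smoothing bandwidth for the curve, in bins
#'   (default 1; 0 disables smoothing).
#' @return A `lineage_regression` list: `mask` (logical), `fraction`,
#'   `threshold`, `sd`, and (when `pseudotime` is given) `curve`, a tibble
#'   with per-bin regressing fraction, standard error, and the
#'   Gaussian-smoothed fraction.
#' @export
classify_lineage_regression <- function(delta_p, threshold_multiplier = 0.5,
                                        pseudotime = NULL, n_bins = 20,
                                        smooth_sigma = 1) {
  delta_p <- as.numeric(delta_p)
  if (length(delta_p) < 2) abort("need at least 2 cells")
  sigma <- sd(delta_p)
  if (sigma == 0) {
    warn("delta pseudotime is constant; no cells classified as regressing")
    mask <- rep(FALSE, length(delta_p))
  } else {
    mask <- delta_p < -threshold_multiplier * sigma
  }
  out <- list(mask = mask, fraction = mean(mask),
              threshold = -threshold_multiplier * sigma, sd = sigma,
              threshold_multiplier = threshold_multiplier)
  if (!is.null(pseudotime)) {
    breaks <- seq(min(pseudotime), max(pseudotime), length.out = n_bins + 1)
    bin_of <- cut(pseudotime, breaks, include.lowest = TRUE, labels = FALSE)
    n_in <- vapply(seq_len(n_bins), function(b) sum(bin_of == b), 0)
    frac_in <- vapply(seq_len(n_bins), function(b) {
      idx <- bin_of == b
      if (!any(idx)) NA_real_ else mean(mask[idx])
    }, numeric(1))
    curve <- tibble(
      bin = seq_len(n_bins),
      bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
      n_cells = n_in,
      fraction = frac_in
    )
    curve$se <- sqrt(curve$fraction * (1 - curve$fraction) /
                       pmax(curve$n_cells, 1))
    curve$fraction_smooth <- gaussian_smooth(curve$fraction, smooth_sigma)
    out$curve <- curve
  }
  structure(out, class = "lineage_regression")
}

gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  n <- length(y)
  idx <- seq_len(n)
  vapply(idx, function(i) {
    w <- exp(-(idx - i)^2 / (2 * sigma^2))
    ok <- !is.na(y)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * y[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Sample initial phase-point positions from the primitive activated region
#'
#' The default initialization rule for phase-point simulations: cells of the
#' activated timepoint whose pseudotime lies below that group's `q`-th
#' quantile.
#'
#' @param coords cells x d embedding coordinates.
#' @param pseudotime per-cell pseudotime.
#' @param activated logical per-cell flag for the activated timepoint.
#' @param n_points positions to sample (with replacement; default 1000).
#' @param q pseudotime quantile bounding the "primitive" region (default
#'   0.25).
#' @param seed sampling seed.
#' @return n_points x d matrix of starting positions.
#' @export
primitive_init <- function(coords, pseudotime, activated, n_points = 1000,
                           q = 0.25, seed = 1) {
  idx <- which(activated & pseudotime <=
                 quantile(pseudotime[activated], q))
  if (!length(idx)) abort("primitive-activated init region is empty")
  set.seed(seed)
  as.matrix(coords)[sample(idx, n_points, replace = TRUE), , drop = FALSE]
}

#' Simulate phase points through a kNN velocity field
#'
#' Advects `n_points` phase points through the embedding for `n_steps`
#' explicit-Euler steps. At each step a point's velocity is the mean
#' embedded velocity of its `k_field` nearest cells (of one group), and the
#' point moves by `step_size` times that velocity plus optional Gaussian
#' positional noise. With `noise_sd = 0` and a fixed seed the simulation is
#' bit-reproducible.
#'
#' Velocities are pre-scaled so the supplied `velocity_scale` (by default the
#' median per-cell velocity magnitude of this field) equals one; when
#' comparing groups, pass a shared scale (see [shared_velocity_scale()]).
#' `step_size = NULL` picks a step so that travel at unit speed over the
#' simulation covers about four bounding-box diagonals; groups whose
#' velocities were rescaled by a shared normalization (and hence move at a
#' fraction of unit speed) can then still traverse the full trajectory
#' within the simulated window, while convergence to the terminal attractor
#' occupies the window rather than its first few steps.
#'
#' @param coords cells x d embedding coordinates of the group's cells.
#' @param velocity_embed matching cells x d embedded velocities.
#' @param init initial positions: a matrix from [primitive_init()], or NULL
#'   to sample uniformly from `coords` rows.
#' @param n_points points to simulate when `init` is NULL (default 1000).
#' @param n_steps Euler steps (default 5000).
#' @param k_field neighbors for the velocity lookup (default 30).
#' @param step_size Euler step length (NULL = automatic, see Details).
#' @param noise_sd positional jitter per step per coordinate (default 0).
#' @param velocity_scale magnitude that is rescaled to one (NULL = this
#'   field's median magnitude).
#' @param record_stride store positions every this many steps (default
#'   keeps about 200 snapshots).
#' @param density_grid number of density-histogram cells per axis (default
#'   100 over the embedding bounding box).
#' @param seed RNG seed (noise and any init sampling).
#' @return A `phase_sim` list: `trajectories` (n_points x n_recorded x d
#'   array), `rec_steps`, `terminal` (n_points x d), `density` (grid
#'   matrix with attributes `xlim`/`ylim`), and the effective `step_size`
#'   and `velocity_scale`.
#' @export
simulate_phase_points <- function(coords, velocity_embed, init = NULL,
                                  n_points = 1000, n_steps = 5000,
                                  k_field = 30, step_size = NULL,
                                  noise_sd = 0, velocity_scale = NULL,
                                  record_stride = NULL, density_grid = 100,
                                  seed = 1) {
  coords <- as.matrix(coords)
  v <- as.matrix(velocity_embed)
  stopifnot(all(dim(coords) == dim(v)))
  if (nrow(coords) < k_field) abort("group has fewer cells than `k_field`")
  set.seed(seed)
  if (is.null(init)) {
    init <- coords[sample.int(nrow(coords), n_points, replace = TRUE), ,
                   drop = FALSE]
  }
  init <- as.matrix(init)
  if (is.null(velocity_scale)) {
    velocity_scale <- median(field_magnitudes(coords, v, k = k_field))
  }
  if (velocity_scale > 0) v <- v / velocity_scale
  rng <- apply(coords, 2, range)
  diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  if (is.null(step_size)) {
    step_size <- 4 * diag_len / n_steps
  }
  if (is.null(record_stride)) {
    record_stride <- max(1L, floor(n_steps / 200))
  }
  pad <- 0.05 * (rng[2, 1:2] - rng[1, 1:2] + 1e-9)
  xlim <- c(rng[1, 1] - pad[1], rng[2, 1] + pad[1])
  ylim <- if (ncol(coords) >= 2) c(rng[1, 2] - pad[2], rng[2, 2] + pad[2]) else c(-1, 1)
  res <- cpp_phase_sim(coords, v, init, as.integer(n_steps),
                       as.integer(k_field), step_size, noise_sd,
                       as.integer(record_stride),
                       as.integer(density_grid), as.integer(density_grid),
                       xlim, ylim)
  attr(res$density, "xlim") <- xlim
  attr(res$density, "ylim") <- ylim
  structure(list(trajectories = res$trajectories,
                 rec_steps = as.integer(res$rec_steps),
                 terminal = res$terminal, density = res$density,
                 init = init, n_steps = n_steps, step_size = step_size,
                 velocity_scale = velocity_scale, noise_sd = noise_sd,
                 k_field = k_field),
            class = "phase_sim")
}

#' Magnitude of the kNN-averaged velocity field at each cell
#'
#' Evaluates the velocity field the phase simulation will actually see -
#' the mean velocity of each position's `k` nearest cells - at every cell
#' position, and returns the per-cell field magnitudes. Per-cell velocity
#' noise is averaged down by the neighborhood mean, so these magnitudes
#' reflect the systematic field rather than count noise.
#'
#' @param coords cells x d embedding coordinates.
#' @param velocity_embed matching cells x d embedded velocities.
#' @param k neighborhood size (default 30, matching the simulation default).
#' @return numeric per-cell field magnitudes.
#' @export
field_magnitudes <- function(coords, velocity_embed, k = 30) {
  coords <- as.matrix(coords)
  v <- as.matrix(velocity_embed)
  nb <- cpp_knn_query(coords, coords, as.integer(min(k, nrow(coords))))
  f <- t(vapply(seq_len(nrow(v)),
                function(i) colMeans(v[nb[i, ], , drop = FALSE]),
                numeric(ncol(v))))
  sqrt(rowSums(f^2))
}

#' Median field magnitude shared across groups
#'
#' Computes one normalization constant from the pooled kNN-averaged field
#' magnitudes of several groups, so group simulations remain comparable
#' (each group's velocities are divided by the same constant).
#'
#' @param ... per-group `list(coords = , velocity = )` pairs (or a single
#'   list of such pairs); plain velocity matrices are accepted for backward
#'   compatibility and are then used without field averaging.
#' @param k field-averaging neighborhood (default 30).
#' @return scalar median field magnitude.
#' @export
shared_velocity_scale <- function(..., k = 30) {
  vs <- list(...)
  if (length(vs) == 1 && is.list(vs[[1]]) && !is.matrix(vs[[1]]) &&
      is.null(vs[[1]]$coords)) {
    vs <- vs[[1]]
  }
  mags <- unlist(lapply(vs, function(x) {
    if (is.list(x) && !is.null(x$coords)) {
      field_magnitudes(x$coords, x$velocity, k = k)
    } else {
      sqrt(rowSums(as.matrix(x)^2))
    }
  }))
  median(mags)
}

#' Compare pseudotime progression between two phase-point simulations
#'
#' Predicts a pseudotime coordinate for every recorded phase-point position
#' with the kNN regression map and summarizes, per recorded step, the mean
#' inferred pseudotime of each simulation and their difference. Also reports
#' the distance between the two terminal-position centroids.
#'
#' @param result_a,result_b `phase_sim` objects sharing the embedding
#'   convention of `map`.
#' @param map a `pseudotime_map`.
#' @return A `progression_comparison` list: `curves` (tibble `step`,
#'   `mean_pt_a`, `mean_pt_b`, `diff`), `terminal_centroid_distance`.
#' @export
compare_progression <- function(result_a, result_b, map) {
  da <- dim(result_a$trajectories)
  db <- dim(result_b$trajectories)
  if (da[3] != db[3] || da[3] != ncol(map$coords)) {
    abort("phase simulations and map must share embedding dimensionality")
  }
  pt_curve <- function(res) {
    d <- dim(res$trajectories)
    flat <- matrix(aperm(res$trajectories, c(1, 2, 3)), d[1] * d[2], d[3])
    pt <- predict(map, flat)
    colMeans(matrix(pt, d[1], d[2]))
  }
  a <- pt_curve(result_a)
  b <- pt_curve(result_b)
  steps <- intersect(result_a$rec_steps, result_b$rec_steps)
  ia <- match(steps, result_a$rec_steps)
  ib <- match(steps, result_b$rec_steps)
  curves <- tibble(step = steps, mean_pt_a = a[ia], mean_pt_b = b[ib],
                   diff = a[ia] - b[ib])
  cent_a <- colMeans(result_a$terminal)
  cent_b <- colMeans(result_b$terminal)
  structure(list(curves = curves,
                 terminal_centroid_distance = sqrt(sum((cent_a - cent_b)^2))),
            class = "progression_comparison")
}

#' Per-gene velocity difference between forward- and backward-moving cells
#'
#' For each gene, the difference between the mean velocity in forward-moving
#' (non-regressing) cells and backward-moving (regressing) cells, ranked in
#' descending order.
#'
#' @param velocity_gene genes x cells velocity matrix.
#' @param regressing_mask logical per-cell mask (TRUE = backward-moving).
#' @return tibble with `gene_id`, `forward_mean`, `backward_mean`,
#'   `difference`, `rank` (1 = largest difference), sorted by rank.
#' @export
velocity_difference_by_direction <- function(velocity_gene, regressing_mask) {
  regressing_mask <- as.logical(regressing_mask)
  if (!any(regressing_mask) || all(regressing_mask)) {
    abort("both forward and backward directions must be non-empty")
  }
  fw <- unname(rowMeans(velocity_gene[, !regressing_mask, drop = FALSE]))
  bw <- unname(rowMeans(velocity_gene[, regressing_mask, drop = FALSE]))
  out <- tibble(gene_id = rownames(velocity_gene) %||%
                  paste0("gene", seq_along(fw)),
                forward_mean = fw, backward_mean = bw,
                difference = fw - bw)
  out$rank <- rank(-out$difference, ties.method = "first")
  arrange(out, .data$rank)
}
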