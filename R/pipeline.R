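#' Full RNA-velocity kinetics workflow for an activation dataset
#'
#' Chains the transcriptome kinetics stages into one call: a preliminary
#' embedding to order cells, pseudotime-extreme anchor selection, the
#' anchored steady-state degradation fit, velocity computation, the final
#' embedding (fitted on the size-normalized spliced layer so velocities
#' project through the same transform), the rank-scaled pseudotime
#' fallback, velocity projection, and the kNN pseudotime regression map.
#'
#' @param x a [layered_counts()] object with `timepoint` (and typically
#'   `age`) in its cell metadata.
#' @param d embedding dimensionality (default 2).
#' @param n_hvg variable genes for the embeddings (default all).
#' @param anchor_quantile pseudotime quantile defining the root/terminal
#'   anchor sets for the degradation fit (default 0.3: bottom and top 30%).
#' @param pool_k kNN pooling size for the degradation fit (default 30).
#' @param map_k neighbor count of the pseudotime regression map (default 5).
#' @param pseudotime optional externally computed per-cell pseudotime; the
#'   rank-PC1 fallback is used when absent.
#' @return A `kinetics_state` list: `field` (velocity field), `embedding`
#'   (with pseudotime), `velocity_embed` (cells x d), `map`
#'   (pseudotime regression map), and `cell_metadata`.
#' @export
activation_kinetics <- function(x, d = 2, n_hvg = NULL, anchor_quantile = 0.3,
                                pool_k = 30, map_k = 5, pseudotime = NULL) {
  stopifnot(inherits(x, "layered_counts"))
  md <- x$cell_metadata
  if (!"timepoint" %in% names(md)) abort("cell metadata must contain `timepoint`")
  activated <- md$timepoint == "activated"

  pre <- preprocess_embed(x, n_hvg = n_hvg, d = 2)
  pre <- assign_pseudotime(pre, values = pseudotime, activated = activated)
  anchors <- rep(NA_character_, nrow(md))
  anchors[pre$pseudotime <= quantile(pre$pseudotime, anchor_quantile)] <- "root"
  anchors[pre$pseudotime >= quantile(pre$pseudotime, 1 - anchor_quantile)] <- "terminal"

  fit <- fit_gamma(x$spliced, x$unspliced, pool_k = pool_k, anchors = anchors)
  field <- compute_velocity(fit)
  emb <- preprocess_embed(field$spliced_norm, scale_total = NULL, log = TRUE,
                          n_hvg = n_hvg, d = d)
  emb <- assign_pseudotime(emb, values = pseudotime, activated = activated)
  v_embed <- embed_velocity(field, emb)
  map <- fit_pseudotime_map(emb, k = map_k)
  structure(list(field = field, embedding = emb, velocity_embed = v_embed,
                 map = map, cell_metadata = md),
            class = "kinetics_state")
}

#' @export
print.kinetics_state <- function(x, ...) {
  cat(sprintf("<kinetics_state> %d cells, %d genes, %d components\n",
              nrow(x$embedding$coordinates), nrow(x$field$spliced_norm),
              ncol(x$embedding$coordinates)))
  invisible(x)
}

#' Compare state-transition kinetics between two cell groups
#'
#' Runs the group-level kinetic comparison of an activation dataset: binned
#' velocity-magnitude curves on a common pseudotime axis, and phase-point
#' simulations through each group's velocity field from a shared set of
#' initial positions in the primitive activated region, summarized by
#' [compare_progression()].
#'
#' @param ks a `kinetics_state` from [activation_kinetics()].
#' @param group per-cell two-level factor (e.g. age); the FIRST level is
#'   reported as group A.
#' @param n_bins pseudotime bins for the magnitude curves (default 20).
#' @param n_points,n_steps phase-simulation size (defaults 1000 x 2000).
#' @param k_field velocity-lookup neighborhood (default 30).
#' @param noise_sd positional jitter per step (default 0).
#' @param seed seed for initialization sampling and per-group simulations.
#' @return A `kinetics_comparison` list: `curve_a`, `curve_b` (magnitude
#'   tibbles), `sim_a`, `sim_b` (`phase_sim` objects), `progression`
#'   (a `progression_comparison`), `levels`.
#' @export
compare_group_kinetics <- function(ks, group, n_bins = 20, n_points = 1000,
                                   n_steps = 2000, k_field = 30,
                                   noise_sd = 0, seed = 1) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  a <- g == levels(g)[1]
  emb <- ks$embedding
  pt <- emb$pseudotime
  v <- ks$velocity_embed
  breaks <- seq(min(pt), max(pt), length.out = n_bins + 1)
  curve_a <- magnitude_by_pseudotime(v[a, , drop = FALSE], pt[a], breaks = breaks)
  curve_b <- magnitude_by_pseudotime(v[!a, , drop = FALSE], pt[!a], breaks = breaks)
  vs <- shared_velocity_scale(
    list(coords = emb$coordinates[a, , drop = FALSE], velocity = v[a, , drop = FALSE]),
    list(coords = emb$coordinates[!a, , drop = FALSE], velocity = v[!a, , drop = FALSE]),
    k = k_field
  )
  activated <- ks$cell_metadata$timepoint == "activated"
  init <- primitive_init(emb$coordinates, pt, activated, n_points = n_points,
                         seed = seed)
  sim_a <- simulate_phase_points(emb$coordinates[a, , drop = FALSE],
                                 v[a, , drop = FALSE], init = init,
                                 n_steps = n_steps, k_field = k_field,
                                 noise_sd = noise_sd, velocity_scale = vs,
                                 seed = seed + 1)
  sim_b <- simulate_phase_points(emb$coordinates[!a, , drop = FALSE],
                                 v[!a, , drop = FALSE], init = init,
                                 n_steps = n_steps, k_field = k_field,
                                 noise_sd = noise_sd, velocity_scale = vs,
                                 seed = seed + 2)
  structure(list(curve_a = curve_a, curve_b = curve_b,
                 sim_a = sim_a, sim_b = sim_b,
                 progression = compare_progression(sim_a, sim_b, ks$map),
                 levels = levels(g)),
            class = "kinetics_comparison")
}

#' @export
print.kinetics_comparison <- function(x, ...) {
  ok <- !x$curve_a$masked & !x$curve_b$masked
  cat(sprintf("<kinetics_comparison> %s vs %s\n", x$levels[1], x$levels[2]))
  cat(sprintf("mean binned velocity magnitude: %.3f vs %.3f over %d matched bins\n",
              mean(x$curve_a$magnitude_smooth[ok]),
              mean(x$curve_b$magnitude_smooth[ok]), sum(ok)))
  cat(sprintf("terminal centroid distance: %.3f\n",
              x$progression$terminal_centroid_distance))
  invisible(x)
}

#' Robustness of the group kinetics comparison to seeds and noise
#'
#' Reruns the phase-point group comparison over a grid of initialization
#' seeds and per-step positional noise levels and tabulates the headline
#' outcomes, echoing the robustness-to-initialization-and-noise check of
#' dynamical phase-point analyses.
#'
#' @param ks a `kinetics_state`.
#' @param group two-level per-cell factor.
#' @param seeds integer vector of seeds.
#' @param noise_grid numeric vector of `noise_sd` values (default `c(0, 0.01, 0.05)`).
#' @param ... further arguments passed to [compare_group_kinetics()].
#' @return tibble with one row per (seed, noise_sd): early-step fraction on
#'   which group B lags group A, terminal centroid distance, and the two
#'   groups' mean matched-bin velocity magnitudes.
#' @export
phase_robustness <- function(ks, group, seeds = 1:3,
                             noise_grid = c(0, 0.01, 0.05), ...) {
  grid <- expand.grid(seed = seeds, noise_sd = noise_grid)
  purrr::map2(grid$seed, grid$noise_sd, function(sd_, ns) {
    cmp <- compare_group_kinetics(ks, group, noise_sd = ns, seed = sd_, ...)
    cv <- cmp$progression$curves
    early <- cv[cv$step > 0 & cv$step <= max(cv$step) / 10, ]
    ok <- !cmp$curve_a$masked & !cmp$curve_b$masked
    tibble(seed = sd_, noise_sd = ns,
           early_b_behind_fraction = mean(early$mean_pt_b < early$mean_pt_a),
           terminal_centroid_distance = cmp$progression$terminal_centroid_distance,
           magnitude_a = mean(cmp$curve_a$magnitude_smooth[ok]),
           magnitude_b = mean(cmp$curve_b$magnitude_smooth[ok]))
  }) %>% bind_rows()
}
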