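#' Tidy a pseudotime map
#'
#' @param x a `pseudotime_map`.
#' @param ... unused.
#' @return tibble of reference coordinates and pseudotime.
#' @export
tidy.pseudotime_map <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$coords))
  names(out) <- paste0("dim", seq_len(ncol(out)))
  out$pseudotime <- x$pseudotime
  out
}

#' @rdname tidy.pseudotime_map
#' @export
glance.pseudotime_map <- function(x, ...) {
  tibble(n_reference = nrow(x$coords), k = x$k, weighting = x$weighting,
         pt_min = min(x$pseudotime), pt_max = max(x$pseudotime))
}

#' Tidy a lineage-regression classification
#'
#' @param x a `lineage_regression` object.
#' @param ... unused.
#' @return the per-bin frequency curve when present, otherwise the per-cell
#'   mask as a tibble.
#' @export
tidy.lineage_regression <- function(x, ...) {
  if (!is.null(x$curve)) x$curve else tibble(regressing = x$mask)
}

#' @rdname tidy.lineage_regression
#' @export
glance.lineage_regression <- function(x, ...) {
  tibble(fraction = x$fraction, sd = x$sd, threshold = x$threshold,
         threshold_multiplier = x$threshold_multiplier, n = length(x$mask))
}

#' Tidy a sparse classification path
#'
#' @param x a `sparse_path`.
#' @param ... unused.
#' @return the per-C path tibble.
#' @export
tidy.sparse_path <- function(x, ...) x$path

#' @rdname tidy.sparse_path
#' @export
glance.sparse_path <- function(x, ...) {
  tibble(chosen_c = x$chosen_c, n_selected = length(x$selected_genes),
         accuracy_at_chosen = x$accuracy_at_chosen,
         best_accuracy = x$best_accuracy, one_se = x$one_se)
}

#' Tidy a KL divergence estimate
#'
#' @param x a `kl_estimate`.
#' @param ... unused.
#' @return one-row tibble with the estimate and classifier accuracy.
#' @export
tidy.kl_estimate <- function(x, ...) {
  tibble(kl = x$kl, accuracy = x$accuracy, n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.kl_estimate
#' @export
glance.kl_estimate <- function(x, ...) tidy.kl_estimate(x)

#' Tidy a phase-point simulation
#'
#' @param x a `phase_sim`.
#' @param ... unused.
#' @return tibble of recorded positions (`point`, `step`, `dim1`, `dim2`,
#'   ...).
#' @export
tidy.phase_sim <- function(x, ...) {
  d <- dim(x$trajectories)
  flat <- matrix(x$trajectories, d[1] * d[2], d[3])
  out <- tibble(point = rep(seq_len(d[1]), d[2]),
                step = rep(x$rec_steps, each = d[1]))
  for (c in seq_len(d[3])) out[[paste0("dim", c)]] <- flat[, c]
  out
}

#' @rdname tidy.phase_sim
#' @export
glance.phase_sim <- function(x, ...) {
  tibble(n_points = dim(x$trajectories)[1], n_steps = x$n_steps,
         step_size = x$step_size, velocity_scale = x$velocity_scale,
         noise_sd = x$noise_sd, k_field = x$k_field)
}

#' Tidy a progression comparison
#'
#' @param x a `progression_comparison`.
#' @param ... unused.
#' @return per-step curve tibble.
#' @export
tidy.progression_comparison <- function(x, ...) x$curves

#' @rdname tidy.progression_comparison
#' @export
glance.progression_comparison <- function(x, ...) {
  tibble(terminal_centroid_distance = x$terminal_centroid_distance,
         n_steps_compared = nrow(x$curves))
}
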