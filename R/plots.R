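#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_tile geom_col labs theme_minimal scale_fill_viridis_c
NULL

#' @export
ggplot2::autoplot

#' Plot a binned velocity-magnitude curve
#'
#' @param object tibble from [magnitude_by_pseudotime()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_velocity_curve <- function(object, ...) {
  ggplot(filter(object, !.data$masked),
         aes(x = .data$bin_center, y = .data$magnitude_smooth)) +
    geom_line(linewidth = 0.8) +
    geom_point(aes(y = .data$magnitude), alpha = 0.5) +
    labs(x = "pseudotime", y = "mean velocity magnitude") +
    theme_minimal()
}

#' @param object a `lineage_regression` with a frequency curve.
#' @param ... unused.
#' @rdname classify_lineage_regression
#' @export
autoplot.lineage_regression <- function(object, ...) {
  if (is.null(object$curve)) abort("no frequency curve; pass pseudotime when classifying")
  cv <- filter(object$curve, !is.na(.data$fraction))
  ggplot(cv, aes(x = .data$bin_center, y = .data$fraction_smooth)) +
    geom_ribbon(aes(ymin = pmax(.data$fraction - .data$se, 0),
                    ymax = pmin(.data$fraction + .data$se, 1)), alpha = 0.2) +
    geom_line(linewidth = 0.8) +
    labs(x = "pseudotime", y = "fraction regressing") +
    theme_minimal()
}

#' @param object a `phase_sim`.
#' @param ... unused.
#' @rdname simulate_phase_points
#' @export
autoplot.phase_sim <- function(object, ...) {
  dens <- object$density
  xl <- attr(dens, "xlim"); yl <- attr(dens, "ylim")
  df <- expand.grid(
    x = seq(xl[1], xl[2], length.out = nrow(dens)),
    y = seq(yl[1], yl[2], length.out = ncol(dens))
  )
  df$visits <- as.numeric(dens)
  ggplot(df, aes(.data$x, .data$y, fill = log1p(.data$visits))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log1p(visits)") +
    labs(x = "dim 1", y = "dim 2") +
    theme_minimal()
}

#' @param object a `progression_comparison`.
#' @param ... unused.
#' @rdname compare_progression
#' @export
autoplot.progression_comparison <- function(object, ...) {
  cv <- tidyr::pivot_longer(object$curves, c("mean_pt_a", "mean_pt_b"),
                            names_to = "group", values_to = "mean_pt")
  ggplot(cv, aes(.data$step, .data$mean_pt, color = .data$group)) +
    geom_line(linewidth = 0.8) +
    labs(x = "simulation step", y = "mean inferred pseudotime") +
    theme_minimal()
}

#' @param object a `sparse_path`.
#' @param ... unused.
#' @rdname fit_sparse_path
#' @export
autoplot.sparse_path <- function(object, ...) {
  ggplot(object$path, aes(.data$c, .data$accuracy)) +
    geom_line() + geom_point(aes(size = .data$n_nonzero), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$chosen_c, linetype = 2) +
    labs(x = "C (inverse regularization strength)", y = "holdout accuracy",
         size = "nonzero genes") +
    theme_minimal()
}
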