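#' Extract behavioral features from motility tracks
#'
#' Computes a 10-feature behavioral profile per cell over an analysis window:
#' total path length, net displacement, net/total ratio, mean/max/min speed
#' (um per minute), linearity (squared Pearson correlation of y on x;
#' 1 for an axis-aligned line, 0 for a stationary cell), progressivity
#' (Spearman rank correlation of distance-from-origin with time), mean cosine
#' of the turning angle between successive displacements, and the fraction of
#' frames moving faster than `move_threshold`.
#'
#' All features except linearity are invariant to translation and rotation of
#' the field of view; linearity is measured in the camera's axis convention.
#'
#' @param tracks tibble with `cell_id`, `frame`, `x_um`, `y_um` (a `time_h`
#'   column is derived from `frame` and `frame_interval_min` when absent).
#' @param frame_interval_min minutes per frame (default 6.5).
#' @param window_h analysis window in hours, default `c(10, 35)` — the
#'   standard tracking window for activation time lapses. `NULL` uses all
#'   frames.
#' @param move_threshold speed above which a frame counts as "moving", in um
#'   per frame (default 0.5, about one pixel).
#' @return tibble of features, one row per cell; cells with fewer than 3
#'   frames in the window are dropped with a message.
#' @export
extract_features <- function(tracks, frame_interval_min = 6.5,
                             window_h = c(10, 35), move_threshold = 0.5) {
  tracks <- as_tibble(tracks)
  all_cells <- unique(tracks$cell_id)
  if (!"time_h" %in% names(tracks)) {
    tracks$time_h <- tracks$frame * frame_interval_min / 60
  }
  if (!is.null(window_h)) {
    tracks <- filter(tracks, .data$time_h >= window_h[1],
                     .data$time_h <= window_h[2])
  }
  n_frames <- tracks %>% count(.data$cell_id)
  short <- union(n_frames$cell_id[n_frames$n < 3],
                 setdiff(all_cells, n_frames$cell_id))
  if (length(short)) {
    message(length(short), " track(s) shorter than the window were excluded")
    tracks <- filter(tracks, !.data$cell_id %in% short)
  }
  if (!nrow(tracks)) abort("no tracks long enough for feature extraction")
  tracks <- arrange(tracks, .data$cell_id, .data$frame)
  xs <- split(tracks$x_um, tracks$cell_id)
  ys <- split(tracks$y_um, tracks$cell_id)
  feats <- t(vapply(seq_along(xs), function(i) {
    track_features_one(xs[[i]], ys[[i]], frame_interval_min, move_threshold)
  }, numeric(10)))
  colnames(feats) <- c("total_distance", "net_distance", "net_total_ratio",
                       "mean_speed", "max_speed", "min_speed", "linearity",
                       "progressivity", "mean_turn_angle_cos",
                       "time_moving_fraction")
  bind_cols(tibble(cell_id = names(xs)), as_tibble(feats))
}

track_features_one <- function(x, y, frame_interval_min, move_threshold) {
  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)
  total <- sum(step)
  net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  speeds <- step / frame_interval_min
  r_from_origin <- sqrt((x - x[1])^2 + (y - y[1])^2)
  lin <- if (total == 0) 0
         else if (var(x) < 1e-12 || var(y) < 1e-12) 1
         else cor(x, y)^2
  prog <- if (total == 0 || var(r_from_origin) < 1e-12) 0
          else suppressWarnings(cor(r_from_origin, seq_along(r_from_origin),
                                    method = "spearman"))
  nz <- which(step > 1e-12)
  turn <- 0
  if (length(nz) >= 2) {
    i <- nz[-length(nz)]; j <- nz[-1]
    cosang <- (dx[i] * dx[j] + dy[i] * dy[j]) / (step[i] * step[j])
    turn <- mean(pmin(pmax(cosang, -1), 1))
  }
  c(total, net, if (total == 0) 0 else net / total,
    mean(speeds), max(speeds), min(speeds), lin, prog, turn,
    mean(step > move_threshold))
}

feature_matrix <- function(features) {
  m <- as.matrix(features[setdiff(names(features),
                                  c("cell_id", "group", "sub_window"))])
  rownames(m) <- features$cell_id
  m
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s < 1e-12] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

#' Hierarchically cluster behavior states
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between
#' z-scored feature vectors (population mean 0, variance 1 per feature), cut
#' at `k` states. Labels are ordered by ascending cluster-mean `mean_speed`,
#' so cluster 1 is the least motile state.
#'
#' @param features output of [extract_features()].
#' @param k number of behavior states (default 3).
#' @return tibble (`cell_id`, `cluster`) with the `hclust` dendrogram in a
#'   `dendrogram` attribute.
#' @export
cluster_behavior <- function(features, k = 3) {
  if (k < 2) abort("`k` must be at least 2")
  m <- feature_matrix(features)
  if (nrow(m) < k) abort("fewer cells than clusters")
  z <- zscore_cols(m)
  hc <- hclust(dist(z), method = "ward.D2")
  raw <- cutree(hc, k = k)
  speed_by <- tapply(features$mean_speed, raw, mean)
  remap <- rank(speed_by, ties.method = "first")
  out <- tibble(cell_id = features$cell_id,
                cluster = as.integer(remap[as.character(raw)]))
  attr(out, "dendrogram") <- hc
  out
}

#' Build a behavior state space with per-cell transition vectors
#'
#' Splits the analysis window into two equal halves, extracts features per
#' half, z-scores them jointly, embeds both halves in one behavior PCA
#' (fitted on the stacked half-window features), and defines each cell's
#' transition vector as its later-half coordinates minus its earlier-half
#' coordinates.
#'
#' @inheritParams extract_features
#' @param d behavior-PCA dimensionality for transitions (default 2).
#' @return A `behavior_space` list: `features` (full-window feature tibble),
#'   `half_features`, `coords_early`, `coords_late` (cells x d), and
#'   `transitions` (cells x d matrix, later minus earlier).
#' @export
behavior_space <- function(tracks, frame_interval_min = 6.5,
                           window_h = c(10, 35), move_threshold = 0.5, d = 2) {
  mid <- mean(window_h)
  early <- extract_features(tracks, frame_interval_min,
                            c(window_h[1], mid), move_threshold)
  late <- extract_features(tracks, frame_interval_min,
                           c(mid, window_h[2]), move_threshold)
  common <- intersect(early$cell_id, late$cell_id)
  early <- early[match(common, early$cell_id), ]
  late <- late[match(common, late$cell_id), ]
  stacked <- rbind(feature_matrix(early), feature_matrix(late))
  z <- zscore_cols(stacked)
  pc <- prcomp(z, center = FALSE, rank. = d)
  flip <- apply(pc$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  n <- length(common)
  coords_early <- scores[seq_len(n), , drop = FALSE]
  coords_late <- scores[n + seq_len(n), , drop = FALSE]
  rownames(coords_early) <- rownames(coords_late) <- common
  structure(list(
    cell_id = common,
    features = extract_features(tracks, frame_interval_min, window_h,
                                move_threshold),
    coords_early = coords_early, coords_late = coords_late,
    transitions = coords_late - coords_early
  ), class = "behavior_space")
}

#' State-transition magnitude of a cell group
#'
#' The Euclidean norm of the group's mean transition vector in behavior
#' space, with a percentile bootstrap confidence interval (cells resampled).
#' Exactly detailed-balanced transitions (paired +v/-v) give magnitude 0.
#'
#' @param transitions cells x d matrix of transition vectors, or a
#'   `behavior_space` object.
#' @param group_mask optional logical/index vector selecting the group.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return tibble with `magnitude`, `ci_lo`, `ci_hi`, `n`.
#' @export
transition_magnitude <- function(transitions, group_mask = NULL,
                                 n_boot = 1000, conf = 0.95, seed = 1) {
  if (inherits(transitions, "behavior_space")) {
    transitions <- transitions$transitions
  }
  v <- as.matrix(transitions)
  if (!is.null(group_mask)) v <- v[group_mask, , drop = FALSE]
  if (nrow(v) < 2) abort("need at least 2 cells in the group")
  mag <- sqrt(sum(colMeans(v)^2))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(v), replace = TRUE)
    sqrt(sum(colMeans(v[idx, , drop = FALSE])^2))
  }, numeric(1))
  a <- (1 - conf) / 2
  tibble(magnitude = mag,
         ci_lo = unname(quantile(boot, a)),
         ci_hi = unname(quantile(boot, 1 - a)),
         n = nrow(v))
}

#' Test for age preference among behavior states
#'
#' Contingency chi-squared test (no continuity correction) of age x behavior
#' cluster. When any expected cell count is below 1 the test falls back to
#' Fisher's exact test, flagged in the output. When a covariate (e.g. LRC
#' status) is supplied, additionally fits a logistic regression of cluster-1
#' membership on age plus the covariate and reports the Wald p-value for age.
#'
#' @param cluster integer behavior-state labels per cell.
#' @param age factor-like age labels per cell.
#' @param covariate optional factor-like per-cell covariate.
#' @return tibble with `statistic`, `df`, `p_value`, `method`, and (when a
#'   covariate is given) `age_coef` and `age_p_adjusted_for_covariate`.
#' @export
state_preference_test <- function(cluster, age, covariate = NULL) {
  tab <- table(age, cluster)
  if (any(rowSums(tab) == 0)) abort("every age must have at least one cell")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    ft <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 6)
    out <- tibble(statistic = NA_real_, df = NA_real_, p_value = ft$p.value,
                  method = "fisher_exact_fallback")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out <- tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                  p_value = ct$p.value, method = "chisq")
  }
  if (!is.null(covariate)) {
    df <- data.frame(in1 = as.integer(cluster == 1),
                     age = factor(age), cov = factor(covariate))
    fit <- glm(in1 ~ age + cov, family = binomial(), data = df)
    sm <- summary(fit)$coefficients
    age_row <- grep("^age", rownames(sm))[1]
    out$age_coef <- sm[age_row, 1]
    out$age_p_adjusted_for_covariate <- sm[age_row, 4]
  }
  out
}

#' Per-feature age comparisons with Holm-Bonferroni correction
#'
#' Two-tailed unpaired t-tests of each z-scored behavior feature between two
#' groups, Holm-Bonferroni corrected.
#'
#' @param features output of [extract_features()].
#' @param group two-level per-cell grouping.
#' @return tibble with per-feature group means (z-scored), t statistic, raw
#'   and Holm-adjusted p-values.
#' @export
compare_features <- function(features, group) {
  m <- zscore_cols(feature_matrix(features))
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  res <- purrr::map(colnames(m), function(f) {
    tt <- tryCatch(stats::t.test(m[g == lv[1], f], m[g == lv[2], f]),
                   error = function(e) NULL)  # constant feature
    tibble(feature = f,
           mean_1 = mean(m[g == lv[1], f]), mean_2 = mean(m[g == lv[2], f]),
           statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }) %>% bind_rows()
  names(res)[2:3] <- paste0("mean_", lv)
  res$p_holm <- p.adjust(res$p_value, method = "holm")
  res
}
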