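#' Simulate two-state switching motility tracks
#'
#' Cells perform a two-state (immotile / motile) random walk sampled at a
#' fixed frame interval. In the motile state a cell takes a step of random
#' length (folded-normal) in a uniformly random direction; in the immotile
#' state it does not move. Switching is a per-frame Markov chain whose
#' immotile-to-motile probability can ramp linearly over the recording to
#' emulate progressive activation; the motile-to-immotile probability is
#' constant. Aged-like populations are emulated by a weaker ramp (lower
#' motile-state occupancy).
#'
#' @param n_cells number of tracks.
#' @param duration_h recording length in hours.
#' @param frame_interval_min minutes per frame (default 6.5, the standard
#'   time-lapse sampling interval for these assays).
#' @param p_on_start,p_on_end immotile-to-motile switch probability per frame
#'   at the start and end of the recording (linear ramp between them).
#' @param p_off motile-to-immotile switch probability per frame.
#' @param speed_mean,speed_sd motile step-length distribution (um per frame);
#'   step lengths are `abs(rnorm(speed_mean, speed_sd))`.
#' @param init_state `"immotile"`, `"motile"`, or `"stationary"` (draw the
#'   initial state from the chain's stationary distribution at the starting
#'   switch rates).
#' @param group optional label stored in the output (e.g. `"young"`).
#' @param seed integer seed.
#' @return A list with `tracks`, a tibble (`cell_id`, `frame`, `time_h`,
#'   `x_um`, `y_um`, `group`), and `states`, a tibble of the ground-truth
#'   state sequence (`cell_id`, `frame`, `state`).
#' @export
simulate_tracks <- function(n_cells = 200, duration_h = 48,
                            frame_interval_min = 6.5,
                            p_on_start = 0.01, p_on_end = 0.12, p_off = 0.06,
                            speed_mean = 2.5, speed_sd = 0.8,
                            init_state = c("immotile", "motile", "stationary"),
                            group = NA_character_, seed = 1) {
  init_state <- match.arg(init_state)
  if (duration_h <= 0) abort("`duration_h` must be positive")
  n_frames <- floor(duration_h * 60 / frame_interval_min) + 1
  if (n_frames < 2) abort("duration must cover at least 2 frames")
  probs <- c(p_on_start, p_on_end, p_off)
  if (any(probs < 0 | probs > 1)) abort("switch probabilities must lie in [0,1]")
  if (speed_mean < 0 || speed_sd < 0) abort("speeds must be nonnegative")
  set.seed(seed)

  ramp <- seq(p_on_start, p_on_end, length.out = n_frames)
  # states: 0 = immotile, 1 = motile; one matrix pass over frames
  st <- matrix(0L, n_cells, n_frames)
  st[, 1] <- switch(init_state,
    immotile = 0L, motile = 1L,
    stationary = as.integer(runif(n_cells) < ramp[1] / (ramp[1] + p_off + 1e-12))
  )
  u_switch <- matrix(runif(n_cells * (n_frames - 1)), n_cells, n_frames - 1)
  for (f in 2:n_frames) {
    prev <- st[, f - 1]
    p_sw <- ifelse(prev == 1L, p_off, ramp[f])
    st[, f] <- ifelse(u_switch[, f - 1] < p_sw, 1L - prev, prev)
  }
  steps <- abs(matrix(rnorm(n_cells * (n_frames - 1), speed_mean, speed_sd),
                      n_cells, n_frames - 1))
  theta <- matrix(runif(n_cells * (n_frames - 1), 0, 2 * pi),
                  n_cells, n_frames - 1)
  moving <- st[, -1] == 1L
  dx <- steps * cos(theta) * moving
  dy <- steps * sin(theta) * moving
  x <- cbind(0, t(apply(dx, 1, cumsum)))
  y <- cbind(0, t(apply(dy, 1, cumsum)))

  prefix <- if (is.na(group)) "track" else paste0(group, "_track")
  ids <- sprintf("%s%04d", prefix, seq_len(n_cells))
  frames <- seq_len(n_frames) - 1L
  tracks <- tibble(
    cell_id = rep(ids, each = n_frames),
    frame = rep(frames, n_cells),
    time_h = rep(frames, n_cells) * frame_interval_min / 60,
    x_um = as.numeric(t(x)),
    y_um = as.numeric(t(y)),
    group = group
  )
  states <- tibble(
    cell_id = rep(ids, each = n_frames),
    frame = rep(frames, n_cells),
    state = ifelse(as.integer(t(st)) == 1L, "motile", "immotile")
  )
  list(tracks = tracks, states = states,
       frame_interval_min = frame_interval_min)
}

#' Simulate paired young and aged track sets
#'
#' The canonical two-group motility simulation: both groups share speed
#' parameters and start immotile, but the aged group's activation ramp is
#' weaker (lower final immotile-to-motile switching) and its
#' motile-to-immotile rate higher, yielding lower motile-state occupancy and
#' smaller behavior-state transitions.
#'
#' @param n_cells_per_group tracks per group (default 500).
#' @param duration_h recording length (default 48 h).
#' @param young,aged per-group switch parameters: lists with `p_on_start`,
#'   `p_on_end`, `p_off`.
#' @param speed_mean,speed_sd motile step-length parameters (um/frame).
#' @param seed integer seed (group seeds are derived from it).
#' @return list with `tracks` (both groups bound together; `group` column
#'   set) and `states`.
#' @export
simulate_track_groups <- function(n_cells_per_group = 500, duration_h = 48,
                                  young = list(p_on_start = 0.01,
                                               p_on_end = 0.12, p_off = 0.06),
                                  aged = list(p_on_start = 0.01,
                                              p_on_end = 0.05, p_off = 0.10),
                                  speed_mean = 2.5, speed_sd = 0.8, seed = 1) {
  yo <- simulate_tracks(n_cells = n_cells_per_group, duration_h = duration_h,
                        p_on_start = young$p_on_start, p_on_end = young$p_on_end,
                        p_off = young$p_off, speed_mean = speed_mean,
                        speed_sd = speed_sd, group = "young", seed = seed)
  ag <- simulate_tracks(n_cells = n_cells_per_group, duration_h = duration_h,
                        p_on_start = aged$p_on_start, p_on_end = aged$p_on_end,
                        p_off = aged$p_off, speed_mean = speed_mean,
                        speed_sd = speed_sd, group = "aged", seed = seed + 10000)
  list(tracks = dplyr::bind_rows(yo$tracks, ag$tracks),
       states = dplyr::bind_rows(yo$states, ag$states))
}
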