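#' Kinetic specification of a simulated gene
#'
#' Each simulated gene follows the standard transcription-splicing-degradation
#' model: unspliced mRNA is produced at rate alpha(t), spliced at rate beta
#' from the unspliced pool, and degraded at rate gamma,
#' \deqn{du/dt = \alpha(t) - \beta u, \qquad ds/dt = \beta u - \gamma s.}
#' The transcription rate alpha(t) varies over latent activation time t in
#' \[0, 1\] according to `profile`:
#' \describe{
#'   \item{flat}{constant `alpha_max`; cells sit at the analytic steady state
#'     u* = alpha/beta, s* = alpha/gamma.}
#'   \item{monotone_up}{alpha rises as a logistic switch from `alpha_floor`
#'     to `alpha_max` with midpoint `t_center` and steepness scale
#'     `t_width`. The switch saturates at both ends of latent time, so the
#'     most extreme cells sit near kinetic equilibrium — the regime the
#'     steady-state velocity estimator assumes.}
#'   \item{monotone_down}{the mirrored logistic decrease.}
#'   \item{pulse}{a Gaussian bump centered at `t_center` with standard
#'     deviation `t_width`, on a floor of `alpha_floor`.}
#' }
#'
#' @param profile one of `"flat"`, `"monotone_up"`, `"monotone_down"`,
#'   `"pulse"`.
#' @param alpha_max peak transcription rate (molecules per unit latent time),
#'   must be positive.
#' @param beta splicing rate (1 / unit time), positive.
#' @param gamma degradation rate (1 / unit time), positive.
#' @param noise_dispersion negative-binomial dispersion of the observed counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param alpha_floor baseline transcription rate for the time-varying
#'   profiles, as a fraction of `alpha_max`.
#' @param t_center,t_width latent-time center and width of the profile: the
#'   logistic midpoint and steepness scale for monotone profiles, the bump
#'   center and standard deviation for the pulse.
#' @param name optional gene name.
#' @return A `kinetic_gene` list.
#' @export
kinetic_gene <- function(profile = c("flat", "monotone_up", "monotone_down", "pulse"),
                         alpha_max = 20, beta = 1, gamma = 0.5,
                         noise_dispersion = 0.1, alpha_floor = 0.05,
                         t_center = 0.5, t_width = 0.12,
                         name = NULL) {
  profile <- match.arg(profile)
  bad <- c(
    if (!is.numeric(alpha_max) || alpha_max <= 0) "alpha_max",
    if (!is.numeric(beta) || beta <= 0) "beta",
    if (!is.numeric(gamma) || gamma <= 0) "gamma",
    if (!is.numeric(noise_dispersion) || noise_dispersion < 0) "noise_dispersion"
  )
  if (length(bad)) {
    abort(sprintf("invalid kinetic parameter(s) %s for gene %s",
                  paste(bad, collapse = ", "),
                  if (is.null(name)) "<unnamed>" else name))
  }
  structure(list(profile = profile, alpha_max = alpha_max, beta = beta,
                 gamma = gamma, noise_dispersion = noise_dispersion,
                 alpha_floor = alpha_floor, t_center = t_center,
                 t_width = t_width, name = name),
            class = "kinetic_gene")
}

alpha_of_t <- function(gene, t) {
  floor_rate <- gene$alpha_floor * gene$alpha_max
  rise <- stats::plogis((t - gene$t_center) / gene$t_width)
  switch(gene$profile,
    flat = rep(gene$alpha_max, length(t)),
    monotone_up = floor_rate + (gene$alpha_max - floor_rate) * rise,
    monotone_down = floor_rate + (gene$alpha_max - floor_rate) * (1 - rise),
    pulse = floor_rate + (gene$alpha_max - floor_rate) *
      exp(-(t - gene$t_center)^2 / (2 * gene$t_width^2))
  )
}

# Integrate du/dt = (alpha(t) - beta u)/rate, ds/dt = (beta u - gamma s)/rate
# over latent time t on a fine grid with the exact integrating-factor update
# per grid step (alpha held at the step midpoint). `rate` is the latent-time
# progression speed: slower groups (rate < 1) spend more wall-clock time per
# unit latent time, so their transcripts track the moving equilibrium more
# closely and their kinetic lag shrinks.
integrate_gene_kinetics <- function(gene, rate, n_grid = 512) {
  tg <- seq(0, 1, length.out = n_grid)
  dt <- tg[2] - tg[1]
  b <- gene$beta / rate
  g <- gene$gamma / rate
  a <- alpha_of_t(gene, tg) / rate
  u <- numeric(n_grid)
  s <- numeric(n_grid)
  # start at equilibrium for alpha(0)
  u[1] <- a[1] / b
  s[1] <- b * u[1] / g
  eb <- exp(-b * dt)
  eg <- exp(-g * dt)
  for (i in 2:n_grid) {
    am <- (a[i - 1] + a[i]) / 2
    u[i] <- am / b + (u[i - 1] - am / b) * eb
    prod_m <- b * (u[i - 1] + u[i]) / 2
    s[i] <- prod_m / g + (s[i - 1] - prod_m / g) * eg
  }
  list(t = tg, u = u, s = s)
}

#' Simulate a layered spliced/unspliced count matrix with known kinetics
#'
#' Generates cells along a latent activation-time axis with two discrete
#' timepoint clusters (quiescent, activated), group-specific progression-rate
#' scaling (aged cells progress more slowly), and label-retaining-cell (LRC)
#' fractions matching physiological proportions (35% in young, 15% in aged
#' animals). Per-gene mean expression comes from integrating the
#' transcription-splicing-degradation ODE at each cell's latent time with the
#' group's progression rate; observed counts are drawn negative-binomially
#' (Poisson at dispersion 0, or the rounded mean when `noise = FALSE`).
#'
#' @param genes a list of [kinetic_gene()] specs (at least one).
#' @param n_cells_per_group cells per age group (at least 2).
#' @param age_rate_multiplier named numeric vector of positive latent-time
#'   progression speeds per age; default `c(young = 1, aged = 0.5)`.
#' @param lrc_fraction named numeric fractions in \[0,1\] of label-retaining
#'   cells per age; exactly `round(fraction * n)` cells per age are labeled.
#' @param activated_fraction fraction of cells drawn from the activated
#'   latent-time mode (the rest are quiescent).
#' @param transit_fraction fraction of activated-timepoint cells drawn
#'   uniformly between the two mode centers instead of from the activated
#'   mode (default 0.2), emulating asynchronous activation: a portion of the
#'   later timepoint is still in transit along the continuous activation
#'   axis, as in real populations.
#' @param position_lag fraction of the age rate multiplier applied to latent
#'   positions (default 0.2). Ageing delays state transitions mostly at the
#'   kinetic level: per-gene spliced/unspliced imbalances always carry the
#'   full rate scaling, while latent positions are scaled by the milder
#'   `1 - position_lag * (1 - multiplier)`, so age groups overlap along the
#'   trajectory (as observed for activated-state occupancy in vivo) yet the
#'   group mean latent time stays ordered by the multiplier.
#' @param quiescent_mode,activated_mode mean and sd (latent-time units) of the
#'   two mixture components, each a length-2 numeric `c(mean, sd)`.
#' @param noise draw stochastic counts? `FALSE` returns rounded means.
#' @param depth_scale multiplier applied to every gene's mean to emulate
#'   library depth; 1 leaves rates untouched.
#' @param seed integer seed; all randomness flows through one generator.
#' @return A list with `counts` (a [layered_counts()] object) and `truth`, a
#'   tibble with per-cell `cell_id`, `age`, `lrc`, `timepoint`, `latent_time`
#'   plus a `gene_truth` attribute table of the true per-gene rates
#'   (`gamma_over_beta` is the slope recovered by the steady-state velocity
#'   fit on normalized layers).
#' @export
simulate_expression <- function(genes, n_cells_per_group = 500,
                                age_rate_multiplier = c(young = 1, aged = 0.5),
                                lrc_fraction = c(young = 0.35, aged = 0.15),
                                activated_fraction = 0.5,
                                transit_fraction = 0.2,
                                position_lag = 0.2,
                                quiescent_mode = c(0.15, 0.06),
                                activated_mode = c(0.85, 0.08),
                                noise = TRUE, depth_scale = 1, seed = 1) {
  if (inherits(genes, "kinetic_gene")) genes <- list(genes)
  if (length(genes) < 1) abort("need at least one gene spec")
  if (n_cells_per_group < 2) abort("n_cells_per_group must be >= 2")
  if (any(age_rate_multiplier <= 0)) abort("age rate multipliers must be positive")
  if (any(lrc_fraction < 0 | lrc_fraction > 1)) abort("lrc fractions must lie in [0,1]")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (!inherits(g, "kinetic_gene")) abort("`genes` must be kinetic_gene objects")
    if (is.null(g$name)) genes[[i]]$name <- paste0("gene", i)
  }
  ages <- names(age_rate_multiplier)
  set.seed(seed)

  cells <- purrr::map(ages, function(a) {
    n <- n_cells_per_group
    act <- runif(n) < activated_fraction
    transit <- act & runif(n) < transit_fraction
    tau <- ifelse(act,
                  rnorm(n, activated_mode[1], activated_mode[2]),
                  rnorm(n, quiescent_mode[1], quiescent_mode[2]))
    tau[transit] <- runif(sum(transit), quiescent_mode[1], activated_mode[1])
    tau <- pmin(pmax(tau, 0), 1)
    pos_rate <- 1 - position_lag * (1 - age_rate_multiplier[[a]])
    lt <- pmin(pos_rate * tau, 1)
    n_lrc <- round(lrc_fraction[[a]] * n)
    lrc <- rep("nonLRC", n)
    lrc[sample.int(n, n_lrc)] <- "LRC"
    tibble(age = a,
           timepoint = ifelse(act, "activated", "quiescent"),
           lrc = lrc, latent_time = lt)
  }) %>% bind_rows()
  cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))

  n_total <- nrow(cells)
  n_genes <- length(genes)
  mu_u <- matrix(0, n_genes, n_total)
  mu_s <- matrix(0, n_genes, n_total)
  for (a in ages) {
    idx <- which(cells$age == a)
    lt <- cells$latent_time[idx]
    for (j in seq_len(n_genes)) {
      kin <- integrate_gene_kinetics(genes[[j]], age_rate_multiplier[[a]])
      mu_u[j, idx] <- stats::approx(kin$t, kin$u, xout = lt)$y
      mu_s[j, idx] <- stats::approx(kin$t, kin$s, xout = lt)$y
    }
  }
  mu_u <- mu_u * depth_scale
  mu_s <- mu_s * depth_scale

  draw <- function(mu, disp) {
    if (!noise) return(round(mu))
    if (disp == 0) return(rpois(length(mu), mu))
    rnbinom(length(mu), size = 1 / disp, mu = mu)
  }
  U <- mu_u; S <- mu_s
  for (j in seq_len(n_genes)) {
    d <- genes[[j]]$noise_dispersion
    U[j, ] <- draw(mu_u[j, ], d)
    S[j, ] <- draw(mu_s[j, ], d)
  }
  gene_names <- purrr::map_chr(genes, "name")
  rownames(U) <- rownames(S) <- gene_names
  colnames(U) <- colnames(S) <- cells$cell_id

  gene_truth <- tibble(
    gene_id = gene_names,
    profile = purrr::map_chr(genes, "profile"),
    alpha_max = map_dbl(genes, "alpha_max"),
    beta = map_dbl(genes, "beta"),
    gamma = map_dbl(genes, "gamma"),
    gamma_over_beta = map_dbl(genes, ~ .x$gamma / .x$beta),
    noise_dispersion = map_dbl(genes, "noise_dispersion")
  )
  truth <- cells %>% select("cell_id", "age", "lrc", "timepoint", "latent_time")
  attr(truth, "gene_truth") <- gene_truth
  counts <- layered_counts(S, U,
                           cells %>% select("cell_id", "age", "lrc", "timepoint"))
  list(counts = counts, truth = truth, gene_truth = gene_truth)
}

#' A default gene panel for simulated activation data
#'
#' A mixture of monotone-up, monotone-down, pulse, and flat genes emulating
#' the pseudotemporal expression-module structure of activating stem cells.
#'
#' Kinetic rates default to being fast relative to the latent trajectory
#' (splicing and degradation timescales well below one latent-time unit, as
#' for mRNA turnover during a multi-day activation), so cells at the
#' trajectory extremes approach kinetic equilibrium - the regime the
#' steady-state velocity estimator assumes - while cells mid-switch carry a
#' genuine spliced/unspliced imbalance.
#'
#' @param n_up,n_down,n_pulse,n_flat number of genes of each profile.
#' @param alpha_range range of peak transcription rates (sampled uniformly).
#' @param beta splicing rate shared by all genes.
#' @param gamma_range range of degradation rates. The lower bound, together
#'   with `t_center_range`, keeps every gene's switch-plus-relaxation inside
#'   the observed trajectory, so both trajectory ends are equilibrated.
#' @param t_center_range latent-time switch centers (sampled uniformly).
#' @param t_width switch steepness / pulse width shared by all genes.
#' @param noise_dispersion NB dispersion shared by all genes.
#' @param seed integer seed.
#' @return list of [kinetic_gene()] specs.
#' @export
activation_gene_panel <- function(n_up = 30, n_down = 30, n_pulse = 20,
                                  n_flat = 20, alpha_range = c(30, 120),
                                  beta = 8, gamma_range = c(4, 10),
                                  t_center_range = c(0.3, 0.5),
                                  t_width = 0.08,
                                  noise_dispersion = 0.1, seed = 1) {
  set.seed(seed)
  profs <- rep(c("monotone_up", "monotone_down", "pulse", "flat"),
               c(n_up, n_down, n_pulse, n_flat))
  purrr::imap(profs, function(p, i) {
    kinetic_gene(profile = p,
                 alpha_max = runif(1, alpha_range[1], alpha_range[2]),
                 beta = beta,
                 gamma = runif(1, gamma_range[1], gamma_range[2]),
                 noise_dispersion = noise_dispersion,
                 t_center = runif(1, t_center_range[1], t_center_range[2]),
                 t_width = t_width,
                 name = sprintf("%s_%03d", sub("monotone_", "", p), i))
  })
}
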