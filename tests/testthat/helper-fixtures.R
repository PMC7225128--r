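# Small deterministic fixtures shared across test files.

# straight-line track along x at 1 um per frame
line_track <- function(n_frames = 10, cell = "c1") {
  tibble::tibble(cell_id = cell, frame = seq_len(n_frames) - 1L,
                 x_um = as.numeric(seq_len(n_frames) - 1L), y_um = 0)
}

stationary_track <- function(n_frames = 10, cell = "c1") {
  tibble::tibble(cell_id = cell, frame = seq_len(n_frames) - 1L,
                 x_um = 0, y_um = 0)
}

# closed unit-square loop returning to the origin
square_track <- function(cell = "c1") {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  tibble::tibble(cell_id = cell, frame = 0:4, x_um = xy[, 1], y_um = xy[, 2])
}

# minimal velocity fit list for arithmetic checks
toy_fit <- function(s, u, gamma) {
  list(spliced_norm = matrix(s, 1, length(s)),
       unspliced_norm = matrix(u, 1, length(u)),
       gamma_hat = gamma)
}

# an embedding_state with identity transform over `genes` gene names
identity_embedding <- function(genes, coords = NULL) {
  d <- length(genes)
  structure(list(
    coordinates = coords,
    loadings = diag(d),
    gene_means = stats::setNames(rep(0, d), genes),
    genes = genes, sdev = rep(1, d),
    scale_total = NULL, log = FALSE,
    cell_ids = NULL, pseudotime = NULL
  ), class = "embedding_state")
}

# steady-state flat probe genes inside the default activation panel
probe_panel <- function(ratios = c(0.2, 0.5, 1.0), panel_seed = 99) {
  probes <- lapply(ratios, function(g) {
    kinetic_gene("flat", alpha_max = 20, beta = 1, gamma = g,
                 noise_dispersion = 0.1, name = sprintf("probe_%g", g))
  })
  c(probes, activation_gene_panel(seed = panel_seed))
}
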