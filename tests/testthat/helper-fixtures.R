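# In-code fixtures shared across the suite.

# Minimal survey: one subplot, explicit counts matrix (quadrats in row-major
# order), optional env table built from named vectors of per-quadrat values.
make_survey <- function(counts, grid_shape, env = NULL, treatment = "grazed",
                        quadrat_size = 0.5, subplot = "s1") {
  counts <- as.matrix(counts)
  grid <- expand.grid(col = 0:(grid_shape[2] - 1),
                      row = 0:(grid_shape[1] - 1))[c("row", "col")]
  ab <- tibble::tibble(subplot = subplot, grid)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sp%02d", seq_len(ncol(counts)))
  }
  ab[colnames(counts)] <- as.data.frame(counts)
  ev <- NULL
  if (!is.null(env)) {
    ev <- tibble::tibble(subplot = subplot, grid)
    ev[names(env)] <- env
  }
  survey_data(ab, env = ev, treatment = treatment, grid_shape = grid_shape,
              quadrat_size = quadrat_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# survey in which every quadrat holds exactly one individual of one species
single_species_survey <- function(grid_shape = c(4, 4)) {
  make_survey(matrix(1, prod(grid_shape), 1,
                     dimnames = list(NULL, "solo")), grid_shape)
}

# small multi-subplot random community, Poisson counts, no spatial structure
random_survey <- function(grid_shape = c(6, 6), n_species = 8, n_subplots = 2,
                          lambda = 2, seed = 1, treatment = "grazed") {
  withr::with_seed(seed, {
    tabs <- lapply(seq_len(n_subplots), function(s) {
      grid <- expand.grid(col = 0:(grid_shape[2] - 1),
                          row = 0:(grid_shape[1] - 1))[c("row", "col")]
      ab <- tibble::tibble(subplot = paste0("s", s), grid)
      ab[sprintf("sp%02d", seq_len(n_species))] <-
        as.data.frame(matrix(rpois(prod(grid_shape) * n_species, lambda),
                             ncol = n_species))
      ab
    })
    survey_data(dplyr::bind_rows(tabs), treatment = treatment,
                grid_shape = grid_shape)
  })
}

# brute-force all-pairs semivariogram oracle (independent of the estimator)
brute_variogram <- function(values, coords, lag_width, max_lag) {
  coords <- as.matrix(coords)
  n <- length(values)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= max_lag) {
        rows[[length(rows) + 1]] <-
          data.frame(bin = floor(d / lag_width),
                     sq = (values[i] - values[j])^2)
      }
    }
  }
  df <- do.call(rbind, rows)
  agg_n <- aggregate(sq ~ bin, df, length)
  agg_s <- aggregate(sq ~ bin, df, sum)
  data.frame(h = (agg_n$bin + 0.5) * lag_width,
             gamma = agg_s$sq / (2 * agg_n$sq),
             np = agg_n$sq)[order(agg_n$bin), ]
}
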