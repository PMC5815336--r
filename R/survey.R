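#' Construct a quadrat-grid survey object
#'
#' A `survey` bundles everything recorded for one treatment of a gridded
#' vegetation survey: a wide per-quadrat species abundance table, an optional
#' per-quadrat environmental table, and the sampling geometry (grid shape and
#' quadrat side length). One object holds all replicate subplots of a
#' treatment; per-subplot quantities are always computed within subplot and
#' averaged afterwards (see [subplot_mean()]).
#'
#' @param abundance Data frame with columns `subplot`, `row`, `col` followed by
#'   one integer count column per species. `row`/`col` are 0-based grid
#'   indices.
#' @param env Optional data frame with columns `subplot`, `row`, `col` followed
#'   by one numeric column per environmental variable, covering every quadrat.
#' @param treatment `"grazed"` or `"fenced"`.
#' @param grid_shape Integer vector `c(rows, cols)`. Inferred from the indices
#'   when `NULL`.
#' @param quadrat_size Side length of one quadrat in metres (default 0.5).
#' @param site_id Free-text site label.
#' @param subplot_gap Distance in metres between the edges of consecutive
#'   subplots when quadrats of all subplots are laid out on one common
#'   coordinate system (used by the variance-partitioning stage). Default 5.
#'
#' @return An object of class `survey`.
#' @export
survey_data <- function(abundance, env = NULL,
                        treatment = c("grazed", "fenced"),
                        grid_shape = NULL, quadrat_size = 0.5,
                        site_id = "site", subplot_gap = 5) {
  treatment <- match.arg(treatment)
  abundance <- tibble::as_tibble(abundance)
  key <- c("subplot", "row", "col")
  if (!all(key %in% names(abundance))) {
    stop("abundance table must have columns subplot, row, col", call. = FALSE)
  }
  abundance$subplot <- as.character(abundance$subplot)
  species <- setdiff(names(abundance), key)
  if (length(species) == 0L) stop("abundance table has no species columns", call. = FALSE)
  if (is.null(grid_shape)) {
    grid_shape <- c(max(abundance$row) + 1L, max(abundance$col) + 1L)
  }
  grid_shape <- as.integer(grid_shape)

  env_vars <- character(0)
  if (!is.null(env)) {
    env <- tibble::as_tibble(env)
    if (!all(key %in% names(env))) {
      stop("env table must have columns subplot, row, col", call. = FALSE)
    }
    env$subplot <- as.character(env$subplot)
    env_vars <- setdiff(names(env), key)
  }

  x <- structure(
    list(
      abundance = abundance[c(key, species)],
      env = env,
      species = species,
      env_vars = env_vars,
      subplots = sort(unique(abundance$subplot)),
      treatment = treatment,
      site_id = site_id,
      grid_shape = grid_shape,
      quadrat_size = quadrat_size,
      subplot_gap = subplot_gap
    ),
    class = "survey"
  )
  validate_survey(x)
}

#' @export
print.survey <- function(x, ...) {
  cat(sprintf(
    "<survey> %s / %s: %d subplot(s), %dx%d grid of %.2g m quadrats, %d species%s\n",
    x$site_id, x$treatment, length(x$subplots),
    x$grid_shape[1], x$grid_shape[2], x$quadrat_size, length(x$species),
    if (is.null(x$env)) ", no env table" else
      sprintf(", %d env variables", length(x$env_vars))
  ))
  invisible(x)
}

# Hard validation of the survey invariants: complete unique grid per subplot,
# non-negative integer counts, no ragged env missingness.
validate_survey <- function(x) {
  ab <- x$abundance
  rows <- x$grid_shape[1]; cols <- x$grid_shape[2]
  bad <- ab$row < 0 | ab$row >= rows | ab$col < 0 | ab$col >= cols
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("quadrat (subplot %s, row %d, col %d) outside declared %dx%d grid",
                 ab$subplot[i], ab$row[i], ab$col[i], rows, cols), call. = FALSE)
  }
  keys <- paste(ab$subplot, ab$row, ab$col)
  if (anyDuplicated(keys)) {
    k <- keys[duplicated(keys)][1]
    stop(sprintf("duplicate quadrat key (subplot row col): %s", k), call. = FALSE)
  }
  n_per <- table(ab$subplot)
  if (any(n_per != rows * cols)) {
    s <- names(n_per)[n_per != rows * cols][1]
    stop(sprintf("subplot %s has %d quadrats, expected %d",
                 s, n_per[[s]], rows * cols), call. = FALSE)
  }
  counts <- as.matrix(ab[x$species])
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    ij <- which(is.na(counts) | !is.finite(counts) | counts < 0 |
                  counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "abundance must be a finite non-negative integer; offending cell: subplot %s, row %d, col %d, species %s (value %s)",
      ab$subplot[ij[1]], ab$row[ij[1]], ab$col[ij[1]],
      x$species[ij[2]], format(counts[ij[1], ij[2]])), call. = FALSE)
  }
  if (!is.null(x$env)) {
    ek <- paste(x$env$subplot, x$env$row, x$env$col)
    if (anyDuplicated(ek)) stop("duplicate quadrat key in env table", call. = FALSE)
    if (!setequal(ek, keys) || length(ek) != length(keys)) {
      stop("env table must cover exactly the quadrats of the abundance table", call. = FALSE)
    }
    if (anyNA(x$env[x$env_vars])) {
      stop("env variables must be present for every quadrat (no ragged missingness); drop the variable or the whole env table instead", call. = FALSE)
    }
  }
  x
}

#' Read a survey from CSV tables
#'
#' Two layouts are supported: (a) separate abundance and environment CSVs, each
#' keyed by `subplot,row,col`; (b) a single wide CSV holding both, where
#' species columns are identified by a common name prefix and all remaining
#' non-key columns are treated as environmental variables.
#'
#' @param abundance_path CSV with header `subplot,row,col,<species...>`, or the
#'   combined wide CSV when `species_prefix` is given.
#' @param env_path Optional CSV with header `subplot,row,col,<var...>`. Ignored
#'   when `species_prefix` is used.
#' @param species_prefix If non-`NULL`, columns of `abundance_path` whose names
#'   start with this prefix are species counts and the rest (minus the key) are
#'   environment.
#' @inheritParams survey_data
#' @return A validated [survey_data()] object.
#' @export
read_survey <- function(abundance_path, env_path = NULL, species_prefix = NULL,
                        treatment = c("grazed", "fenced"), grid_shape = NULL,
                        quadrat_size = 0.5, site_id = "site") {
  tab <- readr::read_csv(abundance_path, show_col_types = FALSE, progress = FALSE)
  env <- NULL
  if (!is.null(species_prefix)) {
    key <- c("subplot", "row", "col")
    sp <- grep(paste0("^", species_prefix), setdiff(names(tab), key), value = TRUE)
    if (length(sp) == 0L) {
      stop(sprintf("no columns start with species prefix '%s'", species_prefix),
           call. = FALSE)
    }
    ev <- setdiff(names(tab), c(key, sp))
    if (length(ev) > 0) env <- tab[c(key, ev)]
    tab <- tab[c(key, sp)]
  } else if (!is.null(env_path)) {
    env <- readr::read_csv(env_path, show_col_types = FALSE, progress = FALSE)
  }
  survey_data(tab, env = env, treatment = treatment, grid_shape = grid_shape,
              quadrat_size = quadrat_size, site_id = site_id)
}

#' Write a survey to CSV tables
#'
#' Inverse of [read_survey()] in the two-file layout; `read_survey()` on the
#' written files reproduces the object.
#'
#' @param x A `survey`.
#' @param abundance_path,env_path Output CSV paths; `env_path` may be `NULL`
#'   when the survey has no environment table.
#' @return `x`, invisibly.
#' @export
write_survey <- function(x, abundance_path, env_path = NULL) {
  stopifnot(inherits(x, "survey"))
  readr::write_csv(x$abundance, abundance_path, progress = FALSE)
  if (!is.null(x$env)) {
    if (is.null(env_path)) stop("survey has an env table but env_path is NULL", call. = FALSE)
    readr::write_csv(x$env, env_path, progress = FALSE)
  }
  invisible(x)
}

#' Enumerate square sampling windows on a quadrat grid
#'
#' Windows are squares of `k` x `k` quadrats. In `tiling` mode (the default)
#' windows are non-overlapping, anchored at (0,0); leftover quadrats on the
#' far edges are dropped when `k` does not divide the grid. In `sliding` mode
#' every possible placement is returned.
#'
#' @param grid_shape `c(rows, cols)`.
#' @param k Window side length in quadrat units, `1 <= k <= min(rows, cols)`.
#' @param mode `"tiling"` or `"sliding"`.
#' @param quadrat_size Quadrat side in metres, used for the window area.
#' @return Tibble with 0-based window origins `window_row`, `window_col`, the
#'   side `k` and the window `area` in m^2.
#' @export
enumerate_windows <- function(grid_shape, k, mode = c("tiling", "sliding"),
                              quadrat_size = 0.5) {
  mode <- match.arg(mode)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (k < 1 || k > min(rows, cols)) {
    stop(sprintf("k must be in [1, %d], got %s", min(rows, cols), format(k)),
         call. = FALSE)
  }
  k <- as.integer(k)
  if (mode == "tiling") {
    org_r <- seq(0L, (rows %/% k) * k - 1L, by = k)
    org_c <- seq(0L, (cols %/% k) * k - 1L, by = k)
  } else {
    org_r <- seq(0L, rows - k)
    org_c <- seq(0L, cols - k)
  }
  out <- tidyr::expand_grid(window_row = org_r, window_col = org_c)
  out$k <- k
  out$area <- (k * quadrat_size)^2
  out
}

#' Quadrat centre coordinates
#'
#' Centres in metres for a 0-based (row, col) grid: quadrat (r, c) has centre
#' `((c + 0.5) * quadrat_size, (r + 0.5) * quadrat_size)`.
#'
#' @inheritParams enumerate_windows
#' @return Tibble `row`, `col`, `x`, `y`.
#' @export
quadrat_centers <- function(grid_shape, quadrat_size = 0.5) {
  g <- tidyr::expand_grid(row = seq_len(grid_shape[1]) - 1L,
                          col = seq_len(grid_shape[2]) - 1L)
  g$x <- (g$col + 0.5) * quadrat_size
  g$y <- (g$row + 0.5) * quadrat_size
  g
}

#' Average a per-subplot quantity across subplots
#'
#' Implements the aggregation convention used throughout the pipeline:
#' quantities (diversity values, curve points) are evaluated per subplot first
#' and the replicate subplots are averaged afterwards -- never by pooling raw
#' counts across subplots. Undefined per-subplot values (`NA`) are skipped.
#'
#' @param df Data frame with a `subplot` column.
#' @param value Column to average (tidy-eval).
#' @param ... Grouping columns defining one averaged quantity (e.g. `k`,
#'   `area`, `metric`).
#' @return Tibble of the grouping columns plus `mean_value` and `n_subplots`
#'   (number of subplots with a defined value).
#' @export
subplot_mean <- function(df, value, ...) {
  df |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_subplots = dplyr::n_distinct(.data$subplot[!is.na({{ value }})]),
      mean_value = mean({{ value }}, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_value = ifelse(.data$n_subplots == 0, NA_real_,
                                      .data$mean_value))
}

# Pool species counts into windows. Returns one tibble: subplot, window_row,
# window_col, k, area, then one column per species with pooled counts.
window_counts <- function(x, k, mode = c("tiling", "sliding")) {
  mode <- match.arg(mode)
  win <- enumerate_windows(x$grid_shape, k, mode, x$quadrat_size)
  ab <- x$abundance
  if (mode == "tiling") {
    keep <- ab$row < (x$grid_shape[1] %/% k) * k &
      ab$col < (x$grid_shape[2] %/% k) * k
    ab <- ab[keep, ]
    ab$window_row <- (ab$row %/% k) * k
    ab$window_col <- (ab$col %/% k) * k
    out <- ab |>
      dplyr::group_by(.data$subplot, .data$window_row, .data$window_col) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(x$species), sum),
                       .groups = "drop")
  } else {
    per_win <- purrr::pmap(win, function(window_row, window_col, k, area) {
      sel <- ab$row >= window_row & ab$row < window_row + k &
        ab$col >= window_col & ab$col < window_col + k
      sub <- ab[sel, ]
      pooled <- sub |>
        dplyr::group_by(.data$subplot) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(x$species), sum),
                         .groups = "drop")
      pooled$window_row <- window_row
      pooled$window_col <- window_col
      pooled
    })
    out <- dplyr::bind_rows(per_win)
  }
  out$k <- k
  out$area <- (k * x$quadrat_size)^2
  dplyr::relocate(out, "subplot", "window_row", "window_col", "k", "area")
}

# Quadrats of all subplots on one shared coordinate system: subplots are laid
# out left to right along x, separated by subplot_gap metres.
pooled_quadrats <- function(x) {
  centers <- quadrat_centers(x$grid_shape, x$quadrat_size)
  extent <- x$grid_shape[2] * x$quadrat_size
  offsets <- tibble::tibble(
    subplot = x$subplots,
    x_offset = (seq_along(x$subplots) - 1) * (extent + x$subplot_gap)
  )
  x$abundance |>
    dplyr::left_join(centers, by = c("row", "col")) |>
    dplyr::left_join(offsets, by = "subplot") |>
    dplyr::mutate(x = .data$x + .data$x_offset) |>
    dplyr::select(-"x_offset")
}
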