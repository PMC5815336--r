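#' Configuration for a full pipeline run
#'
#' Collects every tunable of the analysis chain into one object that
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]). When `abundance_paths` is `NULL` the surveys are
#' simulated with [simulate_community()] under the paperlike preset.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   child seed from it, so stages are individually reproducible.
#' @param abundance_paths,env_paths Named lists (`grazed`, `fenced`) of CSV
#'   paths, or `NULL` to simulate.
#' @param ks Window sides for the diversity-area curves (`NULL`: 1..grid).
#' @param metrics Metrics to trace across areas.
#' @param families Model families fitted to each curve.
#' @param null_reps Randomization replicates for the richness null model.
#' @param lag_width,max_lag Variogram binning (`NULL`: defaults).
#' @param alpha,n_perm Forward-selection threshold and permutation count.
#' @param cor_threshold Collinearity pre-filter for environmental variables.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       abundance_paths = NULL, env_paths = NULL,
                       ks = NULL,
                       metrics = c("richness", "abundance", "shannon"),
                       families = c("power", "power_additive",
                                    "exponential", "logistic"),
                       null_reps = 999,
                       lag_width = NULL, max_lag = NULL,
                       alpha = 0.05, n_perm = 999, cor_threshold = 0.8) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full spatial-diversity analysis
#'
#' Orchestrates the whole chain for a grazed/fenced survey pair: diversity
#' surfaces, diversity-area curves with model fits and the random-placement
#' null model, per-quadrat variograms with exponential fits, and
#' PCNM/environment variance partitioning with permutation-based forward
#' selection. Writes one CSV per report (curve points, model-comparison
#' table, null envelope, variogram lag table and fit table, forward-selection
#' table, partition table) plus a JSON manifest, and returns the tables
#' invisibly. Identical `config` (including seed) gives byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param surveys Optional named list `grazed`/`fenced` of
#'   [survey_data()] objects, overriding both file input and simulation.
#' @return Invisibly, a named list of the report tibbles.
#' @export
run_full_analysis <- function(config = run_config(), out_dir, surveys = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }

  if (is.null(surveys)) {
    if (is.null(config$abundance_paths)) {
      logf("stage load: simulating paperlike community (seed %d)",
           derive_seed(config$seed, 1))
      surveys <- simulate_community(synth_config(seed = derive_seed(config$seed, 1)))
    } else {
      logf("stage load: reading surveys from CSV")
      surveys <- purrr::imap(config$abundance_paths, function(p, tr) {
        read_survey(p, env_path = config$env_paths[[tr]], treatment = tr)
      })
    }
  }
  stopifnot(all(c("grazed", "fenced") %in% names(surveys)))

  out <- list()

  # --- diversity-area curves, model fits, null model ---------------------
  logf("stage sar: curves and model fits")
  curves <- list(); models <- list(); nulls <- list()
  for (tr in c("grazed", "fenced")) {
    sv <- surveys[[tr]]
    for (metric in config$metrics) {
      cv <- sar_curve(sv, metric, ks = config$ks)
      curves[[paste(tr, metric)]] <-
        dplyr::mutate(tibble::as_tibble(cv), treatment = tr, metric = metric)
      fits <- purrr::map(config$families, function(fam) {
        tryCatch(fit_sar(cv, fam), error = function(e) NULL)
      })
      fits <- purrr::compact(fits)
      if (length(fits) >= 2) {
        rank <- compare_sar(fits)
        models[[paste(tr, metric)]] <- purrr::map(fits, function(f) {
          tidy(f) |>
            dplyr::mutate(treatment = tr, metric = metric,
                          family = f$family, ssr = f$ssr)
        }) |>
          dplyr::bind_rows() |>
          dplyr::left_join(rank[c("family", "rank")], by = "family")
      }
    }
    # richness null model: closed form + randomization envelope
    cole <- expected_sar_coleman(sv, ks = config$ks)
    rnd <- randomization_sar(sv, ks = config$ks, n_reps = config$null_reps,
                             seed = derive_seed(config$seed, 2,
                                                match(tr, c("grazed", "fenced"))))
    obs <- sar_curve(sv, "richness", ks = config$ks)
    nulls[[tr]] <- tibble::tibble(
      treatment = tr, k = rnd$k, area = rnd$area,
      observed = obs$value, coleman = cole$value,
      null_mean = rnd$expected, lower = rnd$lower, upper = rnd$upper,
      outside_envelope = obs$value < rnd$lower | obs$value > rnd$upper
    )
  }
  out$curves <- dplyr::bind_rows(curves)
  out$sar_models <- dplyr::bind_rows(models)
  out$sar_null <- dplyr::bind_rows(nulls)
  if (any(out$sar_null$outside_envelope)) {
    logf("stage sar: observed richness outside the 95%% null envelope at %d of %d areas",
         sum(out$sar_null$outside_envelope), nrow(out$sar_null))
  }

  # --- variograms --------------------------------------------------------
  logf("stage variogram: per-quadrat diversity variables")
  vg_fits <- list(grazed = list(), fenced = list())
  lag_rows <- list(); vg_rows <- list()
  for (tr in c("grazed", "fenced")) {
    for (metric in config$metrics) {
      emp <- diversity_variogram(surveys[[tr]], metric,
                                 lag_width = config$lag_width,
                                 max_lag = config$max_lag)
      fit <- fit_variogram(emp, "exponential")
      vg_fits[[tr]][[metric]] <- fit
      lag_rows[[paste(tr, metric)]] <-
        dplyr::mutate(tibble::as_tibble(emp), treatment = tr, metric = metric)
      vg_rows[[paste(tr, metric)]] <-
        dplyr::mutate(tidy(fit), treatment = tr, metric = metric)
    }
  }
  out$variogram_lags <- dplyr::bind_rows(lag_rows)
  out$variograms <- dplyr::bind_rows(vg_rows)
  out$spatial_structure <- spatial_structure_summary(vg_fits)

  # --- variance partitioning --------------------------------------------
  logf("stage varpart: PCNM + forward selection (alpha %.3g, %d permutations)",
       config$alpha, config$n_perm)
  sel_rows <- list(); part_rows <- list()
  for (tr in c("grazed", "fenced")) {
    sv <- surveys[[tr]]
    if (is.null(sv$env)) { logf("stage varpart: %s has no env table, skipped", tr); next }
    quads <- pooled_quadrats(sv)
    env_raw <- sv$env |>
      dplyr::semi_join(quads, by = c("subplot", "row", "col")) |>
      dplyr::arrange(.data$subplot, .data$row, .data$col)
    quads <- dplyr::arrange(quads, .data$subplot, .data$row, .data$col)
    env_std <- standardize_env(env_raw[sv$env_vars])
    env_std <- decorrelate_env(env_std, config$cor_threshold)
    basis <- pcnm(quads[c("x", "y")])
    for (metric in config$metrics) {
      vals <- apply(as.matrix(quads[sv$species]), 1, metric_fun(metric))
      ok <- !is.na(vals)
      y <- vals[ok]
      xe <- env_std[ok, , drop = FALSE]
      xs <- basis$vectors[ok, , drop = FALSE]
      tr_i <- match(tr, c("grazed", "fenced"))
      m_i <- match(metric, config$metrics)
      glob_env <- adjusted_r2(as.numeric(rda_r2(y, xe)), length(y), ncol(xe))
      sel_env <- forward_select(y, xe, alpha = config$alpha,
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 3, tr_i, m_i),
                                global_adjr2 = glob_env)
      glob_sp <- adjusted_r2(as.numeric(rda_r2(y, xs)), length(y), ncol(xs))
      sel_sp <- forward_select(y, xs, alpha = config$alpha,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 4, tr_i, m_i),
                               global_adjr2 = glob_sp)
      sel_rows[[paste(tr, metric)]] <- dplyr::bind_rows(
        dplyr::mutate(sel_env, set = "environment"),
        dplyr::mutate(sel_sp, set = "pcnm")
      ) |> dplyr::mutate(treatment = tr, metric = metric)
      part <- partition_variation(
        y,
        env = xe[, sel_env$variable, drop = FALSE],
        space = xs[, sel_sp$variable, drop = FALSE],
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, 5, tr_i, m_i))
      part_rows[[paste(tr, metric)]] <-
        dplyr::mutate(tidy(part), treatment = tr, metric = metric)
    }
  }
  out$selection <- dplyr::bind_rows(sel_rows)
  out$varpart <- dplyr::bind_rows(part_rows)

  # --- reports and manifest ---------------------------------------------
  for (nm in names(out)) {
    readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("steppediv")),
    r_version = R.version.string,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    reports = paste0(names(out), ".csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done in %.1f s", manifest$wall_time_s)
  invisible(out)
}
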