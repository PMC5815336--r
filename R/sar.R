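#' Build an empirical diversity-area curve
#'
#' For each window side `k`, the chosen metric is evaluated on every window of
#' every subplot ([diversity_surface()]), averaged over windows within each
#' subplot, and the subplot means are then averaged ([subplot_mean()]
#' contract). Point areas are `(k * quadrat_size)^2`.
#'
#' @param x A [survey_data()] object.
#' @param metric Diversity metric, see [diversity_surface()].
#' @param ks Window sides; default `1:min(rows, cols)`.
#' @param mode Window placement, `"tiling"` (default) or `"sliding"`.
#' @return A `sar_curve`: tibble `k`, `area`, `value`, `n_subplots` with the
#'   metric, treatment and mode carried as attributes.
#' @export
sar_curve <- function(x, metric = "richness", ks = NULL,
                      mode = c("tiling", "sliding")) {
  stopifnot(inherits(x, "survey"))
  mode <- match.arg(mode)
  if (is.null(ks)) ks <- seq_len(min(x$grid_shape))
  if (length(ks) == 0) stop("ks must be non-empty", call. = FALSE)
  pts <- purrr::map(sort(unique(as.integer(ks))), function(k) {
    surf <- diversity_surface(x, k, metric, mode)
    per_sub <- surf |>
      dplyr::group_by(.data$subplot) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                       .groups = "drop")
    tibble::tibble(k = k, area = (k * x$quadrat_size)^2,
                   value = mean(per_sub$value, na.rm = TRUE),
                   n_subplots = sum(!is.na(per_sub$value)))
  }) |> dplyr::bind_rows()
  new_sar_curve(pts, metric = metric, treatment = x$treatment, mode = mode,
                provenance = "empirical")
}

new_sar_curve <- function(pts, metric, treatment = NA_character_,
                          mode = "tiling", provenance = "empirical") {
  stopifnot(!is.unsorted(pts$area, strictly = TRUE))
  structure(pts,
            class = c("sar_curve", class(tibble::tibble()))) |>
    `attr<-`("metric", metric) |>
    `attr<-`("treatment", treatment) |>
    `attr<-`("mode", mode) |>
    `attr<-`("provenance", provenance)
}

#' Assemble a diversity-area curve from (area, value) pairs
#'
#' Escape hatch for fitting models to externally supplied curves (e.g. values
#' read from a published table).
#'
#' @param area,value Numeric vectors, `area` strictly increasing and positive.
#' @param metric Metric label.
#' @return A `sar_curve`.
#' @export
as_sar_curve <- function(area, value, metric = "richness") {
  stopifnot(length(area) == length(value), all(area > 0))
  new_sar_curve(tibble::tibble(k = NA_integer_, area = area, value = value,
                               n_subplots = NA_integer_),
                metric = metric, provenance = "external")
}

sar_family_names <- c("power", "power_additive", "exponential", "logistic",
                      "parabolic", "linear")

n_params_family <- function(family) {
  c(power = 2, power_additive = 2, exponential = 2, logistic = 3,
    parabolic = 3, linear = 2)[[family]]
}

# Model value for a named parameter vector. `lg` is the log used by the
# logistic and parabolic forms (natural by default, base 10 optional); the
# exponential family is defined with the natural log.
sar_predict <- function(family, pars, area, log_base = exp(1)) {
  lg <- log(area, base = log_base)
  switch(family,
    power = pars[["alpha"]] * area^pars[["beta"]],
    power_additive = pars[["alpha"]] + area^pars[["beta"]],
    exponential = pars[["alpha"]] * log(area) + pars[["beta"]],
    logistic = pars[["beta"]] /
      (1 + exp((pars[["delta"]] - lg) / pars[["alpha"]])),
    parabolic = pars[["alpha"]] * lg^2 + pars[["beta"]] * lg + pars[["delta"]],
    linear = pars[["alpha"]] * area + pars[["beta"]]
  )
}

#' Fit a diversity-area model family to a curve
#'
#' Least squares on the original response scale. Six families are available:
#' \describe{
#'   \item{power}{S = alpha * A^beta (multiplicative form)}
#'   \item{power_additive}{S = alpha + A^beta}
#'   \item{exponential}{S = alpha * ln(A) + beta}
#'   \item{logistic}{S = beta / (1 + exp((delta - log A) / alpha))}
#'   \item{parabolic}{S = alpha * log(A)^2 + beta * log(A) + delta}
#'   \item{linear}{S = alpha * A + beta}
#' }
#' Linear-in-parameter families are solved exactly by [stats::lm()]; the
#' power and logistic families use Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]) over a fixed, documented multi-start grid (logistic:
#' beta0 = 1.05 max S, delta0 = log median A, alpha0 in {0.5, 1, 2, 5}; power:
#' slope of the log-log regression), so fits are deterministic. 95% confidence
#' half-widths come from the Jacobian-based covariance (t quantile x standard
#' error).
#'
#' @param curve A [sar_curve()].
#' @param family One of `"power"`, `"power_additive"`, `"exponential"`,
#'   `"logistic"`, `"parabolic"`, `"linear"`.
#' @param log_base Base of the log used inside the logistic and parabolic
#'   forms (default natural log).
#' @return A `sar_fit` with elements `family`, `params` (term, estimate,
#'   std_error, ci_halfwidth, conf_low, conf_high), `ssr`, `n`, `converged`.
#'   Supports [tidy()] and [glance()].
#' @export
fit_sar <- function(curve, family = sar_family_names, log_base = exp(1)) {
  family <- match.arg(family)
  stopifnot(inherits(curve, "sar_curve"))
  A <- curve$area; S <- curve$value
  p <- n_params_family(family)
  if (any(!is.finite(S))) stop("curve has undefined values", call. = FALSE)
  if (length(A) < p + 1) {
    stop(sprintf("need at least %d points to fit %s", p + 1, family),
         call. = FALSE)
  }
  if (stats::sd(S) == 0) {
    return(flat_sar_fit(curve, family, log_base))
  }
  lg <- log(A, base = log_base)
  dat <- data.frame(A = A, S = S, lg = lg, lnA = log(A))

  if (family %in% c("exponential", "parabolic", "linear")) {
    fm <- switch(family,
      exponential = S ~ lnA,
      parabolic = S ~ I(lg^2) + lg,
      linear = S ~ A
    )
    fit <- stats::lm(fm, data = dat)
    co <- summary(fit)$coefficients
    # map lm coefficients (intercept first) onto the published parameter names
    ord <- switch(family,
      exponential = c(alpha = 2, beta = 1),
      linear = c(alpha = 2, beta = 1),
      parabolic = c(alpha = 2, beta = 3, delta = 1)
    )
    est <- co[ord, 1]; se <- co[ord, 2]
    names(est) <- names(se) <- names(ord)
    ssr <- sum(stats::resid(fit)^2)
    df <- stats::df.residual(fit)
    return(new_sar_fit(curve, family, est, se, ssr, df, TRUE, log_base))
  }

  starts <- sar_starts(family, A, S, lg)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                     ptol = 1e-15)
  pnames <- if (family == "logistic") c("alpha", "beta", "delta") else
    c("alpha", "beta")
  resid_fn <- function(par) {
    pred <- sar_predict(family, as.list(setNames(par, pnames)), A, log_base)
    r <- S - pred
    r[!is.finite(r)] <- 1e8   # overflow guard for extreme trial parameters
    r
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st[pnames]), fn = resid_fn,
                         control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$par)) &&
        (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop(sprintf("%s fit failed to converge from any start", family),
         call. = FALSE)
  }
  co <- tryCatch(summary(best)$coefficients,
                 error = function(e) cbind(best$par, NA_real_))
  est <- setNames(co[, 1], pnames); se <- setNames(co[, 2], pnames)
  new_sar_fit(curve, family, est, se, best$deviance,
              length(A) - length(pnames), TRUE, log_base)
}

# Deterministic multi-start grids for the nonlinear families.
sar_starts <- function(family, A, S, lg) {
  if (family == "logistic") {
    b0 <- max(S) * 1.05
    grid <- expand.grid(alpha = c(0.1, 0.25, 0.5, 1, 2, 5),
                        delta = c(stats::median(lg), min(lg)))
    return(purrr::pmap(grid, function(alpha, delta) {
      list(alpha = alpha, beta = b0, delta = delta)
    }))
  }
  pos <- S > 0
  slope <- if (sum(pos) >= 2) {
    stats::coef(stats::lm(log(S[pos]) ~ log(A[pos])))[[2]]
  } else 0.25
  if (family == "power") {
    a0 <- exp(mean(log(S[pos])) - slope * mean(log(A[pos])))
    purrr::map(unique(c(slope, 0.1, 0.25, 0.5)),
               ~ list(alpha = a0, beta = .x))
  } else {
    # additive dialect: offset candidates below min(S), exponent near loglog
    grid <- expand.grid(alpha = c(0, min(S) * 0.5, min(S) - 1),
                        beta = unique(c(slope, 0.1, 0.25, 0.5)))
    purrr::pmap(grid, function(alpha, beta) list(alpha = alpha, beta = beta))
  }
}

flat_sar_fit <- function(curve, family, log_base) {
  S0 <- curve$value[1]; n <- nrow(curve)
  est <- switch(family,
    power = c(alpha = S0, beta = 0),
    power_additive = c(alpha = S0 - 1, beta = 0),
    exponential = c(alpha = 0, beta = S0),
    linear = c(alpha = 0, beta = S0),
    parabolic = c(alpha = 0, beta = 0, delta = S0),
    logistic = stop("logistic family cannot represent a constant curve",
                    call. = FALSE)
  )
  warning(sprintf("curve has zero variance; returning flat %s fit", family),
          call. = FALSE)
  new_sar_fit(curve, family, est, setNames(rep(0, length(est)), names(est)),
              0, n - length(est), TRUE, log_base)
}

new_sar_fit <- function(curve, family, est, se, ssr, df, converged, log_base) {
  hw <- stats::qt(0.975, df) * se
  structure(
    list(
      family = family,
      params = tibble::tibble(
        term = names(est), estimate = unname(est), std_error = unname(se),
        ci_halfwidth = unname(hw),
        conf_low = unname(est - hw), conf_high = unname(est + hw)
      ),
      ssr = ssr, n = length(curve$area), df = df, converged = converged,
      log_base = log_base, metric = attr(curve, "metric"),
      curve = tibble::as_tibble(curve)[c("area", "value")]
    ),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit> %s model for %s-area curve (%d points)\n",
              x$family, x$metric, x$n))
  print(x$params)
  cat(sprintf("SSR = %.6g\n", x$ssr))
  invisible(x)
}

#' Predicted values from a fitted diversity-area model
#'
#' @param object A `sar_fit`.
#' @param newdata Optional data frame with an `area` column.
#' @param ... Unused.
#' @export
predict.sar_fit <- function(object, newdata = NULL, ...) {
  area <- if (is.null(newdata)) object$curve$area else newdata$area
  pars <- setNames(object$params$estimate, object$params$term)
  sar_predict(object$family, pars, area, object$log_base)
}

#' Rank diversity-area model fits by residual sum of squares
#'
#' Fits must come from the same curve. Ranking is by ascending SSR with ties
#' broken in favour of the model with fewer parameters.
#'
#' @param ... `sar_fit` objects, or a single list of them.
#' @return Tibble `family`, `n_params`, `ssr`, `rank`.
#' @export
compare_sar <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "sar_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2, all(purrr::map_lgl(fits, inherits, "sar_fit")))
  ref <- fits[[1]]$curve
  same <- purrr::map_lgl(fits, ~ isTRUE(all.equal(.x$curve, ref)))
  if (!all(same)) stop("fits compare different curves", call. = FALSE)
  out <- purrr::map(fits, ~ tibble::tibble(
    family = .x$family, n_params = nrow(.x$params), ssr = .x$ssr)) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$ssr, .data$n_params)
  out$rank <- seq_len(nrow(out))
  out
}

#' Per-parameter confidence-interval overlap between two fits
#'
#' Two fits of the same family differ in a parameter when their 95% intervals
#' `[estimate - halfwidth, estimate + halfwidth]` are disjoint.
#'
#' @param fit1,fit2 `sar_fit` objects of the same family.
#' @return Tibble `term`, `estimate_1`, `estimate_2`, `disjoint`.
#' @export
curves_differ <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "sar_fit"), inherits(fit2, "sar_fit"))
  if (fit1$family != fit2$family) {
    stop("fits are from different model families", call. = FALSE)
  }
  dplyr::inner_join(fit1$params, fit2$params, by = "term",
                    suffix = c("_1", "_2")) |>
    dplyr::transmute(
      .data$term, .data$estimate_1, .data$estimate_2,
      disjoint = .data$conf_high_1 < .data$conf_low_2 |
        .data$conf_high_2 < .data$conf_low_1
    )
}

#' Expected diversity-area curve under random placement
#'
#' Closed-form expectation of species richness in a subarea `a` when every
#' individual is placed independently and uniformly over the subplot
#' (Coleman's random-placement model): with species totals N_i and subplot
#' area A_tot, `E S(a) = sum_i (1 - (1 - a/A_tot)^N_i)`. Evaluated per
#' subplot at the same areas as the empirical curve, then subplot-averaged.
#'
#' @inheritParams sar_curve
#' @return A `sar_curve` with provenance `"coleman"`.
#' @export
expected_sar_coleman <- function(x, ks = NULL) {
  stopifnot(inherits(x, "survey"))
  if (is.null(ks)) ks <- seq_len(min(x$grid_shape))
  a_tot <- prod(x$grid_shape) * x$quadrat_size^2
  areas <- (sort(unique(as.integer(ks))) * x$quadrat_size)^2
  if (any(areas > a_tot + 1e-12)) stop("window area exceeds subplot area", call. = FALSE)
  totals <- x$abundance |>
    dplyr::group_by(.data$subplot) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(x$species), sum),
                     .groups = "drop")
  if (sum(as.matrix(totals[x$species])) == 0) {
    stop("total abundance is zero", call. = FALSE)
  }
  per_sub <- apply(as.matrix(totals[x$species]), 1, function(N) {
    vapply(areas, function(a) sum(1 - (1 - a / a_tot)^N), numeric(1))
  })
  pts <- tibble::tibble(
    k = sort(unique(as.integer(ks))), area = areas,
    value = rowMeans(as.matrix(per_sub)),
    n_subplots = nrow(totals)
  )
  new_sar_curve(pts, metric = attr(x, "metric") %||% "richness",
                treatment = x$treatment, provenance = "coleman")
}

#' Randomization null model for the diversity-area curve
#'
#' Monte-Carlo counterpart of [expected_sar_coleman()]: each replicate places
#' every individual independently and uniformly over the quadrats of its
#' subplot (species totals preserved), recomputes the empirical richness-area
#' curve and the replicate curves give the null mean and a 95% envelope.
#'
#' @inheritParams sar_curve
#' @param n_reps Number of randomization replicates (default 999).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A `sar_null` tibble: `k`, `area`, `expected`, `lower`, `upper`
#'   (2.5% and 97.5% quantiles), with the replicate matrix in attribute
#'   `"reps"`.
#' @export
randomization_sar <- function(x, ks = NULL, n_reps = 999, seed = NULL,
                              metric = "richness") {
  stopifnot(inherits(x, "survey"), n_reps >= 1)
  if (is.null(ks)) ks <- seq_len(min(x$grid_shape))
  ks <- sort(unique(as.integer(ks)))
  rows <- x$grid_shape[1]; cols <- x$grid_shape[2]
  q <- rows * cols
  # tiling window id of each quadrat (row-major quadrat order) for each k;
  # NA marks edge quadrats dropped at that k
  quad <- tidyr::expand_grid(row = 0:(rows - 1), col = 0:(cols - 1))
  win_id <- purrr::map(ks, function(k) {
    keep <- quad$row < (rows %/% k) * k & quad$col < (cols %/% k) * k
    id <- (quad$row %/% k) * (cols %/% k) + (quad$col %/% k) + 1L
    id[!keep] <- NA_integer_
    id
  })
  totals <- x$abundance |>
    dplyr::arrange(.data$subplot) |>
    dplyr::group_by(.data$subplot) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(x$species), sum),
                     .groups = "drop")
  tot_mat <- as.matrix(totals[x$species])
  fn <- metric_fun(metric)
  reps <- with_seed(seed, function() {
   reps <- matrix(NA_real_, nrow = n_reps, ncol = length(ks))
   for (r in seq_len(n_reps)) {
    per_sub <- matrix(NA_real_, nrow = nrow(tot_mat), ncol = length(ks))
    for (s in seq_len(nrow(tot_mat))) {
      counts <- vapply(tot_mat[s, ], function(N) {
        if (N == 0) integer(q) else
          as.integer(rmultinom(1, N, rep(1 / q, q)))
      }, integer(q))
      for (j in seq_along(ks)) {
        id <- win_id[[j]]
        pooled <- rowsum(counts[!is.na(id), , drop = FALSE],
                         id[!is.na(id)])
        per_sub[s, j] <- mean(apply(pooled, 1, fn))
      }
    }
    reps[r, ] <- colMeans(per_sub)
   }
   reps
  })
  out <- tibble::tibble(
    k = ks, area = (ks * x$quadrat_size)^2,
    expected = colMeans(reps),
    lower = apply(reps, 2, stats::quantile, 0.025),
    upper = apply(reps, 2, stats::quantile, 0.975)
  )
  attr(out, "reps") <- reps
  attr(out, "metric") <- metric
  class(out) <- c("sar_null", class(tibble::tibble()))
  out
}
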