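#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted diversity-area model
#'
#' @param x A `sar_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std_error`,
#'   `ci_halfwidth`, `conf_low`, `conf_high`.
#' @export
tidy.sar_fit <- function(x, ...) x$params

#' @rdname tidy.sar_fit
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(family = x$family, metric = x$metric,
                 n_params = nrow(x$params), ssr = x$ssr, n = x$n,
                 converged = x$converged)
}

#' Tidy a fitted variogram model
#'
#' @param x A `variogram_fit`.
#' @param ... Unused.
#' @return One row with `model`, nugget `c0`, structural variance `c`, sill,
#'   structural proportion `prop`, range parameter `a`, practical range
#'   `range` (A0) and fit `r2`.
#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble::tibble(model = x$model, c0 = x$c0, c = x$c, sill = x$sill,
                 prop = x$prop, a = x$a, range = x$range, r2 = x$r2)
}

#' @rdname tidy.variogram_fit
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, ssr = x$ssr,
                 n_lags = nrow(x$empirical))
}

#' Tidy a variance partition
#'
#' @param x A `varpart_fit`.
#' @param floor_zero Clamp slightly negative adjusted-R^2 fractions to zero
#'   for display (default `FALSE`: raw values).
#' @param ... Unused.
#' @return One row per fraction (`a`, `b`, `c`, `d` and the total `abc`)
#'   with `adj_r2`, `pct` and permutation `p_value` where tested.
#' @export
tidy.varpart_fit <- function(x, floor_zero = FALSE, ...) {
  fr <- x$fractions
  if (floor_zero) {
    fr$adj_r2 <- pmax(fr$adj_r2, 0)
    fr$pct <- pmax(fr$pct, 0)
  }
  fr
}

#' @rdname tidy.varpart_fit
#' @export
glance.varpart_fit <- function(x, ...) {
  tibble::tibble(n = x$n, m_env = x$m_env, m_space = x$m_space,
                 n_perm = x$n_perm,
                 total_explained = x$fractions$adj_r2[x$fractions$fraction == "abc"])
}
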