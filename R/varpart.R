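#' Hellinger transformation of a community abundance matrix
#'
#' Each cell becomes the square root of the species' relative abundance in
#' its row: `y_ij -> sqrt(y_ij / sum_j y_ij)`. Rows with zero total stay zero
#' (with a warning); every positive row of the result has unit sum of
#' squares. The transform makes abundance data suitable for Euclidean-based
#' ordination and regression.
#'
#' @param x Matrix or data frame of non-negative counts (sites x species).
#' @return Numeric matrix of the same shape.
#' @export
hellinger_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    warning(sprintf("%d all-zero row(s) left as zeros", sum(rs == 0)),
            call. = FALSE)
  }
  out <- sqrt(sweep(x, 1, pmax(rs, 1), "/"))
  out[rs == 0, ] <- 0
  out
}

#' Standardize environmental variables to z-scores
#'
#' Columns are centred to mean 0 and scaled to sample standard deviation 1.
#' Zero-variance columns carry no information and are dropped with a warning.
#'
#' @param x Matrix or data frame of numeric variables (sites x variables).
#' @return Numeric matrix with possibly fewer columns.
#' @export
standardize_env <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(x)[, , drop = FALSE]
}

#' Drop one of each highly correlated pair of environmental variables
#'
#' Screens predictors before forward selection: while any absolute pairwise
#' Pearson correlation exceeds the threshold, the later column of the worst
#' pair is removed.
#'
#' @param x Matrix or data frame of numeric variables.
#' @param threshold Absolute correlation above which a pair is collinear
#'   (default 0.8).
#' @return `x` with collinear columns removed; dropped names in attribute
#'   `"dropped"`.
#' @export
decorrelate_env <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  dropped <- character(0)
  repeat {
    if (ncol(x) < 2) break
    cm <- abs(stats::cor(x)); diag(cm) <- 0
    if (max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    drop_j <- max(ij)
    dropped <- c(dropped, colnames(x)[drop_j])
    x <- x[, -drop_j, drop = FALSE]
  }
  attr(x, "dropped") <- dropped
  x
}

# Prim's algorithm: longest edge of the minimum spanning tree of a distance
# matrix. Small n (quadrat counts), so the O(n^2) version is fine.
mst_longest_edge <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    if (best[j] == 0) stop("coincident points: minimum spanning tree degenerate",
                           call. = FALSE)
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' Principal Coordinates of Neighbour Matrices (PCNM) spatial eigenvectors
#'
#' Builds orthogonal spatial predictors from site coordinates: the Euclidean
#' distance matrix is truncated at `t` (default: the longest edge of its
#' minimum spanning tree, the smallest distance keeping all sites connected),
#' distances beyond `t` are replaced by `4t`, and the truncated matrix is
#' submitted to principal-coordinates analysis (eigendecomposition of the
#' double-centred `-D^2/2` matrix). Axes with positive eigenvalues model
#' spatial structure from broad (leading axes) to fine scales.
#'
#' @param coords Two-column matrix or data frame of site coordinates.
#' @param truncation Truncation distance; `NULL` for the MST default.
#' @param tol Relative eigenvalue threshold for retaining axes (default
#'   `1e-10` times the largest eigenvalue).
#' @return A `pcnm_basis`: list with `vectors` (sites x axes, unit-norm,
#'   centred, columns `PCNM1..`), `values` (descending positive
#'   eigenvalues), `truncation`.
#' @export
pcnm <- function(coords, truncation = NULL, tol = 1e-10) {
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 3) stop("need at least 3 distinct points", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  if (is.null(truncation)) truncation <- mst_longest_edge(d)
  dt <- d
  dt[dt > truncation] <- 4 * truncation
  diag(dt) <- 0
  n <- nrow(dt)
  a <- -0.5 * dt^2
  # Gower double-centring
  g <- a - rowMeans(a) %*% t(rep(1, n)) - rep(1, n) %*% t(colMeans(a)) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  v <- e$vectors[, keep, drop = FALSE]
  colnames(v) <- paste0("PCNM", seq_len(ncol(v)))
  structure(list(vectors = v, values = e$values[keep],
                 truncation = truncation, coords = coords),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("<pcnm_basis> %d axes from %d sites, truncation %.4g\n",
              ncol(x$vectors), nrow(x$vectors), x$truncation))
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - r2) (n - 1) / (n - m - 1)` for a model with `m` predictors on
#' `n` observations; the standard adjustment used on all variance-partition
#' fractions.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param m Number of predictors (0 returns `r2` unchanged).
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n - m - 1 <= 0) stop("adjusted R2 undefined: n - m - 1 <= 0", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

# Centred response / QR of predictors-with-intercept. Rank-deficient
# predictor sets are reduced with a warning, never silently.
rda_qr <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  qx <- qr(cbind(`(Intercept)` = 1, x))
  if (qx$rank < ncol(x) + 1 && warn) {
    warning(sprintf("dropping %d collinear predictor column(s)",
                    ncol(x) + 1 - qx$rank), call. = FALSE)
  }
  qx
}

#' Redundancy-analysis R-squared
#'
#' Least-squares projection of the column-centred response matrix onto the
#' predictors; R^2 is the trace of the explained sum of squares over the
#' trace of the total sum of squares. For a single response column this is
#' ordinary multiple-regression R^2; for a multivariate (e.g. Hellinger
#' transformed community) response it is the canonical RDA statistic.
#'
#' @param response Numeric matrix or vector (n x p, p >= 1).
#' @param predictors Numeric matrix or data frame (n x m), or `NULL` /
#'   zero-column for the null model (R^2 = 0).
#' @return Unadjusted R^2 with attribute `"m"`, the predictor rank actually
#'   used.
#' @export
rda_r2 <- function(response, predictors) {
  y <- as.matrix(response)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sstot <- sum(yc^2)
  if (sstot == 0) stop("response has zero variance", call. = FALSE)
  if (is.null(predictors) || NCOL(predictors) == 0) {
    return(structure(0, m = 0L))
  }
  if (NROW(predictors) != nrow(y)) stop("dimension mismatch", call. = FALSE)
  qx <- rda_qr(predictors)
  fit <- qr.fitted(qx, yc)
  structure(sum(fit^2) / sstot, m = as.integer(qx$rank - 1L))
}

# Run fn with a temporary RNG state seeded by `seed`, restoring the caller's
# state afterwards; seed NULL uses (and advances) the current stream.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Forward selection of predictors with permutation tests
#'
#' Stepwise predictor inclusion for (possibly multivariate) least-squares
#' redundancy analysis. At each step the candidate adding the most R^2 is
#' tested with a Monte-Carlo permutation F-test: under a non-empty current
#' model, residuals of the response on the selected predictors are permuted
#' (conditioning on what is already in the model); with an empty model,
#' response rows are permuted. Because the tested candidate is itself the
#' best of many, each permutation recomputes the maximum partial F over all
#' remaining candidates (a max-statistic test), which keeps the per-step
#' type-I error at the nominal level instead of inflating it with the number
#' of candidates. Selection stops when the best candidate's p-value exceeds
#' `alpha`, or -- the double-stopping rule -- when the cumulative adjusted
#' R^2 would exceed `global_adjr2` (typically the adjusted R^2 of the full
#' model).
#'
#' @param response n x p response matrix (p >= 1).
#' @param candidates n x m matrix of candidate predictors (named columns).
#' @param alpha Significance threshold (default 0.05).
#' @param n_perm Number of permutations (default 999); p-values are
#'   `(#permuted F >= observed + 1) / (n_perm + 1)`.
#' @param seed Integer seed for the permutations; the caller's RNG state is
#'   left untouched.
#' @param global_adjr2 Optional adjusted-R^2 ceiling for the double stop.
#' @return Tibble `variable`, `order`, `r2_add`, `r2_cum`, `adj_r2_cum`,
#'   `f_stat`, `p_value` for the selected set (possibly empty). Ties on added
#'   R^2 break to the lowest column index.
#' @export
forward_select <- function(response, candidates, alpha = 0.05, n_perm = 999,
                           seed = NULL, global_adjr2 = NULL) {
  y <- as.matrix(response)
  x <- as.matrix(candidates)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  stopifnot(nrow(x) == nrow(y), ncol(x) >= 1)
  n <- nrow(y)
  with_seed(seed, function() {
    sel <- integer(0)
    rows <- list()
    r2_cur <- 0
    repeat {
      remaining <- setdiff(seq_len(ncol(x)), sel)
      if (length(remaining) == 0) break
      m_new <- length(sel) + 1L
      df2 <- n - m_new - 1
      # QR of the current model (intercept only when nothing selected)
      qs <- rda_qr(if (length(sel) > 0) x[, sel, drop = FALSE] else
        matrix(nrow = n, ncol = 0), warn = FALSE)
      resid_y <- qr.resid(qs, y)     # response residual, orthogonal to model
      # candidates residualized on the current model, unit-normalized; the
      # added sum of squares of candidate j is then ||e_j' resid||^2
      e <- qr.resid(qs, x[, remaining, drop = FALSE])
      e_norm <- sqrt(colSums(e^2))
      degenerate <- e_norm < 1e-10 * sqrt(n)  # collinear with current model
      e <- sweep(e, 2, pmax(e_norm, 1e-300), "/")
      step_f <- function(r) {
        ss_res <- sum(r^2)
        add_ss <- rowSums((crossprod(e, r))^2)
        add_ss[degenerate] <- 0
        add_ss / ((ss_res - add_ss) / df2)
      }
      f_all <- step_f(resid_y)
      jpos <- which.max(f_all)       # first max: lowest candidate index
      if (degenerate[jpos]) break
      jbest <- remaining[jpos]
      f_obs <- f_all[jpos]
      r2_new <- as.numeric(rda_r2(y, x[, c(sel, jbest), drop = FALSE]))
      f_perm <- vapply(seq_len(n_perm), function(i) {
        rp <- qr.resid(qs, resid_y[sample.int(n), , drop = FALSE])
        max(step_f(rp))
      }, numeric(1))
      p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
      if (p > alpha) break
      adj_new <- adjusted_r2(r2_new, n, m_new)
      if (!is.null(global_adjr2) && adj_new > global_adjr2) break
      sel <- c(sel, jbest)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = colnames(x)[jbest], order = length(sel),
        r2_add = r2_new - r2_cur, r2_cum = r2_new, adj_r2_cum = adj_new,
        f_stat = f_obs, p_value = p
      )
      r2_cur <- r2_new
    }
    if (length(rows) == 0) {
      tibble::tibble(variable = character(0), order = integer(0),
                     r2_add = numeric(0), r2_cum = numeric(0),
                     adj_r2_cum = numeric(0), f_stat = numeric(0),
                     p_value = numeric(0))
    } else {
      dplyr::bind_rows(rows)
    }
  })
}

# Permutation test of a partial model: added R2 of `test` over `cond`,
# permuting residuals of the response on `cond` (or rows when cond empty).
partial_perm_test <- function(y, test, cond, n_perm) {
  n <- nrow(y)
  m_test <- if (NCOL(test) > 0) attr(rda_r2(y, test), "m") else 0L
  m_cond <- if (!is.null(cond) && NCOL(cond) > 0)
    attr(rda_r2(y, cond), "m") else 0L
  both <- if (m_cond > 0) cbind(cond, test) else test
  r2_full <- as.numeric(rda_r2(y, both))
  r2_cond <- if (m_cond > 0) as.numeric(rda_r2(y, cond)) else 0
  df2 <- n - m_test - m_cond - 1
  f_obs <- ((r2_full - r2_cond) / m_test) / ((1 - r2_full) / df2)
  if (m_cond > 0) {
    qs <- rda_qr(cond, warn = FALSE)
    fitted_part <- qr.fitted(qs, y)
    resid_part <- qr.resid(qs, y)
  } else {
    fitted_part <- matrix(colMeans(y), n, ncol(y), byrow = TRUE)
    resid_part <- sweep(y, 2, colMeans(y))
  }
  f_perm <- vapply(seq_len(n_perm), function(i) {
    yp <- fitted_part + resid_part[sample.int(n), , drop = FALSE]
    r2p_full <- as.numeric(rda_r2(yp, both))
    r2p_cond <- if (m_cond > 0) as.numeric(rda_r2(yp, cond)) else 0
    ((r2p_full - r2p_cond) / m_test) / ((1 - r2p_full) / df2)
  }, numeric(1))
  list(f = f_obs, p = (sum(f_perm >= f_obs) + 1) / (n_perm + 1))
}

#' Partition response variation into environment, space and residual
#'
#' Classical two-table variance partitioning on the adjusted-R^2 scale. With
#' `ab = adjR2(env)`, `bc = adjR2(space)` and `abc = adjR2(env + space)`:
#' `[a] = abc - bc` (pure environment), `[c] = abc - ab` (pure space),
#' `[b] = ab + bc - abc` (spatially structured environment), `[d] = 1 - abc`
#' (residual). The fractions sum to 1 exactly; `[a]`--`[c]` can be slightly
#' negative (an adjusted-R^2 artifact) and are reported as-is. `[a]`, `[c]`
#' and the total `[a+b+c]` get permutation p-values from partial-model tests
#' (residuals permuted under the conditioning model).
#'
#' @param response n x p response matrix (a univariate diversity variable or
#'   a Hellinger-transformed community matrix).
#' @param env Selected environmental predictor matrix (may have 0 columns).
#' @param space Selected spatial (PCNM) predictor matrix (may have 0
#'   columns).
#' @param n_perm Permutations for the fraction tests (default 999).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A `varpart_fit` object: tibble `fractions` (`fraction`, `adj_r2`,
#'   `pct`, `p_value`), plus `n`, `m_env`, `m_space`, `n_perm`, `seed`.
#' @export
partition_variation <- function(response, env, space, n_perm = 999,
                                seed = NULL) {
  y <- as.matrix(response)
  env <- if (is.null(env)) matrix(nrow = nrow(y), ncol = 0) else as.matrix(env)
  space <- if (is.null(space)) matrix(nrow = nrow(y), ncol = 0) else as.matrix(space)
  n <- nrow(y)
  m_env <- if (ncol(env) > 0) attr(rda_r2(y, env), "m") else 0L
  m_space <- if (ncol(space) > 0) attr(rda_r2(y, space), "m") else 0L
  if (n - m_env - m_space - 1 <= 0) {
    stop("too few observations for the combined model", call. = FALSE)
  }
  r2_env <- if (m_env > 0) as.numeric(rda_r2(y, env)) else 0
  r2_space <- if (m_space > 0) as.numeric(rda_r2(y, space)) else 0
  r2_both <- if (m_env + m_space > 0)
    as.numeric(rda_r2(y, cbind(env, space))) else 0
  ab <- if (m_env > 0) adjusted_r2(r2_env, n, m_env) else 0
  bc <- if (m_space > 0) adjusted_r2(r2_space, n, m_space) else 0
  abc <- if (m_env + m_space > 0)
    adjusted_r2(r2_both, n, m_env + m_space) else 0
  a <- abc - bc; c_ <- abc - ab; b <- ab + bc - abc; d <- 1 - abc

  ps <- with_seed(seed, function() {
    p_a <- if (m_env > 0)
      partial_perm_test(y, env, if (m_space > 0) space else NULL, n_perm)$p
    else NA_real_
    p_c <- if (m_space > 0)
      partial_perm_test(y, space, if (m_env > 0) env else NULL, n_perm)$p
    else NA_real_
    p_abc <- if (m_env + m_space > 0)
      partial_perm_test(y, cbind(env, space), NULL, n_perm)$p
    else NA_real_
    c(p_a, p_c, p_abc)
  })

  fr <- tibble::tibble(
    fraction = c("a", "b", "c", "d", "abc"),
    adj_r2 = c(a, b, c_, d, abc),
    pct = 100 * c(a, b, c_, d, abc),
    p_value = c(ps[1], NA_real_, ps[2], NA_real_, ps[3])
  )
  structure(list(fractions = fr, n = n, m_env = m_env, m_space = m_space,
                 n_perm = n_perm, seed = seed),
            class = "varpart_fit")
}

#' @export
print.varpart_fit <- function(x, ...) {
  cat(sprintf("<varpart> n = %d, %d env + %d spatial predictors\n",
              x$n, x$m_env, x$m_space))
  print(x$fractions)
  invisible(x)
}
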