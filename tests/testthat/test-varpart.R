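test_that("Hellinger transform normalizes rows of relative abundance", {
  expect_equal(hellinger_transform(rbind(c(4, 0)))[1, ], c(1, 0),
               ignore_attr = TRUE)
  expect_equal(hellinger_transform(rbind(rep(1, 4)))[1, ], rep(0.5, 4),
               ignore_attr = TRUE)
  withr::with_seed(2, {
    m <- matrix(rpois(60, 3), 10, 6)
    m[m < 0] <- 0
    h <- hellinger_transform(m)
    pos <- rowSums(m) > 0
    expect_equal(rowSums(h[pos, ]^2), rep(1, sum(pos)), ignore_attr = TRUE)
    skip_if_not_installed("vegan")
    expect_equal(h[pos, ], vegan::decostand(m[pos, ], "hellinger"),
                 ignore_attr = TRUE)
  })
  expect_warning(hellinger_transform(rbind(c(1, 1), c(0, 0))), "all-zero")
  expect_error(hellinger_transform(rbind(c(-1, 2))), "non-negative")
})

test_that("standardization gives z-scores and drops constant columns", {
  z <- standardize_env(cbind(a = c(1, 2, 3)))
  expect_equal(as.vector(z), c(-1, 0, 1))
  expect_warning(out <- standardize_env(cbind(a = 1:4, b = rep(2, 4))),
                 "zero-variance")
  expect_equal(colnames(out), "a")
  # idempotent
  withr::with_seed(4, {
    m <- matrix(rnorm(30), 10, 3)
    z1 <- standardize_env(m)
    expect_equal(standardize_env(z1), z1, ignore_attr = TRUE)
  })
})

test_that("collinearity pre-filter removes one of each correlated pair", {
  withr::with_seed(6, {
    a <- rnorm(50); b <- a + rnorm(50, sd = 0.05); c <- rnorm(50)
    out <- decorrelate_env(cbind(a = a, b = b, c = c), 0.8)
    expect_equal(colnames(out), c("a", "c"))
    expect_equal(attr(out, "dropped"), "b")
  })
})

test_that("PCNM matches the independent eigen-decomposition oracle", {
  skip_if_not_installed("vegan")
  withr::with_seed(3, {
    for (rep in 1:3) {
      xy <- cbind(runif(10, 0, 5), runif(10, 0, 5))
      b <- steppediv::pcnm(xy)
      v <- vegan::pcnm(dist(xy))
      expect_equal(b$truncation, v$threshold)
      expect_equal(ncol(b$vectors), ncol(v$vectors))
      for (i in seq_len(ncol(b$vectors))) {
        expect_gt(abs(cor(b$vectors[, i], v$vectors[, i])), 1 - 1e-8)
      }
    }
  })
})

test_that("PCNM axes are orthogonal, centred, with positive eigenvalues", {
  cc <- as.matrix(quadrat_centers(c(6, 6), 0.5)[c("x", "y")])
  b <- steppediv::pcnm(cc)
  g <- crossprod(b$vectors)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_lt(max(abs(colMeans(b$vectors))), 1e-8)
  expect_true(all(b$values > 0))
  expect_true(!is.unsorted(rev(b$values)))
  # equidistant collinear points: truncation is the spacing
  line <- cbind(0:3, 0)
  expect_equal(steppediv::pcnm(line)$truncation, 1)
  expect_error(steppediv::pcnm(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident|distinct")
})

test_that("leading PCNM axes are broad-scale (Moran's I ordering)", {
  cc <- as.matrix(quadrat_centers(c(10, 10), 0.5)[c("x", "y")])
  b <- steppediv::pcnm(cc)
  moran <- function(z) {
    w <- as.matrix(dist(cc)) <= b$truncation + 1e-9
    diag(w) <- FALSE
    zc <- z - mean(z)
    (length(z) / sum(w)) * sum(w * outer(zc, zc)) / sum(zc^2)
  }
  expect_gt(moran(b$vectors[, 1]), moran(b$vectors[, ncol(b$vectors)]))
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0, 100, 1), -1 / 98)
  expect_equal(adjusted_r2(0.5, 30, 0), 0.5)
  expect_error(adjusted_r2(0.5, 5, 4), "undefined")
})

test_that("RDA R2 reduces to known identities", {
  withr::with_seed(9, {
    x <- rnorm(40)
    expect_equal(as.numeric(rda_r2(x, cbind(x))), 1)
    # p = 1, m = 1: squared Pearson correlation
    y <- 2 * x + rnorm(40)
    expect_equal(as.numeric(rda_r2(y, cbind(x))), cor(x, y)^2)
    # orthonormal predictors: R2 adds over single-predictor R2s
    xc <- matrix(rnorm(40 * 3), 40, 3)
    q <- qr.Q(qr(sweep(xc, 2, colMeans(xc))))  # orthonormal, centred columns
    yy <- q %*% c(1, 2, 3) + rnorm(40, sd = 0.5)
    total <- as.numeric(rda_r2(yy, q))
    singles <- sum(sapply(1:3, function(j) as.numeric(rda_r2(yy, q[, j]))))
    expect_equal(total, singles, tolerance = 1e-8)
    # pure noise, large n: R2 near zero
    yn <- rnorm(1000)
    xn <- rnorm(1000)
    expect_lt(as.numeric(rda_r2(yn, cbind(xn))), 0.01)
    # collinear predictors reduced with a warning
    expect_warning(rda_r2(y, cbind(x, x)), "collinear")
  })
})

test_that("forward selection finds a planted predictor with minimal p", {
  withr::with_seed(15, {
    n <- 80
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    y <- X[, 4] + rnorm(n, sd = 0.2)
    sel <- forward_select(y, X, n_perm = 199, seed = 3)
    expect_equal(sel$variable[1], "v4")
    expect_equal(sel$p_value[1], 1 / 200)
    # determinism and candidate-order invariance of the selected set
    sel2 <- forward_select(y, X, n_perm = 199, seed = 3)
    expect_identical(sel, sel2)
    perm_cols <- sample(10)
    sel3 <- forward_select(y, X[, perm_cols], n_perm = 199, seed = 3)
    expect_setequal(sel3$variable, sel$variable)
  })
})

test_that("double stopping halts at the global adjusted R2", {
  withr::with_seed(16, {
    n <- 60
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- X %*% c(1, 1, 1, 0, 0) + rnorm(n, sd = 0.5)
    free <- forward_select(y, X, n_perm = 99, seed = 1)
    capped <- forward_select(y, X, n_perm = 99, seed = 1,
                             global_adjr2 = free$adj_r2_cum[1])
    expect_lt(nrow(capped), nrow(free))
  })
})

test_that("partition fractions sum to one and collapse with empty sets", {
  withr::with_seed(18, {
    n <- 90
    env <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("e1", "e2")))
    space <- matrix(rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("s", 1:3)))
    y <- env %*% c(1, -0.5) + rnorm(n, sd = 0.5)
    p <- partition_variation(y, env, space, n_perm = 99, seed = 2)
    fr <- p$fractions
    expect_equal(sum(fr$adj_r2[fr$fraction %in% c("a", "b", "c", "d")]), 1,
                 tolerance = 1e-9)
    expect_equal(sum(fr$pct[fr$fraction %in% c("a", "b", "c", "d")]), 100,
                 tolerance = 1e-7)
    # no spatial predictors: b = c = 0 and a = adjR2(env) exactly
    p0 <- partition_variation(y, env, NULL, n_perm = 49, seed = 2)
    fr0 <- p0$fractions
    expect_equal(fr0$adj_r2[fr0$fraction == "b"], 0)
    expect_equal(fr0$adj_r2[fr0$fraction == "c"], 0)
    expect_equal(fr0$adj_r2[fr0$fraction == "a"],
                 adjusted_r2(as.numeric(rda_r2(y, env)), n, 2))
    # column order of predictors does not change the fractions
    p_perm <- partition_variation(y, env[, 2:1], space[, c(2, 1, 3)],
                                  n_perm = 99, seed = 2)
    expect_equal(p_perm$fractions$adj_r2, fr$adj_r2)
  })
})

test_that("an env-driven, space-free response puts the variance in [a]", {
  withr::with_seed(19, {
    res <- replicate(10, {
      n <- 100
      env <- matrix(rnorm(n * 2), n, 2)
      space <- matrix(rnorm(n * 3), n, 3)
      y <- env %*% c(1, 0.5) + rnorm(n, sd = 0.3)
      p <- partition_variation(y, env, space, n_perm = 19)
      fr <- p$fractions
      c(a = fr$adj_r2[fr$fraction == "a"], c = fr$adj_r2[fr$fraction == "c"])
    })
    expect_lt(abs(mean(res["c", ])), 0.02)
    expect_gt(mean(res["a", ]), 0.8)
  })
})

test_that("partition agrees with vegan::varpart on the adjusted fractions", {
  skip_if_not_installed("vegan")
  withr::with_seed(20, {
    n <- 70
    env <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("e1", "e2")))
    space <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("s1", "s2")))
    y <- env %*% c(1, -1) + space %*% c(0.5, 0) + rnorm(n, sd = 0.6)
    mine <- partition_variation(y, env, space, n_perm = 19)
    ref <- vegan::varpart(y, env, space)
    ind <- ref$part$indfract$Adj.R.square
    # vegan labels the two-table fractions [a]=env-only, [b]=space-only,
    # [c]=shared; map onto the env/shared/space/residual order used here
    expect_equal(mine$fractions$adj_r2[1:4], ind[c(1, 3, 2, 4)],
                 tolerance = 1e-8)
  })
})
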