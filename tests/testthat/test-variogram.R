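test_that("semivariance estimator matches hand computations", {
  # constant field: gamma = 0 at every lag
  cc <- as.matrix(quadrat_centers(c(3, 3), 1)[c("x", "y")])
  emp <- empirical_variogram(rep(4, 9), cc, lag_width = 1, max_lag = 5)
  expect_true(all(emp$gamma == 0))
  # two points, values 0 and 2 at distance 1: gamma = 2^2 / 2 = 2
  emp2 <- empirical_variogram(c(0, 2), rbind(c(0, 0), c(1, 0)),
                              lag_width = 1, max_lag = 2)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$np, 1L)
  expect_error(empirical_variogram(c(1, 2), rbind(c(0, 0), c(9, 9)),
                                   lag_width = 0.5, max_lag = 1),
               "no pairs")
})

test_that("estimator equals the brute-force all-pairs oracle on small grids", {
  for (shape in list(c(3, 3), c(4, 5), c(5, 5))) {
    withr::with_seed(shape[1] * 10 + shape[2], {
      v <- rnorm(prod(shape))
      cc <- as.matrix(quadrat_centers(shape, 0.5)[c("x", "y")])
      ml <- max(dist(cc)) / 2
      emp <- empirical_variogram(v, cc, lag_width = 0.5, max_lag = ml)
      oracle <- brute_variogram(v, cc, lag_width = 0.5, max_lag = ml)
      expect_equal(emp$h, oracle$h)
      expect_equal(emp$gamma, oracle$gamma)
      expect_equal(emp$np, oracle$np)
    })
  }
})

test_that("NA values are dropped pairwise", {
  cc <- as.matrix(quadrat_centers(c(2, 2), 1)[c("x", "y")])
  v <- c(1, NA, 3, 5)
  emp <- empirical_variogram(v, cc, lag_width = 1, max_lag = 3)
  oracle <- brute_variogram(v[-2], cc[-2, ], 1, 3)
  expect_equal(emp$gamma, oracle$gamma)
})

test_that("model fitting recovers exact parameters from model evaluations", {
  hs <- seq(0.25, 5, by = 0.5)
  for (model in c("exponential", "spherical", "gaussian")) {
    # a sits well inside the lag window so every parameter is identifiable
    # (a spherical model with a below the second lag is underdetermined)
    truth <- c(c0 = 0.1, c = 0.9, a = 1.2)
    g <- steppediv:::variogram_predict(model, truth, hs)
    emp <- structure(tibble::tibble(h = hs, gamma = g,
                                    np = rep(10L, length(hs))),
                     class = c("empirical_variogram",
                               class(tibble::tibble())),
                     variance = 1)
    fit <- fit_variogram(emp, model)
    expect_lt(abs(fit$c0 - 0.1), 1e-6)
    expect_lt(abs(fit$c - 0.9), 1e-6)
    expect_lt(abs(fit$a - 1.2), 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    # practical-range conventions
    expect_equal(fit$range,
                 switch(model, exponential = 3 * fit$a,
                        gaussian = sqrt(3) * fit$a, spherical = fit$a))
  }
})

test_that("a constant field yields a pure-nugget structure", {
  cc <- as.matrix(quadrat_centers(c(4, 4), 0.5)[c("x", "y")])
  emp <- empirical_variogram(rep(2.5, 16), cc, 0.5)
  fit <- fit_variogram(emp, "pure_nugget")
  expect_equal(fit$c, 0)
  expect_equal(fit$prop, 0)
  expect_equal(fit$c0, 0)
})

test_that("fitted model curves are non-decreasing in lag", {
  hs <- seq(0.1, 6, by = 0.1)
  for (model in c("exponential", "spherical", "gaussian")) {
    g <- steppediv:::variogram_predict(model, c(c0 = 0.3, c = 1.7, a = 1.2), hs)
    expect_true(all(diff(g) >= -1e-12))
  }
})

test_that("GRF simulation-estimation recovers sill and range on average", {
  res <- sapply(1:20, function(s) {
    z <- gaussian_random_field(c(30, 30), 0.5, nugget = 0.1,
                               partial_sill = 0.9, range = 0.5, seed = s)
    cc <- quadrat_centers(c(30, 30), 0.5)[c("x", "y")]
    fit <- fit_variogram(empirical_variogram(z, cc, 0.5), "exponential")
    c(sill = fit$sill, a = fit$a)
  })
  expect_lt(abs(mean(res["sill", ]) - 1), 0.25)
  expect_lt(abs(mean(res["a", ]) - 0.5) / 0.5, 0.4)
})

test_that("survey variograms average subplots by pair count and fit sensibly", {
  svs <- simulate_community(synth_config(seed = 7))
  emp <- diversity_variogram(svs$grazed, "richness")
  expect_true(all(emp$gamma >= 0))
  expect_true(!is.unsorted(emp$h, strictly = TRUE))
  # pair counts sum over the three subplots
  one <- diversity_variogram(
    survey_data(svs$grazed$abundance[svs$grazed$abundance$subplot == "g1", ],
                treatment = "grazed", grid_shape = c(10, 10)), "richness")
  expect_equal(emp$np, 3L * one$np)
  fit <- fit_variogram(emp, "exponential")
  expect_gte(fit$prop, 0); expect_lte(fit$prop, 1)
  expect_gt(fit$sill, 0)
})

test_that("treatment comparison labels sill changes and flips on swap", {
  mk <- function(sill) {
    structure(list(model = "exponential", c0 = 0.1 * sill, c = 0.9 * sill,
                   a = 0.3, range = 0.9, sill = sill, prop = 0.9, r2 = 0.8,
                   ssr = 0, empirical = tibble::tibble()),
              class = "variogram_fit")
  }
  fits <- list(grazed = list(richness = mk(0.614), abundance = mk(30.29)),
               fenced = list(richness = mk(0.488), abundance = mk(32.09)))
  tab <- spatial_structure_summary(fits)
  expect_equal(tab$change[tab$variable == "richness"], "decreased")
  expect_equal(tab$change[tab$variable == "abundance"], "increased")
  swapped <- spatial_structure_summary(list(grazed = fits$fenced,
                                            fenced = fits$grazed))
  expect_equal(swapped$change[swapped$variable == "richness"], "increased")
  same <- spatial_structure_summary(list(grazed = fits$grazed,
                                         fenced = fits$grazed))
  expect_true(all(same$change == "unchanged"))
  expect_error(spatial_structure_summary(list(grazed = fits$grazed)),
               "fenced")
})
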