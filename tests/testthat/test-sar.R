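test_that("empirical curves use the stated areas and subplot-mean contract", {
  sv <- random_survey(grid_shape = c(10, 10), n_subplots = 3, seed = 2)
  cv <- sar_curve(sv, "richness", ks = c(1, 10))
  expect_equal(cv$area, c(0.25, 25))
  # subplot means averaged after per-subplot evaluation
  per_sub <- sapply(sv$subplots, function(s) {
    surf <- diversity_surface(sv, 1, "richness")
    mean(surf$value[surf$subplot == s])
  })
  expect_equal(cv$value[1], mean(per_sub))
  expect_error(sar_curve(sv, ks = integer(0)), "non-empty")
})

test_that("richness curves are non-decreasing in area", {
  for (seed in 1:3) {
    sv <- random_survey(grid_shape = c(8, 8), n_subplots = 2, seed = seed)
    cv <- sar_curve(sv, "richness")
    expect_true(all(diff(cv$value) >= -1e-12))
  }
})

test_that("a uniform single-species community gives a flat richness curve", {
  sv <- single_species_survey(c(4, 4))
  cv <- sar_curve(sv, "richness")
  expect_equal(cv$value, rep(1, 4))
  expect_warning(fit <- fit_sar(cv, "exponential"), "zero variance")
  expect_equal(tidy(fit)$estimate, c(0, 1))
  expect_error(suppressWarnings(fit_sar(cv, "logistic")), "constant")
})

test_that("all model families recover generating parameters on noise-free curves", {
  A <- (1:10 * 0.5)^2
  cases <- list(
    logistic = c(alpha = 2, beta = 26, delta = 0.1),
    power = c(alpha = 3, beta = 0.3),
    power_additive = c(alpha = 5, beta = 0.45),
    exponential = c(alpha = 3, beta = 5),
    parabolic = c(alpha = -0.2, beta = 1.5, delta = 4),
    linear = c(alpha = 0.8, beta = 2)
  )
  for (fam in names(cases)) {
    truth <- cases[[fam]]
    S <- steppediv:::sar_predict(fam, as.list(truth), A)
    fit <- suppressWarnings(fit_sar(as_sar_curve(A, S), fam))
    expect_lt(max(abs(tidy(fit)$estimate - unname(truth))), 1e-6)
    expect_lt(fit$ssr, 1e-12)
  }
})

test_that("parameter recovery degrades gracefully with shrinking noise", {
  A <- (1:10 * 0.5)^2
  truth <- c(alpha = 3, beta = 0.3)
  err <- sapply(c(0.2, 0.02), function(sigma) {
    withr::with_seed(31, {
      mean(replicate(10, {
        S <- 3 * A^0.3 + rnorm(length(A), sd = sigma)
        max(abs(tidy(fit_sar(as_sar_curve(A, S), "power"))$estimate -
                  unname(truth)))
      }))
    })
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("model comparison ranks by SSR with the fewer-parameter tie rule", {
  sv <- random_survey(grid_shape = c(10, 10), n_subplots = 2, seed = 9)
  cv <- sar_curve(sv, "richness")
  fits <- lapply(c("logistic", "power", "exponential"), fit_sar, curve = cv)
  rk <- compare_sar(fits)
  expect_equal(rk$ssr, sort(rk$ssr))
  expect_equal(compare_sar(rev(fits))$family, rk$family)  # input-order invariant
  # tie rule via two fits with identical SSR but different parameter counts
  A <- (1:6)^2
  S <- 2 * log(A) + 1
  f2 <- suppressWarnings(fit_sar(as_sar_curve(A, S), "exponential"))  # exact, 2 params
  f3 <- suppressWarnings(fit_sar(as_sar_curve(A, S), "parabolic"))    # exact, 3 params
  f3$ssr <- f2$ssr
  expect_equal(compare_sar(list(f3, f2))$family[1], "exponential")
  # refusing to compare fits of different curves
  other <- fit_sar(sar_curve(random_survey(seed = 77), "richness"), "exponential")
  expect_error(compare_sar(list(fits[[1]], other)), "different curves")
})

test_that("confidence-interval overlap verdicts follow interval geometry", {
  A <- (1:10 * 0.5)^2
  f1 <- fit_sar(as_sar_curve(A, 26.6 / (1 + exp((0.115 - log(A)) / 1.99))),
                "logistic")
  expect_false(any(curves_differ(f1, f1)$disjoint))
  f2 <- fit_sar(as_sar_curve(A, 28.2 / (1 + exp((0.115 - log(A)) / 2.60))),
                "logistic")
  verdict <- curves_differ(f1, f2)
  expect_true(verdict$disjoint[verdict$term == "alpha"])
  expect_true(verdict$disjoint[verdict$term == "beta"])
  f_other <- fit_sar(as_sar_curve(A, 3 * A^0.3), "power")
  expect_error(curves_differ(f1, f_other), "different model families")
})

test_that("Coleman expectation obeys its boundary identities", {
  sv <- random_survey(grid_shape = c(6, 6), n_subplots = 2, seed = 4)
  cole <- expected_sar_coleman(sv)
  # at the full subplot area the expectation equals observed richness
  obs <- sar_curve(sv, "richness", ks = 6)
  expect_equal(cole$value[cole$k == 6], obs$value)
  # concave non-decreasing in area
  expect_true(all(diff(cole$value) >= -1e-12))
  slopes <- diff(cole$value) / diff(cole$area)
  expect_true(all(diff(slopes) <= 1e-9))
  # single individual: expectation is linear, a / A_total
  counts <- matrix(0, 16, 1); counts[7, 1] <- 1
  sv1 <- make_survey(counts, c(4, 4))
  cole1 <- expected_sar_coleman(sv1)
  expect_equal(cole1$value, cole1$area / 4)
})

test_that("randomization null is seeded and brackets unstructured data", {
  sv <- random_survey(grid_shape = c(8, 8), n_subplots = 2, seed = 12)
  r1 <- randomization_sar(sv, n_reps = 29, seed = 5)
  r2 <- randomization_sar(sv, n_reps = 29, seed = 5)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  # spatially unstructured data should sit inside the envelope nearly always
  rnd <- randomization_sar(sv, n_reps = 199, seed = 8)
  obs <- sar_curve(sv, "richness")
  inside <- obs$value >= rnd$lower & obs$value <= rnd$upper
  expect_gte(sum(inside), length(inside) - 1)
})

test_that("clustered communities fall below the random-placement expectation", {
  svs <- simulate_community(synth_config(seed = 21, clustering = 1.2))
  sv <- svs$grazed
  cole <- expected_sar_coleman(sv, ks = 1:3)
  obs <- sar_curve(sv, "richness", ks = 1:3)
  expect_true(all(obs$value < cole$value))
})
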