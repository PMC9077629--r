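test_that("free linear fit matches the normal-equations solution", {
  for (seed in c(1, 2, 3)) {
    pts <- fixture_points(n = 12, seed = seed)
    fit <- fit_constrained_linear(pts, taxon = FALSE)
    X <- cbind(1, pts$x)
    expect_equal(unname(fit$coefficients[c("intercept", "slope")]),
                 normal_equations_oracle(X, pts$y), tolerance = 1e-10)

    # with sum-to-zero taxon deviations
    fit_t <- fit_constrained_linear(pts, taxon = TRUE)
    lev <- intersect(insuladiv::taxon_groups, unique(pts$taxon_group))
    Ct <- stats::contr.sum(length(lev))
    Xt <- cbind(1, pts$x, Ct[as.integer(factor(pts$taxon_group, lev)), ])
    expect_equal(unname(fit_t$coefficients),
                 unname(normal_equations_oracle(Xt, pts$y)),
                 tolerance = 1e-10)
  }
})

test_that("exact data are fitted exactly and constraints force residuals", {
  pts <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3))
  fit <- fit_constrained_linear(pts, taxon = FALSE)
  expect_equal(unname(fit$coefficients[["intercept"]]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[["slope"]]), 1, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-20)

  # one-to-one null on shifted data: residuals are y - x
  pts2 <- tibble::tibble(x = c(1, 2), y = c(2, 3))
  null <- fit_constrained_linear(pts2, slope = "fixed", intercept = "fixed",
                                 taxon = FALSE)
  expect_equal(null$residuals, c(1, 1))
  expect_equal(null$sigma2, 1)
  expect_equal(null$k, 1L)  # only the residual variance is estimated
})

test_that("fixed-coefficient models and rank-deficiency behave as specified", {
  pts <- fixture_points(n = 10, seed = 4)
  semi <- fit_constrained_linear(pts, intercept = "fixed", taxon = FALSE)
  # semi-null solves the through-origin normal equation directly
  expect_equal(unname(semi$coefficients[["slope"]]),
               sum(pts$x * pts$y) / sum(pts$x^2), tolerance = 1e-10)
  expect_equal(unname(semi$coefficients[["intercept"]]), 0)

  degenerate <- pts
  degenerate$x <- 2
  expect_error(fit_constrained_linear(degenerate, taxon = FALSE),
               "rank deficient")
})

test_that("transformed fits reduce to OLS on the transformed regressor", {
  pts <- fixture_points(n = 15, seed = 5, x_range = c(1, 4))
  pts$y <- 2 * log(pts$x)
  fit <- fit_transformed(pts, "log", taxon = FALSE)
  expect_equal(unname(fit$coefficients[["slope"]]), 2, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)

  # log fit equals a linear fit on (log x, y)
  pts2 <- fixture_points(n = 15, seed = 6, x_range = c(1, 4))
  log_fit <- fit_transformed(pts2, "log", taxon = FALSE)
  lin_on_log <- fit_constrained_linear(
    dplyr::mutate(pts2, x = log(x)), taxon = FALSE)
  expect_equal(log_fit$coefficients, lin_on_log$coefficients,
               tolerance = 1e-12)
  expect_equal(log_fit$rss, lin_on_log$rss, tolerance = 1e-12)

  exp_fit <- fit_transformed(pts2, "exp", taxon = FALSE)
  lin_on_exp <- fit_constrained_linear(
    dplyr::mutate(pts2, x = exp(x)), taxon = FALSE)
  expect_equal(exp_fit$rss, lin_on_exp$rss, tolerance = 1e-12)
})

test_that("broken-stick recovers a known breakpoint and matches grid search", {
  # noiseless piecewise data: slope 1 then 0, breakpoint at 0.5 on [0, 1]
  x <- seq(0, 1, length.out = 41)
  pts <- tibble::tibble(x = x, y = pmin(x, 0.5))
  fit <- fit_broken_stick(pts, taxon = FALSE, tol = 1e-8)
  expect_false(fit$boundary_flag)
  expect_equal(fit$psi, 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["slope"]]), 1, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["slope_change"]]), -1,
               tolerance = 1e-6)

  # iterative estimate agrees with a dense grid-search RSS minimizer on
  # noisy instances
  for (seed in c(11, 12)) {
    set.seed(seed)
    x <- sort(runif(120, 1, 5))
    y <- 1 + 0.9 * x - 0.7 * pmax(x - 3, 0) + rnorm(120, 0, 0.15)
    pts <- tibble::tibble(x = x, y = y)
    fit <- fit_broken_stick(pts, taxon = FALSE, tol = 1e-8)
    oracle <- grid_search_psi(x, y)
    expect_false(fit$boundary_flag)
    expect_equal(fit$psi, oracle$psi, tolerance = 0.01)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-4)
  }

  # purely linear data: no interior breakpoint exists
  pts_lin <- tibble::tibble(x = seq(1, 5, length.out = 30),
                            y = 0.2 + 0.8 * seq(1, 5, length.out = 30))
  fit_lin <- fit_broken_stick(pts_lin, taxon = FALSE)
  expect_true(fit_lin$boundary_flag)
  lin <- fit_constrained_linear(pts_lin, taxon = FALSE)
  expect_lte(fit_lin$rss, lin$rss + 1e-12)
})

test_that("model nesting is respected: constrained RSS never beats freer RSS", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- 20
    pts <- tibble::tibble(
      taxon_group = sample(insuladiv::taxon_groups, n, replace = TRUE),
      x = runif(n, 1, 5),
      y = runif(n, 0.5, 5.5)
    )
    fits <- suppressWarnings(fit_model_suite(pts, side = "within"))
    expect_gte(fits$null$rss, fits$semi_null$rss - 1e-10)
    expect_gte(fits$semi_null$rss, fits$linear$rss - 1e-10)
    expect_gte(fits$linear$rss, fits$broken_stick$rss - 1e-10)
  }
})

test_that("AICc follows the closed form and exceeds AIC", {
  # n = 10, k = 3, logLik = -5: AIC = 16, AICc = 16 + 24/6 = 20
  fit <- structure(list(n = 10L, k = 3L, loglik = -5), class = "gd_fit")
  expect_equal(aicc(fit), 20)
  for (i in 1:20) {
    set.seed(i)
    n <- sample(8:200, 1)
    k <- sample(1:5, 1)
    ll <- runif(1, -100, 0)
    fit <- structure(list(n = n, k = k, loglik = ll), class = "gd_fit")
    aic <- 2 * k - 2 * ll
    expect_equal(aicc(fit), aic + 2 * k * (k + 1) / (n - k - 1))
    expect_gt(aicc(fit), aic)
  }
  # the correction vanishes for large n
  fit_big <- structure(list(n = 1e7L, k = 1L, loglik = -5), class = "gd_fit")
  expect_equal(aicc(fit_big), 2 * 1 + 10, tolerance = 1e-5)
  # undefined below the sample-size floor
  fit_small <- structure(list(n = 4L, k = 3L, loglik = -5), class = "gd_fit")
  expect_error(aicc(fit_small), "AICc undefined")
})

test_that("Akaike weights and evidence ratios follow the closed forms", {
  # equal AICc -> equal weights
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  # invariance to adding a constant
  a <- c(100, 103.2, 110.9)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3))
  # monotone decreasing in delta
  w <- akaike_weights(c(0, 1, 4, 9))
  expect_true(all(diff(w) < 0))

  pts <- fixture_points(n = 30, seed = 8)
  fits <- fit_model_suite(pts, side = "within", taxon = FALSE)
  cmp <- compare_models(fits)
  expect_equal(sum(cmp$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(cmp$table$delta_aicc), 0)
  expect_equal(
    evidence_ratio(cmp, cmp$table$model[1], cmp$table$model[2]),
    exp((cmp$table$delta_aicc[2] - cmp$table$delta_aicc[1]) / 2),
    tolerance = 1e-12
  )

  # permutation invariance
  cmp2 <- compare_models(rev(fits))
  expect_equal(cmp$table, cmp2$table)

  # different point sets are non-comparable
  other <- fit_constrained_linear(fixture_points(n = 30, seed = 9),
                                  taxon = FALSE)
  expect_error(compare_models(c(fits["null"], list(other = other))),
               "different point sets")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  pts <- fixture_points(n = 20, seed = 10)
  fit <- fit_constrained_linear(pts, taxon = TRUE)
  td <- tidy(fit)
  expect_true(all(c("intercept", "slope") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n, 20L)
  expect_equal(gl$AICc, aicc(fit))
  cmp <- compare_models(fit_model_suite(pts, side = "within"))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$best_model, cmp$table$model[1])
})
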