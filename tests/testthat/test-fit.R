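test_that("a noiseless line is fitted exactly", {
  otd <- seq(-60, 30, length.out = 10)
  d <- tibble::tibble(otd_norm = otd, si = 0.5 * otd + 40)
  fit <- suppressWarnings(fit_si_on_otd(d)) # perfect fit: summary.lm warns
  expect_equal(fit$B, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 40, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("the fit agrees with the closed-form OLS oracle on random data", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    otd <- rnorm(n, 0, 40)
    si <- 45 + 0.4 * otd + rnorm(n, 0, 8)
    d <- tibble::tibble(otd_norm = otd, si = si)
    fit <- fit_si_on_otd(d)
    oracle <- ols_oracle(otd, si)
    expect_equal(fit$B, oracle$B, tolerance = 1e-6)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-6)
    expect_equal(fit$se_B, oracle$se_B, tolerance = 1e-6)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-6)
  }
})

test_that("univariate identities hold on every fit", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 25, seed = 13))
  for (scope in SCOPE_LEVELS) {
    fit <- fit_si_on_otd(ff, scope = scope)
    expect_lt(abs(fit$beta^2 - fit$r_squared), 1e-9)
    expect_identical(fit$vif, 1)
    expect_equal(fit$t_stat, fit$B / fit$se_B)
    expect_lte(fit$ci95_B[["lower"]], fit$B)
    expect_gte(fit$ci95_B[["upper"]], fit$B)
    # t-based CI halfwidth
    expect_equal(unname(diff(fit$ci95_B)), 2 * qt(0.975, fit$n - 2) * fit$se_B,
                 tolerance = 1e-9)
  }
})

test_that("split-flagged and missing-OTD footfalls are excluded from the fit", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 20, seed = 14))
  ff$otd_norm[1:10] <- NA
  fit <- fit_si_on_otd(ff)
  expect_identical(fit$n, sum(!ff$split_belt & !is.na(ff$otd_norm)))
})

test_that("degenerate inputs are rejected", {
  d2 <- tibble::tibble(otd_norm = c(1, 2), si = c(10, 20))
  expect_error(fit_si_on_otd(d2), "at least 3")
  flat <- tibble::tibble(otd_norm = rep(5, 10), si = rnorm(10, 50))
  expect_error(fit_si_on_otd(flat), "zero variance")
  expect_error(fit_si_on_otd(tibble::tibble(x = 1:5)), "missing required")
  expect_error(fit_si_on_otd(tibble::tibble(otd_norm = 1:5, si = 1:5),
                             scope = "flat"), "surface")
})

test_that("tidy and glance expose the broom-shaped summaries", {
  ff <- simulate_footfalls(tiny_spec(seed = 15))
  fit <- fit_si_on_otd(ff)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "otd_norm"))
  expect_equal(td$estimate, c(fit$intercept, fit$B))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_named(gl, c("scope", "B", "intercept", "t", "beta", "vif", "p.value",
                     "ci_lower_B", "ci_upper_B", "r.squared", "n"))
})

test_that("fit_all_scopes returns one row per scope with attached fits", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 15, seed = 16))
  tbl <- fit_all_scopes(ff)
  expect_identical(tbl$scope, SCOPE_LEVELS)
  fits <- attr(tbl, "fits")
  expect_named(fits, SCOPE_LEVELS)
  expect_s3_class(fits$flat, "si_otd_fit")
})

test_that("predicted SI follows the line and clamps to the physical range", {
  line <- si_otd_line(0.444, 45.84, ci95_B = c(0.441, 0.448))
  expect_equal(predict_si(line, 0), 45.84, ignore_attr = TRUE)
  expect_equal(predict_si(line, -28.92), 33, tolerance = 0.01,
               ignore_attr = TRUE)
  far <- predict_si(line, c(-200, 200))
  expect_equal(as.numeric(far), c(0, 100))
  expect_identical(attr(far, "out_of_range"), c(TRUE, TRUE))
  # a degenerate zero-slope line cannot be constructed
  expect_error(si_otd_line(0, 50), "non-zero")
})

test_that("the fit plot renders scatter, line and band boundaries", {
  ff <- simulate_footfalls(tiny_spec(seed = 17))
  p <- autoplot(fit_si_on_otd(ff))
  expect_s3_class(p, "ggplot")
  expect_error(autoplot(si_otd_line(0.4, 45)), "no data")
})
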