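test_that("record count is the product of the design counts", {
  cases <- list(
    list(ns = 2, fp = 5, surf = SURFACE_LEVELS, pat = PATTERN_LEVELS),
    list(ns = 7, fp = 3, surf = "flat", pat = PATTERN_LEVELS),
    list(ns = 1, fp = 1, surf = c("flat", "declined"), pat = "MFS")
  )
  for (cs in cases) {
    spec <- population_spec(n_subjects = cs$ns, surfaces = cs$surf,
                            patterns = cs$pat, footfalls_per_condition = cs$fp,
                            seed = 9)
    expect_identical(nrow(simulate_footfalls(spec)),
                     as.integer(cs$ns * length(cs$surf) * length(cs$pat) * cs$fp))
  }
})

test_that("generation is reproducible from the seed", {
  a <- simulate_footfalls(tiny_spec(seed = 77))
  b <- simulate_footfalls(tiny_spec(seed = 77))
  c <- simulate_footfalls(tiny_spec(seed = 78))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("records satisfy their field invariants", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 30, seed = 5))
  expect_true(all(ff$si >= 0 & ff$si <= 100))
  expect_true(all(ff$foot_length >= 20 & ff$foot_length <= 30))
  expect_true(all(sign(ff$otd_norm) == sign(ff$otd_raw)))
  # normalisation consistency: otd_norm is the foot-length-corrected otd_raw
  expect_equal(ff$otd_norm, normalize_otd(ff$otd_raw, ff$foot_length),
               tolerance = 1e-12)
  # one foot length per subject
  per_subject <- dplyr::n_distinct(
    dplyr::distinct(ff, subject_id, foot_length)$subject_id)
  expect_identical(per_subject, dplyr::n_distinct(ff$subject_id))
})

test_that("invalid design parameters are rejected by name", {
  expect_error(population_spec(surfaces = c("flat", "uphill")), "surface")
  expect_error(population_spec(patterns = "toe-run"), "pattern")
  expect_error(population_spec(exclusion_rate = 1.2), "exclusion_rate")
  expect_error(population_spec(n_subjects = 0), "counts")
  expect_error(population_spec(slope_by_surface = c(flat = -1, inclined = 0.4, declined = 0.5)),
               "slope")
})

test_that("a noiseless population lies exactly on the generating lines", {
  spec <- population_spec(
    n_subjects = 10, footfalls_per_condition = 5, seed = 11,
    noise_sd_by_surface = c(flat = 0, inclined = 0, declined = 0),
    exclusion_rate = 0
  )
  ff <- simulate_footfalls(spec)
  for (s in SURFACE_LEVELS) {
    # a perfect fit makes summary.lm warn; that is the point of the test
    fit <- suppressWarnings(fit_si_on_otd(ff, scope = s))
    expect_equal(fit$B, unname(spec$slope_by_surface[s]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(spec$intercept_by_surface[s]),
                 tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("the split-belt flag rate matches its binomial expectation", {
  spec <- tiny_spec(n_subjects = 60, footfalls = 15, seed = 21)
  ff <- simulate_footfalls(spec)
  n <- nrow(ff)
  expected <- n * spec$exclusion_rate
  tol <- 3 * sqrt(n * spec$exclusion_rate * (1 - spec$exclusion_rate))
  expect_lt(abs(sum(ff$split_belt) - expected), tol)
})

test_that("per-surface refit recovers slope and calibrated R-squared at large n", {
  # ~10,000 footfalls on one surface
  spec <- surface_spec("flat", n_subjects = 112, footfalls = 30, seed = 31,
                       exclusion_rate = 0)
  ff <- simulate_footfalls(spec)
  fit <- fit_si_on_otd(ff, scope = "flat")
  expect_equal(fit$B, 0.440, tolerance = 0.02)
  expect_equal(fit$r_squared, 0.836, tolerance = 0.02)
})
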