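test_that("strike-index bands assign RFS/MFS/FFS with downward ties", {
  expect_identical(as.character(classify_si(c(20, 33, 33.01, 50, 66, 66.01, 80))),
                   c("RFS", "RFS", "MFS", "MFS", "MFS", "FFS", "FFS"))
  expect_identical(as.character(classify_si(c(0, 100))), c("RFS", "FFS"))
  expect_error(classify_si(c(50, 101)), "outside")
  expect_error(classify_si(-1), "outside")
})

test_that("OTD windows classify against the pooled reference calibration", {
  win <- derive_cutoffs(reference_line("all"))
  expect_identical(as.character(classify_otd(c(-40, 0, 60), win)),
                   c("RFS", "MFS", "FFS"))
  expect_error(classify_otd(0, c(10, -10)), "Inverted")
})

test_that("the two classification routes through one model never disagree", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 20, seed = 23))
  set.seed(24)
  otd <- runif(2000, -150, 150)
  for (scope in SCOPE_LEVELS) {
    fit <- fit_si_on_otd(ff, scope = scope)
    win <- derive_cutoffs(fit)
    via_otd <- classify_otd(otd, win)
    via_si <- classify_si(as.numeric(predict_si(fit, otd)))
    expect_identical(via_otd, via_si)
  }
})

test_that("agreement of identical labels is perfect and confusion sums to n", {
  labs <- classify_si(c(10, 50, 90, 20, 70))
  rep_same <- agreement_report(labs, labs)
  expect_equal(rep_same$overall, 1)
  expect_true(all(diag(rep_same$confusion) == rowSums(rep_same$confusion)))
  expect_identical(sum(rep_same$confusion), length(labs))
  expect_true(all(rep_same$confusion >= 0))
})

test_that("a degenerate all-midfoot classifier scores one third on balanced truth", {
  truth <- factor(rep(c("RFS", "MFS", "FFS"), each = 100),
                  levels = c("RFS", "MFS", "FFS"))
  pred <- factor(rep("MFS", 300), levels = levels(truth))
  rep_deg <- agreement_report(truth, pred)
  expect_equal(rep_deg$overall, 1 / 3, tolerance = 1e-9)
  expect_equal(unname(rep_deg$recall), c(0, 1, 0))
  expect_error(agreement_report(truth, pred[-1]), "equal length")
})

test_that("tidy and glance summarise an agreement report", {
  labs <- classify_si(c(10, 50, 90))
  rep1 <- agreement_report(labs, labs)
  expect_identical(nrow(tidy(rep1)), 9L)
  expect_identical(sum(tidy(rep1)$count), 3L)
  expect_named(glance(rep1),
               c("n", "overall", "recall_RFS", "recall_MFS", "recall_FFS"))
})

test_that("surface-matched windows beat wrong-surface windows on flat data", {
  ff <- simulate_footfalls(surface_spec("flat", n_subjects = 40, seed = 25))
  ff <- dplyr::filter(ff, !split_belt)
  truth <- classify_si(ff$si)
  flat_win <- derive_cutoffs(reference_line("flat"))
  incl_win <- derive_cutoffs(reference_line("inclined"))
  agree_flat <- agreement_report(truth, classify_otd(ff$otd_norm, flat_win))
  agree_incl <- agreement_report(truth, classify_otd(ff$otd_norm, incl_win))
  expect_gt(agree_flat$overall, agree_incl$overall)
  expect_gt(agree_flat$overall, 1 / 3) # materially above chance
})
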