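test_that("a heel-tip landing puts the initial-contact COP at the heel", {
  tr <- simulate_traces(toy_record(si = 0, otd_raw = -60))
  truth <- attr(tr, "truth")
  i_ic <- which(tr$time == truth$t_ic)
  expect_equal(tr$cop_long[i_ic], 0)
  # heel fires 60 ms before the toe
  expect_equal(truth$t_heel - truth$t_toe, -0.060, tolerance = 1e-12)
  on_heel <- detect_onset(tr$fsr_heel, attr(tr, "sampling_rate"))
  on_toe <- detect_onset(tr$fsr_toe, attr(tr, "sampling_rate"))
  expect_equal(on_toe - on_heel, 0.060, tolerance = 1e-3)
})

test_that("a simultaneous landing triggers both sensors on the same sample", {
  tr <- simulate_traces(toy_record(si = 50, otd_raw = 0))
  fs <- attr(tr, "sampling_rate")
  expect_identical(detect_onset(tr$fsr_heel, fs), detect_onset(tr$fsr_toe, fs))
})

test_that("trace channels satisfy the structural invariants", {
  for (rec in list(toy_record(), toy_record(si = 85, otd_raw = 70, split_belt = TRUE))) {
    tr <- simulate_traces(rec)
    truth <- attr(tr, "truth")
    expect_true(all(tr$vgrf >= 0))
    lens <- lengths(list(tr$vgrf, tr$cop_long, tr$cop_lat, tr$fsr_heel, tr$fsr_toe))
    expect_true(all(lens == nrow(tr)))
    # COP is defined exactly on the contact window
    defined <- !is.na(tr$cop_long)
    expect_true(all(tr$time[defined] >= truth$t_ic & tr$time[defined] <= truth$t_off))
    expect_false(any(defined & tr$time < truth$t_ic))
    # COP rolls monotonically toeward and stays within the foot
    cop <- tr$cop_long[defined]
    expect_true(all(diff(cop) >= 0))
    expect_true(all(cop >= 0 & cop <= rec$foot_length + 1e-9))
    # lateral COP encodes the split flag
    lat <- tr$cop_lat[!is.na(tr$cop_lat)][1]
    if (isTRUE(rec$split_belt)) expect_lte(abs(lat), 1) else expect_gt(abs(lat), 1)
  }
})

test_that("onsets outside the stance are rejected", {
  expect_error(simulate_traces(toy_record(otd_raw = 260), stance_duration = 0.25),
               "stance")
  expect_error(simulate_traces(toy_record(otd_raw = -250), stance_duration = 0.25),
               "stance")
})

test_that("full chain recovers SI and OTD within quantisation bounds across the OTD sweep", {
  cfg <- run_config()
  for (otd in seq(-100, 100, by = 20)) {
    si <- 50 + 0.44 * otd # keep the pair physically consistent-ish
    tr <- simulate_traces(toy_record(si = si, otd_raw = otd, foot_length = 23))
    rec <- suppressWarnings(process_traces(tr, cfg))
    expect_identical(nrow(rec), 1L)
    expect_lt(abs(rec$si - si), 0.5)
    expect_lt(abs(rec$otd_raw - otd), 1 + 1e-9)
  }
})

test_that("a trial concatenates stances with per-stance ground truth", {
  ff <- simulate_footfalls(tiny_spec(n_subjects = 1, footfalls = 4, seed = 3))
  trial <- dplyr::filter(ff, surface == "flat", instructed_pattern == "MFS")
  tr <- simulate_trial(trial)
  truth <- attr(tr, "truth")
  expect_identical(nrow(truth), nrow(trial))
  expect_true(all(diff(truth$t_ic) > 0))
  expect_equal(truth$otd_raw, trial$otd_raw, tolerance = 1e-12)
})

test_that("an optional sensor lag delays both channels without breaking recovery", {
  set.seed(42)
  tr <- simulate_traces(toy_record(si = 40, otd_raw = -30),
                        sensor_lag_range = c(0, 0.003))
  rec <- suppressWarnings(process_traces(tr))
  # each channel may lag independently by up to 3 ms
  expect_lt(abs(rec$otd_raw - (-30)), 3 + 1 + 1e-9)
})
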