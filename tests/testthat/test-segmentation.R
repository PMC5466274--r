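test_that("a square force pulse yields one stance of the right duration", {
  fs <- 1000
  vgrf <- rep(0, 600)
  vgrf[151:400] <- 800 # 250 ms
  seg <- segment_stances(vgrf, fs)
  expect_identical(nrow(seg), 1L)
  dur_samples <- seg$i_off - seg$i_ic + 1L
  expect_lte(abs(dur_samples - 250L), 1L)
})

test_that("an all-zero signal yields no stances and empty input is tolerated", {
  expect_identical(nrow(segment_stances(rep(0, 1000), 1000)), 0L)
  expect_identical(nrow(segment_stances(numeric(0), 1000)), 0L)
})

test_that("a train of half-sine pulses is segmented with sample-accurate contacts", {
  fs <- 1000
  n_pulses <- 30
  pulse <- 1500 * sinpi(seq_len(250) / 251)
  gap <- rep(0, 150)
  vgrf <- c(gap, rep(c(pulse, gap), n_pulses))
  seg <- segment_stances(vgrf, fs)
  expect_identical(nrow(seg), as.integer(n_pulses))
  true_starts <- 150 + (seq_len(n_pulses) - 1) * 400 + 1
  # contact detected at the 10 N crossing, within a sample or two of onset
  expect_true(all(abs(seg$i_ic - true_starts) <= 2))
})

test_that("sub-minimum contact episodes are discarded as noise", {
  fs <- 1000
  vgrf <- rep(0, 500)
  vgrf[100:119] <- 400 # 20 ms blip
  vgrf[200:400] <- 400 # 201 ms stance
  seg <- segment_stances(vgrf, fs, min_stance_ms = 50)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$i_ic, 200L)
})

test_that("keep_last_n returns the trailing footfalls in order", {
  seg45 <- tibble::tibble(stance = 1:45, t_ic = as.numeric(1:45))
  expect_identical(keep_last_n(seg45, 30)$stance, 16:45)
  expect_identical(keep_last_n(seg45[1:30, ], 30)$stance, 1:30)
  expect_warning(kept <- keep_last_n(seg45[1:12, ], 30), "12")
  expect_identical(kept$stance, 1:12)
})

test_that("split-belt exclusion removes exactly the in-zone landings, in order", {
  seg <- tibble::tibble(stance = 1:5,
                        cop_ic_lat = c(5, 0.4, -3, -0.9, 2))
  res <- exclude_split_belt(seg, split_zone_halfwidth = 1)
  expect_identical(res$n_excluded, 2L)
  expect_identical(res$kept$stance, c(1L, 3L, 5L))
  # zero half-width with no landing exactly on the midline keeps everything
  res0 <- exclude_split_belt(seg, split_zone_halfwidth = 0)
  expect_identical(res0$n_excluded, 0L)
  expect_identical(res0$kept, seg)
})

test_that("exclusion conserves rows and never invents segments", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    seg <- tibble::tibble(stance = seq_len(n), cop_ic_lat = rnorm(n, 0, 2))
    hw <- runif(1, 0, 3)
    res <- exclude_split_belt(seg, hw)
    expect_identical(nrow(res$kept) + res$n_excluded, n)
    expect_true(all(res$kept$stance %in% seg$stance))
    expect_false(is.unsorted(res$kept$stance))
  }
})
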