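test_that("difference selection takes the smaller flanking difference", {
  r <- select_differences(c(120, 121, 122, 119, 118, 121, 120))
  expect_equal(unname(r$selected), c(1, 1, 1))
  expect_equal(unname(r$flanking["p4", ]), c(3, 1))
  # all seven equal
  expect_equal(unname(select_differences(rep(100, 7))$selected), c(0, 0, 0))
  # both flanks equal: the minimum is that common value
  r2 <- select_differences(c(100, 110, 100, 110, 100, 110, 100))
  expect_equal(unname(r2$selected), c(10, 10, 10))
  expect_error(select_differences(c(120, NA, 120, 120, 120, 120, 120)),
               "incomplete")
})

test_that("selected differences never exceed either flank (property)", {
  set.seed(11)
  for (i in 1:200) {
    v <- round(rnorm(7, 120, 15))
    r <- select_differences(v)
    expect_true(all(r$selected <= r$flanking[, 1]))
    expect_true(all(r$selected <= r$flanking[, 2]))
    expect_true(all(r$selected >= 0))
    expect_equal(unname(r$selected),
                 unname(pmin(r$flanking[, 1], r$flanking[, 2])))
  }
})

test_that("band counts are cumulative, inclusive at the boundary", {
  bp <- esh_bands("SBP")
  expect_equal(band_counts(matrix(0, 100, 3), bp),
               c(b1 = 300, b2 = 300, b3 = 300, beyond = 0))
  expect_equal(band_counts(c(4, 6, 20), bp),
               c(b1 = 1, b2 = 2, b3 = 2, beyond = 1))
  # a difference of exactly 5 mm Hg counts inside the first band
  expect_equal(band_counts(c(5, 10, 15), bp),
               c(b1 = 1, b2 = 2, b3 = 3, beyond = 0))
  hr <- esh_bands("HR")
  expect_equal(unname(hr), c(3, 5, 8))
  expect_equal(band_counts(c(3, 8, 8.5), hr),
               c(b1 = 1, b2 = 1, b3 = 2, beyond = 1))
})

test_that("cumulative band counts are monotone over random inputs", {
  set.seed(3)
  for (i in 1:50) {
    d <- abs(rnorm(3 * 33, 0, 8))
    ct <- band_counts(d, esh_bands("SBP"))
    expect_true(ct[["b1"]] <= ct[["b2"]])
    expect_true(ct[["b2"]] <= ct[["b3"]])
    expect_equal(ct[["b3"]] + ct[["beyond"]], length(d))
  }
})

test_that("requirement scaling reproduces the published thresholds", {
  r100 <- scale_requirements(100)
  expect_equal(r100$pair_two_of, c(219L, 261L, 288L))
  expect_equal(r100$pair_all_of, c(195L, 243L, 279L))
  expect_equal(r100$subj_min_good, 72L)
  expect_equal(r100$subj_max_bad, 9L)
  r33 <- scale_requirements(33)
  expect_equal(r33$pair_two_of, c(73L, 87L, 96L))
  expect_equal(r33$pair_all_of, c(65L, 81L, 93L))
  expect_equal(r33$subj_min_good, 24L)
  expect_equal(r33$subj_max_bad, 3L)
  r66 <- scale_requirements(66)
  expect_equal(r66$pair_two_of, c(146L, 174L, 192L))
  expect_equal(r66$pair_all_of, c(130L, 162L, 186L))
  expect_equal(r66$subj_min_good, 48L)
  expect_equal(r66$subj_max_bad, 6L)
  expect_error(scale_requirements(32), "33")
})

test_that("phase 1 combines the two-of and all-of rules", {
  req <- scale_requirements(100)
  expect_equal(evaluate_phase1(c(242, 286, 298), req)$verdict, "pass")
  expect_equal(evaluate_phase1(c(277, 295, 299), req)$verdict, "pass")
  # two-of can be met through bands 2 and 3 while all-of fails on band 1
  out <- evaluate_phase1(c(194, 300, 300), req)
  expect_equal(out$verdict, "fail")
  expect_equal(sum(out$criteria_met$two_of), 2L)
  expect_false(all(out$criteria_met$all_of))
  expect_error(evaluate_phase1(c(298, 286, 242), req), "cumulative")
})

test_that("phase 2 counts good and bad participants", {
  req <- scale_requirements(100)
  mk <- function(good, bad) c(rep(3L, good), rep(0L, bad),
                              rep(1L, 100 - good - bad))
  expect_equal(evaluate_phase2(mk(87, 0), req)$verdict, "pass")
  expect_equal(evaluate_phase2(mk(95, 2), req)$verdict, "pass")
  expect_equal(evaluate_phase2(mk(71, 0), req)$verdict, "fail")
  expect_equal(evaluate_phase2(mk(72, 10), req)$verdict, "fail")
  expect_error(evaluate_phase2(rep(3L, 99), req), "does not match")
  expect_error(evaluate_phase2(c(rep(3L, 99), 4L), req), "0..3")
})

test_that("identical devices pass trivially with zero mean difference", {
  df <- make_study_df(sprintf("P%02d", 1:33), 1:2, "SBP",
                      gen = function(id, s, v) rep(120 + nchar(id), 7))
  ds <- study_dataset(df)
  v <- validate_device(ds, "SBP")
  expect_equal(v$overall, "pass")
  comp <- v$components$SBP1
  expect_equal(comp$mean_difference, 0)
  expect_equal(comp$sd_difference, 0)
  expect_equal(unname(comp$band_counts[1:3]), c(99, 99, 99))
})

test_that("a +20 mm Hg test bias fails phase 1 with every pair beyond band 3", {
  cfg <- simulation_config(n_subjects = 40, dropout = 0,
                           variables = list(SBP = list(test_bias = 20,
                                                       within_subject_sd = 1)))
  ds <- generate_study(cfg, seed = 5)
  v <- validate_device(ds, "SBP")
  expect_equal(v$overall, "fail")
  expect_equal(v$components$SBP1$phase1$verdict, "fail")
  expect_gt(v$components$SBP1$band_counts[["beyond"]], 100)
})

test_that("fewer than 33 completers is a protocol error", {
  ds <- generate_study(simulation_config(n_subjects = 20, dropout = 0),
                       seed = 1)
  expect_error(validate_device(ds), "33")
})

test_that("verdicts match the brute-force oracle on random small studies", {
  set.seed(101)
  for (i in 1:25) {
    ds <- random_small_study()
    v <- validate_device(ds, "SBP")
    for (s in 1:2) {
      o <- oracle_verdict(ds, "SBP", s, esh_bands("SBP"))
      comp <- v$components[[paste0("SBP", s)]]
      expect_identical(comp$phase1$verdict == "pass", o$phase1)
      expect_identical(comp$phase2$verdict == "pass", o$phase2)
      expect_equal(unname(comp$band_counts[1:3]), o$counts)
    }
  }
})

test_that("adding a positive offset to the test device never rescues a failure", {
  cfg <- simulation_config(n_subjects = 33, dropout = 0,
                           variables = list(SBP = list(test_bias = 4,
                                                       test_noise_sd = 4)))
  ds <- generate_study(cfg, seed = 9)
  verdicts <- vapply(c(0, 2, 5, 10, 25), function(off) {
    validate_device(shift_test_readings(ds, off), "SBP")$overall
  }, character(1))
  # once failing, stays failing as the offset grows
  failed <- verdicts == "fail"
  expect_true(all(failed[which(failed)[1]:length(failed)]))
  expect_equal(verdicts[length(verdicts)], "fail")
})

test_that("the paper-like scenario passes end to end", {
  ds <- generate_study(esh_scenario("paper_like"), seed = 20101)
  expect_equal(length(v <- validate_device(ds)$overall), 1L)
  expect_equal(v, "pass")
})
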