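make_const_study <- function(ids = c("A", "B", "C"), value = 100) {
  study_dataset(make_study_df(ids, 1:2, "SBP",
                              gen = function(id, s, v) rep(value, 7)))
}

test_that("participant means average the right readings per device", {
  df <- series_rows("A", 1, "SBP", c(120, 130, 122, 131, 118, 129, 121))
  ds <- study_dataset(df)
  m <- participant_means(ds, "session1", "SBP")
  expect_equal(m$criterion_mean, mean(c(120, 122, 118, 121)))  # 120.25
  expect_equal(m$test_mean, mean(c(130, 131, 129)))
  # all readings equal
  mc <- participant_means(make_const_study(), "session1", "SBP")
  expect_true(all(mc$criterion_mean == 100 & mc$test_mean == 100))
})

test_that("intersession scope equals the mean of the two session means", {
  set.seed(2)
  ds <- generate_study(simulation_config(n_subjects = 6, dropout = 0),
                       seed = 2)
  m1 <- participant_means(ds, "session1", "SBP")
  m2 <- participant_means(ds, "session2", "SBP")
  mi <- participant_means(ds, "intersession", "SBP")
  expect_equal(mi$criterion_mean, (m1$criterion_mean + m2$criterion_mean) / 2)
  expect_equal(mi$test_mean, (m1$test_mean + m2$test_mean) / 2)
})

test_that("participants with incomplete scope are excluded with a warning", {
  df <- rbind(make_study_df(c("A", "B"), 1:2, "SBP",
                            gen = function(id, s, v) 100 + 1:7),
              series_rows("C", 1, "SBP", 100 + 1:7))  # C misses session 2
  ds <- suppressWarnings(study_dataset(df))
  expect_warning(m <- participant_means(ds, "intersession", "SBP"),
                 "excluded")
  expect_setequal(m$participant_id, c("A", "B"))
})

test_that("device mean comparison handles identical and shifted devices", {
  m <- participant_means(make_const_study(), "session1", "SBP")
  r <- device_mean_comparison(m)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # forced separation: constant +10 with tiny noise
  set.seed(8)
  df <- make_study_df(sprintf("P%02d", 1:30), 1, "SBP",
                      gen = function(id, s, v) {
                        base <- rnorm(1, 120, 1)
                        round(base + ifelse(1:7 %% 2 == 0, 10, 0) +
                                rnorm(7, 0, 0.2), 2)
                      })
  rs <- device_mean_comparison(participant_means(study_dataset(df), "session1", "SBP"))
  expect_lt(rs$p, 0.001)
  rp <- device_mean_comparison(participant_means(study_dataset(df), "session1", "SBP"),
                               mode = "paired")
  expect_lt(rp$p, 0.001)
  expect_equal(rp$mode, "paired")
})

test_that("independent t type-I error is calibrated at the 5% level", {
  set.seed(14)
  n_rep <- 10000L; n <- 100L
  # vectorised two-sample Welch t under a true null
  x <- matrix(rnorm(n_rep * n), n_rep)
  y <- matrix(rnorm(n_rep * n), n_rep)
  se <- sqrt(apply(x, 1, var) / n + apply(y, 1, var) / n)
  tstat <- (rowMeans(y) - rowMeans(x)) / se
  rej <- mean(abs(tstat) > qnorm(0.975))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("device correlation matches the summation-formula oracle", {
  x <- c(118, 125, 131, 140, 122)
  y <- c(120, 126, 130, 143, 121)
  m <- data.frame(participant_id = letters[1:5], variable = "SBP",
                  criterion_mean = x, test_mean = y)
  r <- device_correlation(m)
  expect_equal(r$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(r$p, cor.test(x, y)$p.value)
  # perfect and affine-perfect correlation
  m$test_mean <- m$criterion_mean
  expect_equal(device_correlation(m)$r, 1)
  m$test_mean <- 3 + 1.5 * m$criterion_mean
  expect_equal(device_correlation(m)$r, 1)
  # degenerate: no variance on one axis
  m$test_mean <- 100
  expect_true(device_correlation(m)$degenerate)
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(19)
  x <- rnorm(40, 120, 12); y <- x + rnorm(40, 0, 4)
  m <- data.frame(participant_id = seq_along(x), variable = "SBP",
                  criterion_mean = x, test_mean = y)
  r0 <- device_correlation(m)$r
  m$criterion_mean <- 2 + 0.5 * x
  m$test_mean <- -10 + 3 * y
  expect_equal(device_correlation(m)$r, r0, tolerance = 1e-12)
})

test_that("Bland-Altman recovers closed-form limits under normal differences", {
  m <- participant_means(make_const_study(), "session1", "SBP")
  ba0 <- bland_altman(m)$SBP
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  set.seed(23)
  n <- 10000
  crit <- rnorm(n, 120, 10)
  diffs <- rnorm(n, 1.5, 2)
  mm <- data.frame(participant_id = seq_len(n), variable = "SBP",
                   criterion_mean = crit, test_mean = crit + diffs)
  ba <- bland_altman(mm)$SBP
  expect_equal(ba$bias, 1.5, tolerance = 0.1)
  expect_equal(ba$loa_low, -2.42, tolerance = 0.15)
  expect_equal(ba$loa_high, 5.42, tolerance = 0.15)
  # about 95% of points inside the limits
  inside <- mean(diffs >= ba$loa_low & diffs <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
  expect_equal(nrow(ba$points), n)
})

test_that("bias is antisymmetric in the device roles", {
  set.seed(29)
  ds <- generate_study(simulation_config(
    n_subjects = 30, dropout = 0,
    variables = list(SBP = list(test_bias = 3))), seed = 29)
  m <- participant_means(ds, "session1", "SBP")
  ba <- bland_altman(m)$SBP
  swapped <- transform(m, criterion_mean = test_mean,
                       test_mean = criterion_mean)
  ba_swapped <- bland_altman(swapped)$SBP
  expect_equal(ba_swapped$bias, -ba$bias)
  expect_equal(ba_swapped$loa_low, -ba$loa_high)
  expect_equal(ba_swapped$loa_high, -ba$loa_low)
})

test_that("zero-bias generator yields small bias at n=100 across seeds", {
  cfg <- simulation_config(n_subjects = 100, dropout = 0)
  ok <- vapply(1:20, function(s) {
    ds <- generate_study(cfg, seed = 3000 + s)
    m <- participant_means(ds, "intersession", "SBP")
    abs(bland_altman(m)$SBP$bias) < 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
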