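test_that("amplitude_series matches a hand-computed toy oracle", {
  # 8-sample window, smoothing disabled (width 1) so arithmetic is exact
  w <- matrix(0, 9, 8, dimnames = list(CHANNELS, NULL))
  w["acc_x", ] <- c(1, 1, 2, 2, 0, 0, 1, 1)
  w["gyro_y", ] <- c(0, -1, 0, 2, 0, 0, 0, 0)
  w["eog_h", ] <- c(0.5, -0.5, 0.5, -0.5, 0, 0, 0, 0)
  out <- amplitude_series(w, smooth_width = 1)
  # |diff acc_x with leading 0| + |gyro_y| + |eog_h|
  exp_acc <- abs(c(0, 0, 1, 0, -2, 0, 1, 0))
  exp_out <- exp_acc + abs(w["gyro_y", ]) + abs(w["eog_h", ])
  expect_equal(out, exp_out, tolerance = 1e-12)
})

test_that("excluded channels contribute nothing", {
  w <- matrix(0, 9, 32, dimnames = list(CHANNELS, NULL))
  w["acc_z", ] <- rnorm(32)
  w["gyro_z", ] <- rnorm(32)
  w["eog_l", ] <- rnorm(32)
  expect_equal(amplitude_series(w, smooth_width = 1), rep(0, 32))
  # constant ACC X contributes 0 (difference of constants)
  w["acc_x", ] <- 5
  expect_equal(amplitude_series(w, smooth_width = 1), rep(0, 32))
})

test_that("autocorrelation matches the closed-form expectations", {
  # lag-0 coefficient is 1
  set.seed(2)
  x <- rnorm(512)
  ac <- autocorrelation(x, 150)
  expect_equal(ac$acf[1], 1)
  # matches the direct formula
  k <- 7
  xm <- mean(x)
  r_brute <- sum((x[1:(512 - k)] - xm) * (x[(k + 1):512] - xm)) /
    sum((x - xm)^2)
  expect_equal(ac$acf[k + 1], r_brute, tolerance = 1e-12)
  # sine of period 100: local maximum at lag 100 +/- 2
  s <- sin(2 * pi * (0:511) / 100)
  acs <- autocorrelation(s, 150)$acf
  pk <- peak_lag(acs, range = c(50, 150))
  expect_lte(abs(pk - 100), 2)
  # white noise: small coefficients at positive lags
  expect_true(all(abs(ac$acf[-1]) < 0.15))
  # constant series flagged
  expect_true(autocorrelation(rep(1, 200), 50)$undefined)
  expect_error(autocorrelation(rnorm(100), 150), "length")
})

test_that("peak_lag finds strict local maxima, plateaus, and absences", {
  co <- rep(0, 151)
  co[91] <- 0.5; co[90] <- 0.3; co[92] <- 0.3
  expect_equal(peak_lag(co), 90)  # lags are 0-based
  # monotonically decreasing -> absent
  expect_true(is.na(peak_lag(seq(1, 0, length.out = 151))))
  # plateau resolves to its smallest lag
  co2 <- c(seq(0, 1, length.out = 50), rep(1, 5),
           seq(1, 0, length.out = 96))
  expect_equal(peak_lag(co2, range = c(10, 150)), 49)
  # largest of several local maxima wins
  co3 <- rep(0, 151); co3[31] <- 0.2; co3[101] <- 0.6
  expect_equal(peak_lag(co3), 100)
  expect_error(peak_lag(rep(0, 100), range = c(10, 150)), "range")
})

test_that("trend_test reports monotone association and inconclusive cases", {
  prof <- structure(list(levels = c(-1, 0, 1, 2),
                         peak_lag = c(120, 100, 80, 60)),
                    class = "autocorr_profile")
  expect_equal(trend_test(prof)$rho, -1)
  prof$peak_lag <- c(60, 80, 100, 120)
  expect_equal(trend_test(prof)$rho, 1)
  prof$peak_lag <- c(100, NA, NA, 90)
  tt <- trend_test(prof)
  expect_true(tt$inconclusive)
  expect_equal(tt$n_absent, 2)
  # constant peak lags: rho undefined, flagged
  prof$peak_lag <- c(90, 90, 90, 90)
  expect_true(trend_test(prof)$inconclusive)
})

test_that("sweep_generate enumerates the level x identity x repetition grid", {
  model <- init_model(tiny_arch(), roster_size = 2, seed = 6)
  sw <- sweep_generate(model, sweep_config(levels = c(-1, 0, 1),
                                           n_per_level = 4, seed = 2))
  expect_equal(dim(sw$windows)[3], 3 * 2 * 4)
  expect_equal(nrow(sw$tags), 24)
  expect_equal(sort(unique(sw$tags$level)), c(-1, 0, 1))
  expect_equal(as.vector(table(sw$tags$level)), rep(8, 3))
  # deterministic given seed
  sw2 <- sweep_generate(model, sweep_config(levels = c(-1, 0, 1),
                                            n_per_level = 4, seed = 2))
  expect_identical(sw$windows, sw2$windows)
  # single repetition, single level -> roster-sized output
  sw3 <- sweep_generate(model, sweep_config(levels = 0, n_per_level = 1,
                                            seed = 1))
  expect_equal(dim(sw3$windows)[3], 2)
})

test_that("profile_by_level averages per-window autocorrelations", {
  set.seed(9)
  w1 <- array(rnorm(9 * 512), c(9, 512))
  w2 <- array(rnorm(9 * 512), c(9, 512))
  windows <- array(c(w1, w2, w2), c(9, 512, 3))
  tags <- data.frame(level = c(-1, 1, 1))
  prof <- profile_by_level(windows, tags, max_lag = 60)
  expect_s3_class(prof, "autocorr_profile")
  # lag-0 mean coefficient is exactly 1 for every level
  expect_equal(unname(prof$mean_acf[, 1]), c(1, 1))
  # single-window level equals that window's own autocorrelation
  a1 <- autocorrelation(amplitude_series(w1), 60)$acf
  expect_equal(unname(prof$mean_acf[1, ]), a1, tolerance = 1e-12)
  # two identical windows average to either one
  a2 <- autocorrelation(amplitude_series(w2), 60)$acf
  expect_equal(unname(prof$mean_acf[2, ]), a2, tolerance = 1e-12)
})

test_that("sweep_config validates levels", {
  expect_error(sweep_config(levels = c(1, 1, 2)), "increasing")
  expect_error(sweep_config(n_per_level = 0), "n_per_level")
  expect_equal(length(sweep_config()$levels), 11)
})
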