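test_that("a constant analyser offset is removed exactly", {
  tr <- make_trace(hours = 3, feo2 = 0.2085,
                   drift_fun = function(s) rep(0.002, length(s)))
  cb <- correct_baseline(tr)
  expect_equal(cb$o2_fraction, rep(0.2085, nrow(cb)), tolerance = 1e-14)
  expect_false(attr(cb, "calibration_warning"))
})

test_that("linear drift is interpolated between zero-window midpoints", {
  # drift holds 0 through the first zero window, rises linearly to 0.0010 by
  # the second window's midpoint, and holds there; near the midpoint of the
  # two window midpoints about 0.0005 must be removed, and the corrected
  # animal samples must equal the drift-free truth exactly
  mid1 <- 145   # midpoint (s) of samples 0..290 in the first window
  mid2 <- 3600 + 145
  slope <- 0.0010 / (mid2 - mid1)
  drift_fun <- function(s) {
    d <- pmin(pmax((s - mid1) * slope, 0), 0.0010)
    d[s < 300] <- 0            # plateau across the first zero window
    d[s >= 3600] <- 0.0010     # plateau across the second
    d
  }
  tr <- make_trace(hours = 2, feo2 = 0.2085, drift_fun = drift_fun)
  cb <- correct_baseline(tr)
  halfway <- tr$timestamp[1] + (mid1 + mid2) / 2
  i <- which.min(abs(as.numeric(cb$timestamp) - as.numeric(halfway)))
  sec_i <- as.numeric(cb$timestamp[i]) - as.numeric(tr$timestamp[1])
  expect_equal(cb$drift[i], (sec_i - mid1) * slope, tolerance = 1e-12)
  expect_equal(cb$drift[i], 0.0005, tolerance = 5e-3)
  expect_equal(max(abs(cb$o2_fraction - 0.2085)), 0, tolerance = 1e-12)
})

test_that("baseline correction is exact for generator piecewise-linear drift", {
  cfg <- quiet_sim_config(seed = 6, drift_rate = 5e-4)
  p <- true_model_params()
  co <- simulate_cohort(cfg, p)
  denom <- 1 - cfg$fio2_ambient * (1 - p$rq)
  for (key in names(co$traces)) {
    tr <- co$traces[[key]]
    truth <- co$truth$samples[[key]]
    cb <- correct_baseline(tr)
    feo2_true <- cfg$fio2_ambient -
      truth$vo2_true_ml_h[!tr$is_zero_check] * denom / cfg$flow_rate
    expect_lt(max(abs(cb$o2_fraction - feo2_true)), 1e-12)
  }
})

test_that("traces without zero checks are rejected, off reference warns", {
  tr <- make_trace(hours = 2)
  tr$is_zero_check <- FALSE
  expect_error(correct_baseline(tr), "no zero-check")
  tr2 <- make_trace(hours = 2, drift_fun = function(s) rep(0.01, length(s)))
  expect_warning(correct_baseline(tr2), "calibration")
})

test_that("STP correction matches the ideal-gas scaling", {
  expect_equal(stp_correct(1000, 0, 101.325), 1000)
  expect_equal(stp_correct(1000, 20, 101.325), 1000 * 273.15 / 293.15)
  expect_equal(stp_correct(1000, 20, 101.325), 931.77, tolerance = 1e-5)
  expect_equal(stp_correct(1000, 0, 101.325 / 2), 500)
  expect_error(stp_correct(1000, -300, 101.325))
})

test_that("compute_vo2 evaluates the open-flow equation", {
  calib <- calibration_info()
  tr <- data.frame(timestamp = Sys.time(), o2_fraction = 0.2085,
                   is_zero_check = FALSE)
  v <- compute_vo2(tr, calib)
  expect_equal(v$vo2_ml_h, 80000 * 0.001 / (1 - 0.2095 * 0.15))
  expect_equal(v$vo2_ml_h, 82.60, tolerance = 1e-4)
  # no depletion, no consumption
  tr$o2_fraction <- 0.2095
  expect_equal(compute_vo2(tr, calib)$vo2_ml_h, 0)
  # bad calibration is caught
  bad <- structure(list(fio2_reference = 5, rq = 0.7, flow_rate_stp = 8e4,
                        energy_equivalent = 20.37, flow_at_stp = TRUE),
                   class = "calibration_info")
  expect_error(compute_vo2(tr, bad), "denominator")
})

test_that("VO2 is linear in the O2-fraction depletion", {
  calib <- calibration_info()
  delta <- runif(20, 0, 0.003)
  tr <- data.frame(timestamp = Sys.time() + seq_along(delta),
                   o2_fraction = 0.2095 - delta, is_zero_check = FALSE)
  v <- compute_vo2(tr, calib)$vo2_ml_h
  slope <- v / delta
  expect_lt((max(slope) - min(slope)) / mean(slope), 1e-8)
})

test_that("energy conversion is an exact fixed scalar multiple", {
  expect_equal(vo2_to_kj(149.84), 3.05, tolerance = 5e-3)
  expect_equal(vo2_to_kj(149.84) * 1000 / 20.37, 149.84)  # round trip
  calib <- calibration_info()
  tr <- data.frame(timestamp = Sys.time(), o2_fraction = 0.2080,
                   is_zero_check = FALSE)
  v <- compute_vo2(tr, calib)
  expect_equal(v$energy_j_h, v$vo2_ml_h * 20.37)
})

test_that("negative VO2 within tolerance is clipped, beyond is flagged", {
  calib <- calibration_info()
  tr <- data.frame(timestamp = Sys.time() + 0:1,
                   o2_fraction = c(0.20951, 0.2150),  # small vs gross excess
                   is_zero_check = FALSE)
  v <- compute_vo2(tr, calib, noise_sd_vo2 = 1)
  expect_equal(v$vo2_ml_h[1], 0)
  expect_false(v$flag_negative[1])
  expect_true(v$flag_negative[2])
  expect_lt(v$vo2_ml_h[2], 0)
})

test_that("an externally supplied occupancy mask overrides detection", {
  vo2 <- data.frame(timestamp = Sys.time() + seq(0, 3600, 10),
                    vo2_ml_h = 100)
  mask <- rep(c(TRUE, FALSE), length.out = nrow(vo2))
  expect_identical(detect_absence(vo2, override_mask = mask), mask)
})

test_that("constant positive VO2 yields an all-present mask", {
  t0 <- as.POSIXct("2018-05-01 14:00:00", tz = "UTC")
  vo2 <- data.frame(timestamp = t0 + seq(0, 24 * 3600 - 10, 10),
                    vo2_ml_h = 150)
  expect_true(all(detect_absence(vo2)))
})

test_that("a two-hour absence bout is detected with >=95% overlap", {
  set.seed(42)
  t0 <- as.POSIXct("2018-05-01 14:00:00", tz = "UTC")
  sec <- seq(0, 24 * 3600 - 10, 10)
  vo2_val <- 150 + rnorm(length(sec), 0, 5)
  true_absent <- sec >= 6 * 3600 & sec < 8 * 3600
  vo2_val[true_absent] <- abs(rnorm(sum(true_absent), 0, 1))
  vo2 <- data.frame(timestamp = t0 + sec, vo2_ml_h = vo2_val)
  mask <- detect_absence(vo2, threshold_fraction = 0.25, min_bout_min = 30)
  overlap <- sum(!mask & true_absent) / sum(true_absent)
  expect_gte(overlap, 0.95)
  # and detection does not eat into clearly-occupied time
  expect_lt(sum(!mask & !true_absent) / sum(!true_absent), 0.05)
})

test_that("an all-absent day is flagged empty", {
  vo2 <- data.frame(timestamp = Sys.time() + seq(0, 7200, 10), vo2_ml_h = 0)
  mask <- detect_absence(vo2)
  expect_true(isTRUE(attr(mask, "empty_day")) || all(!mask))
})
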