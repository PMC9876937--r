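ts10 <- function(date = "2018-05-01", h0 = 0, hours = 1, tz = "Europe/Berlin") {
  t0 <- as.POSIXct(paste(date, sprintf("%02d:00:00", h0)), tz = tz)
  t0 + seq(0, hours * 3600 - 600, by = 600)
}

test_that("nest-temperature outliers are replaced by the other boxes' median", {
  tt <- ts10()
  mk <- function(tn) data.frame(timestamp = tt,
                                t_nest_c = rep(tn, length(tt)),
                                t_a_c = 15.0)
  env <- list(a = mk(18.6), b = mk(15.4), c = mk(15.2), d = mk(15.6))
  out <- clean_tnest(env)
  # 18.6 - 15.0 = 3.6 > 3: replaced by median(15.4, 15.2, 15.6) = 15.4
  expect_true(all(out$a$t_nest_c == 15.4))
  expect_true(all(out$a$t_nest_replaced))
  # 17.9 - 15.0 = 2.9 <= 3: kept
  env2 <- list(a = mk(17.9), b = mk(15.4))
  out2 <- clean_tnest(env2)
  expect_true(all(out2$a$t_nest_c == 17.9))
  expect_false(any(out2$a$t_nest_replaced))
})

test_that("simultaneously outlying boxes are dropped with a warning", {
  tt <- ts10()
  mk <- function(tn) data.frame(timestamp = tt, t_nest_c = tn, t_a_c = 15.0)
  env <- list(a = mk(19.5), b = mk(19.9))
  expect_warning(expect_warning(out <- clean_tnest(env), "no concurrent box"),
                 "no concurrent box")
  expect_true(all(is.na(out$a$t_nest_c)))
  expect_true(all(is.na(out$b$t_nest_c)))
})

test_that("lowest-30% filter keeps the ceiling(0.3 n) smallest values", {
  expect_equal(lowest30_filter(10:1), c(1, 2, 3))
  expect_length(lowest30_filter(rnorm(7)), 3)   # ceiling(2.1)
  expect_equal(mean(lowest30_filter(rep(5, 9))), 5)
  expect_length(lowest30_filter(1), 1)          # never empty
  # ties at the cutoff break by earlier timestamp: k = 2 of 4 kept
  kept <- lowest30_filter(c(2, 1, 2, 2), timestamps = c(4, 3, 1, 2))
  expect_equal(sort(kept), c(1, 2))
})

test_that("body mass interpolates linearly across the housing period", {
  d0 <- as.Date("2018-05-01")
  expect_equal(interpolate_mass(334.2, 343.8, d0, d0 + 14, d0 + 7), 339.0)
  expect_equal(interpolate_mass(334.2, 343.8, d0, d0 + 14, d0), 334.2)
  expect_equal(interpolate_mass(400, 400, d0, d0 + 10, d0 + 3), 400)
  expect_error(interpolate_mass(334.2, 343.8, d0, d0 + 14, d0 + 20),
               "outside")
})

test_that("burst contamination never lowers the retained-subset mean", {
  set.seed(11)
  for (i in 1:50) {
    v <- rlnorm(sample(5:80, 1), log(150), 0.1)
    burst <- v
    idx <- sample(length(v), sample(length(v), 1))
    burst[idx] <- burst[idx] * runif(length(idx), 2, 4)
    expect_gte(mean(lowest30_filter(burst)), mean(lowest30_filter(v)) - 1e-12)
  }
})

# a hand-built extraction scenario: two clock hours, the second fully absent
test_that("hourly records honour absence, temperature range and minimum n", {
  tz <- "Europe/Berlin"
  t0 <- as.POSIXct("2018-05-01 00:00:00", tz = tz)
  sec <- seq(0, 3 * 3600 - 10, 10)
  vo2 <- list("sq01_2018-05-01" = data.frame(
    timestamp = t0 + sec,
    vo2_ml_h = 150,
    flag_negative = FALSE
  ))
  mask <- rep(TRUE, length(sec))
  mask[sec >= 3600 & sec < 7200] <- FALSE        # hour 1 fully absent
  masks <- list("sq01_2018-05-01" = mask)
  et <- t0 + seq(0, 3 * 3600 - 600, 600)
  env <- list(sq01 = data.frame(timestamp = et,
                                t_nest_c = c(rep(15.2, 6), rep(15.2, 6),
                                             rep(29.6, 6)),
                                t_a_c = 15.0, t_nest_replaced = FALSE))
  md <- data.frame(id = "sq01", habitat = "forest", run = 1,
                   mass_start_g = 370, mass_end_g = 380,
                   date_in = as.Date("2018-04-25"),
                   date_out = as.Date("2018-05-09"))
  ex <- extract_hourly_rmr(vo2, masks, env, md, hamburg$lat, hamburg$lon)
  # hour 0 survives; hour 1 absent; hour 2 dropped by the 8-29 range rule
  expect_equal(nrow(ex$records), 1)
  expect_equal(ex$records$hour, 0)
  expect_equal(ex$records$t_nest_int, 15)
  expect_equal(ex$records$diel, "night")
  expect_equal(ex$audit$hours$absence, 1)
  expect_equal(ex$audit$hours$t_out_of_range, 1)
  # mass on 2018-05-01 is 6/14 through housing
  mass <- 370 + 6 / 14 * 10
  expect_equal(ex$records$rmr_mass_specific, 150 / mass)
  expect_equal(ex$records$housing_half, "first")
})

test_that("noise-free extraction reproduces the truth-ledger resting rate", {
  cfg <- quiet_sim_config(seed = 12, spikes = 0)
  p <- true_model_params()
  co <- simulate_cohort(cfg, p)
  calib <- calibration_info(fio2_reference = cfg$fio2_ambient,
                            flow_rate_stp = cfg$flow_rate, rq = p$rq)
  vo2 <- list(); masks <- list()
  for (key in names(co$traces)) {
    tr <- co$traces[[key]]
    v <- compute_vo2(correct_baseline(tr), calib)
    vo2[[key]] <- v
    masks[[key]] <- co$truth$samples[[key]]$occupied[!tr$is_zero_check]
  }
  env <- clean_tnest(co$env)
  ex <- extract_hourly_rmr(vo2, masks, env, co$metadata,
                           cfg$lat, cfg$lon)
  expect_gt(nrow(ex$records), 10)
  # oracle: recompute each record's resting rate from the truth ledger with
  # a plain sort-and-average of the lowest 30% of true VO2 in that hour
  tz <- cfg$tz
  for (r in sample(nrow(ex$records), 10)) {
    rec <- ex$records[r, ]
    key <- paste0(rec$id, "_", format(rec$day))
    truth <- co$truth$samples[[key]]
    tr <- co$traces[[key]]
    keep <- !tr$is_zero_check
    tt <- truth$timestamp[keep]
    hh <- as.integer(format(tt, "%H"))
    dd <- as.Date(tt, tz = tz)
    dl <- classify_diel(tt, cfg$lat, cfg$lon)
    # the trace runs 14:00 to 14:00: hours < 14 fall on the next calendar day
    sel <- hh == rec$hour & dd == (rec$day + (rec$hour < 14)) &
      truth$occupied[keep] & dl != "excluded"
    vv <- sort(truth$vo2_true_ml_h[keep][sel])
    oracle <- mean(vv[seq_len(ceiling(0.3 * length(vv)))])
    expect_equal(rec$rmr_total, oracle, tolerance = 1e-6)
  }
})
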