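test_that("rolling medians match an exhaustive window scan", {
  # constant series
  rm0 <- rolling_median(seq(0, 100, by = 2), rep(10, 51))
  expect_true(all(rm0$med == 10))

  # a single outlier cannot move a 15-sample window median
  t <- seq(2, 30, by = 2)
  v <- rep(20, 15)
  v[8] <- 500
  expect_equal(rolling_median(t, v, window = 30)$med[15], 20)

  # random irregular series vs brute force
  for (s in 1:5) {
    set.seed(s)
    t <- cumsum(runif(120, 0.2, 4))
    v <- rnorm(120)
    expect_equal(rolling_median(t, v, window = 30)$med,
                 brute_rolling_median(t, v, window = 30))
  }
  expect_error(rolling_median(numeric(0), numeric(0)), "empty")
})

test_that("peak VO2 scans the final minute of ramp and ignores recovery", {
  ses <- piecewise_session(vat = 13, s1 = 0.9, s2 = 1.2)
  pk <- peak_vo2(ses)
  ramp_end <- max(ses$time_s)
  expect_equal(pk, brute_peak_final(ses$time_s[ses$phase == "ramp"],
                                    ses$vo2[ses$phase == "ramp"],
                                    ramp_end))
  # appending recovery changes nothing
  rec <- ses[ses$phase == "ramp", ]
  rec$time_s <- rec$time_s + max(ses$time_s)
  rec$vo2 <- rev(rec$vo2) + 5  # higher values, but in recovery
  rec$phase <- "recovery"
  expect_equal(peak_vo2(rbind(ses, rec)), pk)
  expect_equal(peak_rer(rbind(ses, rec)), peak_rer(ses))
  expect_equal(ve_vco2_nadir(rbind(ses, rec), weight_kg = 75),
               ve_vco2_nadir(ses, weight_kg = 75))

  # too-short ramp is refused with a reason
  short <- ses[ses$phase == "unloaded" | ses$time_s <= 100, ]
  expect_error(peak_vo2(short), "ramp phase spans")
})

test_that("percent-predicted peak VO2 follows the reference equations", {
  # ratio identity and linearity
  pred_f <- (60 + 43) * (22.78 - 0.17 * 40) / 60  # mL/kg/min, by hand
  expect_equal(percent_predicted_peak_vo2(pred_f, 40, "female",
                                          weight_kg = 60), 100)
  expect_equal(percent_predicted_peak_vo2(2 * pred_f, 40, "female",
                                          weight_kg = 60), 200)
  # frozen hand computation: female, 40 y, 60 kg, measured 20 mL/kg/min
  # predicted = (60+43)*(22.78-6.8) = 1645.94 mL/min = 27.43233 mL/kg/min
  expect_equal(percent_predicted_peak_vo2(20, 40, "female", weight_kg = 60),
               20 / 27.432333333 * 100, tolerance = 1e-9)
  # male arm: predicted per kg = 50.72 - 0.372*age, independent of weight
  expect_equal(percent_predicted_peak_vo2(50.72 - 0.372 * 50, 50, "male",
                                          weight_kg = 80), 100)
  expect_error(percent_predicted_peak_vo2(20, 140, "male", weight_kg = 80),
               "nonpositive predicted")
})

test_that("V-slope detection finds planted breakpoints and flags lines", {
  grid <- piecewise_grid()
  vat <- grid[120]
  res <- detect_vat(piecewise_session(vat = vat, s1 = 0.9, s2 = 1.2))
  expect_lt(abs(res$vat_vo2 - vat), 2 * max(diff(grid)))
  expect_false(res$low_confidence)
  expect_lt(res$slopes["lower"], 1)
  expect_gt(res$slopes["upper"], 1)

  # straight line: no breakpoint evidence
  line <- detect_vat(piecewise_session(vat = grid[120], s1 = 1.05,
                                       s2 = 1.05))
  expect_true(line$low_confidence)

  # concave data (upper slope smaller): no admissible breakpoint
  conc <- detect_vat(piecewise_session(vat = grid[120], s1 = 1.2, s2 = 0.8))
  expect_true(is.na(conc$vat_vo2))
  expect_true(conc$low_confidence)

  expect_error(detect_vat(piecewise_session(vat = 13, s1 = 0.9, s2 = 1.2,
                                            n_ramp = 10)), "fewer than 20")
})

test_that("VE/VCO2 nadir is the lowest smoothed ratio during exercise", {
  # constant ratio
  t <- seq(0, 400, by = 2)
  n <- length(t)
  ser <- tibble::tibble(time_s = t, vo2 = rep(20, n), vco2 = rep(20, n),
                        ve = 27 * 20 * 75 / 1000, hr = 120, workload = 50,
                        phase = rep(c("unloaded", "ramp"), c(30, n - 30)))
  expect_equal(ve_vco2_nadir(ser, weight_kg = 75), 27)

  # a dip narrower than half a window is smoothed away
  ser2 <- ser
  dip <- 100:102
  ser2$ve[dip] <- ser2$ve[dip] * 0.5
  expect_gt(ve_vco2_nadir(ser2, weight_kg = 75), 27 * 0.5)

  # brute-force agreement on a random session
  rs <- random_session(n = 250, seed = 7)
  ex <- rs[rs$phase %in% c("unloaded", "ramp"), ]
  expect_equal(ve_vco2_nadir(rs, weight_kg = 80),
               min(brute_rolling_median(ex$time_s,
                                        ex$ve / (ex$vco2 * 80 / 1000))))
  rs$vco2[5] <- 0
  expect_error(ve_vco2_nadir(rs, weight_kg = 80), "nonpositive VCO2")
})

test_that("percent-predicted maximum HR uses the age-based formula", {
  t <- seq(0, 400, by = 2)
  n <- length(t)
  ser <- tibble::tibble(time_s = t, vo2 = 20, vco2 = 20, ve = 40,
                        hr = rep(180, n), workload = 50,
                        phase = rep(c("unloaded", "ramp"), c(30, n - 30)))
  # age 40: denominator 208 - 28 = 180 -> exactly 100%
  expect_equal(percent_predicted_max_hr(ser, age = 40), 100)
  # age 0 boundary: denominator 208, finite result
  expect_equal(percent_predicted_max_hr(ser, age = 0), 100 * 180 / 208)
})

test_that("SBP/workload slope is the printed formula, signed", {
  expect_equal(sbp_w_slope(120, 190, 200)$slope, 0.35)
  expect_equal(sbp_w_slope(150, 150, 100)$slope, 0)
  neg <- sbp_w_slope(150, 130, 100)
  expect_equal(neg$slope, -0.2)
  expect_true(neg$hypotensive_flag)
  expect_error(sbp_w_slope(120, 190, 0), "positive")
})

test_that("peak RER marks inadequate effort below the inclusive 1.05 cut", {
  t <- seq(0, 400, by = 2)
  n <- length(t)
  ser <- tibble::tibble(time_s = t, vo2 = rep(20, n), vco2 = rep(20, n),
                        ve = 40, hr = 150, workload = 50,
                        phase = rep(c("unloaded", "ramp"), c(30, n - 30)))
  expect_equal(peak_rer(ser), 1)

  # 1.04 is excluded, exactly 1.05 passes (cut is inclusive)
  mk <- function(rer) {
    s <- ser
    s$vco2 <- s$vo2 * rer
    process_cpet_session(s, age = 50, sex = "male", height_cm = 178,
                         weight_kg = 80, rest_sbp = 120, peak_sbp = 180,
                         peak_workload = 150)
  }
  expect_false(mk(1.04)$adequate_effort)
  expect_true(mk(1.05)$adequate_effort)

  # brute-force agreement on a random session
  rs <- random_session(n = 220, seed = 11)
  r <- rs[rs$phase == "ramp", ]
  expect_equal(peak_rer(rs),
               brute_peak_final(r$time_s, r$vco2 / r$vo2, max(r$time_s)))
})
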