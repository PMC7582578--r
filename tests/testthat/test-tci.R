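# Weather-side heat assessment: wet-bulb approximation, index polynomial,
# correction weights, stage classification.

test_that("wet-bulb approximation matches its closed form and the psychrometric solution", {
  # independent inline evaluation of the same closed form
  closed <- function(ta, rh)
    ta * atan(0.151977 * (rh + 8.313659)^0.5) + atan(ta + rh) -
      atan(rh - 1.676331) + 0.00391838 * rh^(3 / 2) * atan(0.023101 * rh) -
      4.686035
  for (ta in seq(5, 45, by = 5)) for (rh in c(5, 20, 50, 80, 99))
    expect_lt(abs(wet_bulb_temperature(ta, rh) - closed(ta, rh)), 1e-9)

  expect_equal(wet_bulb_temperature(20, 50), 13.7, tolerance = 0.4 / 13.7)
  expect_lt(abs(wet_bulb_temperature(30, 100) - 30), 1.0)

  # mid-range psychrometric reference points (iterative oracle)
  pts <- rbind(c(20, 50), c(30, 70), c(35, 40), c(15, 80), c(25, 60),
               c(10, 90))
  for (i in seq_len(nrow(pts)))
    expect_lt(abs(wet_bulb_temperature(pts[i, 1], pts[i, 2]) -
                    oracle_wet_bulb(pts[i, 1], pts[i, 2])), 0.5)
})

test_that("wet-bulb temperature is below dry-bulb and increasing in humidity", {
  for (ta in c(5, 15, 25, 35, 45)) {
    tw <- wet_bulb_temperature(ta, seq(5, 99, by = 2))
    expect_true(all(diff(tw) > 0))
    expect_true(all(tw <= ta + 0.5))
  }
  expect_lt(wet_bulb_temperature(30, 20), wet_bulb_temperature(30, 80))
  expect_error(wet_bulb_temperature(20, 120), "rh")
  expect_error(wet_bulb_temperature(20, NA), "finite")
  expect_warning(wet_bulb_temperature(55, 50), "validity")
})

test_that("raw index is the exact printed polynomial", {
  expect_identical(tci_raw(0, 0), -0.24418)
  # frozen hand-substitutions of the polynomial
  expect_equal(tci_raw(25, 33), 29.570913, tolerance = 1e-12)
  expect_equal(tci_raw(10, 10), 9.91039, tolerance = 1e-12)
  expect_error(tci_raw(Inf, 0), "finite")
})

test_that("time-of-day weights reproduce the published table with nearest-slot mapping", {
  expect_identical(time_of_day_weight(12, "construction_site"), 1.6)
  expect_identical(time_of_day_weight(3, "construction_site"), 1.2)
  expect_identical(time_of_day_weight(18, "children"), -0.9)
  expect_identical(time_of_day_weight(21, "heat_vulnerable_area"), 5.0)
  # nearest slot: hour 13 -> slot 12, hour 14 -> slot 15, hour 0/1 -> slot 24
  expect_identical(time_of_day_weight(13, "construction_site"), 1.6)
  expect_identical(time_of_day_weight(14, "construction_site"), 1.2)
  expect_identical(time_of_day_weight(0, "construction_site"), 1.2)
  expect_identical(time_of_day_weight(1, "greenhouse"), 0.5)
  expect_error(time_of_day_weight(25, "road"), "hour")
  expect_error(time_of_day_weight(12, "moon_base"))
  expect_identical(ncol(tci_weight_table()), 8L)
  expect_identical(length(site_environments()), 7L)
})

test_that("stage classification partitions the index with half-open bounds", {
  got <- classify_stage(c(20, 23, 26, 29, 31))
  expect_identical(as.character(got$stage),
                   c("Attention", "Concern", "Caution", "Warning", "Severe"))
  expect_match(got$action[5], "stop working immediately")
  expect_identical(got$action[1], "")
  # boundaries closed on the upper end
  expect_identical(as.character(classify_stage(30)$stage), "Warning")
  expect_identical(as.character(classify_stage(30.0001)$stage), "Severe")
  expect_identical(as.character(classify_stage(21)$stage), "Attention")
  # total and monotone over a fine grid
  grid <- seq(-5, 45, by = 0.01)
  st <- classify_stage(grid)$stage
  expect_false(anyNA(st))
  expect_true(all(diff(as.integer(st)) >= 0))
})

test_that("full assessment composes wet-bulb, index, additive weight and stage", {
  w <- data.frame(
    timestamp = as.POSIXct(c("2020-08-01 12:00", "2020-08-01 03:00"),
                           tz = "UTC"),
    ta_c = c(33, 26), rh_pct = c(60, 80))
  a <- ohs_assess(w, "construction_site")
  expect_s3_class(a, "ohs_assessment")
  expect_equal(a$tw_c, wet_bulb_temperature(w$ta_c, w$rh_pct))
  expect_equal(a$tci_raw, tci_raw(a$tw_c, a$ta_c))
  expect_identical(a$weight, c(1.6, 1.2))
  expect_equal(a$tci, a$tci_raw + a$weight)
  expect_identical(as.character(a$stage),
                   as.character(classify_stage(a$tci)$stage))

  # zero-weight slot leaves the index unweighted (identity)
  w0 <- data.frame(timestamp = as.POSIXct("2020-08-01 03:00", tz = "UTC"),
                   ta_c = 30, rh_pct = 50)
  a0 <- ohs_assess(w0, "shipyard")   # weight 0 at slot 03
  expect_identical(a0$weight, 0)
  expect_equal(a0$tci, a0$tci_raw)

  # a raw index of 29 plus the midday construction weight crosses into
  # the work-stoppage stage
  expect_identical(as.character(classify_stage(29 + 1.6)$stage), "Severe")
})
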