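# Fuzzy risk engine: membership construction, Karvonen anchors, Mamdani
# inference, categorization.

test_that("maximum heart rate and Karvonen threshold are exact", {
  expect_identical(hr_max(30), 186)
  expect_identical(hr_max(50), 172)
  expect_error(hr_max(0), "age")
  expect_error(hr_max(90), "age")
  expect_identical(caution_threshold(186, 60, 0.5), 123)
  expect_identical(caution_threshold(186, 60, 1.0), 186)
  expect_identical(caution_threshold(172, 99, 0.25), 117.25)
  expect_error(caution_threshold(100, 120, 0.5), "below")
  expect_error(caution_threshold(186, 60, 0), "w must")
})

test_that("pi and triangular memberships satisfy their shape invariants", {
  p <- pi_mf(10, 20, 30, 40)
  expect_identical(p(c(5, 10, 40, 50)), c(0, 0, 0, 0))
  expect_identical(p(c(20, 25, 30)), c(1, 1, 1))
  expect_equal(p(15), 0.5)   # left ramp midpoint
  expect_equal(p(35), 0.5)   # right ramp midpoint
  expect_true(all(p(seq(10, 40, 0.1)) >= 0 & p(seq(10, 40, 0.1)) <= 1))
  sh <- pi_mf(-Inf, -Inf, 30, 40)
  expect_identical(sh(c(-100, 0, 30)), c(1, 1, 1))
  tr <- tri_mf(0, 5, 10.5)
  expect_identical(tr(5), 1)
  expect_identical(tr(c(-1, 0, 10.5, 12)), c(0, 0, 0, 0))
  expect_equal(tr(2.5), 0.5)
})

test_that("worker-specific fuzzy sets anchor at the published breakpoints", {
  sys <- fuzzy_risk_system(worker_profile(30))   # HRmax 186, caution 123
  mu <- evaluate_memberships(sys, list(h = 75, ct = 37, t = 2))
  expect_identical(mu$hr[["Normal"]], 1)
  expect_identical(mu$ct[["Normal"]], 1)
  expect_identical(mu$t[["Safe"]], 1)
  expect_identical(mu$w[["Medium"]], 1)

  expect_identical(evaluate_memberships(sys, list(h = 190, ct = 37, t = 0))$hr[["Danger"]], 1)
  expect_identical(evaluate_memberships(sys, list(h = 123, ct = 37, t = 0))$hr[["Caution"]], 1)
  # ramp midpoint between normal plateau (99) and caution anchor (123)
  expect_equal(evaluate_memberships(sys, list(h = 111, ct = 37, t = 0))$hr[["Normal"]], 0.5)
  expect_equal(evaluate_memberships(sys, list(h = 111, ct = 37, t = 0))$hr[["Caution"]], 0.5)
  # core-temperature anchors
  expect_identical(evaluate_memberships(sys, list(h = 75, ct = 34, t = 0))$ct[["Low"]], 1)
  expect_identical(evaluate_memberships(sys, list(h = 75, ct = 31, t = 0))$ct[["TooLow"]], 1)
  expect_identical(evaluate_memberships(sys, list(h = 75, ct = 39, t = 0))$ct[["High"]], 1)
  expect_identical(evaluate_memberships(sys, list(h = 75, ct = 41, t = 0))$ct[["TooHigh"]], 1)
  expect_equal(evaluate_memberships(sys, list(h = 75, ct = 35.5, t = 0))$ct[["Low"]], 0.5)
  # out-of-universe inputs clamp to the edge sets
  expect_identical(evaluate_memberships(sys, list(h = -50, ct = 37, t = 0))$hr[["Normal"]], 1)
  expect_identical(evaluate_memberships(sys, list(h = 75, ct = 60, t = 0))$ct[["TooHigh"]], 1)
})

test_that("every universe point is covered by some fuzzy set", {
  for (age in c(20, 35, 60)) {
    sys <- fuzzy_risk_system(worker_profile(age))
    for (v in names(sys$vars)) {
      u <- sys$vars[[v]]$universe
      xs <- seq(u[1], u[2], length.out = 500)
      cover <- sapply(xs, function(x)
        max(sapply(sys$vars[[v]]$sets, function(f) f(x))))
      expect_gte(min(cover), 0.01)
    }
  }
})

test_that("profile validation and the Karvonen clamp behave as documented", {
  expect_error(worker_profile(10), "age")
  expect_error(worker_profile(30, resting_hr = 200), "resting_hr")
  # high intensity with a low resting rate pushes the Karvonen value under
  # the 99 bpm plateau; the anchor is clamped with a warning
  expect_warning(fuzzy_risk_system(worker_profile(30, work_intensity = "high")),
                 "clamped")
  expect_identical(worker_profile(30, work_intensity = "light")$w, 0.75)
})

test_that("Mamdani inference matches the known corner cases", {
  sys <- fuzzy_risk_system(worker_profile(30))
  safe <- mamdani_infer(sys, h = 75, ct = 37, t = 2)
  expect_gte(safe$rl, 0)
  expect_lte(safe$rl, 10)
  expect_identical(as.character(safe$category), "Safe")
  expect_false(safe$alert)

  hot <- mamdani_infer(sys, h = 196, ct = 41, t = 40, w = 0.25)
  expect_gte(hot$rl, 21)
  expect_lte(hot$rl, 40)
  expect_true(as.character(hot$category) %in% c("Attention", "Danger"))
  expect_true(hot$alert)

  set.seed(21)
  for (i in 1:25) {
    r <- mamdani_infer(sys, h = runif(1, 40, 220), ct = runif(1, 30, 43),
                       t = runif(1, 0, 60))
    expect_gte(r$rl, 0)
    expect_lte(r$rl, 40)
  }
})

test_that("defuzzification agrees with the brute-force oracle", {
  sys <- fuzzy_risk_system(worker_profile(40))
  set.seed(31)
  for (i in 1:40) {
    h <- runif(1, 50, 210); ct <- runif(1, 30, 43); t <- runif(1, 0, 50)
    expect_lt(abs(mamdani_infer(sys, h, ct, t)$rl -
                    oracle_mamdani(sys, h, ct, t)), 0.05)
  }
})

test_that("risk response is monotone in each input with the others at status plateaus", {
  sys <- fuzzy_risk_system(worker_profile(30))
  hm <- sys$profile$hrmax
  for (ct0 in c(37, 39, 41)) for (t0 in c(0, 20, 40)) {
    rl <- predict(sys, data.frame(h = seq(60, hm + 30, 2), ct = ct0, t = t0))$rl
    expect_true(all(diff(rl) >= -1e-8))
  }
  for (h0 in c(75, 123, hm + 10)) for (t0 in c(0, 20, 40)) {
    rl <- predict(sys, data.frame(h = h0, ct = seq(36, 42, 0.1), t = t0))$rl
    expect_true(all(diff(rl) >= -1e-8))
  }
  for (h0 in c(75, 123, hm + 10)) for (ct0 in c(37, 39, 41)) {
    rl <- predict(sys, data.frame(h = h0, ct = ct0, t = seq(0, 45, 0.5)))$rl
    expect_true(all(diff(rl) >= -1e-8))
  }
})

test_that("older workers are assessed at equal or higher risk", {
  rls <- sapply(c(25, 35, 45, 55, 65), function(a)
    mamdani_infer(fuzzy_risk_system(worker_profile(a)), 150, 37, 10)$rl)
  expect_true(all(diff(rls) >= -1e-8))
})

test_that("risk categories follow the published ranges", {
  expect_identical(as.character(categorize_risk(5)), "Safe")
  expect_identical(as.character(categorize_risk(25)), "Attention")
  expect_identical(as.character(categorize_risk(35)), "Danger")
  expect_identical(as.character(categorize_risk(c(10, 10.5, 20.5, 30.5))),
                   c("Safe", "Concern", "Attention", "Danger"))
  expect_error(categorize_risk(41), "rl")
  expect_error(categorize_risk(-1), "rl")
})

test_that("rule base round-trips through YAML and rejects unknown sets", {
  rules <- default_rule_base()
  path <- tempfile(fileext = ".yaml")
  write_rules_yaml(rules, path)
  back <- read_rules_yaml(path)
  expect_identical(back, rules)
  sysA <- fuzzy_risk_system(worker_profile(30), rules = path)
  sysB <- fuzzy_risk_system(worker_profile(30))
  expect_identical(mamdani_infer(sysA, 140, 38.2, 12)$rl,
                   mamdani_infer(sysB, 140, 38.2, 12)$rl)
  bad <- rules
  bad[[1]]$`if`$ct <- "Tepid"
  expect_error(fuzzy_risk_system(worker_profile(30), rules = bad), "unknown set")
  unlink(path)
})

test_that("packaged rules file matches the built-in rule base", {
  path <- system.file("extdata", "risk_rules.yaml", package = "heatwatch")
  expect_identical(read_rules_yaml(path), default_rule_base())
})
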