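test_that("average_rates is the person-year-weighted mean", {
  t1 <- rate_table(50:59, rep(0.001, 10), rep(4e-4, 10), rep(0.01, 10),
                   rep(1000, 10))
  expect_equal(average_rates(list(t1)), t1)

  t3 <- rate_table(50:59, rep(0.003, 10), rep(12e-4, 10), rep(0.03, 10),
                   rep(1000, 10))
  avg <- average_rates(list(t1, t3))
  expect_equal(avg$incidence, rep(0.002, 10))

  t2 <- rate_table(50:59, rep(0.002, 10), rep(4e-4, 10), rep(0.01, 10),
                   rep(3000, 10))
  avg2 <- average_rates(list(t1, t2))
  expect_equal(avg2$incidence, rep(0.00175, 10))

  t_off <- rate_table(51:60, rep(0.001, 10), rep(4e-4, 10), rep(0.01, 10),
                      rep(1000, 10))
  expect_error(average_rates(list(t1, t_off)), "misaligned")
})

test_that("rate_table validates its schedule", {
  expect_error(rate_table(c(50, 52), c(0.1, 0.1), c(0, 0), c(0.2, 0.2),
                          c(1, 1)), "contiguous")
  expect_error(rate_table(50:51, c(-0.1, 0.1), c(0, 0), c(0.2, 0.2),
                          c(1, 1)), "incidence")
  expect_error(rate_table(50:51, c(0.1, 0.1), c(0.3, 0.3), c(0.2, 0.2),
                          c(1, 1)), "below CRC mortality")
})

test_that("life table matches the constant-hazard competing-risk oracle", {
  for (h in c(1e-4, 1e-3, 1e-2)) {
    for (m in c(0, 0.01, 0.05)) {
      for (T in c(5, 10, 25)) {
        rt <- flat_rates(h, m)
        got <- age_conditional_risk(rt, 40, T)
        expect_equal(got, constant_hazard_risk(h, m, T), tolerance = 1e-4)
      }
    }
  }
  ## relative risk multiplies the diagnosis hazard only
  rt <- flat_rates(0.001, 0.02)
  expect_equal(age_conditional_risk(rt, 40, 10, rr = 2),
               constant_hazard_risk(0.002, 0.02, 10), tolerance = 1e-10)
})

test_that("absolute risks are probabilities with the expected monotonicity", {
  rt <- synth_rates(calibrate = list(age = 60, horizon = 10, risk = 0.0196))
  risks_h <- sapply(c(0, 5, 10, 25), function(T)
    age_conditional_risk(rt, 50, T))
  expect_equal(risks_h[1], 0)
  expect_true(all(diff(risks_h) > 0))
  expect_true(all(risks_h >= 0 & risks_h <= 1))

  risks_rr <- sapply(c(0.5, 1, 2, 5), function(r)
    age_conditional_risk(rt, 50, 10, r))
  expect_true(all(diff(risks_rr) > 0))

  ## non-increasing in competing mortality
  risks_m <- sapply(c(0, 0.01, 0.05, 0.2), function(m)
    age_conditional_risk(flat_rates(0.001, m), 40, 10))
  expect_true(all(diff(risks_m) < 0))

  expect_error(age_conditional_risk(rt, 90, 20), "not all covered")
  expect_error(age_conditional_risk(rt, 50, 10, rr = 0), "rr must be > 0")

  ## zero incidence: zero risk
  expect_equal(age_conditional_risk(flat_rates(0, 0.02), 40, 10), 0)
})

test_that("small-rate linearity holds without competing mortality", {
  rt <- flat_rates(1e-4, 0)
  got <- age_conditional_risk(rt, 40, 10, rr = 1.5)
  expect_equal(got, 1.5 * 1e-4 * 10, tolerance = 0.01)
})

test_that("eligibility threshold reproduces its closed form and ordering", {
  rt196 <- flat_rates(0.00198, 0)
  expect_equal(eligibility_threshold(rt196, 60, 10), 1 - exp(-0.0198),
               tolerance = 1e-10)
  ## increasing incidence schedule: threshold increases with reference age
  rt <- synth_rates()
  thr <- sapply(c(50, 55, 60, 65), function(a) eligibility_threshold(rt, a))
  expect_true(all(diff(thr) > 0))
  expect_equal(eligibility_threshold(rt, 94, 0), 0)
})

test_that("stratified_identification inverts risk and applies the tails", {
  rt <- synth_rates(calibrate = list(age = 60, horizon = 10, risk = 0.0196))
  d <- risk_distribution(sigma2 = 0.21)
  s <- sqrt(0.21)

  ## threshold at the band's own average risk: rr* = 1, closed-form tails
  band_thr <- weighted.mean(
    sapply(55:59, function(a) age_conditional_risk(rt, a, 10)),
    rt$population[match(55:59, rt$age)])
  id <- stratified_identification(rt, d, 55:59, band_thr)
  expect_equal(id$rr_star, 1, tolerance = 1e-6)
  expect_equal(id$pct_population / 100, 1 - pnorm(s / 2), tolerance = 1e-6)
  expect_equal(id$pct_cases / 100, pnorm(s / 2), tolerance = 1e-6)
  expect_lt(id$pct_population, 50)
  expect_gt(id$pct_cases, 50)

  ## bisection solves the risk equation to high precision
  thr <- eligibility_threshold(rt, 60, 10)
  id2 <- stratified_identification(rt, d, 55:59, thr)
  band_risk <- weighted.mean(
    sapply(55:59, function(a) age_conditional_risk(rt, a, 10, id2$rr_star)),
    rt$population[match(55:59, rt$age)])
  expect_equal(band_risk, thr, tolerance = 1e-8)
  ## adding risk-factor variance identifies more cases
  d2 <- combine_risk(d, binary_factor("smoking", 0.5, 1.18))
  id3 <- stratified_identification(rt, d2, 55:59, thr)
  expect_gt(id3$pct_cases, id2$pct_cases)

  ## degenerate distribution above an unattainable-at-baseline threshold
  d0 <- risk_distribution(sigma2 = 0)
  id0 <- stratified_identification(rt, d0, 55:59, thr * 1.5)
  expect_equal(id0$pct_population, 0)
  expect_equal(id0$pct_cases, 0)

  expect_warning(out <- stratified_identification(rt, d, 55:59, 1.5),
                 "unattainable")
  expect_equal(out$pct_population, 0)
})

test_that("prevention impact orders scenarios and percentiles correctly", {
  rt <- synth_rates(calibrate = list(age = 60, horizon = 10, risk = 0.0196))
  d <- risk_distribution(sigma2 = 0.21)
  factors <- list(
    binary_factor("smoking", 0.5, 1.18),
    binary_factor("aspirin", 0.046, 0.68),
    risk_factor("alcohol", c("high", "mid", "low"), c(0.2, 0.5, 0.3),
                c(1.3, 1.1, 1))
  )

  ## null factors prevent nothing
  null_f <- list(binary_factor("x", 0.5, 1))
  expect_equal(prevention_impact(rt, d, 0.9, null_f, "all")$prevented_exact,
               0)

  ## non-decreasing in percentile
  prev <- sapply(c(0.01, 0.5, 0.9, 0.99), function(x)
    prevention_impact(rt, d, x, factors, "all")$prevented_exact)
  expect_true(all(diff(prev) > 0))

  ## scenario set inclusion at several percentiles
  for (x in c(0.1, 0.5, 0.99)) {
    all_s <- prevention_impact(rt, d, x, factors, "all")$prevented_exact
    asp <- prevention_impact(rt, d, x, factors, "aspirin_only")$prevented_exact
    life <- prevention_impact(rt, d, x, factors,
                              "lifestyle_only")$prevented_exact
    expect_gte(all_s, asp)
    expect_gte(all_s, life)
  }

  ## internal consistency with direct bound arithmetic
  x <- 0.99
  b <- lifestyle_bounds(factors)
  rr_avg <- exp(sqrt(0.21) * qnorm(x))
  rr_min <- rr_avg * exp(b$rs_modmin - b$rs_modav)
  direct <- 10000 * (age_conditional_risk(rt, 50, 25, rr_avg) -
                       age_conditional_risk(rt, 50, 25, rr_min))
  got <- prevention_impact(rt, d, x, factors, "all")$prevented_exact
  expect_equal(got, direct, tolerance = 1e-10)

  ## reported counts are rounded to the nearest 10
  res <- prevention_impact(rt, d, 0.99, factors, "all")
  expect_equal(res$prevented %% 10, 0)
  expect_lte(abs(res$prevented - res$prevented_exact), 5)
})
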