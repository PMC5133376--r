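make_fit <- function(family, params, shift = 0) {
  structure(list(family = family, params = params, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_, shift = shift, n = 0L),
            class = "fitted_censored")
}

test_that("in-package gumbel and log-logistic functions are consistent", {
  ## CDF equals the integrated density; quantile inverts the CDF
  for (q in c(0.1, 0.5, 0.9)) {
    x <- qgumbel(q, loc = 2, scale = 1.5)
    num <- integrate(dgumbel, -Inf, x, loc = 2, scale = 1.5)$value
    expect_equal(num, q, tolerance = 1e-5)
    expect_equal(pgumbel(x, 2, 1.5), q, tolerance = 1e-12)

    y <- qllogis(q, shape = 3, scale = 2)
    num <- integrate(dllogis, 0, y, shape = 3, scale = 2)$value
    expect_equal(num, q, tolerance = 1e-5)
    expect_equal(pllogis(y, 3, 2), q, tolerance = 1e-12)
  }
})

test_that("censored fitting recovers generating parameters within 10%", {
  cases <- list(
    list(family = "gamma", params = list(shape = 2, rate = 0.5),
         edges = c(0, 1, 2, 4, 6, 8, 12, 20)),
    list(family = "normal", params = list(mean = 25, sd = 4),
         edges = seq(14, 38, by = 3)),
    list(family = "weibull", params = list(shape = 1.8, scale = 5),
         edges = c(0, 1, 2, 3, 5, 7, 10, 14)),
    list(family = "lognormal", params = list(meanlog = 1, sdlog = 0.5),
         edges = c(0, 1, 2, 3, 4, 6, 8, 12)),
    list(family = "exponential", params = list(rate = 0.25),
         edges = c(0, 1, 2, 4, 6, 10, 16)),
    list(family = "gumbel", params = list(loc = 10, scale = 3),
         edges = seq(4, 28, by = 3)),
    list(family = "loglogistic", params = list(shape = 4, scale = 6),
         edges = c(0, 2, 4, 6, 8, 10, 14, 20))
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    s <- synth_survey(cs$family, cs$params, 10000, cs$edges, seed = 100 + i)
    fit <- fit_censored(s, cs$family)
    truth <- unlist(cs$params)
    expect_equal(unname(fit$params[names(truth)]), unname(truth),
                 tolerance = 0.10,
                 label = paste(cs$family, "estimates"))
  }
})

test_that("normal fit centre matches the interval-weighted midpoint", {
  s <- synth_survey("normal", list(mean = 25, sd = 4), 10000,
                    seq(13, 37, by = 3), seed = 7)
  fit <- fit_censored(s, "normal")
  mids <- (s$low + pmin(s$high, 40)) / 2
  expect_equal(unname(fit$params["mean"]), weighted.mean(mids, s$count),
               tolerance = 0.02)
})

test_that("degenerate and invalid samples are rejected", {
  expect_error(censored_sample(0, 0, 0), "total count")
  one <- censored_sample(c(0, 2), c(2, 4), c(50, 0))
  expect_error(fit_censored(one, "gamma"), "degenerate sample")
  expect_error(censored_sample(c(0, 1), c(2, 3), c(5, 5)), "overlap")
  expect_error(censored_sample(c(2), c(1), c(5)), "low < high")
})

test_that("interval shifting applies only with a zero point mass", {
  s_pos <- synth_survey("gamma", list(shape = 2, rate = 0.5), 5000,
                        c(0, 1, 2, 4, 6, 8, 12, 20), seed = 31)
  f_a <- fit_censored(s_pos, "gamma", shift_increment = 0.5)
  f_b <- fit_censored(s_pos, "gamma", shift_increment = 0)
  expect_equal(f_a$shift, 0)
  expect_equal(f_a$params, f_b$params)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-6)

  s_zi <- synth_survey("gamma", list(shape = 2, rate = 0.5), 5000,
                       c(0, 1, 2, 4, 6, 8, 12, 20), zero_inflation = 0.2,
                       seed = 32)
  f_z <- fit_censored(s_zi, "gamma")
  expect_equal(f_z$shift, 0.01)
  ## un-shifted scale: CDF at large x approaches 1, quantiles are finite
  expect_equal(crcrisk:::.fit_p(f_z, 1e3), 1, tolerance = 1e-6)
})

test_that("select_family picks the generating family by BIC", {
  skew <- synth_survey("gamma", list(shape = 2, rate = 0.5), 8000,
                       c(0, 1, 2, 4, 6, 8, 12, 20), seed = 41)
  best <- select_family(skew, c("normal", "gamma"))
  expect_equal(best$family, "gamma")
  expect_s3_class(attr(best, "comparison"), "data.frame")
  expect_equal(nrow(attr(best, "comparison")), 2L)

  sym <- synth_survey("normal", list(mean = 25, sd = 4), 8000,
                      seq(13, 37, by = 3), seed = 42)
  expect_equal(select_family(sym, c("normal", "gamma"))$family, "normal")

  single <- select_family(skew, "gamma")
  expect_equal(single$family, "gamma")
})

test_that("standardize_score uses analytic family moments", {
  g <- make_fit("gamma", c(shape = 4, rate = 2))
  expect_equal(unname(standardize_score(g, 2)), 0)   # x = mean
  expect_equal(unname(standardize_score(g, 3)), 1)   # sd = 1
  n <- make_fit("normal", c(mean = 25, sd = 4))
  expect_equal(unname(standardize_score(n, 33)), 2)
})

test_that("discretize_exposure conserves mass and maps effects", {
  s <- synth_survey("gamma", list(shape = 2, rate = 0.5), 8000,
                    c(0, 1, 2, 4, 6, 8, 12, 20), seed = 51)
  fit <- fit_censored(s, "gamma")

  null_fac <- discretize_exposure(fit, log(1), name = "null")
  expect_true(all(null_fac$levels$beta == 0))
  expect_equal(factor_moments(null_fac)$var_contrib, 0)

  fac <- discretize_exposure(fit, log(1.12), unit = 5, name = "meat")
  expect_equal(sum(fac$levels$prob), 1, tolerance = 1e-9)

  ## two bins split at the median: binary-factor variance formula
  med <- crcrisk:::.fit_q(fit, 0.5)
  two <- discretize_exposure(fit, log(1.2), unit = 5, bin_edges = med,
                             name = "two")
  b <- two$levels$beta
  expect_equal(factor_moments(two)$var_contrib, 0.25 * (b[2] - b[1])^2,
               tolerance = 1e-6)

  ## BMI-style floor: a bin entirely below the reference has no effect
  sb <- synth_survey("normal", list(mean = 27, sd = 4), 8000,
                     seq(16, 40, by = 3), seed = 52)
  bfit <- fit_censored(sb, "normal")
  bmi <- discretize_exposure(bfit, log(1.29), unit = 8, reference = 25,
                             bin_edges = c(20, 25, 30, 35), name = "bmi",
                             floor_at_reference = TRUE)
  expect_equal(bmi$levels$beta[1:2], c(0, 0))
  expect_gt(bmi$levels$beta[nrow(bmi$levels)], 0)
})

test_that("discretized factor reproduces the continuous effect variance", {
  b_unit <- log(1.12)  # per 5 servings
  s <- synth_survey("gamma", list(shape = 2, rate = 0.5), 10000,
                    c(0, 1, 2, 4, 6, 8, 12, 20), seed = 61)
  fit <- fit_censored(s, "gamma")
  fac <- discretize_exposure(fit, b_unit, unit = 5, name = "meat")
  true_var <- (b_unit / 5)^2 * 2 / 0.5^2   # Var(beta/unit * X), X ~ gamma
  got <- factor_moments(fac)$var_contrib
  expect_lt(abs(got - true_var) / true_var, 0.15)
})
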