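## Synthetic inputs emulating the study's data sources: a GWAS SNP panel,
## interval-censored exposure surveys, and male vital-statistics rate tables.
## All generators are deterministic given a seed.

#' Generate a synthetic SNP risk panel
#'
#' Emulates a GWAS susceptibility panel: risk-allele frequencies uniform in
#' `freq_range`, odds-ratio magnitudes log-uniform in `or_range`, with a
#' fraction of protective alleles (log OR sign flipped). When
#' `target_sigma2` is given, all log odds ratios are rescaled by a common
#' factor so the panel's polygenic variance equals the target exactly.
#'
#' @param n_snps number of variants (default 37, the size of the known CRC
#'   panel).
#' @param freq_range range of risk-allele frequencies.
#' @param or_range range of odds-ratio magnitudes (sampled log-uniformly).
#' @param p_protective probability a variant's allele is protective.
#' @param target_sigma2 optional polygenic variance to rescale to.
#' @param seed RNG seed.
#' @return A [risk_panel()].
#' @examples
#' pan <- synth_panel(37, target_sigma2 = 0.21, seed = 1)
#' prs_moments(pan)$sigma2
#' @export
synth_panel <- function(n_snps = 37, freq_range = c(0.05, 0.95),
                        or_range = c(1.02, 1.6), p_protective = 0.15,
                        target_sigma2 = NULL, seed = NULL) {
  if (n_snps < 1) stop_input("n_snps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  freq <- runif(n_snps, freq_range[1], freq_range[2])
  beta <- runif(n_snps, log(or_range[1]), log(or_range[2]))
  flip <- runif(n_snps) < p_protective
  beta[flip] <- -beta[flip]
  if (!is.null(target_sigma2)) {
    raw <- sum(2 * freq * (1 - freq) * beta^2)
    if (raw == 0 && target_sigma2 > 0) {
      stop_input("cannot rescale a zero-variance panel to a positive target")
    }
    if (target_sigma2 < 0) stop_input("target_sigma2 must be >= 0")
    beta <- beta * if (raw > 0) sqrt(target_sigma2 / raw) else 0
  }
  risk_panel(sprintf("snp%02d", seq_len(n_snps)), freq, exp(beta))
}

#' Generate a synthetic interval-censored exposure survey
#'
#' Draws `n` exposures from a named family (optionally zero-inflated, the
#' "no consumption" point mass surveys report) and bins them into the given
#' intervals, producing the censored table a health survey would publish.
#'
#' @param family a [censored_families()] name.
#' @param params named list of the family's parameters.
#' @param n number of respondents.
#' @param bin_edges ascending interior edges starting at the support's lower
#'   bound; the top interval is open (`[last, Inf)`).
#' @param zero_inflation probability of an exact-zero response, reported as a
#'   `[0, 0]` point-mass interval (default 0).
#' @param seed RNG seed.
#' @return A [censored_sample()].
#' @export
synth_survey <- function(family, params, n, bin_edges,
                         zero_inflation = 0, seed = NULL) {
  if (n < 1) stop_input("n must be >= 1")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_input("bin edges must be strictly ascending")
  }
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop_input("zero_inflation must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  fam <- .resolve_family(family)
  x <- do.call(.family_fun(fam, "r"), c(list(n), params))
  if (zero_inflation > 0) x[runif(n) < zero_inflation] <- 0
  zeros <- sum(x == 0)
  x <- x[x != 0]
  edges <- c(bin_edges, Inf)
  cut_idx <- findInterval(x, edges, rightmost.closed = FALSE)
  cut_idx[cut_idx == 0L] <- 1L   # below the first edge: clamp into bin 1
  counts <- tabulate(cut_idx, nbins = length(edges) - 1L)
  low <- head(edges, -1L); high <- tail(edges, -1L)
  if (zeros > 0) {
    low <- c(0, low); high <- c(0, high); counts <- c(zeros, counts)
  }
  keep <- counts > 0 | (low == 0 & high == 0)
  censored_sample(low[keep], high[keep], counts[keep])
}

#' Generate a synthetic male vital-statistics rate table
#'
#' Builds a 1-year age-band schedule with Gompertz-like exponential growth in
#' CRC incidence and all-cause mortality, CRC mortality proportional to
#' incidence, and a population column following cohort survival. A
#' calibration target rescales incidence so the baseline risk over a stated
#' age window matches a requested value (default: 10-year risk at age 60 of
#' 1.96%, the screening-entry benchmark).
#'
#' @param age_range inclusive band-start range (default 0–94).
#' @param inc0 incidence scale at age 0 (per person-year).
#' @param inc_growth exponential growth rate of incidence per year of age.
#' @param mort0,mort_growth,mort_floor other-cause mortality Gompertz scale,
#'   growth rate and age-independent floor.
#' @param crc_mort_frac CRC mortality as a fraction of incidence.
#' @param pop0 cohort size entering age 0.
#' @param calibrate optional list `list(age=, horizon=, risk=)`; incidence is
#'   rescaled so [age_conditional_risk()] at RR 1 matches `risk`.
#' @param seed accepted for interface uniformity; the generator is
#'   deterministic given its parameters.
#' @return A [rate_table()].
#' @examples
#' rt <- synth_rates(calibrate = list(age = 60, horizon = 10, risk = 0.0196))
#' eligibility_threshold(rt, 60, 10)
#' @export
synth_rates <- function(age_range = c(0, 94), inc0 = 2e-6, inc_growth = 0.09,
                        mort0 = 3e-5, mort_growth = 0.085, mort_floor = 3e-4,
                        crc_mort_frac = 0.45, pop0 = 350000,
                        calibrate = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inc0 < 0 || mort0 < 0 || mort_floor < 0 || crc_mort_frac < 0 ||
      pop0 <= 0) {
    stop_input("rates and population must be nonnegative")
  }
  age <- seq.int(age_range[1], age_range[2])
  build <- function(k) {
    inc <- k * inc0 * exp(inc_growth * age)
    other <- mort_floor + mort0 * exp(mort_growth * age)
    crc_m <- crc_mort_frac * inc
    surv <- exp(-c(0, cumsum(other + crc_m)[-length(age)]))
    rate_table(age, inc, crc_m, crc_m + other, pop0 * surv)
  }
  if (is.null(calibrate)) return(build(1))
  f <- function(log_k) {
    age_conditional_risk(build(exp(log_k)), calibrate$age, calibrate$horizon,
                         rr = 1) - calibrate$risk
  }
  root <- uniroot(f, c(log(1e-6), log(1e6)), tol = 1e-14)
  build(exp(root$root))
}

#' Draw risk scores for controls or cases
#'
#' Control scores are drawn from the population log-risk distribution
#' N(mu, sigma2); case scores from the displaced distribution
#' N(mu + sigma2, sigma2).
#'
#' @param dist a [risk_distribution()].
#' @param n number of draws.
#' @param status `"control"` or `"case"`.
#' @param seed RNG seed.
#' @return Numeric vector of log relative-risk scores.
#' @export
sample_scores <- function(dist, n, status = c("control", "case"),
                          seed = NULL) {
  dist <- as_risk_distribution(dist)
  status <- match.arg(status)
  if (n < 1) stop_input("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  centre <- dist$mu + if (status == "case") dist$sigma2 else 0
  rnorm(n, centre, sqrt(dist$sigma2))
}

#' Synthetic lifestyle risk-factor suite
#'
#' Builds the full nongenetic risk-factor configuration of the CRC model from
#' synthetic survey data: continuous exposures (alcohol, BMI, red meat,
#' fruit, vegetables, physical activity) are generated as zero-inflated gamma
#' or normal surveys, fitted with [fit_censored()] and discretized with the
#' published per-unit odds ratios; smoking, aspirin and IBD are binary
#' factors with the published odds ratios. Survey shapes approximate English
#' male exposure distributions; see the package vignette for the rationale.
#'
#' @param n respondents per survey (default 10,000).
#' @param seed RNG seed.
#' @param aspirin_prevalence long-term daily aspirin use prevalence; default
#'   0.046 (usage during follow-up; 0.023, the enrolment figure, is the
#'   alternative).
#' @param smoking_prevalence ever-smoker prevalence (default 0.55).
#' @return List with `modifiable` (list of eight modifiable
#'   [risk_factor()]s), `ibd` (the host IBD factor) and `fits` (the fitted
#'   exposure distributions).
#' @export
synth_factor_suite <- function(n = 10000, seed = 1,
                               aspirin_prevalence = 0.046,
                               smoking_prevalence = 0.55) {
  set.seed(seed)
  specs <- list(
    ## exposure, generating family/params, survey bins, zero inflation,
    ## per-unit OR and unit from the meta-analyses
    alcohol = list(family = "gamma", params = list(shape = 1.2, rate = 0.08),
                   edges = c(0, 5, 10, 20, 35, 50), zi = 0.15,
                   or = 1.06, unit = 5, ref = 0),
    bmi = list(family = "normal", params = list(mean = 27.2, sd = 4.2),
               edges = c(18, 22, 25, 30, 35, 40), zi = 0,
               or = 1.29, unit = 8, ref = 25, floor = TRUE),
    red_meat = list(family = "gamma", params = list(shape = 2, rate = 0.7),
                    edges = c(0, 1, 2, 3, 5, 7), zi = 0.05,
                    or = 1.12, unit = 5, ref = 0),
    fruit = list(family = "gamma", params = list(shape = 1.8, rate = 0.9),
                 edges = c(0, 0.5, 1, 2, 3, 5), zi = 0.08,
                 or = 0.84, unit = 3, ref = 0),
    vegetables = list(family = "gamma", params = list(shape = 2.2, rate = 0.9),
                      edges = c(0, 0.5, 1, 2, 3, 5), zi = 0.05,
                      or = 0.86, unit = 5, ref = 0),
    activity = list(family = "gamma", params = list(shape = 1.5, rate = 1.5),
                    edges = c(0, 0.25, 0.5, 1, 2, 4), zi = 0.10,
                    or = 0.88, unit = 1, ref = NA)  # per doubling, see below
  )
  fits <- list(); modifiable <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    survey <- synth_survey(sp$family, sp$params, n, sp$edges,
                           zero_inflation = sp$zi,
                           seed = sample.int(2^31 - 1L, 1L))
    fit <- fit_censored(survey, sp$family)
    fits[[nm]] <- fit
    if (nm == "activity") {
      ## effect is per twofold increase in the standardized score; work on a
      ## clamped log2 of the score shifted to positive support
      mom <- fitted_moments(fit)
      sd_fit <- sqrt(mom[["var"]])
      clamp <- 0.05
      trans <- function(v) {
        z <- (v - mom[["mean"]]) / sd_fit
        log2(pmax(z + 3, clamp))   # shift to positive support, clamp at 0.05
      }
      ref_val <- .fit_q(fit, 0.5)
      modifiable[[nm]] <- discretize_exposure(
        fit, log(sp$or), unit = 1, reference = ref_val, name = nm,
        transform = trans)
    } else {
      modifiable[[nm]] <- discretize_exposure(
        fit, log(sp$or), unit = sp$unit, reference = sp$ref, name = nm,
        floor_at_reference = isTRUE(sp$floor))
    }
  }
  modifiable$smoking <- binary_factor("smoking", smoking_prevalence, 1.18)
  modifiable$aspirin <- risk_factor(
    "aspirin", c("long_term_use", "no_long_term_use"),
    c(aspirin_prevalence, 1 - aspirin_prevalence), c(0.68, 1))
  ibd <- binary_factor("ibd", 4 / 10000, 2.93, modifiable = FALSE)
  list(modifiable = modifiable, ibd = ibd, fits = fits)
}
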