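#' Construct a 1-year age-band rate table
#'
#' Vital-statistics schedule for the absolute-risk life table: per-person-year
#' colorectal cancer incidence, CRC mortality, all-cause mortality and the
#' mid-year population, in contiguous 1-year age bands. Other-cause mortality
#' (the competing hazard) is derived as all-cause minus CRC mortality.
#'
#' @param age integer band start ages, contiguous.
#' @param incidence CRC cases per person-year.
#' @param crc_mortality CRC deaths per person-year.
#' @param all_cause_mortality all-cause deaths per person-year; must be >=
#'   `crc_mortality` in every band.
#' @param population mid-year person count per band.
#' @return A `rate_table` data frame with an added `other_mortality` column.
#' @export
rate_table <- function(age, incidence, crc_mortality, all_cause_mortality,
                       population) {
  n <- length(age)
  if (!n) stop_input("empty rate table")
  if (any(lengths(list(incidence, crc_mortality, all_cause_mortality,
                       population)) != n)) {
    stop_input("all rate-table columns must have equal length")
  }
  age <- as.integer(age)
  if (any(diff(age) != 1L)) {
    gap <- age[which(diff(age) != 1L)[1L]]
    stop_input("age bands not contiguous after age ", gap)
  }
  for (nm in c("incidence", "crc_mortality", "all_cause_mortality",
               "population")) {
    v <- get(nm)
    if (any(!is.finite(v) | v < 0)) stop_input(nm, " must be >= 0 and finite")
  }
  other <- all_cause_mortality - crc_mortality
  if (any(other < -1e-12)) {
    stop_input("all-cause mortality below CRC mortality in some band")
  }
  out <- data.frame(age = age, incidence = incidence,
                    crc_mortality = crc_mortality,
                    all_cause_mortality = all_cause_mortality,
                    other_mortality = pmax(other, 0),
                    population = population)
  class(out) <- c("rate_table", "data.frame")
  out
}

as_rate_table <- function(x) {
  if (inherits(x, "rate_table")) return(x)
  if (is.data.frame(x) &&
      all(c("age", "incidence", "crc_mortality", "all_cause_mortality",
            "population") %in% names(x))) {
    return(rate_table(x$age, x$incidence, x$crc_mortality,
                      x$all_cause_mortality, x$population))
  }
  stop_input("expected a rate_table")
}

#' Person-year-weighted average of yearly rate tables
#'
#' Pools several calendar years of rates into a single schedule: each band's
#' rate is the population-weighted mean across years and the population is
#' the across-year mean.
#'
#' @param yearly_tables list of [rate_table()] objects with identical age
#'   bands.
#' @return A single [rate_table()].
#' @export
average_rates <- function(yearly_tables) {
  if (inherits(yearly_tables, "rate_table")) {
    yearly_tables <- list(yearly_tables)
  }
  if (!length(yearly_tables)) stop_input("need at least one rate table")
  tabs <- lapply(yearly_tables, as_rate_table)
  ages <- tabs[[1L]]$age
  for (t in tabs[-1L]) {
    if (!identical(t$age, ages)) stop_input("age bands are misaligned")
  }
  pop <- sapply(tabs, `[[`, "population")   # bands x years
  wmean <- function(col) {
    val <- sapply(tabs, `[[`, col)
    rowSums(val * pop) / rowSums(pop)
  }
  rate_table(ages, wmean("incidence"), wmean("crc_mortality"),
             wmean("all_cause_mortality"), rowMeans(pop))
}

## per-band hazards for a starting age and integer horizon
.band_slice <- function(rates, age_start, horizon) {
  idx <- match(age_start + seq_len(horizon) - 1L, rates$age)
  if (anyNA(idx)) {
    stop_input("ages ", age_start, " to ", age_start + horizon - 1L,
               " not all covered by the rate table")
  }
  idx
}

#' Age-conditional absolute risk of colorectal cancer
#'
#' Probability of a first CRC diagnosis within `[age_start, age_start +
#' horizon)` for a person alive and CRC-free at `age_start`, under competing
#' other-cause mortality. The diagnosis hazard is `rr * incidence(age)`;
#' within each 1-year band the hazards are treated as constant, so the band's
#' diagnosis probability is `h/(h+m) * (1 - exp(-(h+m)))` discounted by
#' survival (event-free) to the band start. The relative risk multiplies the
#' incidence hazard only; competing mortality stays at baseline.
#'
#' @param rates a [rate_table()].
#' @param age_start starting age (band start, years).
#' @param horizon whole years of follow-up; all bands must be in the table.
#' @param rr relative-risk multiplier on incidence, > 0.
#' @return The absolute risk, a probability in `[0, 1]`.
#' @examples
#' rt <- rate_table(50:69, rep(0.001, 20), rep(0, 20), rep(0.02, 20),
#'                  rep(1e5, 20))
#' age_conditional_risk(rt, 60, 10)        # constant-hazard competing risk
#' @export
age_conditional_risk <- function(rates, age_start, horizon, rr = 1) {
  rates <- as_rate_table(rates)
  if (!is.finite(rr) || rr <= 0) stop_input("rr must be > 0")
  if (horizon < 0) stop_input("horizon must be >= 0")
  if (horizon == 0) return(0)
  idx <- .band_slice(rates, age_start, horizon)
  h <- rr * rates$incidence[idx]
  m <- rates$other_mortality[idx]
  tot <- h + m
  p_band <- ifelse(tot > 0, h / tot * (1 - exp(-tot)), 0)
  surv <- exp(-c(0, cumsum(tot)[-length(tot)]))
  sum(p_band * surv)
}

#' Baseline screening-eligibility risk threshold
#'
#' The baseline (RR = 1) absolute risk over `horizon` years at the reference
#' age — e.g. the 10-year risk of an average 60-year-old, the screening-entry
#' benchmark against which younger higher-risk men are compared.
#'
#' @param rates a [rate_table()].
#' @param ref_age reference age (years).
#' @param horizon years (default 10).
#' @return Probability.
#' @export
eligibility_threshold <- function(rates, ref_age, horizon = 10) {
  age_conditional_risk(rates, ref_age, horizon, rr = 1)
}

#' Fraction of population and cases identified as higher risk
#'
#' Finds the minimal relative risk `r*` at which the absolute risk of an
#' age-band member reaches `threshold_risk` (population-weighted across the
#' band's starting ages, monotone bisection), then evaluates what fraction of
#' the population and of cases carry RR at or above `r*` under the model's
#' risk distribution.
#'
#' @param rates a [rate_table()].
#' @param dist a [risk_distribution()].
#' @param band integer vector of starting ages pooled (e.g. `55:59`).
#' @param threshold_risk absolute-risk threshold (e.g. the 1.96% 10-year risk
#'   of an average 60-year-old).
#' @param horizon years (default 10).
#' @return List with `pct_population`, `pct_cases` (percentages) and
#'   `rr_star`. If no finite RR attains the threshold both percentages are 0
#'   with a warning.
#' @export
stratified_identification <- function(rates, dist, band, threshold_risk,
                                      horizon = 10) {
  rates <- as_rate_table(rates)
  dist <- as_risk_distribution(dist)
  band <- as.integer(band)
  w <- rates$population[match(band, rates$age)]
  if (anyNA(w)) stop_input("band ages missing from the rate table")
  band_risk <- function(rr) {
    weighted.mean(vapply(band, function(a)
      age_conditional_risk(rates, a, horizon, rr), numeric(1)), w)
  }
  f <- function(log_rr) band_risk(exp(log_rr)) - threshold_risk
  hi <- 0
  while (f(hi) < 0 && hi < log(1e12)) hi <- hi + log(10)
  if (f(hi) < 0) {
    warning("threshold risk unattainable at any relative risk")
    return(list(pct_population = 0, pct_cases = 0, rr_star = Inf))
  }
  lo <- hi - log(10)
  while (f(lo) > 0 && lo > log(1e-12)) lo <- lo - log(10)
  root <- uniroot(f, c(lo, hi), tol = 1e-15)
  rr_star <- exp(root$root)
  ## polish on the risk scale to the bisection tolerance
  stopifnot(abs(band_risk(rr_star) - threshold_risk) < 1e-8)
  list(pct_population = 100 * case_fraction_above(dist, rr_star, "controls"),
       pct_cases = 100 * case_fraction_above(dist, rr_star, "cases"),
       rr_star = rr_star)
}

## scenario -> subset of modifiable factors minimised
.scenario_factors <- function(factors, scenario, aspirin_name) {
  nms <- vapply(factors, `[[`, character(1), "name")
  keep <- switch(scenario,
                 all = rep(TRUE, length(factors)),
                 aspirin_only = nms == aspirin_name,
                 lifestyle_only = nms != aspirin_name)
  factors[keep]
}

#' Cases prevented by minimising modifiable risk factors
#'
#' Risk-difference estimate of prevention impact: for `cohort_size` men at
#' the `x`-th percentile of the host-factor (SNPs + IBD) risk model, the
#' number of CRC cases prevented over `horizon` years if the scenario's
#' modifiable factors are set to their lowest-risk observed levels, relative
#' to the same men with average modifiable-factor risk.
#'
#' @param rates a [rate_table()].
#' @param host_dist host-factor [risk_distribution()].
#' @param x host-risk percentile in (0, 1).
#' @param factors list of modifiable [risk_factor()] objects.
#' @param scenario `"all"` (every modifiable factor including aspirin),
#'   `"aspirin_only"`, or `"lifestyle_only"` (all but aspirin).
#' @param age_start,horizon age window (default 50 for 25 years).
#' @param cohort_size number of men (default 10,000).
#' @param aspirin_name name identifying the aspirin factor (default
#'   `"aspirin"`).
#' @return List with `prevented` (rounded to the nearest 10, the reporting
#'   granularity), `prevented_exact`, the two absolute risks and the two RRs.
#' @export
prevention_impact <- function(rates, host_dist, x, factors,
                              scenario = c("all", "aspirin_only",
                                           "lifestyle_only"),
                              age_start = 50, horizon = 25,
                              cohort_size = 10000,
                              aspirin_name = "aspirin") {
  scenario <- match.arg(scenario)
  if (cohort_size <= 0) stop_input("cohort_size must be > 0")
  host_dist <- as_risk_distribution(host_dist)
  if (inherits(factors, "risk_factor")) factors <- list(factors)
  sub <- .scenario_factors(factors, scenario, aspirin_name)
  ## minimised factors move from their population-average score to their
  ## minimum observed level; untouched factors stay at average (delta 0)
  delta <- if (length(sub)) {
    b <- lifestyle_bounds(sub)
    b$rs_modmin - b$rs_modav
  } else 0
  rr_avg <- individual_rr(host_dist, x, lifestyle_bounds(list()), "average")
  rr_scn <- rr_avg * exp(delta)
  risk_avg <- age_conditional_risk(rates, age_start, horizon, rr_avg)
  risk_scn <- age_conditional_risk(rates, age_start, horizon, rr_scn)
  exact <- cohort_size * (risk_avg - risk_scn)
  list(prevented = round(exact / 10) * 10,
       prevented_exact = exact,
       risk_average = risk_avg, risk_scenario = risk_scn,
       rr_average = rr_avg, rr_scenario = rr_scn)
}
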