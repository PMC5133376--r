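#' The log-normal relative-risk distribution
#'
#' Container for the population distribution of relative risk (RR): log RR is
#' normal with mean `mu` and variance `sigma2`, so RR itself is log-normal.
#' The case distribution is the same normal displaced to the right by
#' `sigma2` on the log scale. With `mu = -sigma2/2` (mean-centred) the
#' population mean RR is exactly 1.
#'
#' @param mu mean of log relative risk.
#' @param sigma2 variance of log relative risk, >= 0.
#' @param components optional named numeric vector decomposing `sigma2` into
#'   per-SNP / per-factor contributions; must sum to `sigma2`.
#' @return An object of class `risk_distribution`.
#' @examples
#' risk_distribution(sigma2 = 0.21)
#' @export
risk_distribution <- function(mu = -sigma2 / 2, sigma2, components = NULL) {
  if (!is.finite(sigma2) || sigma2 < 0) stop_input("sigma2 must be >= 0")
  if (!is.finite(mu)) stop_input("mu must be finite")
  if (!is.null(components)) {
    if (abs(sum(components) - sigma2) > 1e-8 * max(1, sigma2)) {
      stop_input("variance components do not sum to sigma2")
    }
  } else {
    components <- c(total = sigma2)
  }
  structure(list(mu = mu, sigma2 = sigma2, components = components),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("log-normal relative-risk distribution\n")
  cat(sprintf("  mu = %.6g, sigma2 = %.6g (sd = %.4g)\n",
              x$mu, x$sigma2, sqrt(x$sigma2)))
  cat(sprintf("  mean RR = %.6g, AUC = %.4f\n",
              exp(x$mu + x$sigma2 / 2), risk_auc(x)))
  if (length(x$components) > 1) {
    cat("  components:", length(x$components), "terms\n")
  }
  invisible(x)
}

as_risk_distribution <- function(x) {
  if (inherits(x, "risk_distribution")) return(x)
  stop_input("expected a risk_distribution object")
}

#' Combine genetic and nongenetic risk components
#'
#' Adds the log-scale variance contributed by independent nongenetic risk
#' factors to a genetic risk distribution (the multiplicative-independence
#' assumption: log risks add). Per-factor variance components are preserved
#' in the decomposition.
#'
#' @param genetic a [risk_distribution()] (e.g. from [prs_moments()]).
#' @param factors a list of [risk_factor()] objects.
#' @param center logical; recentre so the combined mean RR is 1 (default TRUE).
#' @return A [risk_distribution()] with total variance
#'   `genetic$sigma2 + sum(factor variances)`.
#' @export
combine_risk <- function(genetic, factors = list(), center = TRUE) {
  genetic <- as_risk_distribution(genetic)
  if (inherits(factors, "risk_factor")) factors <- list(factors)
  comp <- genetic$components
  mu <- genetic$mu
  for (f in factors) {
    fm <- factor_moments(f)
    comp <- c(comp, setNames(fm$var_contrib, f$name))
    mu <- mu + fm$mean_contrib
  }
  sigma2 <- sum(comp)
  if (center) mu <- -sigma2 / 2
  risk_distribution(mu = mu, sigma2 = sigma2, components = comp)
}

#' Relative risk at a percentile of the risk distribution
#'
#' Evaluates the RR at the `q`-th percentile of the population distribution,
#' relative either to the population median (the usual reporting convention)
#' or to the population mean (RR = 1 when centred).
#'
#' @param dist a [risk_distribution()].
#' @param q percentile in (0, 1); vectorised.
#' @param reference `"median"` (default) or `"mean"`.
#' @return Relative risk(s).
#' @examples
#' d <- risk_distribution(sigma2 = 0.21)
#' percentile_rr(d, c(0.90, 0.99))  # ~1.8, ~2.9
#' @export
percentile_rr <- function(dist, q, reference = c("median", "mean")) {
  dist <- as_risk_distribution(dist)
  reference <- match.arg(reference)
  if (any(!is.finite(q) | q <= 0 | q >= 1)) {
    stop_input("percentile q must lie in (0, 1)")
  }
  s <- sqrt(dist$sigma2)
  if (reference == "median") exp(s * qnorm(q)) else exp(dist$mu + s * qnorm(q))
}

#' Polygenic variance implied by a printed percentile relative risk
#'
#' Inverts [percentile_rr()] with the median reference: given the RR at the
#' `q`-th percentile, returns the log-scale variance `(log(rr)/z_q)^2`. Used
#' to back-solve a model's total variance from a reported top-percentile RR.
#'
#' @param rr relative risk at percentile `q` versus the median, > 0.
#' @param q percentile in (0, 1), not 0.5.
#' @return sigma2, the implied variance of log RR.
#' @examples
#' variance_from_percentile_rr(2.9, 0.99)  # ~0.21
#' @export
variance_from_percentile_rr <- function(rr, q) {
  if (any(rr <= 0)) stop_input("rr must be > 0")
  if (any(q <= 0 | q >= 1) || any(q == 0.5)) {
    stop_input("q must lie in (0, 1) and differ from 0.5")
  }
  (log(rr) / qnorm(q))^2
}

#' Discrimination (ROC AUC) of a risk model
#'
#' The probability that a randomly drawn case has a higher risk score than a
#' randomly drawn control. With case scores displaced by `sigma2` on the log
#' scale, the closed form is `pnorm(sigma / sqrt(2))`. The Monte-Carlo method
#' draws control scores from N(mu, sigma2) and case scores from
#' N(mu + sigma2, sigma2) and returns the exceedance fraction (ties count
#' one half).
#'
#' @param dist a [risk_distribution()].
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param n_draws number of case/control pairs for Monte-Carlo.
#' @param seed optional RNG seed for Monte-Carlo.
#' @return AUC in `[0.5, 1)`.
#' @examples
#' risk_auc(risk_distribution(sigma2 = 0.21))  # ~0.627
#' @export
risk_auc <- function(dist, method = c("analytic", "monte_carlo"),
                     n_draws = 1e6, seed = NULL) {
  dist <- as_risk_distribution(dist)
  method <- match.arg(method)
  if (method == "analytic") {
    return(pnorm(sqrt(dist$sigma2) / sqrt(2)))
  }
  if (!is.finite(n_draws) || n_draws <= 0) stop_input("n_draws must be > 0")
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(dist$sigma2)
  controls <- rnorm(n_draws, dist$mu, s)
  cases <- rnorm(n_draws, dist$mu + dist$sigma2, s)
  mean((cases > controls) + 0.5 * (cases == controls))
}

#' Fraction of controls or cases above an RR threshold
#'
#' @param dist a [risk_distribution()].
#' @param rr_threshold relative-risk threshold, > 0 (on the same scale as the
#'   distribution: `exp(mu)` is the population median RR).
#' @param population `"controls"` (the general population) or `"cases"`
#'   (log-scale mean displaced by `sigma2`).
#' @return Fraction in `[0, 1]` at or above the threshold. A degenerate
#'   distribution (`sigma2 = 0`) is treated as a point mass.
#' @examples
#' d <- risk_distribution(sigma2 = 0.21)
#' case_fraction_above(d, exp(d$mu))  # 0.5 of controls above their median
#' @export
case_fraction_above <- function(dist, rr_threshold,
                                population = c("controls", "cases")) {
  dist <- as_risk_distribution(dist)
  population <- match.arg(population)
  if (any(rr_threshold <= 0)) stop_input("rr_threshold must be > 0")
  centre <- dist$mu + if (population == "cases") dist$sigma2 else 0
  if (dist$sigma2 == 0) {
    return(as.numeric(centre >= log(rr_threshold) - .thresh_tol))
  }
  pnorm((log(rr_threshold) - centre) / sqrt(dist$sigma2), lower.tail = FALSE)
}

#' Project polygenic variance to a larger fraction of familial risk
#'
#' Scales the variance explained by the known variants up to a hypothetical
#' discovery fraction, assuming variance grows linearly with the fraction of
#' familial log-risk explained. A calibration multiplier is exposed for
#' alternative projection rules; the default of 1 is pure linear scaling.
#'
#' @param sigma2_known variance of the known-variant score.
#' @param frac_known fraction of familial risk the known variants explain
#'   (e.g. 0.145).
#' @param frac_target target fraction (e.g. 0.275 for half of all variants,
#'   0.55 for all).
#' @param calibration multiplier applied to the linear projection (default 1).
#' @return Projected sigma2.
#' @examples
#' project_variance(0.21, 0.145, 0.55)
#' @export
project_variance <- function(sigma2_known, frac_known, frac_target,
                             calibration = 1) {
  if (sigma2_known < 0) stop_input("sigma2_known must be >= 0")
  if (frac_known <= 0 || frac_target <= 0) {
    stop_input("familial-risk fractions must be positive")
  }
  if (frac_target < frac_known) {
    stop_input("frac_target must be >= frac_known")
  }
  sigma2_known * (frac_target / frac_known) * calibration
}
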