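#' Construct a nongenetic risk factor
#'
#' A nongenetic risk factor is a finite set of levels/categories, each with a
#' population probability and an odds ratio versus the factor's reference
#' level. Factors enter the risk model like risk alleles: a factor with k
#' levels contributes k terms to the mean and variance summations.
#'
#' @param name factor name (e.g. `"smoking"`).
#' @param levels character vector of level labels.
#' @param prob population probability of each level; must sum to 1.
#' @param or_level odds ratio of each level versus the reference, > 0.
#' @param modifiable logical; whether the factor is a modifiable lifestyle
#'   factor (TRUE for alcohol, BMI, red meat, fruit, vegetables, physical
#'   activity, smoking, aspirin) or a host factor (FALSE for IBD).
#' @return An object of class `risk_factor` with a `levels` data frame
#'   holding `label`, `prob`, `or_level`, `beta`.
#' @examples
#' smoking <- risk_factor("smoking", c("ever", "never"), c(0.5, 0.5),
#'                        c(1.18, 1), modifiable = TRUE)
#' factor_moments(smoking)
#' @export
risk_factor <- function(name, levels, prob, or_level, modifiable = TRUE) {
  if (length(levels) < 2L) stop_input("a risk factor needs >= 2 levels")
  if (length(prob) != length(levels) || length(or_level) != length(levels)) {
    stop_input("levels, prob and or_level must have equal length")
  }
  if (any(!is.finite(prob) | prob < 0 | prob > 1)) {
    stop_input("level probabilities must lie in [0, 1] (factor ", name, ")")
  }
  if (abs(sum(prob) - 1) > 1e-9) {
    stop_input("level probabilities of factor ", name,
               " sum to ", format(sum(prob)), ", not 1")
  }
  if (any(!is.finite(or_level) | or_level <= 0)) {
    stop_input("level odds ratios must be > 0 (factor ", name, ")")
  }
  structure(list(
    name = as.character(name),
    levels = data.frame(label = as.character(levels),
                        prob = as.numeric(prob),
                        or_level = as.numeric(or_level),
                        beta = log(as.numeric(or_level)),
                        stringsAsFactors = FALSE),
    modifiable = isTRUE(modifiable)
  ), class = "risk_factor")
}

#' Binary exposed/unexposed risk factor
#'
#' Convenience wrapper for two-level factors such as IBD, smoking or aspirin.
#'
#' @param name factor name.
#' @param p_exposed probability of exposure.
#' @param or odds ratio of the exposed level versus unexposed.
#' @param modifiable see [risk_factor()].
#' @inherit risk_factor return
#' @export
binary_factor <- function(name, p_exposed, or, modifiable = TRUE) {
  risk_factor(name, c("exposed", "unexposed"),
              c(p_exposed, 1 - p_exposed), c(or, 1),
              modifiable = modifiable)
}

#' @export
print.risk_factor <- function(x, ...) {
  fm <- factor_moments(x)
  cat(sprintf("risk factor '%s' (%s): %d levels, var contribution %.4g\n",
              x$name, if (x$modifiable) "modifiable" else "host",
              nrow(x$levels), fm$var_contrib))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Mean and variance contribution of a nongenetic risk factor
#'
#' On the log relative-risk scale: mean contribution `sum(p*beta)` over
#' levels, variance contribution `sum(p*beta^2) - (sum(p*beta))^2`. For a
#' binary factor this reduces to `p*(1-p)*beta^2`.
#'
#' @param factor a [risk_factor()].
#' @return list with `mean_contrib` and `var_contrib` (log-RR scale).
#' @export
factor_moments <- function(factor) {
  stopifnot(inherits(factor, "risk_factor"))
  p <- factor$levels$prob
  b <- factor$levels$beta
  m <- sum(p * b)
  list(mean_contrib = m, var_contrib = sum(p * b^2) - m^2)
}

#' Lifestyle score bounds from the modifiable risk factors
#'
#' The average, minimum and maximum log-risk scores attainable from a set of
#' modifiable risk factors. The average sums `p*beta` over all levels of all
#' factors; the minimum (maximum) takes each factor at its lowest (highest)
#' beta among levels with nonzero population probability — only level
#' combinations actually observed in the population define the bounds.
#'
#' @param factors list of modifiable [risk_factor()] objects (non-modifiable
#'   entries are rejected).
#' @return An object of class `lifestyle_bounds` with fields `rs_modav`,
#'   `rs_modmin`, `rs_modmax`.
#' @export
lifestyle_bounds <- function(factors) {
  if (inherits(factors, "risk_factor")) factors <- list(factors)
  if (!length(factors)) {
    return(structure(list(rs_modav = 0, rs_modmin = 0, rs_modmax = 0),
                     class = "lifestyle_bounds"))
  }
  av <- mn <- mx <- 0
  for (f in factors) {
    stopifnot(inherits(f, "risk_factor"))
    if (!f$modifiable) {
      stop_input("factor '", f$name, "' is not modifiable")
    }
    nz <- f$levels$prob > 0
    if (!any(nz)) stop_input("factor '", f$name, "' has all-zero probabilities")
    av <- av + sum(f$levels$prob * f$levels$beta)
    mn <- mn + min(f$levels$beta[nz])
    mx <- mx + max(f$levels$beta[nz])
  }
  structure(list(rs_modav = av, rs_modmin = mn, rs_modmax = mx),
            class = "lifestyle_bounds")
}

#' @export
print.lifestyle_bounds <- function(x, ...) {
  cat(sprintf(paste0("modifiable-lifestyle log-risk scores: min %.4g, ",
                     "average %.4g, max %.4g\n"),
              x$rs_modmin, x$rs_modav, x$rs_modmax))
  cat(sprintf("  RR span vs average lifestyle: %.3g to %.3g\n",
              exp(x$rs_modmin - x$rs_modav), exp(x$rs_modmax - x$rs_modav)))
  invisible(x)
}

#' Relative risk of a percentile individual under a lifestyle scenario
#'
#' For a host-factor risk model (SNPs + IBD), every individual carries average
#' risk from the modifiable factors (RR contribution 1). An individual at the
#' X-th host percentile with a healthy (unhealthy) lifestyle adds the
#' difference between the minimum (maximum) and average modifiable risk score.
#' The returned RR is relative to the 50th-percentile individual with an
#' average lifestyle.
#'
#' @param host_dist the host-factor [risk_distribution()].
#' @param x percentile in (0, 1); vectorised.
#' @param bounds a [lifestyle_bounds()] object.
#' @param lifestyle `"average"`, `"healthy"` or `"unhealthy"`.
#' @return Relative risk(s) versus the median average-lifestyle individual.
#' @examples
#' d <- risk_distribution(sigma2 = 0.21)
#' individual_rr(d, 0.9, lifestyle_bounds(list()), "average")  # ~1.8
#' @export
individual_rr <- function(host_dist, x, bounds,
                          lifestyle = c("average", "healthy", "unhealthy")) {
  host_dist <- as_risk_distribution(host_dist)
  lifestyle <- match.arg(lifestyle)
  if (any(!is.finite(x) | x <= 0 | x >= 1)) {
    stop_input("percentile must lie in (0, 1)")
  }
  stopifnot(inherits(bounds, "lifestyle_bounds"))
  delta <- switch(lifestyle,
                  average = 0,
                  healthy = bounds$rs_modmin - bounds$rs_modav,
                  unhealthy = bounds$rs_modmax - bounds$rs_modav)
  exp(sqrt(host_dist$sigma2) * qnorm(x) + delta)
}
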