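## Distribution families supported for censored exposure fitting.
## Gumbel and log-logistic d/p/q live here because the fitting backend looks
## families up by name; the closed forms are standard.

#' Gumbel (extreme-value) distribution
#'
#' Density, distribution function and quantile function for the Gumbel
#' distribution with location `loc` and scale `scale`.
#'
#' @param x,q numeric vector of values.
#' @param p numeric vector of probabilities.
#' @param loc location parameter.
#' @param scale scale parameter, > 0.
#' @param log logical; return log density.
#' @return `dgumbel` the density, `pgumbel` the CDF, `qgumbel` the quantiles.
#' @name gumbel
NULL

#' @rdname gumbel
#' @export
dgumbel <- function(x, loc = 0, scale = 1, log = FALSE) {
  z <- (x - loc) / scale
  ld <- -z - exp(-z) - base::log(scale)
  if (log) ld else exp(ld)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, loc = 0, scale = 1) {
  exp(-exp(-(q - loc) / scale))
}

#' @rdname gumbel
#' @export
qgumbel <- function(p, loc = 0, scale = 1) {
  loc - scale * base::log(-base::log(p))
}

#' Log-logistic distribution
#'
#' Density, distribution function and quantile function for the log-logistic
#' distribution with shape `shape` and scale `scale` (the distribution of a
#' variable whose logit of `(x/scale)^shape / (1 + (x/scale)^shape)` is
#' standard logistic).
#'
#' @param x,q numeric vector of values (support x > 0).
#' @param p numeric vector of probabilities.
#' @param shape shape parameter, > 0.
#' @param scale scale parameter (the median), > 0.
#' @param log logical; return log density.
#' @return `dllogis` the density, `pllogis` the CDF, `qllogis` the quantiles.
#' @name llogis
NULL

#' @rdname llogis
#' @export
dllogis <- function(x, shape = 1, scale = 1, log = FALSE) {
  ld <- ifelse(x > 0,
               base::log(shape) - base::log(scale) +
                 (shape - 1) * (base::log(pmax(x, .Machine$double.xmin)) -
                                  base::log(scale)) -
                 2 * log1p((pmax(x, .Machine$double.xmin) / scale)^shape),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname llogis
#' @export
pllogis <- function(q, shape = 1, scale = 1) {
  ifelse(q > 0, 1 / (1 + (q / scale)^-shape), 0)
}

#' @rdname llogis
#' @export
qllogis <- function(p, shape = 1, scale = 1) {
  scale * (p / (1 - p))^(1 / shape)
}

## ---- family registry -------------------------------------------------------

.euler_gamma <- 0.5772156649015329

.family_table <- list(
  normal      = list(distname = "norm",    positive = FALSE,
                     d = stats::dnorm, p = stats::pnorm,
                     q = stats::qnorm, r = stats::rnorm),
  gamma       = list(distname = "gamma",   positive = TRUE,
                     d = stats::dgamma, p = stats::pgamma,
                     q = stats::qgamma, r = stats::rgamma),
  exponential = list(distname = "exp",     positive = TRUE,
                     d = stats::dexp, p = stats::pexp,
                     q = stats::qexp, r = stats::rexp),
  lognormal   = list(distname = "lnorm",   positive = TRUE,
                     d = stats::dlnorm, p = stats::plnorm,
                     q = stats::qlnorm, r = stats::rlnorm),
  loglogistic = list(distname = "llogis",  positive = TRUE,
                     d = NULL, p = NULL, q = NULL, r = NULL),
  weibull     = list(distname = "weibull", positive = TRUE,
                     d = stats::dweibull, p = stats::pweibull,
                     q = stats::qweibull, r = stats::rweibull),
  gumbel      = list(distname = "gumbel",  positive = FALSE,
                     d = NULL, p = NULL, q = NULL, r = NULL)
)

#' Supported exposure-distribution families
#'
#' @return Character vector of family names accepted by [fit_censored()].
#' @export
censored_families <- function() names(.family_table)

.resolve_family <- function(family) {
  family <- match.arg(tolower(family), names(.family_table))
  c(list(name = family), .family_table[[family]])
}

## analytic mean and variance of a fitted family (before un-shifting)
.family_moments <- function(family, params) {
  p <- as.list(params)
  switch(family,
    normal = c(mean = p$mean, var = p$sd^2),
    gamma = c(mean = p$shape / p$rate, var = p$shape / p$rate^2),
    exponential = c(mean = 1 / p$rate, var = 1 / p$rate^2),
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      c(mean = m, var = (exp(p$sdlog^2) - 1) * m^2)
    },
    weibull = {
      m <- p$scale * gamma(1 + 1 / p$shape)
      c(mean = m, var = p$scale^2 * gamma(1 + 2 / p$shape) - m^2)
    },
    loglogistic = {
      if (p$shape <= 2) stop_input(
        "log-logistic variance undefined for shape <= 2")
      b <- pi / p$shape
      m <- p$scale * b / sin(b)
      c(mean = m, var = p$scale^2 * (2 * b / sin(2 * b) - (b / sin(b))^2))
    },
    gumbel = c(mean = p$loc + .euler_gamma * p$scale,
               var = pi^2 * p$scale^2 / 6),
    stop_input("unknown family: ", family)
  )
}

## moment-matched starting values from pseudo (midpoint) data
.family_start <- function(family, m, s) {
  s <- max(s, 1e-3 * max(abs(m), 1))
  switch(family,
    normal = list(mean = m, sd = s),
    gamma = {
      shape <- max((m / s)^2, 0.05)
      list(shape = shape, rate = max(shape / m, 1e-8))
    },
    exponential = list(rate = 1 / max(m, 1e-8)),
    lognormal = {
      cv2 <- (s / m)^2
      list(meanlog = base::log(m) - log1p(cv2) / 2,
           sdlog = sqrt(log1p(cv2)))
    },
    weibull = {
      ## crude CV-based shape start; optimizer refines
      shape <- max(min((m / s)^1.086, 50), 0.2)
      list(shape = shape, scale = m / gamma(1 + 1 / shape))
    },
    loglogistic = list(shape = max(pi / sqrt(3) * m / s, 2.2), scale = m),
    gumbel = {
      sc <- s * sqrt(6) / pi
      list(loc = m - .euler_gamma * sc, scale = sc)
    }
  )
}

## d/p/q/r for a resolved family; the in-package families are wired up here
## (they are NULL in the static table because they are defined in this file)
.family_fun <- function(fam, prefix) {
  fn <- fam[[prefix]]
  if (!is.null(fn)) return(fn)
  switch(paste0(prefix, fam$distname),
         dllogis = dllogis, pllogis = pllogis, qllogis = qllogis,
         rllogis = function(n, shape, scale)
           qllogis(runif(n), shape, scale),
         dgumbel = dgumbel, pgumbel = pgumbel, qgumbel = qgumbel,
         rgumbel = function(n, loc, scale) qgumbel(runif(n), loc, scale),
         stop_input("no ", prefix, " function for ", fam$name))
}
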