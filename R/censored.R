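#' Interval-censored exposure sample
#'
#' Survey exposure data reported as counts per interval. Intervals are
#' half-open `[low, high)`, ascending and non-overlapping; `high = Inf` marks
#' an open top interval and a degenerate `[0, 0]` interval represents a point
#' mass at zero (e.g. respondents reporting no alcohol consumption).
#'
#' @param low,high numeric interval bounds; `high` may be `Inf`.
#' @param count nonnegative integer count per interval; total must be > 0.
#' @return An object of class `censored_sample` (a data frame with columns
#'   `low`, `high`, `count`).
#' @examples
#' censored_sample(c(0, 0, 5, 10), c(0, 5, 10, Inf), c(120, 400, 300, 180))
#' @export
censored_sample <- function(low, high, count) {
  if (length(low) != length(high) || length(low) != length(count)) {
    stop_input("low, high and count must have equal length")
  }
  if (any(!is.finite(low)) || any(is.na(high)) || any(!is.finite(count))) {
    stop_input("interval bounds and counts must be numeric (high may be Inf)")
  }
  if (any(count < 0) || any(count != round(count))) {
    stop_input("counts must be nonnegative integers")
  }
  zero_iv <- low == 0 & high == 0
  if (any(high < low) || any(high[!zero_iv] <= low[!zero_iv])) {
    stop_input("intervals must satisfy low < high (or the [0,0] point mass)")
  }
  ord <- order(low, high)
  low <- low[ord]; high <- high[ord]; count <- count[ord]
  ## overlap check; the [0,0] point mass may abut a [0, x) interval
  if (length(low) > 1L) {
    prev_high <- head(high, -1L); nxt_low <- tail(low, -1L)
    ok <- nxt_low >= prev_high | (head(low, -1L) == 0 & prev_high == 0)
    if (!all(ok)) stop_input("intervals overlap")
  }
  if (sum(count) <= 0) stop_input("total count must be > 0")
  out <- data.frame(low = low, high = high, count = count)
  class(out) <- c("censored_sample", "data.frame")
  out
}

as_censored_sample <- function(x) {
  if (inherits(x, "censored_sample")) return(x)
  if (is.data.frame(x) && all(c("low", "high", "count") %in% names(x))) {
    return(censored_sample(x$low, x$high, x$count))
  }
  stop_input("expected a censored_sample (columns low, high, count)")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat("interval-censored sample:", sum(x$count), "observations in",
      nrow(x), "intervals\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

## expand counts to the left/right data frame the fitting backend expects;
## exact observations (low == high) get left == right
.expand_censdata <- function(sample, shift = 0) {
  left <- rep(sample$low, sample$count) + shift
  right <- rep(sample$high, sample$count) + shift
  data.frame(left = left, right = ifelse(is.finite(right), right, NA))
}

## pseudo-observations (interval representatives) for starting values
.pseudo_values <- function(sample, shift = 0) {
  rep_val <- ifelse(sample$high == sample$low, sample$low,
                    ifelse(is.finite(sample$high),
                           (sample$low + sample$high) / 2,
                           sample$low * 1.5 + 1))
  rep(rep_val + shift, sample$count)
}

#' Fit a parametric distribution to interval-censored data
#'
#' Maximum-likelihood fitting of a single distribution family to censored
#' survey counts, each interval contributing `[F(high) - F(low)]^count` to the
#' likelihood (point-mass intervals contribute the density). When the data
#' contain a zero interval and the family has positive support, a small
#' increment is added to both ends of every interval before fitting and
#' subtracted afterwards, so the returned distribution is on the original
#' scale (a shifted-family fit).
#'
#' @param sample a [censored_sample()].
#' @param family one of `r paste0('"', censored_families(), '"', collapse = ", ")`.
#' @param shift_increment increment (exposure units) used for distribution
#'   shifting; applied only when a zero interval is present and the family
#'   requires positive support. Default 0.01.
#' @return An object of class `fitted_censored` with elements `family`,
#'   `params` (named vector), `loglik`, `aic`, `bic`, `shift`, `n`.
#' @examples
#' s <- censored_sample(c(0, 2, 4, 8), c(2, 4, 8, Inf), c(30, 40, 20, 10))
#' fit_censored(s, "gamma")
#' @export
fit_censored <- function(sample, family = "gamma", shift_increment = 0.01) {
  sample <- as_censored_sample(sample)
  fam <- .resolve_family(family)
  if (shift_increment < 0) stop_input("shift_increment must be >= 0")
  if (sum(sample$count > 0) < 2L) {
    stop_input("degenerate sample: all mass in a single interval")
  }
  has_zero <- any(sample$low == 0 & sample$high == 0 & sample$count > 0)
  shift <- if (has_zero && fam$positive) shift_increment else 0
  cens <- .expand_censdata(sample, shift)
  pseudo <- .pseudo_values(sample, shift)
  start <- .family_start(fam$name, mean(pseudo), stats::sd(pseudo))
  fit <- tryCatch(
    fitdistrplus::fitdistcens(cens, fam$distname, start = start),
    error = function(e) stop_input(
      "censored fit did not converge for family '", fam$name, "': ",
      conditionMessage(e))
  )
  if (any(!is.finite(fit$estimate))) {
    stop_input("censored fit did not converge for family '", fam$name,
               "': non-finite estimates")
  }
  structure(list(
    family = fam$name,
    params = fit$estimate,
    loglik = as.numeric(logLik(fit)),
    aic = fit$aic,
    bic = fit$bic,
    shift = shift,
    n = sum(sample$count)
  ), class = "fitted_censored")
}

#' @export
print.fitted_censored <- function(x, ...) {
  cat(sprintf("censored %s fit (n = %d%s)\n", x$family, x$n,
              if (x$shift > 0) sprintf(", shift %g", x$shift) else ""))
  print(round(x$params, 5))
  cat(sprintf("  loglik %.3f, AIC %.2f, BIC %.2f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

## density / CDF / quantile of the fitted (un-shifted) exposure variable
.fit_d <- function(fit, x) {
  fam <- .resolve_family(fit$family)
  do.call(.family_fun(fam, "d"), c(list(x + fit$shift), as.list(fit$params)))
}

.fit_p <- function(fit, q) {
  fam <- .resolve_family(fit$family)
  do.call(.family_fun(fam, "p"), c(list(q + fit$shift), as.list(fit$params)))
}

.fit_q <- function(fit, p) {
  fam <- .resolve_family(fit$family)
  do.call(.family_fun(fam, "q"), c(list(p), as.list(fit$params))) - fit$shift
}

#' Analytic moments of a fitted exposure distribution
#'
#' @param fit a [fit_censored()] result.
#' @return Named vector with `mean` and `var` on the original exposure scale.
#' @export
fitted_moments <- function(fit) {
  stopifnot(inherits(fit, "fitted_censored"))
  m <- .family_moments(fit$family, fit$params)
  c(mean = unname(m["mean"]) - fit$shift, var = unname(m["var"]))
}

#' Select the best-fitting family for censored exposure data
#'
#' Fits each candidate family with [fit_censored()] and returns the one
#' minimising the chosen information criterion (or maximising the
#' log-likelihood). Candidates that fail to converge are dropped.
#'
#' @param sample a [censored_sample()].
#' @param candidates character vector of family names (>= 2 unless a single
#'   candidate is deliberately passed through).
#' @param criterion `"bic"` (default), `"aic"` or `"loglik"`.
#' @param shift_increment passed to [fit_censored()].
#' @return The winning `fitted_censored`, with a `comparison` attribute (a
#'   data frame of all candidates' metrics).
#' @export
select_family <- function(sample, candidates = c("normal", "gamma"),
                          criterion = c("bic", "aic", "loglik"),
                          shift_increment = 0.01) {
  criterion <- match.arg(criterion)
  fits <- list(); errs <- character()
  for (fam in candidates) {
    f <- tryCatch(fit_censored(sample, fam, shift_increment),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "fitted_censored")) fits[[fam]] <- f
    else errs <- c(errs, f)
  }
  if (!length(fits)) {
    stop_input("no candidate family converged: ",
               paste(errs, collapse = "; "))
  }
  metrics <- data.frame(
    family = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    row.names = NULL
  )
  score <- switch(criterion, bic = metrics$bic, aic = metrics$aic,
                  loglik = -metrics$loglik)
  best <- fits[[which.min(score)]]
  attr(best, "comparison") <- metrics
  best
}

#' Standard score of an exposure value under a fitted distribution
#'
#' `(x - mean) / sd` using the fitted family's analytic moments.
#'
#' @param fit a [fit_censored()] result with finite mean and variance.
#' @param x exposure value(s).
#' @return Standard score(s).
#' @export
standardize_score <- function(fit, x) {
  m <- fitted_moments(fit)
  if (!is.finite(m["var"]) || m["var"] <= 0) {
    stop_input("fitted distribution has undefined or zero variance")
  }
  (x - m["mean"]) / sqrt(m["var"])
}

#' Discretize a fitted continuous exposure into a risk factor
#'
#' Converts a fitted exposure distribution plus a per-unit log odds ratio into
#' a categorical [risk_factor()]: each bin becomes a level whose population
#' probability is the fitted mass in the bin and whose log odds ratio is the
#' per-unit effect applied to the bin's representative exposure (the
#' conditional mean of the fitted distribution within the bin) relative to
#' `reference`.
#'
#' @param fit a [fit_censored()] result.
#' @param per_unit_log_or log odds ratio per `unit` of exposure (e.g.
#'   `log(1.06)` per 5 drinks/week gives `unit = 5`).
#' @param unit exposure units corresponding to `per_unit_log_or` (default 1).
#' @param reference exposure value with log odds ratio 0 (default 0).
#' @param bin_edges interior bin edges; default the fitted 10/35/65/90
#'   percentiles (5 bins).
#' @param name factor name.
#' @param modifiable passed to [risk_factor()].
#' @param floor_at_reference if TRUE, exposures below `reference` carry no
#'   effect (the BMI convention: no excess risk below the normal/low
#'   threshold).
#' @param transform optional monotone transform applied to the representative
#'   value and the reference before differencing (e.g. a clamped `log2` for
#'   effects per doubling of a standardized score).
#' @return A [risk_factor()]; zero-mass bins are dropped with a warning and
#'   the remaining probabilities renormalised.
#' @export
discretize_exposure <- function(fit, per_unit_log_or, unit = 1, reference = 0,
                                bin_edges = NULL, name = "exposure",
                                modifiable = TRUE,
                                floor_at_reference = FALSE,
                                transform = NULL) {
  stopifnot(inherits(fit, "fitted_censored"))
  if (!is.finite(per_unit_log_or)) stop_input("per-unit effect must be finite")
  if (is.null(bin_edges)) {
    bin_edges <- .fit_q(fit, c(0.10, 0.35, 0.65, 0.90))
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_input("bin edges must be strictly ascending")
  }
  fam <- .resolve_family(fit$family)
  lo_support <- if (fam$positive) -fit$shift else -Inf
  edges <- c(lo_support, bin_edges, Inf)
  low <- head(edges, -1L); high <- tail(edges, -1L)
  mass <- .fit_p(fit, high) - .fit_p(fit, low)
  keep <- mass > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-mass bin(s) in factor '%s'",
                    sum(!keep), name))
    low <- low[keep]; high <- high[keep]; mass <- mass[keep]
  }
  mass <- mass / sum(mass)
  rep_val <- mapply(function(l, h, m) {
    stats::integrate(function(x) x * .fit_d(fit, x), l, h,
                     rel.tol = 1e-8)$value / m
  }, low, high, mass)
  eff <- if (!is.null(transform)) {
    transform(rep_val) - transform(reference)
  } else if (floor_at_reference) {
    pmax(rep_val - reference, 0)
  } else {
    rep_val - reference
  }
  beta <- per_unit_log_or * eff / unit
  labels <- sprintf("[%s,%s)", formatC(low, format = "g"),
                    formatC(high, format = "g"))
  risk_factor(name, labels, mass, exp(beta), modifiable = modifiable)
}
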