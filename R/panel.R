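#' Construct a SNP risk panel
#'
#' A risk panel holds one row per susceptibility variant: its risk-allele
#' frequency and per-allele odds ratio. Under the log-additive model each
#' variant contributes two independent allele draws, so a variant with
#' frequency p and log odds ratio beta adds 2*p*beta to the mean polygenic
#' score and 2*p*(1-p)*beta^2 to its variance.
#'
#' @param id character vector of variant labels (unique).
#' @param freq risk-allele frequencies, all strictly inside (0, 1).
#' @param or_per_allele per-allele odds ratios, all > 0. Values below 1 denote
#'   protective alleles and are stored as given.
#' @return A `risk_panel` data frame with columns `id`, `freq`,
#'   `or_per_allele` and `beta` (the log odds ratio).
#' @examples
#' risk_panel("rs1", 0.3, 1.2)
#' @export
risk_panel <- function(id, freq, or_per_allele) {
  if (length(id) == 0L) stop_input("empty panel")
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop_input("duplicate variant ids: ",
               paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(freq) != length(id) || length(or_per_allele) != length(id)) {
    stop_input("id, freq and or_per_allele must have equal length")
  }
  bad_f <- !is.finite(freq) | freq <= 0 | freq >= 1
  if (any(bad_f)) {
    stop_input("risk-allele frequency outside (0, 1) for variant(s): ",
               paste(id[bad_f], collapse = ", "))
  }
  bad_or <- !is.finite(or_per_allele) | or_per_allele <= 0
  if (any(bad_or)) {
    stop_input("odds ratio must be > 0 for variant(s): ",
               paste(id[bad_or], collapse = ", "))
  }
  out <- data.frame(id = id, freq = as.numeric(freq),
                    or_per_allele = as.numeric(or_per_allele),
                    beta = log(as.numeric(or_per_allele)),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_panel", "data.frame")
  out
}

as_risk_panel <- function(x) {
  if (inherits(x, "risk_panel")) return(x)
  if (is.data.frame(x) && all(c("id", "freq", "or_per_allele") %in% names(x))) {
    return(risk_panel(x$id, x$freq, x$or_per_allele))
  }
  stop_input("not a risk panel: need columns id, freq, or_per_allele")
}

#' Moments of the polygenic risk score distribution
#'
#' Computes the normal-approximation parameters of the polygenic risk score
#' (PRS) on the log relative-risk scale. Each SNP contributes
#' `2*p*(1-p)*beta^2` to the variance. When `center = TRUE` the mean is set to
#' `-sigma2/2`, which makes the population mean relative risk exactly 1; when
#' `FALSE` the raw mean `sum(2*p*beta)` is kept.
#'
#' @param panel a [risk_panel()] (or data frame coercible to one).
#' @param center logical; centre the distribution so the mean RR is 1
#'   (default `TRUE`).
#' @return A [risk_distribution()] with per-SNP variance components.
#' @examples
#' pan <- risk_panel("rs1", 0.3, 1.2)
#' prs_moments(pan)$sigma2  # 2 * 0.3 * 0.7 * log(1.2)^2
#' @export
prs_moments <- function(panel, center = TRUE) {
  panel <- as_risk_panel(panel)
  comp <- 2 * panel$freq * (1 - panel$freq) * panel$beta^2
  names(comp) <- panel$id
  sigma2 <- sum(comp)
  mu <- if (center) -sigma2 / 2 else sum(2 * panel$freq * panel$beta)
  risk_distribution(mu = mu, sigma2 = sigma2, components = comp)
}

#' Minimum and maximum risk-allele counts for a PRS threshold
#'
#' Derives the smallest and largest number of risk alleles compatible with a
#' polygenic score at or above `prs_thresh`. Allele slots (two per SNP) are
#' sorted by the gap between the log odds ratio and 0; descending order yields
#' the minimum count (the most efficient alleles first), ascending order the
#' maximum (the least efficient first). A protective allele (OR < 1)
#' contributes a risk term of 0 and a non-risk term equal to its negative log
#' OR, so carrying the non-protective allele is what counts as a risk allele.
#'
#' @param panel a [risk_panel()].
#' @param prs_thresh threshold on the uncentred log relative-risk (PRS) scale.
#'   `-Inf` is allowed and gives a minimum count of 0.
#' @return A list with elements `min_count` and `max_count`.
#' @details Ties in the allele sort are broken by variant id so results are
#'   deterministic. Threshold comparisons use "at or above" with an absolute
#'   tolerance of 1e-12.
#' @examples
#' pan <- risk_panel(c("a", "b", "c"), c(0.3, 0.4, 0.2), c(1.5, 1.2, 0.9))
#' allele_count_bounds(pan, 0.7)
#' @export
allele_count_bounds <- function(panel, prs_thresh) {
  panel <- as_risk_panel(panel)
  ## two allele slots per SNP, each with a risk term r and a non-risk term n
  slot <- data.frame(
    id  = rep(panel$id, each = 2L),
    r   = rep(pmax(panel$beta, 0), each = 2L),
    n   = rep(pmin(panel$beta, 0), each = 2L),
    stringsAsFactors = FALSE
  )
  gain <- slot$r - slot$n   # = |beta|, the PRS increase from taking the slot
  max_prs <- sum(slot$r)
  if (prs_thresh > max_prs + .thresh_tol) {
    stop_input("threshold exceeds maximum PRS (", format(max_prs), ")")
  }
  count_for <- function(decreasing) {
    ord <- order(gain, slot$id, decreasing = decreasing)
    r_s <- slot$r[ord]; n_s <- slot$n[ord]
    ## PRS when the first j sorted slots are taken as risk alleles
    prs_j <- c(sum(n_s), sum(n_s) + cumsum(r_s - n_s))
    which(prs_j >= prs_thresh - .thresh_tol)[1L] - 1L
  }
  list(min_count = count_for(TRUE), max_count = count_for(FALSE))
}

#' @export
print.risk_panel <- function(x, ...) {
  cat("SNP risk panel:", nrow(x), "variants\n")
  cat("  per-allele OR range:", format(range(x$or_per_allele), digits = 3), "\n")
  cat("  polygenic variance (2p(1-p)b^2 sum):",
      format(sum(2 * x$freq * (1 - x$freq) * x$beta^2), digits = 4), "\n")
  invisible(x)
}
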