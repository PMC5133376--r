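## Independent brute-force oracles used across the suite.

## exact PRS moments by exhaustive enumeration of genotype combinations under
## Hardy-Weinberg and the log-additive model (feasible for <= 6 SNPs)
enum_prs_moments <- function(panel) {
  I <- nrow(panel)
  combos <- as.matrix(expand.grid(rep(list(0:2), I)))
  probs <- rep(1, nrow(combos))
  for (i in seq_len(I)) {
    p <- panel$freq[i]
    g <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
    probs <- probs * g[combos[, i] + 1L]
  }
  prs <- drop(combos %*% panel$beta)
  m <- sum(probs * prs)
  list(mean = m, var = sum(probs * prs^2) - m^2)
}

## exhaustive allele-count bounds: a risk allele at a protective SNP is the
## non-protective allele, so count = sum(c | beta>0) + sum(2-c | beta<0)
enum_allele_bounds <- function(panel, thresh, tol = 1e-12) {
  I <- nrow(panel)
  combos <- as.matrix(expand.grid(rep(list(0:2), I)))
  prs <- drop(combos %*% panel$beta)
  cnt <- drop(combos %*% ifelse(panel$beta > 0, 1, -1)) +
    2 * sum(panel$beta < 0)
  min_count <- min(cnt[prs >= thresh - tol])
  min_prs_by_count <- tapply(prs, cnt, min)
  counts <- as.numeric(names(min_prs_by_count))
  max_count <- min(counts[min_prs_by_count >= thresh - tol])
  list(min_count = min_count, max_count = max_count)
}

## constant-hazard competing-risk closed form
constant_hazard_risk <- function(h, m, T) {
  if (h + m == 0) return(0)
  h / (h + m) * (1 - exp(-(h + m) * T))
}

## flat rate table for the life-table oracle
flat_rates <- function(h, m, ages = 0:99, pop = 1e5) {
  rate_table(ages, rep(h, length(ages)), rep(0, length(ages)),
             rep(m, length(ages)), rep(pop, length(ages)))
}
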