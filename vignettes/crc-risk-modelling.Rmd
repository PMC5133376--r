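---
title: "Modelling colorectal cancer risk stratification from polygenic and lifestyle factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colorectal cancer risk stratification from polygenic and lifestyle factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrisk)
```

## The risk model

Colorectal cancer susceptibility is shaped by many common variants of small
effect and by a handful of well-established nongenetic factors. `crcrisk`
models the population distribution of relative risk (RR) analytically rather
than by individual-level simulation.

Under a log-additive model, an individual's polygenic risk score (PRS) is the
sum over risk alleles of allele count times log odds ratio. With allele
frequencies $p_i$ and per-allele log odds ratios $\beta_i$, the PRS is
approximately normal with

$$\mu = \sum_i 2 p_i \beta_i, \qquad
  \sigma^2 = \sum_i 2 p_i (1 - p_i) \beta_i^2,$$

so RR is log-normal in the population. Two standard results drive everything
else. First, the score distribution among future cases is the population
distribution displaced right by $\sigma^2$ on the log scale. Second, setting
$\mu = -\sigma^2/2$ makes the population mean RR exactly 1, so absolute risks
averaged over the population reproduce the baseline rates.

Nongenetic factors are treated exactly like alleles: a factor with levels
$k$, population probabilities $p_k$ and level log odds ratios $\beta_k$
contributes $\sum_k p_k \beta_k$ to the mean and
$\sum_k p_k \beta_k^2 - (\sum_k p_k \beta_k)^2$ to the variance. This rests
on two assumptions that should be kept in mind when interpreting results:
genetic and lifestyle risks multiply (no gene–environment interaction), and
the factors are mutually independent (the level odds ratios come from
meta-analyses adjusted for the other factors, which mitigates but does not
remove this).

From a centred distribution:

```{r closed-forms}
d <- risk_distribution(sigma2 = 0.21)   # known-variant polygenic variance
percentile_rr(d, c(0.10, 0.50, 0.90, 0.99))  # RR vs the population median
risk_auc(d)                                  # Phi(sigma / sqrt(2))
```

Percentile RRs are reported against the population median as the
percentile-point values $e^{\sigma z_q}$. An alternative reading — the mean
RR within a percentile bin — gives systematically different numbers (a
truncated log-normal mean); the point-value convention is the one that
matches the published headline figures for this model class, so it is the
package default and the only convention used here.

The AUC uses the case displacement directly: a case and a control score
differ by $N(\sigma^2, 2\sigma^2)$, so
$\mathrm{AUC} = \Phi(\sigma/\sqrt 2)$. A Monte-Carlo method
(`risk_auc(..., method = "monte_carlo")`) exists purely as a cross-check and
agrees within sampling error.

### Allele-count bounds

For communication it is useful to translate a PRS percentile into "how many
risk alleles". Each SNP contributes two allele slots; a slot taken as a risk
allele adds its risk log OR $r_i$ ($0$ for a protective allele) and a slot
not taken adds its non-risk log OR $n_i$ ($\ln \mathrm{OR} < 0$ for a
protective allele — the risk choice at a protective SNP is *not* carrying
it). Sorting slots by $|\beta|$ descending and taking them greedily yields
the minimum count needed to reach a threshold; ascending order yields the
count that guarantees it (the maximum needed). Both are validated in the test
suite against exhaustive enumeration of all genotype combinations for small
panels, where the greedy and the brute force agree exactly.

### Projecting undiscovered variants

The known variants explain a minority of the familial risk (taken as an
input constant, 14.5%, with heritability arguments putting all common
variants at 55%). `project_variance()` scales $\sigma^2$ linearly with the
fraction of familial risk explained. The projection rule is not uniquely
determined by the published statistics — back-solving the extended models'
top-1% RRs implies variances about 3–5% below pure linear scaling — so the
linear rule is the default and a calibration multiplier is exposed
(`calibration = 1` by default) rather than hard-coding either choice.

## Fitting interval-censored exposure data

Health-survey exposures arrive as counts per interval, often with a point
mass at zero (non-drinkers, non-exercisers). `fit_censored()` maximises the
interval-censored likelihood $\prod_j [F(h_j) - F(l_j)]^{c_j}$ (point-mass
intervals contribute the density) for seven families: normal, gamma,
exponential, log-normal, log-logistic, Weibull, Gumbel.
`select_family()` compares them by BIC (default; AIC and log-likelihood are
available) — in practice normal for BMI and gamma for the right-tailed
consumption and activity exposures.

Numerical choices:

- **Shifting.** When a zero interval is present and the family has positive
  support, `shift_increment` (default 0.01 exposure units) is added to both
  ends of every interval before fitting and subtracted afterwards, so the
  returned distribution sits on the original scale. The increment only needs
  to be small relative to the first interval width; results are insensitive
  to its exact value.
- **Starting values** are moment-matched from interval midpoints (the open
  top interval uses 1.5× its lower bound); the fitting engine is
  `fitdistrplus::fitdistcens`, the standard maximum-likelihood tool for
  censored univariate data. Non-convergence raises an explicit error rather
  than returning a partial fit.
- **Degenerate inputs** (all mass in one interval) are rejected.

```{r censored-demo}
survey <- synth_survey("gamma", list(shape = 2, rate = 0.5), n = 5000,
                       bin_edges = c(0, 1, 2, 4, 6, 8, 12, 20),
                       zero_inflation = 0.15, seed = 42)
fit <- select_family(survey, c("normal", "gamma"))
fit
```

### Discretization into factor levels

`discretize_exposure()` turns a fitted exposure plus a per-unit log OR (e.g.
OR 1.06 per five drinks per week, 1.29 per 8 kg/m² above a BMI of 25) into a
categorical factor. Each bin's probability is the fitted mass; its effect is
the per-unit log OR applied to the bin's **conditional mean** under the
fitted distribution — the unbiased representative for a log-linear effect,
preferred over the midpoint, which has no defensible value for open-ended
bins. Defaults: 5 bins at the fitted 10/35/65/90 percentiles, a compromise
between resolution (between-bin variance captures ~88% of the continuous
effect variance for a gamma exposure at the default settings, verified in
the test suite) and the sparsely populated extremes of survey data.
Floor effects (`floor_at_reference = TRUE`) zero the effect below the
reference, matching the BMI convention of no excess risk at or below
25 kg/m². Physical activity's effect (OR 0.88 per doubling of the
standardized score) is applied through a clamped `log2` transform of the
standard score shifted to positive support; the clamp (at 0.05) only affects
the lowest-activity bin and avoids an undefined logarithm at zero activity.

### Lifestyle bounds

`lifestyle_bounds()` computes the average, minimum and maximum log-risk
scores attainable from the modifiable factors, restricting the extremes to
levels with nonzero population probability — bounds describe lifestyles that
actually occur, not mathematical extremes of a fitted tail.
`individual_rr()` then gives the RR of an individual at any host-risk
percentile with a healthy, average or unhealthy lifestyle, relative to the
median individual with an average lifestyle.

## Absolute risk

`age_conditional_risk()` is a competing-risk life table on 1-year age bands:
with diagnosis hazard $h(a) = \mathrm{RR} \cdot \mathrm{incidence}(a)$ and
other-cause mortality $m(a)$, each band contributes
$\frac{h}{h+m}(1 - e^{-(h+m)})$ discounted by event-free survival to the band
start. Hazards are constant within a band, so for flat schedules the
implementation reproduces the closed form
$\frac{h}{h+m}(1 - e^{-(h+m)T})$ to machine precision — the oracle the test
suite checks across a grid of hazards and horizons. The RR multiplies the
incidence hazard only; competing mortality stays at baseline, which is
consistent with a centred distribution whose mean RR is 1.

`stratified_identification()` inverts the life table (monotone bisection on
the risk scale) to find the RR at which a band member's absolute risk
reaches a benchmark — e.g. the 10-year risk of an average 60-year-old, the
screening-entry age — and reports the fractions of the population and of
cases at or above it. Ages within a pooled band are averaged with population
weights. `prevention_impact()` computes risk differences when a scenario's
modifiable factors are set to their lowest-risk observed levels ("all",
"aspirin only", or everything but aspirin), scaled to a cohort and rounded
to the nearest 10, the conventional reporting granularity for such
projections.

## Synthetic data: what it emulates and what it does not

The real inputs — survey exposure tables, registry incidence and mortality —
are restricted, so the package generates synthetic stand-ins. Their defaults
were fixed once, on the following reasoning, and are not tuned to any
downstream statistic:

- **SNP panels** (`synth_panel()`): frequencies uniform on (0.05, 0.95), OR
  magnitudes log-uniform on (1.02, 1.6) with 15% protective — the range
  typical of GWAS hits for this cancer — optionally rescaled by a common
  factor on the log-OR scale so the panel variance equals a stated value
  (0.21 for the known-variant panel).
- **Exposure surveys** (`synth_survey()`, `synth_factor_suite()`):
  zero-inflated gamma shapes for alcohol (mean 15 drinks/week, 15%
  abstainers), red meat, fruit, vegetables and activity, and normal BMI
  (mean 27.2, sd 4.2 kg/m²), approximating English male survey
  distributions; binary smoking (55% ever), aspirin (4.6% long-term use, the
  during-follow-up figure from the cohort study the effect estimate comes
  from; the enrolment figure 2.3% is available by argument) and IBD (4 per
  10,000, OR 2.93).
- **Rate tables** (`synth_rates()`): Gompertz incidence and mortality
  (exponential growth rates 0.09 and 0.085 per year of age), CRC mortality
  at 45% of incidence, and a calibration mode that rescales incidence so the
  baseline 10-year risk at 60 equals 1.96% — the screening benchmark — so
  threshold analyses are exercised on a realistic scale.

Passing tests on these inputs demonstrates that the *machinery* is correct
(moments, fitting, life table, bisection, bounds); it does not certify the
published population-specific numbers that depend on the real registry and
survey tables (identification percentages, prevented-case counts). Those
quantities are covered instead by exact oracles for each computational step,
and the synthetic end-to-end runs reproduce their orders of magnitude.

Problem sizes used in the test suite — 10,000 respondents per fitted survey,
$10^6$ Monte-Carlo pairs for the AUC cross-check, enumeration oracles up to 8
allele slots — were chosen as the smallest sizes at which the stated
tolerances (±10% parameter recovery, 3 standard errors, exact agreement) are
statistically meaningful.

## Known limitations

- The log-normal RR model is an approximation to the discrete PRS
  distribution; excellent for ~37 variants and better as panels grow, but
  not exact for very small panels (where the enumeration oracle is).
- Independence and multiplicativity of factors are assumed, not tested;
  correlated lifestyle factors would inflate the combined variance.
- The analysis is confined to men; female rate tables and exposure
  distributions would be needed for women.
- Family history is deliberately not modelled.
- Absolute risks carry no sampling uncertainty: inputs are treated as fixed
  population quantities, so no confidence intervals are produced.
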