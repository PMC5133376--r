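## Delimited-file readers/writers for the package's tabular inputs, and the
## six-model report runner. All files are tab-separated with fixed headers.

.read_tsv <- function(path, expected_header) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!identical(names(df), expected_header)) {
    stop_input("unexpected header in ", path, ": got '",
               paste(names(df), collapse = "  "), "', expected '",
               paste(expected_header, collapse = "  "), "'")
  }
  df
}

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (anyNA(v) && length(bad)) {
      stop_input("non-numeric value in column '", cl, "' of ", path,
                 " (row ", bad[1L] + 1L, " of file)")
    }
    df[[cl]] <- v
  }
  df
}

#' Read and write SNP panel files
#'
#' Tab-separated, header `id  risk_allele_freq  or_per_allele`, one row per
#' variant. Validation errors name the offending row.
#'
#' @param path file path.
#' @return `read_panel` a [risk_panel()]; `write_panel` the path, invisibly.
#' @export
read_panel <- function(path) {
  df <- .read_tsv(path, c("id", "risk_allele_freq", "or_per_allele"))
  df <- .check_numeric(df, c("risk_allele_freq", "or_per_allele"), path)
  risk_panel(df$id, df$risk_allele_freq, df$or_per_allele)
}

#' @rdname read_panel
#' @param panel a [risk_panel()].
#' @export
write_panel <- function(panel, path) {
  panel <- as_risk_panel(panel)
  out <- data.frame(id = panel$id, risk_allele_freq = panel$freq,
                    or_per_allele = panel$or_per_allele)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write risk-factor files
#'
#' Tab-separated, header `factor  level  prob  or_level  modifiable`; rows of
#' one factor must be contiguous.
#'
#' @param path file path.
#' @return `read_factors` a named list of [risk_factor()]s; `write_factors`
#'   the path, invisibly.
#' @export
read_factors <- function(path) {
  df <- .read_tsv(path, c("factor", "level", "prob", "or_level", "modifiable"))
  df <- .check_numeric(df, c("prob", "or_level"), path)
  out <- list()
  for (nm in unique(df$factor)) {
    rows <- df[df$factor == nm, ]
    mod <- unique(as.logical(rows$modifiable))
    if (length(mod) != 1L || is.na(mod)) {
      stop_input("inconsistent modifiable flag for factor '", nm, "' in ",
                 path)
    }
    out[[nm]] <- risk_factor(nm, rows$level, rows$prob, rows$or_level,
                             modifiable = mod)
  }
  out
}

#' @rdname read_factors
#' @param factors a list of [risk_factor()]s.
#' @export
write_factors <- function(factors, path) {
  if (inherits(factors, "risk_factor")) factors <- list(factors)
  rows <- do.call(rbind, lapply(factors, function(f) {
    data.frame(factor = f$name, level = f$levels$label,
               prob = f$levels$prob, or_level = f$levels$or_level,
               modifiable = f$modifiable)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write interval-censored survey files
#'
#' Tab-separated, header `low  high  count`; `high = inf` marks the open top
#' interval.
#'
#' @param path file path.
#' @return `read_survey` a [censored_sample()]; `write_survey` the path,
#'   invisibly.
#' @export
read_survey <- function(path) {
  df <- .read_tsv(path, c("low", "high", "count"))
  df$high[tolower(df$high) %in% c("inf", "+inf", "infinity")] <- "Inf"
  df <- .check_numeric(df, c("low", "high", "count"), path)
  censored_sample(df$low, df$high, df$count)
}

#' @rdname read_survey
#' @param sample a [censored_sample()].
#' @export
write_survey <- function(sample, path) {
  sample <- as_censored_sample(sample)
  out <- data.frame(low = sample$low,
                    high = ifelse(is.finite(sample$high),
                                  as.character(sample$high), "inf"),
                    count = sample$count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write rate-table files
#'
#' Tab-separated, header
#' `age  incidence  crc_mortality  all_cause_mortality  population`;
#' other-cause mortality is derived on read. Missing age bands raise a
#' contiguity error.
#'
#' @param path file path.
#' @return `read_rate_table` a [rate_table()]; `write_rate_table` the path,
#'   invisibly.
#' @export
read_rate_table <- function(path) {
  df <- .read_tsv(path, c("age", "incidence", "crc_mortality",
                          "all_cause_mortality", "population"))
  df <- .check_numeric(df, names(df), path)
  rate_table(df$age, df$incidence, df$crc_mortality, df$all_cause_mortality,
             df$population)
}

#' @rdname read_rate_table
#' @param rates a [rate_table()].
#' @export
write_rate_table <- function(rates, path) {
  rates <- as_rate_table(rates)
  out <- rates[c("age", "incidence", "crc_mortality", "all_cause_mortality",
                 "population")]
  write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- six-model runner ------------------------------------------------------

#' Run one of the six stratification models
#'
#' The six models pair three genetic scenarios with and without the
#' nongenetic factors: models 1/2 use the known-SNP panel variance; models
#' 3/4 project it to half of all risk variants (27.5% of familial risk);
#' models 5/6 to all variants (55%). Odd models are genetics-only; even
#' models add IBD and the modifiable factors.
#'
#' @param model_id integer 1–6.
#' @param panel a [risk_panel()] (the known-SNP panel).
#' @param factors list of nongenetic [risk_factor()]s (IBD plus modifiable),
#'   required for even models.
#' @param rates optional [rate_table()]; if given, the report includes the
#'   higher-risk identification percentages for the 55–59 band against the
#'   10-year risk of an average 60-year-old.
#' @param frac_known fraction of familial risk the panel explains (default
#'   0.145).
#' @param frac_half,frac_all projection targets for models 3/4 and 5/6
#'   (defaults 0.275 and 0.55).
#' @param calibration passed to [project_variance()].
#' @param percentiles percentiles reported (default 1/10/50/90/99).
#' @return A `model_report` list: `model_id`, `mu`, `sigma2`, `auc`,
#'   `percentile_rr`, variance `components`, and (with rates)
#'   `identification`.
#' @examples
#' rep1 <- run_model(1, synth_panel(37, target_sigma2 = 0.21, seed = 1))
#' rep1$auc
#' @export
run_model <- function(model_id, panel, factors = list(), rates = NULL,
                      frac_known = 0.145, frac_half = 0.275, frac_all = 0.55,
                      calibration = 1,
                      percentiles = c(0.01, 0.1, 0.5, 0.9, 0.99)) {
  if (!model_id %in% 1:6) stop_input("model_id must be 1..6")
  include_factors <- model_id %% 2L == 0L
  if (include_factors && !length(factors)) {
    stop_input("model ", model_id, " requires nongenetic risk factors")
  }
  gen <- prs_moments(panel, center = TRUE)
  if (model_id %in% c(3, 4, 5, 6)) {
    target <- if (model_id %in% c(3, 4)) frac_half else frac_all
    s2 <- project_variance(gen$sigma2, frac_known, target, calibration)
    gen <- risk_distribution(sigma2 = s2,
                             components = c(projected_genetics = s2))
  }
  dist <- if (include_factors) combine_risk(gen, factors) else gen
  report <- list(
    model_id = model_id,
    mu = dist$mu,
    sigma2 = dist$sigma2,
    auc = risk_auc(dist),
    percentile_rr = setNames(percentile_rr(dist, percentiles),
                             paste0("p", percentiles * 100)),
    components = dist$components
  )
  if (!is.null(rates)) {
    thr <- eligibility_threshold(rates, 60, 10)
    ident <- stratified_identification(rates, dist, 55:59, thr, horizon = 10)
    report$identification <- c(threshold_risk = thr,
                               pct_population = ident$pct_population,
                               pct_cases = ident$pct_cases,
                               rr_star = ident$rr_star)
  }
  class(report) <- "model_report"
  report
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model %d: sigma2 = %.4f, AUC = %.2f\n",
              x$model_id, x$sigma2, round(x$auc, 2)))
  rr <- round(x$percentile_rr, 1)
  cat("  RR vs median at percentiles:",
      paste(names(rr), format(rr, nsmall = 1), collapse = ", "), "\n")
  if (!is.null(x$identification)) {
    cat(sprintf(paste0("  higher-risk (>= %.2f%% 10-year risk): %.1f%% of",
                       " population, %.1f%% of cases\n"),
                100 * x$identification[["threshold_risk"]],
                round(x$identification[["pct_population"]], 1),
                round(x$identification[["pct_cases"]], 1)))
  }
  invisible(x)
}

#' Rounded report values at the publication's precision
#'
#' AUC to 2 decimals, relative risks to 1 decimal, percentages to 1 decimal —
#' the precision used for report parity checks.
#'
#' @param report a [run_model()] result.
#' @return Named list of rounded values.
#' @export
report_rounded <- function(report) {
  stopifnot(inherits(report, "model_report"))
  out <- list(auc = round(report$auc, 2),
              percentile_rr = round(report$percentile_rr, 1))
  if (!is.null(report$identification)) {
    out$pct_population <- round(report$identification[["pct_population"]], 1)
    out$pct_cases <- round(report$identification[["pct_cases"]], 1)
  }
  out
}
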