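# Reported quantities: OCD prevalence among unselected offspring,
# standardized performance gain, BVE accuracy for the breeding-stallion
# cohort, mean kinship, and the across-replicate trend regression.

#' OCD prevalence of a cohort
#'
#' Fraction of animals whose underlying liability exceeds the trait
#' threshold (the radiographic status), evaluated regardless of whether an
#' OCD record was created, so that reference scenarios without OCD
#' recording still have prevalence trajectories.
#'
#' @param status 0/1 vector of liability status for the cohort.
#' @return Proportion in `[0, 1]`.
#' @export
ocd_prevalence <- function(status) {
  if (length(status) == 0) stop("empty cohort")
  mean(status)
}

#' Standardized performance gain
#'
#' Equal-weighted mean over the traits of the 50-day performance test of the
#' cohort's mean true genomic value, expressed as a deviation from the
#' year-0 baseline in founder genetic standard deviations.
#'
#' @param tbv matrix of true genomic values (cohort x traits, named
#'   columns).
#' @param baseline_mean named per-trait baseline (year-0) TBV means.
#' @param genetic_sd named per-trait founder genetic standard deviations.
#' @param traits trait keys to combine (default: the six 50-day traits).
#' @return Gain in genetic standard deviations.
#' @export
performance_gain <- function(tbv, baseline_mean, genetic_sd,
                             traits = .keys$test_50day) {
  if (is.null(baseline_mean)) stop("missing baseline")
  mean((colMeans(tbv[, traits, drop = FALSE]) - baseline_mean[traits]) /
         genetic_sd[traits])
}

#' Across-replicate trend regression
#'
#' Ordinary least squares of the across-replicate yearly means on year,
#' with the 95% confidence interval of the slope from the t-distribution on
#' `n_years - 2` degrees of freedom, and the fitted change over a 20-year
#' horizon.
#'
#' @param years,values yearly means (at least 3 years).
#' @param horizon horizon for the fitted change (default 20 years).
#' @return List with `slope`, `intercept`, `ci` (length-2 vector),
#'   `change` (slope x horizon).
#' @export
replicate_trend <- function(years, values, horizon = 20) {
  n <- length(years)
  if (n < 3) stop("need at least 3 years")
  xb <- mean(years); yb <- mean(values)
  sxx <- sum((years - xb)^2)
  sl <- sum((years - xb) * (values - yb)) / sxx
  ic <- yb - sl * xb
  res <- values - ic - sl * years
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tq <- qt(0.975, df = n - 2)
  list(slope = sl, intercept = ic,
       ci = c(sl - tq * se, sl + tq * se),
       change = sl * horizon)
}

# across-replicate yearly means of one metric
yearly_means <- function(results, metric) {
  m <- results$metrics
  m <- m[m$metric == metric, , drop = FALSE]
  agg <- tapply(m$value, m$year, mean, na.rm = TRUE)
  list(years = as.numeric(names(agg)), values = as.numeric(agg))
}

#' Trend summary of a scenario metric
#'
#' Convenience wrapper: across-replicate yearly means of one metric from a
#' [run_scenario()] result, passed through [replicate_trend()].
#'
#' @param results a `scenario_results` object.
#' @param metric metric name (e.g. `"ocd_fj_prev"`).
#' @param horizon change horizon in years.
#' @return As [replicate_trend()].
#' @export
scenario_trend <- function(results, metric, horizon = 20) {
  ym <- yearly_means(results, metric)
  replicate_trend(ym$years, ym$values, horizon)
}

#' Final-window accuracy report
#'
#' Mean OCD EBV accuracy of the breeding-stallion cohort over the final
#' `window` reporting years, averaged across replicates.
#'
#' @param results a `scenario_results` object.
#' @param metric accuracy metric name (`"acc_ocd_fj"` or `"acc_ocd_hj"`).
#' @param window number of final years to average (default 5).
#' @return Mean accuracy (may be `NA` for scenarios without OCD
#'   evaluation).
#' @export
accuracy_report <- function(results, metric = "acc_ocd_fj", window = 5) {
  m <- results$metrics
  m <- m[m$metric == metric, , drop = FALSE]
  ymax <- max(m$year)
  mean(m$value[m$year > ymax - window], na.rm = TRUE)
}

#' Across-replicate mean of a metric at one reporting year
#' @param results a `scenario_results` object.
#' @param metric metric name.
#' @param year reporting year.
#' @return Mean value across replicates.
#' @export
metric_at_year <- function(results, metric, year) {
  m <- results$metrics
  mean(m$value[m$metric == metric & m$year == year], na.rm = TRUE)
}

#' Write / read the long metric table
#'
#' Values are serialized at full precision so the table round-trips
#' bit-exactly.
#'
#' @param results a `scenario_results` object (or its `metrics` table).
#' @param file path.
#' @export
write_metrics <- function(results, file) {
  m <- if (inherits(results, "scenario_results")) results$metrics
       else results
  m$value <- sprintf("%.17g", m$value)
  write.table(m, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(file) {
  d <- read.table(file, header = TRUE, sep = ",",
                  colClasses = c("character", "integer", "integer",
                                 "character", "numeric"))
  d
}
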