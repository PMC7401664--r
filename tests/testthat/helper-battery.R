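# Scenario battery shared by the acceptance tests (computed once per test
# run). The seven scenarios carrying quantitative prevalence/accuracy
# checks run at the full desk-scale setup (scale 0.1, 10 replicates,
# 20 years); the remaining scenarios, needed only for the across-scenario
# gain bound and directional genomic comparisons, run with fewer
# replicates.
.battery_cache <- new.env()

acceptance_battery <- function() {
  if (!exists("bat", envir = .battery_cache)) {
    key <- c("Reference", "ThreshSel1", "ThreshSel2", "ThreshSelFJ",
             "ThreshSelHJ", "IndexBVE1", "IndexBVE2")
    extra <- c("IndexLicensing1", "IndexLicensing2")
    genomic <- c("ReferenceG", "IndexBVEG2", "IndexLicensingG1",
                 "IndexLicensingG2")
    bat <- c(run_acceptance_battery(seed = 1, replicates = 10,
                                    scenarios = key, verbose = FALSE),
             run_acceptance_battery(seed = 1, replicates = 3,
                                    scenarios = extra, verbose = FALSE),
             run_acceptance_battery(seed = 1, replicates = 1,
                                    scenarios = genomic, verbose = FALSE))
    assign("bat", bat, envir = .battery_cache)
  }
  get("bat", envir = .battery_cache)
}

# per-replicate trend-fitted 20-year changes of a metric (percentage
# points for prevalences)
replicate_changes <- function(results, metric, pct = TRUE) {
  m <- results$metrics
  m <- m[m$metric == metric, , drop = FALSE]
  out <- vapply(sort(unique(m$replicate)), function(r) {
    d <- m[m$replicate == r, ]
    replicate_trend(d$year, d$value)$change
  }, 0)
  if (pct) 100 * out else out
}

change_se <- function(results, metric, pct = TRUE) {
  ch <- replicate_changes(results, metric, pct)
  sd(ch) / sqrt(length(ch))
}
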