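#' Selection index with per-trait scaling
#'
#' Score per animal: `sum_t w_t * value_t / sd_t`. In the breeding program
#' the values are EBVs (stallion side) or phenotypes (mare side) and the
#' scaling SDs are the per-trait EBV standard deviations of the current
#' candidate cohort. OCD traits enter with a negative weight of unit
#' magnitude so that a lower OCD value raises the score.
#'
#' @param values matrix (animals x traits) of index components.
#' @param weights numeric weights per trait (finite).
#' @param scale_sds per-trait scaling standard deviations (> 0).
#' @return Numeric score per animal.
#' @export
selection_index <- function(values, weights, scale_sds) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing value for an included trait")
  stopifnot(all(is.finite(weights)), all(scale_sds > 0),
            length(weights) == ncol(values),
            length(scale_sds) == ncol(values))
  as.vector(values %*% (weights / scale_sds))
}

#' Threshold selection rules on OCD phenotypes
#'
#' Removes candidates by their recorded radiographic OCD status:
#' `FJ_and_HJ` removes candidates affected in both fetlock and hock joints,
#' `FJ_or_HJ` those affected in either, `FJ`/`HJ` those affected in the
#' respective joint, and `none` removes nobody.
#'
#' @param ocd matrix or data frame with columns `ocd_fj` and `ocd_hj`
#'   (0/1 per candidate); required complete under an active rule.
#' @param rule one of `"none"`, `"FJ_and_HJ"`, `"FJ_or_HJ"`, `"FJ"`, `"HJ"`.
#' @return Logical vector: `TRUE` for survivors.
#' @export
apply_threshold_rule <- function(ocd, rule = c("none", "FJ_and_HJ",
                                               "FJ_or_HJ", "FJ", "HJ")) {
  rule <- match.arg(rule)
  if (rule == "none") return(rep(TRUE, nrow(as.data.frame(ocd))))
  fj <- ocd[, "ocd_fj"]; hj <- ocd[, "ocd_hj"]
  if (anyNA(fj) || anyNA(hj))
    stop("missing OCD record under an active threshold rule")
  switch(rule,
         FJ_and_HJ = !(fj == 1 & hj == 1),
         FJ_or_HJ = !(fj == 1 | hj == 1),
         FJ = fj != 1,
         HJ = hj != 1)
}

#' EBV-dependent stallion usage weights
#'
#' Log-linear interpolation between the worst and best selected stallion so
#' that the best is used `max_ratio` times more frequently than the worst:
#' `w_i = max_ratio^((s_i - s_min) / (s_max - s_min))`, normalized to sum 1.
#' Equal scores give uniform weights. The weights are invariant to shifting
#' or rescaling all scores.
#'
#' @param scores index scores of the selected stallions.
#' @param max_ratio usage ratio between best and worst (default 100).
#' @return Normalized mating weight per stallion.
#' @export
stallion_usage_weights <- function(scores, max_ratio = 100) {
  stopifnot(length(scores) >= 1, max_ratio > 1)
  rng <- range(scores)
  if (diff(rng) == 0) return(rep(1 / length(scores), length(scores)))
  w <- max_ratio^((scores - rng[1]) / diff(rng))
  w / sum(w)
}

#' Allocate matings
#'
#' Each dam is independently assigned one stallion by a weighted draw; one
#' offspring per mated dam per year, offspring sex 1:1.
#'
#' @param dams dam ids.
#' @param stallions stallion ids (non-empty).
#' @param weights normalized usage weights (sum to 1).
#' @return Data frame with `dam`, `sire` and `sex` (1 = male, 2 = female)
#'   per planned offspring.
#' @export
allocate_matings <- function(dams, stallions, weights) {
  if (length(stallions) == 0) stop("empty stallion list")
  stopifnot(abs(sum(weights) - 1) < 1e-8,
            length(weights) == length(stallions))
  sire <- stallions[sample.int(length(stallions), length(dams),
                               replace = TRUE, prob = weights)]
  sex <- 1L + (runif(length(dams)) < 0.5)
  data.frame(dam = dams, sire = sire, sex = as.integer(sex))
}

#' Truncation selection of the top k scores
#'
#' Ties are broken towards the lower animal id, which keeps replicates
#' reproducible under fixed seeds.
#'
#' @param candidates candidate ids.
#' @param scores numeric scores (same length).
#' @param k number to select (0 <= k <= number of candidates).
#' @return Selected ids, best first.
#' @export
select_top_k <- function(candidates, scores, k) {
  if (k < 0) stop("k must be >= 0")
  if (k > length(candidates)) stop("k exceeds number of candidates")
  ord <- order(-scores, candidates)
  candidates[ord[seq_len(k)]]
}
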