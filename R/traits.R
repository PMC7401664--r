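#' Default trait configuration
#'
#' Reads the packaged YAML configuration holding the trait definitions
#' (heritabilities and phenotypic standard deviations per recording event,
#' OCD liability traits, height at withers), the published genetic and
#' residual correlations, and the fill rules used for correlation entries
#' without a literature estimate.
#'
#' @param file optional path to an alternative YAML file with the same
#'   structure (the supported route for overriding the correlation fill
#'   rules or the assumed OCD prevalences).
#' @return A list with elements `traits`, `known_genetic_correlations`,
#'   `known_residual_correlations`, `ocd_genetic_correlations_by_name` and
#'   `defaults`.
#' @export
default_trait_config <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "trait_config.yaml",
                        package = "warmbloodsim", mustWork = TRUE)
  yaml::read_yaml(file)
}

#' Trait definitions table
#'
#' @param config a configuration list from [default_trait_config()].
#' @return Data frame with one row per trait: `key`, `name`, `event`,
#'   `kind`, `h2`, `sigma_p`, `prevalence` (NA for continuous traits) and
#'   `mean` (0 unless configured).
#' @export
trait_definitions <- function(config = default_trait_config()) {
  tr <- config$traits
  defs <- data.frame(
    key = vapply(tr, `[[`, "", "key"),
    name = vapply(tr, `[[`, "", "name"),
    event = vapply(tr, `[[`, "", "event"),
    kind = vapply(tr, `[[`, "", "kind"),
    h2 = vapply(tr, `[[`, 0, "h2"),
    sigma_p = vapply(tr, `[[`, 0, "sigma_p"),
    prevalence = vapply(tr, function(x)
      if (is.null(x$prevalence)) NA_real_ else x$prevalence, 0),
    mean = vapply(tr, function(x)
      if (is.null(x$mean)) 0 else x$mean, 0),
    stringsAsFactors = FALSE)
  stopifnot(all(defs$h2 > 0 & defs$h2 <= 1), all(defs$sigma_p > 0),
            !anyNA(defs$prevalence[defs$kind == "binary"]))
  rownames(defs) <- defs$key
  defs
}

# project a symmetric matrix to the nearest positive semi-definite
# correlation matrix: clip eigenvalues at eps, rescale to unit diagonal
nearest_psd_corr <- function(M, eps = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= eps) return(M)
  v <- pmax(e$values, eps)
  R <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Assemble the genetic and residual correlation matrices
#'
#' Published entries (the OCD/height block and the OCD-performance
#' correlations, applied to the trait of the same name at every recording
#' event) are inserted verbatim. The remaining entries follow the documented
#' fill rules: the same trait at different events gets `same_trait_rg`
#' genetic correlation and `cross_event_re` residual correlation; different
#' performance traits get `within_event_rg`/`cross_event_rg` genetically and
#' `within_event_re`/0 residually; unknown OCD and height entries default to
#' zero. Both matrices are then projected to the nearest positive
#' semi-definite correlation matrix (eigenvalue clipping); the projection
#' must not move any published entry by more than `max_shift`.
#'
#' @param trait_defs from [trait_definitions()].
#' @param config configuration list carrying the known blocks and defaults.
#' @param same_trait_rg,cross_event_re overrides of the two headline fill
#'   rules; default from the configuration.
#' @param max_shift largest tolerated movement of a published entry under
#'   the positive semi-definite repair.
#' @return List with `G_corr` and `R_corr` (named square matrices).
#' @export
assemble_correlation_matrices <- function(trait_defs,
                                          config = default_trait_config(),
                                          same_trait_rg = NULL,
                                          cross_event_re = NULL,
                                          max_shift = 0.02) {
  d <- config$defaults
  if (!is.null(same_trait_rg)) d$same_trait_rg <- same_trait_rg
  if (!is.null(cross_event_re)) d$cross_event_re <- cross_event_re
  k <- trait_defs$key
  nt <- length(k)
  perf <- !(k %in% c("ocd_fj", "ocd_hj", "height"))
  G <- matrix(NA_real_, nt, nt, dimnames = list(k, k))
  R <- matrix(NA_real_, nt, nt, dimnames = list(k, k))
  diag(G) <- 1; diag(R) <- 1
  same_event <- outer(trait_defs$event, trait_defs$event, "==")
  same_name <- outer(trait_defs$name, trait_defs$name, "==")
  off <- !diag(nt)
  # fill rules
  pp <- outer(perf, perf, "&")
  G[pp & off & same_event] <- d$within_event_rg
  G[pp & off & !same_event] <- d$cross_event_rg
  G[pp & off & same_name] <- d$same_trait_rg
  R[pp & off & same_event] <- d$within_event_re
  R[pp & off & !same_event] <- d$cross_event_re
  R[pp & off & same_name] <- d$cross_event_re
  ocd <- k %in% c("ocd_fj", "ocd_hj")
  if (any(ocd)) {
    G[ocd, !ocd] <- d$unknown_ocd_rg; G[!ocd, ocd] <- d$unknown_ocd_rg
    R[ocd, !ocd] <- 0; R[!ocd, ocd] <- 0
  }
  if ("height" %in% k) {
    G["height", perf] <- d$height_performance_rg
    G[perf, "height"] <- d$height_performance_rg
    R["height", perf] <- 0; R[perf, "height"] <- 0
  }
  diag(G) <- 1; diag(R) <- 1
  # published entries
  known <- list()
  for (e in config$known_genetic_correlations) {
    G[e[[1]], e[[2]]] <- G[e[[2]], e[[1]]] <- as.numeric(e[[3]])
    known[[length(known) + 1]] <- c(e[[1]], e[[2]], "G", e[[3]])
  }
  for (e in config$known_residual_correlations) {
    R[e[[1]], e[[2]]] <- R[e[[2]], e[[1]]] <- as.numeric(e[[3]])
    known[[length(known) + 1]] <- c(e[[1]], e[[2]], "R", e[[3]])
  }
  byname <- config$ocd_genetic_correlations_by_name
  for (nm in names(byname)) {
    for (oc in names(byname[[nm]])) {
      v <- as.numeric(byname[[nm]][[oc]])
      hit <- k[trait_defs$name == nm]
      for (h in hit) {
        G[h, oc] <- G[oc, h] <- v
        known[[length(known) + 1]] <- c(h, oc, "G", v)
      }
    }
  }
  stopifnot(!anyNA(G), !anyNA(R))
  Gr <- nearest_psd_corr(G)
  Rr <- nearest_psd_corr(R)
  for (e in known) {
    M <- if (e[[3]] == "G") Gr else Rr
    if (abs(M[e[[1]], e[[2]]] - as.numeric(e[[4]])) > max_shift)
      stop("positive semi-definite repair moved published entry ",
           e[[1]], "/", e[[2]], " by more than ", max_shift)
  }
  list(G_corr = Gr, R_corr = Rr)
}

#' Sample pleiotropic QTL effects
#'
#' Chooses `n_qtl` loci uniformly without replacement from the map and draws
#' one multivariate-normal effect vector per locus with correlation matrix
#' `G_corr`; pleiotropy of the shared loci generates the genetic
#' correlations. Effects are raw and meant to be passed through
#' [calibrate_trait_scaling()].
#'
#' @param n_qtl number of QTL (at least the number of traits, at most the
#'   number of loci on the map).
#' @param G_corr genetic correlation matrix.
#' @param map the genetic map.
#' @return Effect matrix (`n_qtl` x traits) with attribute `qtl_idx`
#'   (1-based locus indices, sorted).
#' @export
sample_qtl_effects <- function(n_qtl, G_corr, map) {
  nt <- ncol(G_corr)
  if (n_qtl < nt)
    stop("n_qtl must be at least the number of traits")
  if (n_qtl > map_nloci(map)) stop("n_qtl exceeds number of loci")
  idx <- sort(sample.int(map_nloci(map), n_qtl))
  eff <- matrix(rnorm(n_qtl * nt), n_qtl, nt) %*% chol(G_corr)
  colnames(eff) <- colnames(G_corr)
  attr(eff, "qtl_idx") <- idx
  eff
}

#' Calibrate QTL effects and residual variances to the trait table
#'
#' Rescales each trait's effect column so that the founder-population
#' variance of true genomic values equals `h2 * sigma_p^2` (with
#' `sigma_p = 1` on the liability scale for binary traits) and sets the
#' residual standard deviation to `sigma_p * sqrt(1 - h2)`. The founder TBV
#' mean is stored as the zero-point for gain reporting.
#'
#' @param founders a [generate_founders()] population.
#' @param effect_matrix raw effects from [sample_qtl_effects()].
#' @param trait_defs from [trait_definitions()].
#' @return List with `effects` (scaled), `residual_sd`, `founder_tbv_mean`,
#'   `founder_tbv_sd` and `genetic_sd` (the calibration target
#'   `sqrt(h2) * sigma_p`), all named by trait key.
#' @export
calibrate_trait_scaling <- function(founders, effect_matrix, trait_defs) {
  qtl <- attr(effect_matrix, "qtl_idx")
  tbv <- cpp_tbv(founders$haplotypes, qtl - 1L, effect_matrix)
  v <- apply(tbv, 2, var)
  if (any(v <= 0)) stop("founder TBV variance is zero for some trait")
  target_sd <- sqrt(trait_defs$h2) * trait_defs$sigma_p
  scl <- target_sd / sqrt(v)
  eff <- sweep(effect_matrix, 2, scl, "*")
  attr(eff, "qtl_idx") <- qtl
  tbv <- sweep(tbv, 2, scl, "*")
  list(effects = eff,
       residual_sd = setNames(trait_defs$sigma_p * sqrt(1 - trait_defs$h2),
                              trait_defs$key),
       founder_tbv_mean = setNames(colMeans(tbv), trait_defs$key),
       founder_tbv_sd = setNames(apply(tbv, 2, sd), trait_defs$key),
       genetic_sd = setNames(target_sd, trait_defs$key))
}

#' Liability threshold for a given prevalence
#'
#' Threshold t with `P(liability > t) = prevalence` for a standard-normal
#' founder liability; strictly decreasing in the prevalence.
#'
#' @param prevalence probability in (0, 1).
#' @return Threshold in liability units.
#' @examples
#' liability_threshold(0.5)     # 0
#' liability_threshold(0.1587)  # about 1
#' @export
liability_threshold <- function(prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must be in (0, 1)")
  qnorm(1 - prevalence)
}

# draw n correlated residual vectors for the given trait columns
# (degenerate zero-variance components return exact zeros)
rmvn_chol <- function(n, Sigma) {
  m <- ncol(Sigma)
  pos <- diag(Sigma) > 0
  out <- matrix(0, n, m)
  if (any(pos))
    out[, pos] <- matrix(rnorm(n * sum(pos)), n) %*%
      chol(Sigma[pos, pos, drop = FALSE])
  out
}

#' Build a complete trait set
#'
#' Convenience constructor tying together trait definitions, assembled
#' correlation matrices, sampled and calibrated QTL effects, liability
#' thresholds and the observed-scale (Robertson-transformed) variance
#' components used for breeding value estimation of the binary OCD traits.
#'
#' @param map the genetic map.
#' @param founders founder population used for calibration.
#' @param config trait configuration.
#' @param n_qtl number of shared pleiotropic QTL.
#' @return Object of class `trait_set`.
#' @export
build_trait_set <- function(map, founders, config = default_trait_config(),
                            n_qtl = 2500) {
  defs <- trait_definitions(config)
  cors <- assemble_correlation_matrices(defs, config)
  eff <- sample_qtl_effects(n_qtl, cors$G_corr, map)
  cal <- calibrate_trait_scaling(founders, eff, defs)
  trait_set_new(defs, cors, cal, n_qtl)
}

# assemble a trait_set from pre-computed parts (used by the year loop, which
# may store genomes at QTL-only resolution)
trait_set_new <- function(defs, cors, cal, n_qtl) {
  sg <- cal$genetic_sd
  se <- cal$residual_sd
  G0 <- outer(sg, sg) * cors$G_corr
  R0 <- outer(se, se) * cors$R_corr
  thr <- setNames(rep(NA_real_, nrow(defs)), defs$key)
  bin <- defs$kind == "binary"
  # thresholds are anchored at the founder TBV mean so that the configured
  # prevalence holds exactly in the founder population
  thr[bin] <- liability_threshold(defs$prevalence[bin]) +
    cal$founder_tbv_mean[bin]
  # observed 0/1 scale variance components for binary traits in the BVE
  # (Robertson transformation of the liability-scale heritability)
  sg_bve <- sg
  se_bve <- se
  if (any(bin)) {
    K <- defs$prevalence[bin]
    z <- dnorm(qnorm(1 - K))
    gvar_obs <- defs$h2[bin] * z^2
    evar_obs <- K * (1 - K) - gvar_obs
    sg_bve[bin] <- sqrt(gvar_obs)
    se_bve[bin] <- sqrt(evar_obs)
  }
  structure(list(defs = defs, G_corr = cors$G_corr, R_corr = cors$R_corr,
                 G0 = G0, R0 = R0,
                 effects = cal$effects, qtl_idx = attr(cal$effects, "qtl_idx"),
                 residual_sd = se, thresholds = thr,
                 founder_tbv_mean = cal$founder_tbv_mean,
                 founder_tbv_sd = cal$founder_tbv_sd,
                 genetic_sd = sg, sd_g_bve = sg_bve, sd_e_bve = se_bve,
                 n_qtl = n_qtl),
            class = "trait_set")
}

#' Generate phenotype records for one recording event
#'
#' Draws one multivariate-normal residual vector per animal with covariance
#' restricted to the event's traits and returns continuous phenotypes
#' (trait mean + TBV + residual) or, for binary liability traits, the 0/1
#' indicator of the liability exceeding the trait threshold.
#'
#' @param tbv matrix of true genomic values (animals x all traits, columns
#'   named by trait key); row names are used as animal ids if present.
#' @param event one of the configured recording events.
#' @param trait_set a [build_trait_set()] object.
#' @param year optional recording year stored with the records.
#' @return Data frame with columns `animal_id`, `trait`, `event`, `year`,
#'   `value` (one record per animal x trait).
#' @export
generate_phenotypes <- function(tbv, event, trait_set, year = NA_integer_) {
  defs <- trait_set$defs
  sel <- defs$key[defs$event == event]
  if (length(sel) == 0) stop("unknown event: ", event)
  n <- nrow(tbv)
  Rsub <- trait_set$R0[sel, sel, drop = FALSE]
  resid <- rmvn_chol(n, Rsub)
  vals <- tbv[, sel, drop = FALSE] + resid
  vals <- sweep(vals, 2, defs[sel, "mean"], "+")
  for (jj in seq_along(sel)) {
    if (defs[sel[jj], "kind"] == "binary")
      vals[, jj] <- as.numeric(vals[, jj] > trait_set$thresholds[sel[jj]])
  }
  ids <- rownames(tbv)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(animal_id = rep(ids, length(sel)),
             trait = rep(sel, each = n),
             event = event, year = year,
             value = as.vector(vals),
             stringsAsFactors = FALSE)
}

#' Export phenotype records as tidy CSV
#' @param records data frame from [generate_phenotypes()].
#' @param file output path.
#' @export
write_phenotypes <- function(records, file) {
  write.table(records, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
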