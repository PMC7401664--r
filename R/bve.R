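# Breeding value estimation: multi-trait animal model via Henderson's mixed
# model equations. The solver works on a partition of the evaluated traits
# into blocks; within a block traits are jointly evaluated with their full
# genetic and residual covariance, across blocks they are independent. The
# default partition groups the same trait name across recording events
# (which carries the dominant genetic correlation, 0.85) plus a bivariate
# OCD block; passing a single block containing all traits gives the full
# multi-trait model.

# default trait partition: by trait name, binary OCD traits as one block
default_bve_blocks <- function(trait_set, traits) {
  defs <- trait_set$defs[traits, , drop = FALSE]
  ocd <- defs$key[defs$kind == "binary"]
  perf <- defs[defs$kind != "binary", , drop = FALSE]
  blocks <- split(perf$key, perf$name)
  blocks <- blocks[order(vapply(blocks, function(b)
    match(b[1], trait_set$defs$key), 0L))]
  if (length(ocd) > 0) blocks$ocd <- ocd
  unname(blocks)
}

# variance components of a trait block on the scale used inside the BVE
# (observed 0/1 scale for binary traits, Robertson-transformed)
bve_block_varcomp <- function(trait_set, keys) {
  sg <- trait_set$sd_g_bve[keys]
  se <- trait_set$sd_e_bve[keys]
  G0 <- outer(sg, sg) * trait_set$G_corr[keys, keys, drop = FALSE]
  R0 <- outer(se, se) * trait_set$R_corr[keys, keys, drop = FALSE]
  list(G0 = G0, R0 = R0)
}

# core block solver on a phenotype matrix Y (n animals x traits, NA missing).
# Ainv: sparse dgCMatrix; geno/Dg: optional single-step adjustment.
solve_mme_blocks <- function(Ainv, Y, trait_set, blocks, U0 = NULL,
                             B0 = NULL, fit_mean = TRUE, geno = integer(0),
                             Dg = NULL, tol = 1e-8, maxit = 5000L) {
  n <- nrow(Y)
  keys <- unlist(blocks)
  ebv <- matrix(0, n, length(keys), dimnames = list(NULL, keys))
  means <- vector("list", length(blocks))
  iters <- numeric(0); relres <- numeric(0)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    vc <- bve_block_varcomp(trait_set, b)
    Yb <- Y[, b, drop = FALSE]
    if (!any(is.finite(Yb))) next  # no records anywhere: EBV stays at 0
    u0 <- if (is.null(U0)) matrix(0, n, length(b))
          else U0[, b, drop = FALSE]
    b0 <- if (is.null(B0) || is.null(B0[[k]])) numeric(length(b))
          else B0[[k]]
    sol <- cpp_solve_mme(n, Ainv@i, Ainv@p, Ainv@x, Yb, vc$R0, vc$G0,
                         as.integer(geno),
                         if (is.null(Dg)) matrix(0, 0, 0) else Dg,
                         u0, b0, fit_mean, tol, as.integer(maxit))
    ebv[, b] <- sol$u
    means[[k]] <- sol$b
    iters <- c(iters, sol$iterations)
    relres <- c(relres, sol$relres)
  }
  list(ebv = ebv, means = means, iterations = iters, relres = relres)
}

# records data frame -> phenotype matrix (n x selected traits)
records_to_matrix <- function(records, n, keys) {
  Y <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  r <- records[records$trait %in% keys, , drop = FALSE]
  Y[cbind(as.integer(r$animal_id), match(r$trait, keys))] <- r$value
  Y
}

#' Multi-trait pedigree BLUP
#'
#' Solves the multi-trait mixed model equations with one overall mean per
#' trait, known (co)variance components from the trait set, per-animal
#' residual partitioning of missing records, and the pedigree relationship
#' inverse from [a_inverse()]. Binary OCD records enter as 0/1 observations
#' on the observed scale with Robertson-transformed variance components.
#' The system is solved by a preconditioned conjugate gradient to a relative
#' residual of `tol`.
#'
#' @param records data frame with `animal_id` (integer id into `ped`),
#'   `trait` (trait key) and `value`.
#' @param ped a [pedigree()] covering all record ids.
#' @param trait_set a [build_trait_set()] object.
#' @param traits trait keys to evaluate (default: all with records plus
#'   their block partners).
#' @param blocks trait partition (list of key vectors); default groups the
#'   same trait name across events with a bivariate OCD block. Pass
#'   `list(traits)` for a single full multi-trait run.
#' @param fit_mean fit an overall mean per trait (set `FALSE` to fix the
#'   means at zero).
#' @param tol relative residual tolerance of the iterative solver.
#' @return Object of class `bve_result`: list with `ebv` (animals x traits),
#'   `ebv_sd` (per-trait EBV standard deviation over all animals),
#'   `iterations` and `relres` per solved block.
#' @export
pedigree_blup <- function(records, ped, trait_set, traits = NULL,
                          blocks = NULL, fit_mean = TRUE, tol = 1e-8) {
  if (is.null(traits)) traits <- intersect(trait_set$defs$key,
                                           unique(records$trait))
  if (length(traits) == 0) stop("no traits to evaluate")
  if (is.null(blocks)) blocks <- default_bve_blocks(trait_set, traits)
  n <- nrow(ped)
  Ainv <- a_inverse(ped)
  Y <- records_to_matrix(records, n, unlist(blocks))
  sol <- solve_mme_blocks(Ainv, Y, trait_set, blocks, fit_mean = fit_mean,
                          tol = tol)
  structure(list(ebv = sol$ebv,
                 ebv_sd = apply(sol$ebv, 2, sd),
                 iterations = sol$iterations, relres = sol$relres),
            class = "bve_result")
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 sum p (1 - p))` with dosages centred by twice the founder
#' allele frequencies.
#'
#' @param dosages genotype dosage matrix (animals x loci), entries 0/1/2.
#' @param founder_freqs founder allele frequencies in (0, 1).
#' @return Dense symmetric relationship matrix.
#' @export
grm_vanraden <- function(dosages, founder_freqs) {
  if (any(dosages < 0 | dosages > 2)) stop("dosages must be in {0,1,2}")
  p <- founder_freqs
  if (any(p <= 0 | p >= 1)) stop("founder frequencies must be in (0,1)")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("monomorphic panel: zero denominator")
  Z <- sweep(dosages, 2, 2 * p)
  tcrossprod(Z) / denom
}

#' Single-step GBLUP
#'
#' Identical contract to [pedigree_blup()], with the relationship inverse
#' replaced by `H^-1 = A^-1 + blockdiag(0, tau * Gb^-1 - omega * A22^-1)` on
#' the genotyped block, where `Gb = blend * G + (1 - blend) * A22` (blending
#' for invertibility) and `G` is the VanRaden matrix. With an empty
#' genotyped set the result equals [pedigree_blup()] exactly.
#'
#' @inheritParams pedigree_blup
#' @param genotyped_ids animal ids with genotypes.
#' @param dosages dosage matrix for the genotyped animals (same row order).
#' @param founder_freqs founder allele frequencies used to centre dosages.
#' @param blend weight of G in the blended genomic matrix (default 0.95).
#' @param tau,omega single-step scaling parameters (default 1).
#' @return A `bve_result`, as for [pedigree_blup()].
#' @export
ssgblup <- function(records, ped, genotyped_ids, dosages, founder_freqs,
                    trait_set, traits = NULL, blocks = NULL, fit_mean = TRUE,
                    blend = 0.95, tau = 1, omega = 1, tol = 1e-8) {
  if (is.null(traits)) traits <- intersect(trait_set$defs$key,
                                           unique(records$trait))
  if (is.null(blocks)) blocks <- default_bve_blocks(trait_set, traits)
  n <- nrow(ped)
  Ainv <- a_inverse(ped)
  geno <- as.integer(genotyped_ids)
  Dg <- NULL
  if (length(geno) > 0) {
    sub <- truncate_pedigree(ped, geno, depth = n)
    pos <- match(geno, attr(sub, "orig_id"))
    A22 <- relationship_matrix(sub)[pos, pos, drop = FALSE]
    if (rcond(A22) < 1e-12) stop("A22 is singular")
    G <- grm_vanraden(dosages, founder_freqs)
    Gb <- blend * G + (1 - blend) * A22
    Dg <- tau * solve(Gb) - omega * solve(A22)
  }
  Y <- records_to_matrix(records, n, unlist(blocks))
  sol <- solve_mme_blocks(Ainv, Y, trait_set, blocks, fit_mean = fit_mean,
                          geno = geno, Dg = Dg, tol = tol)
  structure(list(ebv = sol$ebv, ebv_sd = apply(sol$ebv, 2, sd),
                 iterations = sol$iterations, relres = sol$relres),
            class = "bve_result")
}

#' Accuracy of breeding value estimation
#'
#' Pearson correlation between estimated and true genomic values over a
#' cohort. Undefined (missing, never zero) when either vector has no
#' variance or fewer than three animals are available.
#'
#' @param ebv,tbv numeric vectors over the same animals.
#' @return Correlation, or `NA` if undefined.
#' @export
bve_accuracy <- function(ebv, tbv) {
  if (length(ebv) < 3 || length(ebv) != length(tbv)) return(NA_real_)
  if (sd(ebv) == 0 || sd(tbv) == 0) return(NA_real_)
  cor(ebv, tbv)
}

#' Export EBV tables as CSV
#' @param bve a `bve_result`.
#' @param file output path.
#' @param year optional evaluation year column.
#' @export
write_ebv <- function(bve, file, year = NA_integer_) {
  keys <- colnames(bve$ebv)
  d <- data.frame(animal_id = rep(seq_len(nrow(bve$ebv)), length(keys)),
                  trait = rep(keys, each = nrow(bve$ebv)),
                  ebv = as.vector(bve$ebv), year = year)
  write.table(d, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
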