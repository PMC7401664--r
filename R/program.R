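# The yearly simulation loop of the breeding program: cohort bookkeeping,
# the event cascade (foal show -> studbook registration / mare performance
# test -> stallion licensing -> 14-day test -> one-year breeding assignment
# -> 50-day test), annual breeding value estimation, EBV-dependent stallion
# usage, mate allocation, and age-structured culling.

#' Scenario names of the simulated breeding program
#'
#' Nine pedigree-BVE scenarios (reference, four threshold-selection variants
#' at stallion licensing, index selection on the frequency of breeding use
#' with two recording schemes, and additionally index selection at the stage
#' of licensing) plus four genomic (single-step GBLUP) variants.
#' @export
scenario_names <- c("Reference", "ThreshSel1", "ThreshSel2", "ThreshSelFJ",
                    "ThreshSelHJ", "IndexBVE1", "IndexBVE2",
                    "IndexLicensing1", "IndexLicensing2",
                    "ReferenceG", "IndexBVEG2", "IndexLicensingG1",
                    "IndexLicensingG2")

scenario_properties <- function(scenario) {
  scenario <- match.arg(scenario, scenario_names)
  rec <- switch(scenario,
                Reference = , ReferenceG = "none",
                IndexBVE2 = , IndexLicensing2 = , IndexBVEG2 = ,
                IndexLicensingG2 = "licensing_plus",
                "licensing")
  rule <- switch(scenario, ThreshSel1 = "FJ_and_HJ", ThreshSel2 = "FJ_or_HJ",
                 ThreshSelFJ = "FJ", ThreshSelHJ = "HJ", "none")
  genomic <- c("ReferenceG", "IndexBVEG2", "IndexLicensingG1",
               "IndexLicensingG2")
  list(record_ocd = rec, threshold_rule = rule,
       ocd_in_usage = grepl("^Index", scenario),
       ocd_in_licensing = grepl("^IndexLicensing", scenario),
       bve_mode = if (scenario %in% genomic) "ssgblup" else "pedigree")
}

#' Configure a breeding-program scenario
#'
#' Cohort sizes are anchored to the reported population (15,658 breeding
#' mares, 540 breeding stallions, about one foal crop of 9,500 per year);
#' intermediate cohort maxima (600 licensing candidates, 90 licensed, 80
#' passing the 14-day test, 45 new breeding stallions per year) are
#' configurable defaults. A `scale` factor is applied uniformly to all
#' cohort sizes for desk-scale runs.
#'
#' @param scenario one of [scenario_names].
#' @param years reporting years after burn-in (default 20).
#' @param replicates number of independent simulation runs (default 25).
#' @param scale uniform scale factor on all cohort sizes, in (0, 1].
#' @param seed master seed; replicate r uses `seed + r`.
#' @param burn_in burn-in years under the reference scheme before year 0.
#' @param n_chromosomes,n_snps,map_length,n_qtl genome architecture.
#' @param cohort_sizes named list of full-scale cohort sizes.
#' @param mare_survival,stallion_survival yearly plateau survival
#'   probability of breeding animals from first breeding age on. The
#'   stallion default is calibrated so that 45 new breeding stallions per
#'   year sustain a pool of about 540 breeding stallions.
#' @param mare_first_age,stallion_first_age,max_age age structure bounds.
#' @param mare_test_fraction fraction of registered mares taking the mare
#'   performance test.
#' @param extra_record_fraction fraction of the non-candidate birth cohort
#'   with OCD records in the `*2` recording schemes.
#' @param max_ratio usage ratio between best and worst breeding stallion.
#' @param trait_config trait configuration list.
#' @param full_genomes store genomes at full marker resolution even in
#'   pedigree-BVE scenarios (single-step scenarios always do); by default
#'   pedigree scenarios store QTL-resolution genomes, which leaves the
#'   gamete process at the QTL exact.
#' @param tol relative residual tolerance of the MME solver.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "Reference", years = 20,
                            replicates = 25, scale = 1, seed = 1,
                            burn_in = 8, n_chromosomes = 31,
                            n_snps = 50000, map_length = 2500, n_qtl = 2500,
                            cohort_sizes = list(
                              broodmares = 15658, foal_crop = 9500,
                              licensing_candidates = 600, licensed = 90,
                              test14_pass = 80, test50_select = 45,
                              breeding_stallions = 540),
                            mare_survival = 0.85, stallion_survival = 0.92,
                            mare_first_age = 4, stallion_first_age = 3,
                            max_age = 20, mare_test_fraction = 1 / 3,
                            extra_record_fraction = 0.5, max_ratio = 100,
                            trait_config = default_trait_config(),
                            full_genomes = FALSE, tol = 1e-8) {
  stopifnot(scale > 0, scale <= 1, years >= 0, replicates >= 1)
  props <- scenario_properties(scenario)
  cfg <- c(list(scenario = scenario, years = years, replicates = replicates,
                scale = scale, seed = seed, burn_in = burn_in,
                n_chromosomes = n_chromosomes, n_snps = n_snps,
                map_length = map_length, n_qtl = n_qtl,
                cohort_sizes = cohort_sizes,
                mare_survival = mare_survival,
                stallion_survival = stallion_survival,
                mare_first_age = mare_first_age,
                stallion_first_age = stallion_first_age,
                max_age = max_age, mare_test_fraction = mare_test_fraction,
                extra_record_fraction = extra_record_fraction,
                max_ratio = max_ratio, trait_config = trait_config,
                full_genomes = full_genomes, tol = tol),
           props)
  class(cfg) <- "scenario_config"
  cfg
}

# scaled cohort sizes
scaled_sizes <- function(cfg) {
  s <- lapply(cfg$cohort_sizes, function(x) max(1L, as.integer(round(
    x * cfg$scale))))
  s$foal_crop <- max(2L, s$foal_crop)
  s
}

surv_prob <- function(age, first, p, maxage) {
  ifelse(age > maxage, 0, ifelse(age >= first, p, 1))
}

# trait key groups used by the cascade
.keys <- list(
  foal_show = c("fs_type", "fs_exterior", "fs_movement"),
  studbook = c("sb_walk", "sb_trot", "sb_canter"),
  mare_test = c("mt_walk", "mt_trot", "mt_canter", "mt_rideability",
                "mt_freejump"),
  test_14day = c("d14_walk", "d14_trot", "d14_canter", "d14_rideability",
                 "d14_freejump"),
  test_50day = c("d50_walk", "d50_trot", "d50_canter", "d50_rideability",
                 "d50_freejump", "d50_coursejump"),
  dressage = c("d50_walk", "d50_trot", "d50_canter", "d50_rideability"),
  jumping = c("d50_freejump", "d50_coursejump"),
  ocd = c("ocd_fj", "ocd_hj"))

# ---------------------------------------------------------------------------
# population state (environment, preallocated per replicate)

setup_population <- function(cfg) {
  sz <- scaled_sizes(cfg)
  crop <- sz$foal_crop
  half <- crop %/% 2
  genomic <- cfg$bve_mode == "ssgblup"

  full_map <- build_genetic_map(cfg$n_chromosomes, cfg$n_snps,
                                cfg$map_length)
  defs <- trait_definitions(cfg$trait_config)
  cors <- assemble_correlation_matrices(defs, cfg$trait_config)
  eff <- sample_qtl_effects(cfg$n_qtl, cors$G_corr, full_map)
  qtl_full <- attr(eff, "qtl_idx")
  # pedigree-BVE scenarios never touch marker genotypes, so genomes are
  # stored at QTL resolution (recombination along the full chromosomes is
  # unchanged, the gamete process at the QTL is exact)
  sim_loci <- if (genomic || isTRUE(cfg$full_genomes))
    seq_len(map_nloci(full_map)) else qtl_full
  map <- subset_map(full_map, sim_loci)
  qtl_sim <- match(qtl_full, sim_loci)

  # founder cohorts (ages as of simulated year 1): broodmare herd and
  # breeding-stallion pool with a stationary age distribution, young female
  # cohorts feeding studbook registration in years 1-3, young male cohorts
  # feeding licensing in years 1-2, and the stallion pipeline (last year's
  # licensed stallions awaiting the 14-day test, assignment stallions
  # awaiting the 50-day test)
  ages_m <- cfg$mare_first_age:cfg$max_age
  wts_m <- cfg$mare_survival^(ages_m - cfg$mare_first_age)
  n_herd_age <- round(sz$broodmares * wts_m / sum(wts_m))
  n_stal0 <- min(sz$breeding_stallions,
                 round(sz$test50_select / (1 - cfg$stallion_survival)))
  n_stal_age <- round(n_stal0 * wts_m / sum(wts_m))

  founder_spec <- rbind(
    data.frame(age = rep(ages_m, n_herd_age), sex = 2L, role = "herd"),
    data.frame(age = rep(ages_m, n_stal_age), sex = 1L, role = "stallion"),
    data.frame(age = rep(4L, sz$test14_pass), sex = 1L, role = "assignment"),
    data.frame(age = rep(3L, sz$licensed), sex = 1L, role = "licensed_prev"),
    data.frame(age = rep(1:3, each = half), sex = 2L, role = "young_f"),
    data.frame(age = rep(1:2, each = half), sex = 1L, role = "young_m"))
  nf <- nrow(founder_spec)

  founders <- generate_founders(nf, map)
  attr(eff, "qtl_idx") <- qtl_sim
  cal <- calibrate_trait_scaling(founders, eff, defs)
  ts <- trait_set_new(defs, cors, cal, cfg$n_qtl)
  nt <- nrow(defs)

  n_years_total <- cfg$burn_in + cfg$years + 1
  N_max <- nf + crop * n_years_total + 10L
  n_geno_max <- if (genomic) sz$licensing_candidates * (cfg$years + 2L)
                else 0L

  pop <- new.env(parent = emptyenv())
  pop$cfg <- cfg; pop$sz <- sz; pop$map <- map; pop$ts <- ts
  pop$genomic <- genomic
  pop$L <- map_nloci(map)
  pop$qtl_sim <- qtl_sim
  pop$n <- nf
  pop$sex <- integer(N_max); pop$birth_year <- integer(N_max)
  pop$sire <- integer(N_max); pop$dam <- integer(N_max)
  pop$sex[1:nf] <- founder_spec$sex
  pop$birth_year[1:nf] <- 1L - founder_spec$age
  pop$tbv <- matrix(0, N_max, nt, dimnames = list(NULL, defs$key))
  pop$ebv <- matrix(0, N_max, nt, dimnames = list(NULL, defs$key))
  pop$pheno <- matrix(NA_real_, N_max, nt, dimnames = list(NULL, defs$key))
  pop$ocd_status <- matrix(NA_real_, N_max, 2,
                           dimnames = list(NULL, .keys$ocd))
  pop$gen <- vector("list", N_max)
  for (a in seq_len(nf)) pop$gen[[a]] <- founders$haplotypes[, a]
  pop$founder_freq <- founders$freq
  pop$tbv[1:nf, ] <- cpp_tbv(founders$haplotypes, qtl_sim - 1L, ts$effects)
  # thresholds are anchored at the founder TBV mean (see build_trait_set),
  # so the configured prevalences hold exactly in the founder population
  pop$thr_ocd <- ts$thresholds[.keys$ocd]
  res <- rmvn_chol(nf, ts$R0[.keys$ocd, .keys$ocd])
  pop$ocd_status[1:nf, ] <-
    (pop$tbv[1:nf, .keys$ocd] + res) >
    matrix(pop$thr_ocd, nf, 2, byrow = TRUE)

  # inverse relationship bookkeeping (append-only)
  upd <- cpp_ainv_update(pop$sire[1:nf], pop$dam[1:nf], numeric(nf), 1L)
  pop$F <- c(upd$F, numeric(N_max - nf))
  pop$tri <- list(list(i = upd$i, j = upd$j, x = upd$x))
  pop$n_ainv <- nf

  # kinship tracker over breeding and genotyped animals only (foal-crop
  # kinship is derived from parent kinships); dead breeding animals are
  # retained for four years so later-selected offspring can be linked
  K_cap <- as.integer(sz$broodmares + sz$breeding_stallions +
                        sz$test14_pass + sz$licensed + n_geno_max +
                        6L * (sz$broodmares %/% 4 + sz$test50_select +
                                sz$test14_pass) + 200L)
  pop$K <- matrix(0, K_cap, K_cap)
  pop$rowof <- integer(N_max)
  pop$row_used <- logical(K_cap)
  pop$evict_at <- list()

  # cohort registers
  role <- founder_spec$role
  pop$herd <- which(role == "herd")
  pop$stallions <- which(role == "stallion")
  pop$assignment <- which(role == "assignment")
  pop$licensed_prev <- which(role == "licensed_prev")
  kin_track(pop, c(pop$herd, pop$stallions, pop$assignment,
                   pop$licensed_prev))
  pop$bve_means <- list()
  pop$bve_ready <- FALSE
  pop$entry_log <- list()
  pop$fillies <- list(); pop$colts <- list()
  for (a in 1:3)
    pop$fillies[[as.character(1L - a)]] <-
      which(role == "young_f" & founder_spec$age == a)
  for (a in 1:2)
    pop$colts[[as.character(1L - a)]] <-
      which(role == "young_m" & founder_spec$age == a)
  pop$evict_queue <- integer(0)
  pop$crop <- integer(0)

  # genomic containers
  if (genomic) {
    pop$geno_ids <- integer(0)
    pop$Zblocks <- list()
    pop$Gnum <- matrix(0, 0, 0)
    pop$denomG <- 2 * sum(pop$founder_freq * (1 - pop$founder_freq))
    pop$Dg <- NULL
  }

  # foal-show records for the founder youngsters so that early selection
  # steps are informed
  young <- which(role %in% c("young_f", "young_m", "licensed_prev",
                             "assignment"))
  record_event(pop, young, "foal_show")

  # initial mating allocation (uniform usage: no EBVs yet)
  sires0 <- c(pop$stallions, pop$assignment)
  dams0 <- sample(pop$herd, min(crop, length(pop$herd)))
  pop$pending <- allocate_matings(dams0, sires0,
                                  rep(1 / length(sires0), length(sires0)))
  pop$baseline_gain_mean <- NULL
  pop
}

# add animals to the kinship tracker (parents must already be tracked or
# unknown; already-tracked ids are skipped)
kin_track <- function(pop, ids) {
  ids <- ids[pop$rowof[ids] == 0L]
  k <- length(ids)
  if (k == 0) return(invisible())
  free <- which(!pop$row_used)
  if (length(free) < k) stop("kinship tracker capacity exceeded")
  rows <- free[seq_len(k)]
  act <- which(pop$row_used)
  pop$row_used[rows] <- TRUE
  pop$rowof[ids] <- rows
  rs <- ifelse(pop$sire[ids] > 0, pop$rowof[pmax(pop$sire[ids], 1L)], 0L)
  rd <- ifelse(pop$dam[ids] > 0, pop$rowof[pmax(pop$dam[ids], 1L)], 0L)
  if (any(rs == 0 & pop$sire[ids] > 0) || any(rd == 0 & pop$dam[ids] > 0))
    stop("kinship tracker: parent of a tracked animal is not tracked")
  cpp_kin_add(pop$K, as.integer(rows), as.integer(rs), as.integer(rd),
              as.integer(act))
  invisible()
}

kin_evict <- function(pop, ids) {
  if (length(ids) == 0) return(invisible())
  keep_geno <- if (pop$genomic) ids %in% pop$geno_ids else FALSE
  ids <- ids[!keep_geno]
  rows <- pop$rowof[ids]
  rows <- rows[rows > 0]
  pop$row_used[rows] <- FALSE
  pop$rowof[ids] <- 0L
  invisible()
}

# schedule kinship eviction of animals leaving the breeding pools; rows are
# retained until the latest offspring of their final matings (born the year
# after leaving, selectable up to age 3) can no longer enter the tracker
kin_retire <- function(pop, ids, year) {
  if (length(ids) == 0) return(invisible())
  key <- as.character(year + 5L)
  pop$evict_at[[key]] <- c(pop$evict_at[[key]], ids)
  invisible()
}

# mean kinship of the current foal crop, derived from the tracked parent
# kinships: for offspring o_i = (s_i, d_i),
# a(o_i, o_j) = (a(s_i,s_j)+a(s_i,d_j)+a(d_i,s_j)+a(d_i,d_j))/4 for i != j
# and a(o_i,o_i) = 1 + a(s_i,d_i)/2; aggregating parent usage makes the
# double sum a quadratic form in the parent relationship block
kin_crop_mean <- function(pop) {
  s <- pop$sire[pop$crop]; d <- pop$dam[pop$crop]
  rs <- pop$rowof[s]; rd <- pop$rowof[d]
  N <- length(s)
  rows <- c(rs, rd)
  ur <- sort(unique(rows))
  v <- tabulate(match(rows, ur), nbins = length(ur)) / 2
  Ksub <- pop$K[ur, ur, drop = FALSE]
  S <- drop(crossprod(v, Ksub %*% v))
  Kss <- pop$K[cbind(rs, rs)]
  Kdd <- pop$K[cbind(rd, rd)]
  Ksd <- pop$K[cbind(rs, rd)]
  ti <- 0.25 * (Kss + 2 * Ksd + Kdd)
  selfi <- 1 + 0.5 * Ksd
  ((S - sum(ti) + sum(selfi)) / N^2) / 2
}

# phenotype-based selection index (standardized mean over recorded traits),
# used on the mare side and for male selection before the first evaluation
phen_index <- function(pop, ids, keys) {
  P <- pop$pheno[ids, keys, drop = FALSE]
  P <- sweep(P, 2, pop$ts$defs[keys, "sigma_p"], "/")
  s <- rowMeans(P, na.rm = TRUE)
  s[is.nan(s)] <- 0
  s
}

drop_genomes <- function(pop, ids) {
  if (length(ids)) pop$gen[ids] <- list(raw(0))
  invisible()
}

# record phenotypes for an event on a set of animals
record_event <- function(pop, ids, event) {
  if (length(ids) == 0) return(invisible())
  ts <- pop$ts
  keys <- ts$defs$key[ts$defs$event == event]
  resid <- rmvn_chol(length(ids), ts$R0[keys, keys, drop = FALSE])
  pop$pheno[ids, keys] <- pop$tbv[ids, keys, drop = FALSE] + resid
  invisible()
}

# EBV selection index over a candidate cohort, scaled by the cohort EBV SD
ebv_index <- function(pop, ids, keys, weights = rep(1, length(keys))) {
  E <- pop$ebv[ids, keys, drop = FALSE]
  sds <- apply(E, 2, sd)
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  selection_index(E, weights, sds)
}

# ---------------------------------------------------------------------------
# annual breeding value estimation

build_ainv <- function(pop) {
  n <- pop$n
  i <- unlist(lapply(pop$tri, `[[`, "i"), use.names = FALSE)
  j <- unlist(lapply(pop$tri, `[[`, "j"), use.names = FALSE)
  x <- unlist(lapply(pop$tri, `[[`, "x"), use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

# ancestor closure of a seed set (ids), as a logical vector over 1..n
ancestor_closure <- function(pop, seed, n) {
  cpp_ancestor_closure(pop$sire[1:n], pop$dam[1:n], as.integer(seed))
}

# solve one trait block over the ancestor closure of its record-holders
# (plus all genotyped animals under single-step); EBVs of the excluded
# record-less leaves are exact recursive parent averages
solve_block_fast <- function(pop, b, means_slot) {
  n <- pop$n
  ts <- pop$ts
  Yb <- pop$pheno[1:n, b, drop = FALSE]
  rec <- which(rowSums(is.finite(Yb)) > 0)
  if (length(rec) == 0) return(invisible())
  geno <- integer(0); Dg <- matrix(0, 0, 0)
  seed <- rec
  if (pop$genomic && !is.null(pop$Dg)) {
    geno <- pop$geno_ids; Dg <- pop$Dg
    seed <- union(rec, geno)
  }
  keep <- ancestor_closure(pop, seed, n)
  kid <- which(keep)
  vc <- bve_block_varcomp(ts, b)
  Ysub <- Yb[kid, , drop = FALSE]
  if (length(geno) == 0) {
    # pedigree-only: exact leaf absorption + sparse Cholesky
    newid <- integer(n)
    newid[kid] <- seq_along(kid)
    ssub <- newid[pmax(pop$sire[kid], 1L)] * (pop$sire[kid] > 0)
    dsub <- newid[pmax(pop$dam[kid], 1L)] * (pop$dam[kid] > 0)
    nonleaf <- logical(length(kid))
    nonleaf[ssub[ssub > 0]] <- TRUE
    nonleaf[dsub[dsub > 0]] <- TRUE
    built <- cpp_absorb_build(as.integer(ssub), as.integer(dsub),
                              pop$F[kid], nonleaf, Ysub, vc$R0, vc$G0,
                              TRUE)
    dim <- built$dim
    theta <- numeric(0)
    if (dim > 0) {
      Csp <- Matrix::sparseMatrix(i = built$ci, p = built$cp,
                                  x = built$cx, dims = c(dim, dim),
                                  symmetric = TRUE, index1 = FALSE)
      Ch <- Matrix::Cholesky(Csp, LDL = FALSE, super = TRUE)
      theta <- as.numeric(Matrix::solve(Ch, built$rhs))
    }
    res <- cpp_absorb_backsolve(as.integer(ssub), as.integer(dsub),
                                pop$F[kid], nonleaf, Ysub, vc$R0, vc$G0,
                                theta, built$livet)
    sol <- list(u = res$u, b = res$b, iterations = 0L, relres = 0)
  } else {
    # single-step: genotyped animals are kept in the reduced system, the
    # remaining record-holding leaves are absorbed exactly, and the
    # absorbed system plus the dense genomic adjustment is solved by a
    # preconditioned CG warm-started from the pedigree-only direct solve
    newid <- integer(n)
    newid[kid] <- seq_along(kid)
    ssub <- newid[pmax(pop$sire[kid], 1L)] * (pop$sire[kid] > 0)
    dsub <- newid[pmax(pop$dam[kid], 1L)] * (pop$dam[kid] > 0)
    nonleaf <- logical(length(kid))
    nonleaf[ssub[ssub > 0]] <- TRUE
    nonleaf[dsub[dsub > 0]] <- TRUE
    gk <- match(geno, kid)
    nonleaf[gk] <- TRUE
    built <- cpp_absorb_build(as.integer(ssub), as.integer(dsub),
                              pop$F[kid], nonleaf, Ysub, vc$R0, vc$G0,
                              TRUE)
    dim <- built$dim
    m <- length(b)
    Csp <- Matrix::sparseMatrix(i = built$ci, p = built$cp, x = built$cx,
                                dims = c(dim, dim), symmetric = TRUE,
                                index1 = FALSE)
    Cg <- as(Csp, "generalMatrix")
    redid <- cumsum(nonleaf)
    gbase <- as.integer((redid[gk] - 1L) * m + 1L)
    # warm start: last year's solution in the decorrelated coordinates
    Lg <- t(chol(vc$G0))
    Ust <- forwardsolve(Lg, t(pop$ebv[kid, b, drop = FALSE]))
    th0 <- numeric(dim)
    th0[seq_len(built$nl * m)] <- as.vector(Ust[, nonleaf, drop = FALSE])
    b0 <- pop$bve_means[[means_slot]]
    if (!is.null(b0) && built$nb > 0)
      th0[built$nl * m + seq_len(built$nb)] <- b0[built$livet + 1L]
    sol2 <- cpp_solve_sym(Cg@i, Cg@p, Cg@x, built$rhs, gbase, m, Dg,
                          th0, pop$cfg$tol, 5000L)
    res <- cpp_absorb_backsolve(as.integer(ssub), as.integer(dsub),
                                pop$F[kid], nonleaf, Ysub, vc$R0, vc$G0,
                                sol2$x, built$livet)
    pop$bve_means[[means_slot]] <- res$b
    sol <- list(u = res$u, b = res$b, iterations = sol2$iterations,
                relres = sol2$relres)
  }
  E <- matrix(0, n, length(b))
  E[kid, ] <- sol$u
  cpp_parent_average_fill(pop$sire[1:n], pop$dam[1:n], E, keep)
  pop$ebv[1:n, b] <- E
  invisible(sol)
}

# refresh the single-step adjustment after new candidates were genotyped
update_genomic <- function(pop, new_ids) {
  if (length(new_ids) > 0) {
    Znew <- cpp_centered_dosage(pop$gen, as.integer(new_ids),
                                pop$founder_freq)
    kold <- length(pop$geno_ids)
    knew <- length(new_ids)
    Gn <- matrix(0, kold + knew, kold + knew)
    if (kold > 0) {
      Gn[1:kold, 1:kold] <- pop$Gnum
      off <- 0L
      for (B in pop$Zblocks) {
        kb <- ncol(B)
        cr <- crossprod(B, Znew)
        Gn[(off + 1):(off + kb), (kold + 1):(kold + knew)] <- cr
        Gn[(kold + 1):(kold + knew), (off + 1):(off + kb)] <- t(cr)
        off <- off + kb
      }
    }
    Gn[(kold + 1):(kold + knew), (kold + 1):(kold + knew)] <-
      crossprod(Znew)
    pop$Gnum <- Gn
    pop$Zblocks[[length(pop$Zblocks) + 1]] <- Znew
    pop$geno_ids <- c(pop$geno_ids, new_ids)
  }
  k <- length(pop$geno_ids)
  if (k == 0) { pop$Dg <- NULL; return(invisible()) }
  G <- pop$Gnum / pop$denomG
  rows <- pop$rowof[pop$geno_ids]
  A22 <- pop$K[rows, rows, drop = FALSE]
  Gb <- 0.95 * G + 0.05 * A22
  pop$Dg <- chol2inv(chol(Gb)) - chol2inv(chol(A22))
  invisible()
}

run_bve <- function(pop, with_ocd) {
  ts <- pop$ts
  perf <- ts$defs$key[!(ts$defs$key %in% c(.keys$ocd, "height"))]
  blocks <- default_bve_blocks(ts, perf)
  if (with_ocd) blocks <- c(blocks, list(.keys$ocd))
  for (k in seq_along(blocks))
    solve_block_fast(pop, blocks[[k]], paste0("blk", k))
  invisible()
}

# OCD-only refresh used by the licensing-stage index
run_bve_ocd <- function(pop) {
  solve_block_fast(pop, .keys$ocd, "ocd_refresh")
  invisible()
}

# ---------------------------------------------------------------------------
# one simulated year

run_year <- function(pop, year) {
  cfg <- pop$cfg; sz <- pop$sz; ts <- pop$ts
  crop_n <- nrow(pop$pending)
  # scenario treatment (OCD recording/selection, genotyping) starts after
  # burn-in; annual BVE starts two years before reporting so the first
  # reporting-year selections are EBV-based with a warmed-up solver
  ocd_active <- year > cfg$burn_in
  bve_year <- year >= cfg$burn_in - 1L

  # (1) foal crop from last year's matings
  sire <- pop$pending$sire; dam <- pop$pending$dam
  ids <- pop$n + seq_len(crop_n)
  pop$sex[ids] <- pop$pending$sex
  pop$birth_year[ids] <- year
  pop$sire[ids] <- sire; pop$dam[ids] <- dam
  off <- cpp_make_offspring_batch(pop$gen, sire, dam,
                                  attr(pop$map, "chr_start"),
                                  attr(pop$map, "chr_nloci"),
                                  attr(pop$map, "chr_len"), pop$map$pos)
  pop$gen[ids] <- off
  pop$tbv[ids, ] <- cpp_qtl_dosage(pop$gen, ids, pop$qtl_sim - 1L) %*%
    ts$effects
  res <- rmvn_chol(crop_n, ts$R0[.keys$ocd, .keys$ocd])
  pop$ocd_status[ids, ] <-
    (pop$tbv[ids, .keys$ocd] + res) >
    matrix(pop$thr_ocd, crop_n, 2, byrow = TRUE)
  pop$ebv[ids, ] <- (pop$ebv[sire, , drop = FALSE] +
                       pop$ebv[dam, , drop = FALSE]) / 2
  pop$n <- pop$n + crop_n
  upd <- cpp_ainv_update(pop$sire[1:pop$n], pop$dam[1:pop$n],
                         pop$F[1:pop$n], pop$n_ainv + 1L)
  pop$F[1:pop$n] <- upd$F
  pop$tri[[length(pop$tri) + 1]] <- list(i = upd$i, j = upd$j, x = upd$x)
  pop$n_ainv <- pop$n
  # deferred cleanup: genomes of last year's culled animals are no longer
  # needed; kinship rows scheduled four years ago are released
  drop_genomes(pop, pop$evict_queue)
  pop$evict_queue <- integer(0)
  key <- as.character(year)
  kin_evict(pop, pop$evict_at[[key]])
  pop$evict_at[[key]] <- NULL
  pop$crop <- ids
  pop$fillies[[as.character(year)]] <- ids[pop$sex[ids] == 2L]
  pop$colts[[as.character(year)]] <- ids[pop$sex[ids] == 1L]

  # (2) foal show for the complete crop
  record_event(pop, ids, "foal_show")

  # (3) females: studbook registration at age 3, mare performance test for
  # about one third, phenotype-index selection of broodmare replacements
  f3 <- pop$fillies[[as.character(year - 3L)]]
  pop$fillies[[as.character(year - 3L)]] <- NULL
  if (!is.null(f3) && length(f3) > 0) {
    record_event(pop, f3, "studbook")
    tested <- f3[runif(length(f3)) < cfg$mare_test_fraction]
    record_event(pop, tested, "mare_test")
    n_repl <- max(0L, sz$broodmares - length(pop$herd))
    n_repl <- min(n_repl, length(f3))
    mk <- c(.keys$studbook, .keys$mare_test)
    P <- pop$pheno[f3, mk, drop = FALSE]
    P <- sweep(P, 2, ts$defs[mk, "sigma_p"], "/")
    score <- rowMeans(P, na.rm = TRUE)
    repl <- select_top_k(f3, score, n_repl)
    kin_track(pop, repl)
    pop$herd <- c(pop$herd, repl)
    drop_genomes(pop, setdiff(f3, repl))
  }

  # (4) males at age 2: licensing preselection on the foal-show EBV index,
  # OCD recording, genotyping (genomic scenarios), threshold rule or
  # licensing index, licensing selection
  m2 <- pop$colts[[as.character(year - 2L)]]
  pop$colts[[as.character(year - 2L)]] <- NULL
  licensed_now <- integer(0)
  if (!is.null(m2) && length(m2) > 0) {
    n_cand <- min(sz$licensing_candidates, length(m2))
    presc <- if (pop$bve_ready) ebv_index(pop, m2, .keys$foal_show)
             else phen_index(pop, m2, .keys$foal_show)
    cand <- select_top_k(m2, presc, n_cand)
    if (pop$genomic && ocd_active) {
      kin_track(pop, sort(cand))
      update_genomic(pop, sort(cand))
    }
    drop_genomes(pop, setdiff(m2, cand))
    if (ocd_active && cfg$record_ocd != "none") {
      pop$pheno[cand, .keys$ocd] <- pop$ocd_status[cand, ]
      if (cfg$record_ocd == "licensing_plus") {
        cohort <- c(setdiff(m2, cand),
                    pop$fillies[[as.character(year - 2L)]])
        extra <- cohort[runif(length(cohort)) < cfg$extra_record_fraction]
        pop$pheno[extra, .keys$ocd] <- pop$ocd_status[extra, ]
      }
    }
    keep <- rep(TRUE, length(cand))
    if (ocd_active && cfg$threshold_rule != "none")
      keep <- apply_threshold_rule(pop$pheno[cand, .keys$ocd, drop = FALSE],
                                   cfg$threshold_rule)
    surv <- cand[keep]
    if (ocd_active && cfg$ocd_in_licensing) {
      run_bve_ocd(pop)
      sc <- ebv_index(pop, surv, c(.keys$foal_show, .keys$ocd),
                      weights = c(1, 1, 1, -1, -1))
    } else if (pop$bve_ready) {
      sc <- ebv_index(pop, surv, .keys$foal_show)
    } else {
      sc <- phen_index(pop, surv, .keys$foal_show)
    }
    licensed_now <- select_top_k(surv, sc, min(sz$licensed, length(surv)))
    drop_genomes(pop, setdiff(cand, licensed_now))
  }

  # (5) performance tests: 14-day for last year's licensed stallions,
  # 50-day (adding course jumping) for the assignment stallions
  t14 <- pop$licensed_prev
  record_event(pop, t14, "test_14day")
  t50 <- pop$assignment
  record_event(pop, t50, "test_50day")

  # (6) annual breeding value estimation (pedigree BLUP or single-step)
  if (bve_year) {
    run_bve(pop, with_ocd = ocd_active &&
              (cfg$ocd_in_usage || cfg$ocd_in_licensing))
    pop$bve_ready <- TRUE
  }

  # (7) post-BVE stallion selections: 14-day selection, then the 50-day
  # split (half dressage, half jumping), new breeding stallions join the
  # aged cohort of former breeding stallions
  new_assignment <- integer(0)
  if (length(t14) > 0) {
    n14 <- min(sz$test14_pass, length(t14))
    sc14 <- if (pop$bve_ready) ebv_index(pop, t14, .keys$test_14day)
            else phen_index(pop, t14, .keys$test_14day)
    new_assignment <- select_top_k(t14, sc14, n14)
    kin_track(pop, new_assignment)
    drop_genomes(pop, setdiff(t14, new_assignment))
  }
  if (length(t50) > 0) {
    n50 <- min(sz$test50_select, length(t50))
    nd <- ceiling(n50 / 2)
    scd <- if (pop$bve_ready) ebv_index(pop, t50, .keys$dressage)
           else phen_index(pop, t50, .keys$dressage)
    sel_d <- select_top_k(t50, scd, nd)
    restj <- setdiff(t50, sel_d)
    scj <- if (pop$bve_ready) ebv_index(pop, restj, .keys$jumping)
           else phen_index(pop, restj, .keys$jumping)
    sel_j <- select_top_k(restj, scj, min(n50 - nd, length(restj)))
    newstal <- c(sel_d, sel_j)
    # entry snapshot: EBVs of the newly selected breeding stallions at the
    # year they join the cohort (before any progeny information accrues)
    en <- cbind(year, pop$ebv[newstal, .keys$ocd, drop = FALSE],
                pop$tbv[newstal, .keys$ocd, drop = FALSE])
    colnames(en) <- c("year", "ebv.ocd_fj", "ebv.ocd_hj",
                      "tbv.ocd_fj", "tbv.ocd_hj")
    pop$entry_log[[length(pop$entry_log) + 1]] <- en
    pop$stallions <- c(pop$stallions, newstal)
    out <- setdiff(t50, newstal)
    drop_genomes(pop, out)
    kin_retire(pop, out, year)
  }
  pop$assignment <- new_assignment

  # (8) usage weights from the breeding-stallion index and mate allocation
  pool <- c(pop$stallions, pop$assignment)
  if (length(pool) == 0) stop("no breeding stallions alive")
  if (!pop$bve_ready) {
    scores <- rep(0, length(pool))
  } else if (cfg$ocd_in_usage && ocd_active) {
    scores <- ebv_index(pop, pool, c(.keys$test_50day, .keys$ocd),
                        weights = c(rep(1, 6), -1, -1))
  } else {
    scores <- ebv_index(pop, pool, .keys$test_50day)
  }
  w <- stallion_usage_weights(scores, cfg$max_ratio)
  eligible <- pop$herd[year - pop$birth_year[pop$herd] >= cfg$mare_first_age]
  dams <- if (length(eligible) > sz$foal_crop)
    sample(eligible, sz$foal_crop) else eligible
  pop$pending <- allocate_matings(dams, pool, w)
  pop$max_use <- max(tabulate(match(pop$pending$sire, pool)))

  # (9) age-structured culling of the breeding pools
  cull <- function(ids, first, p) {
    age <- year - pop$birth_year[ids]
    pr <- surv_prob(age, first, p, cfg$max_age)
    ids[runif(length(ids)) < pr]
  }
  herd_new <- cull(pop$herd, cfg$mare_first_age, cfg$mare_survival)
  stal_new <- cull(pop$stallions, cfg$stallion_first_age,
                   cfg$stallion_survival)
  ass_new <- cull(pop$assignment, cfg$stallion_first_age,
                  cfg$stallion_survival)
  dead <- c(setdiff(pop$herd, herd_new), setdiff(pop$stallions, stal_new),
            setdiff(pop$assignment, ass_new))
  # genomes of dead breeding animals are still needed when this year's
  # allocated matings produce next year's foal crop; kinship rows are
  # retained longer so late-selected offspring can be linked
  pop$evict_queue <- c(pop$evict_queue, dead)
  kin_retire(pop, dead, year)
  pop$herd <- herd_new; pop$stallions <- stal_new
  pop$assignment <- ass_new
  pop$licensed_prev <- cull(licensed_now, cfg$stallion_first_age,
                            cfg$stallion_survival)
  invisible(pop)
}

# metric snapshot on the current year's unselected foal crop
snapshot <- function(pop, year) {
  ts <- pop$ts
  crop <- pop$crop
  g6 <- .keys$test_50day
  if (is.null(pop$baseline_gain_mean))
    pop$baseline_gain_mean <- colMeans(pop$tbv[crop, g6, drop = FALSE])
  gain <- mean((colMeans(pop$tbv[crop, g6, drop = FALSE]) -
                  pop$baseline_gain_mean) / ts$genetic_sd[g6])
  stal <- pop$stallions
  acc_fj <- acc_hj <- NA_real_
  if ((pop$cfg$ocd_in_usage || pop$cfg$ocd_in_licensing) &&
      year > pop$cfg$burn_in && length(stal) >= 3) {
    acc_fj <- bve_accuracy(pop$ebv[stal, "ocd_fj"], pop$tbv[stal, "ocd_fj"])
    acc_hj <- bve_accuracy(pop$ebv[stal, "ocd_hj"], pop$tbv[stal, "ocd_hj"])
  }
  data.frame(
    ocd_fj_prev = mean(pop$ocd_status[crop, "ocd_fj"]),
    ocd_hj_prev = mean(pop$ocd_status[crop, "ocd_hj"]),
    gain = gain,
    mean_kinship = kin_crop_mean(pop),
    height_mean = ts$defs["height", "mean"] +
      mean(pop$tbv[crop, "height"]) - ts$founder_tbv_mean[["height"]],
    acc_ocd_fj = acc_fj, acc_ocd_hj = acc_hj,
    max_use = pop$max_use)
}

#' Run one breeding-program scenario
#'
#' Establishes an age-structured founder population, runs `burn_in` years of
#' the reference scheme followed by `years` reporting years, for
#' `replicates` independent replicates (replicate r is seeded with
#' `seed + r`). Metrics are recorded on each year's unselected foal crop:
#' OCD prevalences in fetlock and hock joints, the standardized performance
#' index of the 50-day test traits (in founder genetic standard deviations
#' relative to the year-0 cohort), mean kinship, mean height at withers, and
#' the OCD EBV accuracy of the breeding-stallion cohort where OCD is
#' evaluated.
#'
#' @param cfg a [scenario_config()].
#' @return Object of class `scenario_results`: list with `scenario`,
#'   `metrics` (long data frame: scenario, replicate, year, metric, value)
#'   and `config`. Aborted replicates are dropped; more than 10% aborts is
#'   an error.
#' @export
run_scenario <- function(cfg) {
  rows <- vector("list", cfg$replicates)
  aborted <- 0L
  for (r in seq_len(cfg$replicates)) {
    set.seed(cfg$seed + r)
    out <- tryCatch({
      pop <- setup_population(cfg)
      snaps <- vector("list", cfg$years + 1L)
      for (y in seq_len(cfg$burn_in + cfg$years)) {
        run_year(pop, y)
        ry <- y - cfg$burn_in
        if (ry >= 0) snaps[[ry + 1L]] <- cbind(year = ry, snapshot(pop, y))
      }
      snap <- do.call(rbind, snaps)
      # entry-cohort OCD accuracy: EBV at joining the breeding-stallion
      # cohort vs TBV, pooled over the final five reporting years
      el <- do.call(rbind, pop$entry_log)
      acc_e <- c(NA_real_, NA_real_)
      if (!is.null(el)) {
        el <- el[el[, "year"] > cfg$burn_in + cfg$years - 5, , drop = FALSE]
        if (nrow(el) >= 3) {
          acc_e <- c(bve_accuracy(el[, "ebv.ocd_fj"], el[, "tbv.ocd_fj"]),
                     bve_accuracy(el[, "ebv.ocd_hj"], el[, "tbv.ocd_hj"]))
        }
      }
      if (!(cfg$ocd_in_usage || cfg$ocd_in_licensing))
        acc_e <- c(NA_real_, NA_real_)
      snap$acc_entry_fj <- c(rep(NA_real_, nrow(snap) - 1), acc_e[1])
      snap$acc_entry_hj <- c(rep(NA_real_, nrow(snap) - 1), acc_e[2])
      rm(pop)
      snap
    }, error = function(e) e)
    if (inherits(out, "error")) {
      aborted <- aborted + 1L
      warning("replicate ", r, " aborted: ", conditionMessage(out))
      next
    }
    long <- do.call(rbind, lapply(
      setdiff(names(out), "year"),
      function(mt) data.frame(scenario = cfg$scenario, replicate = r,
                              year = out$year, metric = mt,
                              value = out[[mt]])))
    rows[[r]] <- long
  }
  if (aborted > 0.1 * cfg$replicates)
    stop("more than 10% of replicates aborted")
  structure(list(scenario = cfg$scenario,
                 metrics = do.call(rbind, rows),
                 aborted = aborted, config = cfg),
            class = "scenario_results")
}

#' @export
print.scenario_results <- function(x, ...) {
  cat("scenario_results:", x$scenario, "-",
      length(unique(x$metrics$replicate)), "replicates,",
      max(x$metrics$year), "years\n")
  invisible(x)
}
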