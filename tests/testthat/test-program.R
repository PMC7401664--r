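# The year loop is exercised at a very small scale; the full desk-scale
# scenario comparisons live in the acceptance suite.

mini_cfg <- function(scenario = "Reference", years = 2, reps = 1,
                     seed = 5, ...) {
  scenario_config(scenario, years = years, replicates = reps,
                  scale = 0.02, seed = seed, ...)
}

test_that("scenario properties encode the selection table", {
  p <- warmbloodsim:::scenario_properties("Reference")
  expect_equal(p$record_ocd, "none")
  expect_equal(p$threshold_rule, "none")
  expect_false(p$ocd_in_usage)
  p2 <- warmbloodsim:::scenario_properties("ThreshSel2")
  expect_equal(p2$threshold_rule, "FJ_or_HJ")
  expect_false(p2$ocd_in_usage)
  p3 <- warmbloodsim:::scenario_properties("IndexBVE2")
  expect_equal(p3$record_ocd, "licensing_plus")
  expect_true(p3$ocd_in_usage)
  expect_false(p3$ocd_in_licensing)
  p4 <- warmbloodsim:::scenario_properties("IndexLicensingG1")
  expect_true(p4$ocd_in_licensing)
  expect_equal(p4$bve_mode, "ssgblup")
  expect_error(warmbloodsim:::scenario_properties("NoSuch"))
})

test_that("replicates are deterministic under a fixed seed", {
  r1 <- run_scenario(mini_cfg())
  r2 <- run_scenario(mini_cfg())
  expect_identical(r1$metrics, r2$metrics)
})

test_that("zero reporting years yield only the baseline snapshot", {
  r <- run_scenario(mini_cfg(years = 0))
  expect_equal(unique(r$metrics$year), 0)
})

test_that("survival one keeps every breeding animal below the age cap", {
  cfg <- mini_cfg(years = 4, mare_survival = 1, stallion_survival = 1)
  set.seed(cfg$seed + 1)
  pop <- warmbloodsim:::setup_population(cfg)
  h0 <- pop$herd
  for (y in 1:(cfg$burn_in + cfg$years))
    warmbloodsim:::run_year(pop, y)
  y <- cfg$burn_in + cfg$years
  ages <- y - pop$birth_year[pop$herd]
  expect_true(all(ages <= cfg$max_age))
  # no mare below the cap was ever culled
  survivors <- h0[(y - pop$birth_year[h0]) <= cfg$max_age]
  expect_true(all(survivors %in% pop$herd))
})

test_that("plateau survival produces the geometric mean age", {
  # survival 0.8 from age 4: stationary mean age about 8
  cfg <- scenario_config("Reference", years = 6, replicates = 1,
                         scale = 0.05, seed = 2, mare_survival = 0.8)
  ages <- c()
  for (r in 1:3) {
    set.seed(cfg$seed + r)
    pop <- warmbloodsim:::setup_population(cfg)
    for (y in 1:(cfg$burn_in + cfg$years))
      warmbloodsim:::run_year(pop, y)
    y <- cfg$burn_in + cfg$years
    ages <- c(ages, mean(y - pop$birth_year[pop$herd]))
  }
  # stationary age distribution: entry at 3, certain survival to first
  # breeding age 4, then geometric with p = 0.8 up to the age cap
  a <- 3:20
  w <- c(1, 0.8^(0:16))
  expect_lt(abs(mean(ages) - sum(a * w) / sum(w)), 0.4)
})

test_that("cohort ceilings are never exceeded", {
  cfg <- mini_cfg(years = 5)
  sz <- warmbloodsim:::scaled_sizes(cfg)
  set.seed(cfg$seed + 1)
  pop <- warmbloodsim:::setup_population(cfg)
  for (y in 1:(cfg$burn_in + cfg$years)) {
    warmbloodsim:::run_year(pop, y)
    expect_lte(length(pop$herd), sz$broodmares)
    expect_lte(length(pop$licensed_prev), sz$licensed)
    expect_lte(length(pop$assignment), sz$test14_pass)
    expect_lte(nrow(pop$pending), sz$foal_crop)
  }
})

test_that("reference scenarios never create OCD records", {
  cfg <- mini_cfg("Reference", years = 3)
  set.seed(cfg$seed + 1)
  pop <- warmbloodsim:::setup_population(cfg)
  for (y in 1:(cfg$burn_in + cfg$years))
    warmbloodsim:::run_year(pop, y)
  expect_true(all(is.na(pop$pheno[1:pop$n, c("ocd_fj", "ocd_hj")])))
  # threshold scenarios record OCD for licensing candidates only
  cfg2 <- mini_cfg("ThreshSel2", years = 3)
  set.seed(cfg2$seed + 1)
  pop2 <- warmbloodsim:::setup_population(cfg2)
  for (y in 1:(cfg2$burn_in + cfg2$years))
    warmbloodsim:::run_year(pop2, y)
  nrec <- sum(!is.na(pop2$pheno[1:pop2$n, "ocd_fj"]))
  expect_gt(nrec, 0)
  expect_lte(nrec, 3 * warmbloodsim:::scaled_sizes(cfg2)$licensing_candidates)
})

test_that("pedigree and genomic references coincide up to first genotype use", {
  r1 <- run_scenario(mini_cfg("Reference", years = 1, n_snps = 3000,
                              n_qtl = 1500, full_genomes = TRUE))
  r2 <- run_scenario(mini_cfg("ReferenceG", years = 1,
                              n_snps = 3000, n_qtl = 1500))
  m1 <- r1$metrics; m2 <- r2$metrics
  y0 <- which(m1$year == 0)
  expect_equal(m1$value[y0], m2$value[y0], tolerance = 1e-10)
})

test_that("the in-loop evaluator agrees with pedigree_blup", {
  cfg <- mini_cfg(years = 2)
  set.seed(cfg$seed + 1)
  pop <- warmbloodsim:::setup_population(cfg)
  for (y in 1:(cfg$burn_in + cfg$years))
    warmbloodsim:::run_year(pop, y)
  n <- pop$n
  keys <- c("sb_walk", "mt_walk", "d14_walk", "d50_walk")
  Y <- pop$pheno[1:n, keys]
  recs <- data.frame(animal_id = rep(1:n, length(keys)),
                     trait = rep(keys, each = n), value = as.vector(Y))
  recs <- recs[is.finite(recs$value), ]
  ped <- pedigree(pop$sire[1:n], pop$dam[1:n])
  ref <- pedigree_blup(recs, ped, pop$ts, traits = keys,
                       blocks = list(keys), tol = 1e-10)
  expect_equal(unname(pop$ebv[1:n, keys]), unname(ref$ebv),
               tolerance = 1e-5)
})

test_that("the in-loop single-step evaluator agrees with ssgblup", {
  cfg <- mini_cfg("ReferenceG", years = 2, n_snps = 2500, n_qtl = 1200)
  set.seed(cfg$seed + 1)
  pop <- warmbloodsim:::setup_population(cfg)
  for (y in 1:(cfg$burn_in + cfg$years))
    warmbloodsim:::run_year(pop, y)
  n <- pop$n
  expect_gt(length(pop$geno_ids), 3)
  keys <- c("sb_walk", "mt_walk", "d14_walk", "d50_walk")
  Y <- pop$pheno[1:n, keys]
  recs <- data.frame(animal_id = rep(1:n, length(keys)),
                     trait = rep(keys, each = n), value = as.vector(Y))
  recs <- recs[is.finite(recs$value), ]
  ped <- pedigree(pop$sire[1:n], pop$dam[1:n])
  Zc <- do.call(cbind, pop$Zblocks)  # centred dosages, loci x animals
  dosg <- t(Zc + 2 * pop$founder_freq)
  ref <- ssgblup(recs, ped, pop$geno_ids, dosg, pop$founder_freq,
                 pop$ts, traits = keys, blocks = list(keys), tol = 1e-10)
  expect_equal(unname(pop$ebv[1:n, keys]), unname(ref$ebv),
               tolerance = 1e-4)
})
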