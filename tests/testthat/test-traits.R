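test_that("correlation assembly inserts published entries and repairs to PSD", {
  cfg <- default_trait_config()
  defs <- trait_definitions(cfg)
  cm <- assemble_correlation_matrices(defs, cfg)
  G <- cm$G_corr
  expect_equal(G["ocd_fj", "ocd_hj"], -0.27, tolerance = 0.02)
  expect_equal(G["mt_walk", "ocd_hj"], -0.11, tolerance = 0.02)
  expect_equal(G["d50_canter", "ocd_fj"], 0.08, tolerance = 0.02)
  expect_equal(G["ocd_fj", "height"], 0.349, tolerance = 0.02)
  expect_equal(cm$R_corr["ocd_fj", "ocd_hj"], 0.085, tolerance = 0.02)
  # same trait across events, fill rules
  expect_equal(G["sb_walk", "d50_walk"], 0.85, tolerance = 0.02)
  expect_equal(cm$R_corr["sb_walk", "d50_walk"], 0, tolerance = 0.02)
  for (M in cm) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, nrow(M)))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("PSD repair leaves a valid correlation matrix unchanged", {
  M <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(warmbloodsim:::nearest_psd_corr(M), M)
  # and clips an invalid one
  B <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  R <- warmbloodsim:::nearest_psd_corr(B)
  expect_gte(min(eigen(R, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(R)), rep(1, 3))
})

test_that("pleiotropic QTL effects reproduce the target correlations", {
  map <- build_genetic_map(10, 12000, 1000)
  set.seed(31)
  Gc <- diag(5)
  dimnames(Gc) <- list(letters[1:5], letters[1:5])
  eff <- sample_qtl_effects(1e4, Gc, map)
  expect_equal(dim(eff), c(1e4, 5))
  expect_lt(max(abs(cor(eff) - diag(5))), 0.05)

  cfg <- default_trait_config()
  cm <- assemble_correlation_matrices(trait_definitions(cfg), cfg)
  eff2 <- sample_qtl_effects(1e4, cm$G_corr, map)
  expect_equal(cor(eff2)["ocd_fj", "ocd_hj"],
               cm$G_corr["ocd_fj", "ocd_hj"], tolerance = 0.05)

  expect_error(sample_qtl_effects(3, Gc, map))
})

test_that("calibration hits the published variance targets exactly", {
  sts <- small_trait_set()
  ts <- sts$ts
  tbv <- warmbloodsim:::cpp_tbv(sts$founders$haplotypes, ts$qtl_idx - 1L, ts$effects)
  v <- apply(tbv, 2, var)
  # founder TBV variance = h2 * sigma_P^2 (0.33 * 0.80^2 for the 50-day
  # walk; liability-scale 0.369 for hock OCD)
  expect_equal(unname(v[match("d50_walk", ts$defs$key)]), 0.2112,
               tolerance = 1e-10)
  expect_equal(unname(v[match("ocd_hj", ts$defs$key)]), 0.369,
               tolerance = 1e-10)
  # residual SD formula and the h2 = 1 limit
  expect_equal(unname(ts$residual_sd["d14_trot"]),
               0.74 * sqrt(1 - 0.71))
  # recalibration is idempotent
  eff2 <- ts$effects
  cal2 <- calibrate_trait_scaling(sts$founders, eff2, ts$defs)
  expect_lt(max(abs(cal2$effects - ts$effects) /
                  (abs(ts$effects) + 1e-12)), 1e-10)
})

test_that("calibration supports a degenerate h2 = 1 trait", {
  cfgmini <- list(
    traits = list(
      list(key = "t1", name = "t1", event = "foal_show",
           kind = "continuous", h2 = 1.0, sigma_p = 2.0),
      list(key = "t2", name = "t2", event = "foal_show",
           kind = "continuous", h2 = 0.5, sigma_p = 1.0)),
    known_genetic_correlations = list(),
    known_residual_correlations = list(),
    ocd_genetic_correlations_by_name = list(),
    defaults = list(same_trait_rg = 0.85, within_event_rg = 0.4,
                    cross_event_rg = 0.34, within_event_re = 0.2,
                    cross_event_re = 0, unknown_ocd_rg = 0,
                    height_performance_rg = 0))
  defs <- trait_definitions(cfgmini)
  map <- build_genetic_map(2, 100, 100)
  set.seed(2)
  f <- generate_founders(150, map)
  ts <- build_trait_set(map, f, cfgmini, n_qtl = 50)
  expect_equal(unname(ts$residual_sd["t1"]), 0)
  ph <- generate_phenotypes(ts$founder_tbv_mean["t1"] +
                              matrix(0, 5, 2,
                                     dimnames = list(NULL, defs$key)),
                            "foal_show", ts)
  expect_true(all(is.finite(ph$value)))
})

test_that("liability thresholds invert the prevalence", {
  expect_equal(liability_threshold(0.5), 0)
  expect_equal(liability_threshold(0.1587), 1.0, tolerance = 1e-3)
  expect_equal(liability_threshold(0.9), -1.2816, tolerance = 1e-4)
  expect_error(liability_threshold(0))
  expect_error(liability_threshold(1.2))
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(liability_threshold(p)) < 0))
})

test_that("phenotype generation recovers prevalence, SDs and h2", {
  set.seed(77)
  map <- build_genetic_map(10, 2500, 2500)
  founders <- generate_founders(1e4, map)
  ts <- build_trait_set(map, founders, n_qtl = 2500)
  tbv <- warmbloodsim:::cpp_tbv(founders$haplotypes, ts$qtl_idx - 1L, ts$effects)
  colnames(tbv) <- ts$defs$key

  ph <- generate_phenotypes(tbv, "health", ts)
  prev_fj <- mean(ph$value[ph$trait == "ocd_fj"])
  prev_hj <- mean(ph$value[ph$trait == "ocd_hj"])
  expect_lt(abs(prev_fj - 0.25), 0.015)
  expect_lt(abs(prev_hj - 0.10), 0.01)

  ph50 <- generate_phenotypes(tbv, "test_50day", ts)
  for (k in c("d50_walk", "d50_coursejump")) {
    sdk <- sd(ph50$value[ph50$trait == k])
    expect_equal(sdk, ts$defs[k, "sigma_p"], tolerance = 0.03 *
                   ts$defs[k, "sigma_p"])
  }
  # heritability recovery: regression of phenotype on TBV has slope 1 and
  # variance ratio h2
  y <- ph50$value[ph50$trait == "d50_walk"]
  x <- tbv[, "d50_walk"]
  expect_equal(unname(coef(lm(y ~ x))[2]), 1, tolerance = 0.05)
  expect_equal(var(x) / var(y), 0.33, tolerance = 0.02)
  # genetic correlation recovery on founder TBVs
  expect_equal(cor(tbv[, "ocd_fj"], tbv[, "ocd_hj"]), -0.27,
               tolerance = 0.05)
  expect_equal(cor(tbv[, "ocd_fj"], tbv[, "height"]), 0.349,
               tolerance = 0.05)
  expect_error(generate_phenotypes(tbv, "no_such_event", ts))
})
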