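test_that("selection index scales, weights and ranks correctly", {
  v <- matrix(c(3, 1, 2), 3, 1)
  expect_equal(selection_index(v, 1, 1), c(3, 1, 2))
  V <- matrix(c(2, 4, 6, 4, 8, 12), 3, 2)
  sc <- selection_index(V, c(1, 1), c(2, 4))
  expect_equal(sc, c(2 / 2 + 4 / 4, 4 / 2 + 8 / 4, 6 / 2 + 12 / 4))
  expect_equal(order(-sc), c(3, 2, 1))
  # lower OCD EBV raises the score under a negative unit weight
  P <- matrix(c(1, 1, 0.5, 0.2), 2, 2)
  sc2 <- selection_index(P, c(1, -1), c(1, 1))
  expect_gt(sc2[2], sc2[1])
  expect_error(selection_index(matrix(c(1, NA), 1, 2), c(1, 1), c(1, 1)))
})

test_that("threshold rules implement the four exclusion criteria", {
  ocd <- data.frame(ocd_fj = c(1, 0), ocd_hj = c(0, 0))
  expect_equal(apply_threshold_rule(ocd, "FJ_or_HJ"), c(FALSE, TRUE))
  expect_equal(apply_threshold_rule(ocd, "FJ"), c(FALSE, TRUE))
  expect_equal(apply_threshold_rule(ocd, "FJ_and_HJ"), c(TRUE, TRUE))
  expect_equal(apply_threshold_rule(ocd, "HJ"), c(TRUE, TRUE))
  # all four phenotype combinations twice: survivor counts 6, 2, 4, 4
  cohort <- data.frame(ocd_fj = rep(c(0, 0, 1, 1), 2),
                       ocd_hj = rep(c(0, 1, 0, 1), 2))
  expect_equal(sum(apply_threshold_rule(cohort, "FJ_and_HJ")), 6)
  expect_equal(sum(apply_threshold_rule(cohort, "FJ_or_HJ")), 2)
  expect_equal(sum(apply_threshold_rule(cohort, "FJ")), 4)
  expect_equal(sum(apply_threshold_rule(cohort, "HJ")), 4)
  expect_true(all(apply_threshold_rule(cohort, "none")))
  ocd$ocd_fj[1] <- NA
  expect_error(apply_threshold_rule(ocd, "FJ"))
})

test_that("threshold rules are set-monotone", {
  set.seed(9)
  for (k in 1:20) {
    cohort <- data.frame(ocd_fj = rbinom(30, 1, 0.3),
                         ocd_hj = rbinom(30, 1, 0.2))
    s2 <- which(apply_threshold_rule(cohort, "FJ_or_HJ"))
    sf <- which(apply_threshold_rule(cohort, "FJ"))
    s1 <- which(apply_threshold_rule(cohort, "FJ_and_HJ"))
    expect_true(all(s2 %in% sf))
    expect_true(all(sf %in% s1))
  }
})

test_that("usage weights hit the 100:1 ratio with log-linear interpolation", {
  expect_equal(stallion_usage_weights(c(2, 2, 2)), rep(1 / 3, 3))
  w2 <- stallion_usage_weights(c(0, 1))
  expect_equal(w2[2] / w2[1], 100)
  w3 <- stallion_usage_weights(c(0, 0.5, 1))
  expect_equal(w3 / w3[1], c(1, 10, 100))
  # scale and shift invariance
  s <- c(0.1, 0.7, 0.3, 1.4)
  expect_equal(stallion_usage_weights(s),
               stallion_usage_weights(5 * s - 2))
})

test_that("mate allocation draws stallions by weight", {
  set.seed(123)
  m1 <- allocate_matings(1:50, 99L, 1)
  expect_true(all(m1$sire == 99))
  expect_true(all(m1$sex %in% 1:2))
  m <- allocate_matings(1:10000, 1:10, rep(0.1, 10))
  cnt <- table(factor(m$sire, levels = 1:10))
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(cnt - 1000) < 3 * se))
  m2 <- allocate_matings(1:1000, c(7, 8), c(0.99, 0.01))
  expect_lt(abs(sum(m2$sire == 7) - 990), 3 * sqrt(1000 * 0.99 * 0.01) + 1)
  expect_error(allocate_matings(1:5, integer(0), numeric(0)))
})

test_that("top-k truncation breaks ties by id", {
  expect_equal(select_top_k(1:5, c(1, 2, 3, 4, 5), 5), 5:1)
  expect_equal(select_top_k(1:3, c(3, 1, 2), 2), c(1, 3))
  expect_equal(select_top_k(1:4, rep(1, 4), 2), c(1, 2))
  expect_equal(select_top_k(1:3, 1:3, 0), integer(0))
  expect_error(select_top_k(1:3, 1:3, 4))
})

test_that("truncation selection reproduces the breeder's equation", {
  # h2 = 0.5 trait, top half of parents selected on own phenotype
  map <- build_genetic_map(5, 600, 600)
  key <- "fs_type"  # h2 0.50, sigma_p 0.79
  resp <- numeric(20)
  for (r in 1:20) {
    set.seed(700 + r)
    founders <- generate_founders(400, map)
    ts <- build_trait_set(map, founders, n_qtl = 150)
    tbv <- warmbloodsim:::cpp_tbv(founders$haplotypes, ts$qtl_idx - 1L, ts$effects)
    colnames(tbv) <- ts$defs$key
    y <- tbv[, key] + rnorm(400, 0, ts$residual_sd[key])
    sel <- select_top_k(1:400, y, 200)
    sires <- sel[seq(1, 200, by = 2)]
    dams <- sel[seq(2, 200, by = 2)]
    mat <- allocate_matings(dams, sires, rep(1 / 100, 100))
    off <- warmbloodsim:::cpp_make_offspring_batch(
      lapply(1:400, function(a) founders$haplotypes[, a]),
      mat$sire, mat$dam, attr(map, "chr_start"), attr(map, "chr_nloci"),
      attr(map, "chr_len"), map$pos)
    tbvo <- warmbloodsim:::cpp_qtl_dosage(off, seq_along(off),
                                          ts$qtl_idx - 1L) %*% ts$effects
    colnames(tbvo) <- ts$defs$key
    resp[r] <- mean(tbvo[, key]) - mean(tbv[, key])
  }
  expected <- 0.798 * 0.5 * 0.79
  se <- sd(resp) / sqrt(20)
  expect_lt(abs(mean(resp) - expected), 3 * se + 0.01)
})
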