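test_that("single own record shrinks to h2 times the phenotype", {
  sts <- small_trait_set()
  ped <- pedigree(0, 0)
  rec <- data.frame(animal_id = 1, trait = "mt_canter", value = 1.0)
  r <- pedigree_blup(rec, ped, sts$ts, traits = "mt_canter",
                     blocks = list("mt_canter"), fit_mean = FALSE)
  expect_equal(unname(r$ebv[1, 1]), 0.36, tolerance = 1e-7)
})

test_that("iterative multi-trait solver matches a dense direct solve", {
  sts <- small_trait_set()
  ts <- sts$ts
  keys <- c("sb_walk", "mt_walk", "d14_walk", "d50_walk")
  set.seed(12)
  ped <- random_pedigree(60, nf = 15)
  Y <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, keys))
  Y[sample(length(Y), 120)] <- NA
  Y[1:12, ] <- NA
  recs <- data.frame(animal_id = rep(1:60, 4),
                     trait = rep(keys, each = 60),
                     value = as.vector(Y))
  recs <- recs[is.finite(recs$value), ]
  fit <- pedigree_blup(recs, ped, ts, traits = keys, blocks = list(keys),
                       tol = 1e-10)
  vc <- warmbloodsim:::bve_block_varcomp(ts, keys)
  oracle <- dense_mme_solve(ped, Y, vc$G0, vc$R0)
  expect_lt(max(abs(fit$ebv - oracle$u)), 1e-6)
})

test_that("traits without records get zero EBVs (prior mean)", {
  sts <- small_trait_set()
  ped <- pedigree(c(0, 0, 1), c(0, 0, 2))
  rec <- data.frame(animal_id = c(1, 2), trait = "fs_type",
                    value = c(2, -1))
  r <- pedigree_blup(rec, ped, sts$ts,
                     traits = c("fs_type", "d50_coursejump"),
                     blocks = list("fs_type", "d50_coursejump"))
  expect_equal(unname(r$ebv[, "d50_coursejump"]), rep(0, 3))
  expect_true(any(r$ebv[, "fs_type"] != 0))
})

test_that("progeny testing reaches the closed-form accuracy", {
  sts <- small_trait_set()
  ts <- sts$ts
  h2 <- 0.42  # sb_trot
  set.seed(202)
  ns <- 400; np <- 20
  n <- ns + ns * np
  sire <- c(rep(0, ns), rep(seq_len(ns), each = np))
  dam <- rep(0, n)
  ped <- pedigree(sire, dam)
  sg <- sqrt(h2) * 0.88; se <- sqrt(1 - h2) * 0.88
  us <- rnorm(ns, 0, sg)
  uo <- 0.5 * us[sire[-(1:ns)]] + rnorm(ns * np, 0, sqrt(0.75) * sg)
  y <- uo + rnorm(ns * np, 0, se)
  recs <- data.frame(animal_id = (ns + 1):n, trait = "sb_trot", value = y)
  r <- pedigree_blup(recs, ped, ts, traits = "sb_trot",
                     blocks = list("sb_trot"))
  acc <- cor(r$ebv[1:ns, 1], us)
  expected <- sqrt(np * h2 / 4 / (1 + (np - 1) * h2 / 4))
  expect_equal(acc, expected, tolerance = 0.05)
})

test_that("VanRaden G behaves like a relationship matrix", {
  map <- build_genetic_map(5, 2000, 1000)
  f <- generate_founders(1000, map, seed = 55)
  dos <- genotype_dosage(f$haplotypes, map)
  # identical genotype rows
  G2 <- grm_vanraden(dos[c(1, 1), ], f$freq)
  expect_equal(G2[1, 1], G2[1, 2])
  expect_equal(G2[1, 1], G2[2, 2])
  G <- grm_vanraden(dos, f$freq)
  expect_equal(mean(diag(G)), 1.0, tolerance = 0.05)
  # parent-offspring genomic relationship about one half
  set.seed(66)
  offs <- sapply(1:200, function(k)
    make_offspring(f$haplotypes[, k], f$haplotypes[, k + 200], map))
  dall <- genotype_dosage(cbind(f$haplotypes[, 1:200], offs), map)
  Gpo <- grm_vanraden(dall, f$freq)
  po <- mean(Gpo[cbind(1:200, 201:400)])
  expect_equal(po, 0.5, tolerance = 0.05)
  expect_error(grm_vanraden(dos + 2, f$freq))
  expect_error(grm_vanraden(dos, rep(0, ncol(dos))))
})

test_that("single-step with no genotypes equals pedigree BLUP", {
  sts <- small_trait_set()
  set.seed(3)
  ped <- random_pedigree(80, nf = 20)
  recs <- data.frame(animal_id = 21:80, trait = "fs_type",
                     value = rnorm(60))
  a <- pedigree_blup(recs, ped, sts$ts, traits = "fs_type")
  b <- ssgblup(recs, ped, integer(0), NULL, NULL, sts$ts,
               traits = "fs_type")
  expect_identical(a$ebv, b$ebv)
})

test_that("zero blend weight reduces single-step to pedigree BLUP", {
  sts <- small_trait_set()
  set.seed(14)
  map <- sts$map
  ped <- random_pedigree(60, nf = 12)
  recs <- data.frame(animal_id = 13:60, trait = "sb_canter",
                     value = rnorm(48))
  geno <- 1:12
  f <- sts$founders
  dos <- genotype_dosage(f$haplotypes[, 1:12], map)
  a <- pedigree_blup(recs, ped, sts$ts, traits = "sb_canter", tol = 1e-10)
  b <- ssgblup(recs, ped, geno, dos, f$freq, sts$ts, traits = "sb_canter",
               blend = 0, tol = 1e-10)
  expect_lt(max(abs(a$ebv - b$ebv)), 1e-6)
})

test_that("genomic information does not reduce sire accuracy", {
  # half-sib design with genotyped sires, 20 paired replicates
  map <- build_genetic_map(5, 800, 800)
  accs <- matrix(NA_real_, 20, 2)
  for (rep in 1:20) {
    set.seed(300 + rep)
    founders <- generate_founders(120, map)
    ts <- build_trait_set(map, founders, n_qtl = 200)
    ns <- 20; np <- 10
    sires <- 1:ns; dams <- 21:120
    sirev <- c(rep(0L, 120), rep(sires, each = np))
    damv <- c(rep(0L, 120), sample(dams, ns * np, replace = TRUE))
    gen <- lapply(seq_len(120), function(a) founders$haplotypes[, a])
    for (i in 121:(120 + ns * np))
      gen[[i]] <- make_offspring(gen[[sirev[i]]], gen[[damv[i]]], map)
    ped <- pedigree(sirev, damv)
    tbv <- warmbloodsim:::cpp_qtl_dosage(gen, seq_along(gen),
                                         ts$qtl_idx - 1L) %*% ts$effects
    colnames(tbv) <- ts$defs$key
    key <- "fs_movement"
    y <- tbv[121:(120 + ns * np), key] +
      rnorm(ns * np, 0, ts$residual_sd[key])
    recs <- data.frame(animal_id = 121:(120 + ns * np), trait = key,
                       value = y)
    rp <- pedigree_blup(recs, ped, ts, traits = key)
    dos <- genotype_dosage(founders$haplotypes[, sires], map)
    rg <- ssgblup(recs, ped, sires, dos, founders$freq, ts, traits = key)
    accs[rep, ] <- c(cor(rp$ebv[sires, 1], tbv[sires, key]),
                     cor(rg$ebv[sires, 1], tbv[sires, key]))
  }
  expect_gte(mean(accs[, 2] - accs[, 1]), -0.01)
})

test_that("EBV accuracy is the Pearson correlation with NA degenerate cases", {
  x <- rnorm(100)
  expect_equal(bve_accuracy(x, x), 1.0)
  expect_equal(bve_accuracy(-x, x), -1.0)
  expect_true(is.na(bve_accuracy(rep(1, 10), x[1:10])))
  expect_true(is.na(bve_accuracy(x[1:2], x[1:2])))
  set.seed(10)
  u <- rnorm(1000)
  e <- rnorm(1000)
  expect_equal(bve_accuracy(u + e, u), 1 / sqrt(2), tolerance = 0.05)
})

test_that("EBVs are invariant to animal relabelling", {
  sts <- small_trait_set()
  set.seed(41)
  ped <- random_pedigree(50, nf = 10)
  recs <- data.frame(animal_id = 11:50, trait = "mt_trot",
                     value = rnorm(40))
  r1 <- pedigree_blup(recs, ped, sts$ts, traits = "mt_trot", tol = 1e-10)
  # relabel: swap the first two founders (both parentless)
  perm <- c(2L, 1L, 3:50)
  inv <- order(perm)
  remap <- function(p) ifelse(p > 0, inv[pmax(p, 1L)], 0L)
  ped2 <- pedigree(remap(ped$sire[perm]), remap(ped$dam[perm]))
  recs2 <- recs
  recs2$animal_id <- inv[recs$animal_id]
  r2 <- pedigree_blup(recs2, ped2, sts$ts, traits = "mt_trot",
                      tol = 1e-10)
  expect_equal(r2$ebv[inv[11:50], 1], r1$ebv[11:50, 1], tolerance = 1e-7)
})
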