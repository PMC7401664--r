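test_that("pedigree truncation keeps anchors plus bounded ancestry", {
  # chain of 10 generations
  ped <- pedigree(sire = c(0, 1:9), dam = rep(0, 10))
  t1 <- truncate_pedigree(ped, 10, depth = 1)
  expect_equal(nrow(t1), 2)
  t7 <- truncate_pedigree(ped, 10, depth = 7)
  expect_equal(nrow(t7), 8)
  # the eldest retained animal became a founder
  expect_equal(t7$sire[1], 0L)
  # anchors without parents unchanged
  ped0 <- pedigree(c(0, 0), c(0, 0))
  expect_equal(nrow(truncate_pedigree(ped0, 1:2, 3)), 2)
  # idempotence at fixed depth
  t7b <- truncate_pedigree(t7, seq_len(nrow(t7)), depth = 7)
  expect_equal(t7b$sire, t7$sire)
  expect_equal(t7b$dam, t7$dam)
  expect_error(truncate_pedigree(ped, 99, 7))
})

test_that("a_inverse matches dense tabular inversion", {
  # unrelated founders -> identity
  ped <- pedigree(c(0, 0, 0), c(0, 0, 0))
  expect_equal(as.matrix(a_inverse(ped)), diag(3), ignore_attr = TRUE)
  # non-inbred trio, hand-derived inverse
  trio <- pedigree(c(0, 0, 1), c(0, 0, 2))
  expect_equal(as.matrix(a_inverse(trio)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               ignore_attr = TRUE)
  # random multi-generation pedigree against the tabular oracle
  ped <- random_pedigree(200, nf = 20, seed = 99)
  A <- relationship_matrix(ped)
  M <- as.matrix(a_inverse(ped)) %*% A
  expect_lt(max(abs(M - diag(200))), 1e-8)
})

test_that("inbreeding coefficients are exact and non-negative", {
  # parent-offspring mating: F = 0.25
  ped <- pedigree(sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3))
  expect_equal(inbreeding(ped), c(0, 0, 0, 0.25))
  ped2 <- random_pedigree(300, nf = 12, seed = 5)
  F2 <- inbreeding(ped2)
  expect_true(all(F2 >= 0))
  expect_equal(F2, diag(relationship_matrix(ped2)) - 1, tolerance = 1e-12)
})

test_that("mean kinship averages Phi = A/2 over the cohort", {
  solo <- pedigree(0, 0)
  expect_equal(mean_kinship(solo, 1), 0.5)
  two <- pedigree(c(0, 0), c(0, 0))
  expect_equal(mean_kinship(two, 1:2), 0.25)
  sibs <- pedigree(c(0, 0, 1, 1), c(0, 0, 2, 2))
  expect_equal(mean_kinship(sibs, 3:4, include_self = FALSE), 0.25)
  expect_error(mean_kinship(two, integer(0)))
})

test_that("pedigree text files round trip", {
  ped <- random_pedigree(40, nf = 8, seed = 1)
  f <- tempfile(fileext = ".ped")
  write_pedigree(ped, f)
  ped2 <- read_pedigree(f)
  expect_equal(ped2$sire, ped$sire)
  expect_equal(ped2$dam, ped$dam)
})
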