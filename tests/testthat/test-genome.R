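test_that("genetic map distributes loci evenly with proportional lengths", {
  m1 <- build_genetic_map(1, 10, 100)
  expect_equal(nrow(m1), 10)
  expect_equal(m1$pos, seq(0, 100, length.out = 10))

  m2 <- build_genetic_map(2, 4, 200)
  expect_equal(as.integer(table(m2$chr)), c(2L, 2L))
  expect_equal(diff(m2$pos[m2$chr == 1]), 100)
  expect_equal(diff(m2$pos[m2$chr == 2]), 100)

  m3 <- build_genetic_map(31, 50000, 2500)
  expect_equal(nrow(m3), 50000)
  expect_equal(length(unique(m3$chr)), 31)
  expect_true(all(diff(order(m3$chr)) > 0))
  expect_equal(sum(attr(m3, "chr_len")), 2500)

  expect_error(build_genetic_map(0, 10, 100))
  expect_error(build_genetic_map(2, 1, 100))
  expect_error(build_genetic_map(2, 10, -5))
})

test_that("founder generation matches target frequencies and is seeded", {
  map <- build_genetic_map(3, 300, 300)
  f1 <- generate_founders(1, map, seed = 7)
  expect_equal(dim(f1$haplotypes), c(600L, 1L))

  f <- generate_founders(2000, map, maf_low = 0.05, maf_high = 0.5,
                         seed = 11)
  expect_lt(mean(abs(f$target_freq - f$freq)), 0.02)

  g1 <- generate_founders(50, map, seed = 3)
  g2 <- generate_founders(50, map, seed = 3)
  expect_identical(g1$haplotypes, g2$haplotypes)

  expect_error(generate_founders(0, map))
  expect_error(generate_founders(5, map, maf_low = 0, maf_high = 0.5))
  expect_error(generate_founders(5, map, maf_low = 0.1, maf_high = 0.6))
})

test_that("meiosis reduces to a parental haplotype without recombination", {
  map <- build_genetic_map(1, 20, 1e-9)
  set.seed(5)
  f <- generate_founders(1, map)
  g <- f$haplotypes[, 1]
  L <- 20
  h1 <- g[1:L]; h2 <- g[L + 1:L]
  hits <- c(h1 = 0, h2 = 0)
  for (k in 1:200) {
    gam <- meiosis(g, map)
    expect_true(identical(gam, h1) || identical(gam, h2))
    if (identical(gam, h1)) hits["h1"] <- hits["h1"] + 1
    else hits["h2"] <- hits["h2"] + 1
  }
  # both strands occur with probability about one half
  expect_gt(min(hits), 60)
})

test_that("crossover counts are Poisson with mean equal to Morgan length", {
  map <- build_genetic_map(1, 10, 100)
  set.seed(21)
  f <- generate_founders(1, map)
  g <- f$haplotypes[, 1]
  counts <- vapply(seq_len(1e5), function(i)
    meiosis(g, map, detail = TRUE)$crossovers[1], 0L)
  expect_lt(abs(mean(counts) - 1.0), 0.01)
  # goodness of fit against Poisson(1) at alpha = 0.01
  tab <- table(factor(pmin(counts, 5), levels = 0:5))
  p <- dpois(0:4, 1); p <- c(p, 1 - sum(p))
  expect_gt(chisq.test(as.integer(tab), p = p)$p.value, 0.01)
})

test_that("recombinant fraction follows the Haldane map function", {
  map <- build_genetic_map(1, 2, 50)
  set.seed(8)
  # heterozygous phase parent: 1,1 / 0,0
  g <- as.raw(c(1, 1, 0, 0))
  rec <- vapply(seq_len(1e5), function(i) {
    gam <- as.integer(meiosis(g, map))
    gam[1] != gam[2]
  }, NA)
  expected <- 0.5 * (1 - exp(-1))
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("offspring genomes follow Mendelian expectations", {
  map <- build_genetic_map(2, 100, 200)
  L <- 100
  # both parents homozygous 1 -> offspring homozygous 1
  all1 <- as.raw(rep(1, 2 * L))
  set.seed(4)
  off <- make_offspring(all1, all1, map)
  expect_identical(off, all1)
  # fully inbred distinct parents -> heterozygous where they differ
  p1 <- as.raw(rep(c(1, 0), each = L))[c(1:L, 1:L)]
  p1 <- as.raw(rep(1, 2 * L))
  p2 <- as.raw(rep(0, 2 * L))
  off <- make_offspring(p1, p2, map)
  d <- as.integer(off[1:L]) + as.integer(off[L + 1:L])
  expect_true(all(d == 1))
  # cohort allele frequency near mid-parent frequency
  f <- generate_founders(2, map, seed = 9)
  s <- f$haplotypes[, 1]; dd <- f$haplotypes[, 2]
  dos <- matrix(0, L, 400)
  for (k in 1:400) {
    o <- make_offspring(s, dd, map)
    dos[, k] <- as.integer(o[1:L]) + as.integer(o[L + 1:L])
  }
  midp <- (as.integer(s[1:L]) + as.integer(s[L + 1:L]) +
             as.integer(dd[1:L]) + as.integer(dd[L + 1:L])) / 4
  expect_lt(mean(abs(rowMeans(dos) / 2 - midp)), 0.05)
})

test_that("plink export writes consistent ped/map text files", {
  map <- build_genetic_map(2, 10, 100)
  f <- generate_founders(3, map, seed = 2)
  gens <- lapply(1:3, function(a) f$haplotypes[, a])
  pre <- file.path(tempdir(), "wb_test")
  write_plink(gens, map, pre)
  mp <- read.table(paste0(pre, ".map"))
  expect_equal(nrow(mp), 10)
  pd <- readLines(paste0(pre, ".ped"))
  expect_equal(length(pd), 3)
  expect_equal(length(strsplit(pd[1], "\t")[[1]]), 6 + 20)
})
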