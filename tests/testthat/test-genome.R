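test_that("the default locus table encodes the initial-frequency design", {
  loci <- locus_table_default()
  expect_equal(nrow(loci), 50L)
  sums <- tapply(loci$freq, loci$locus, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # locus 4: a rare-allele profile
  expect_equal(loci$freq[loci$locus == 4], c(0.01, 0.04, 0.15, 0.30, 0.50))
  # loci 1-5 fully neutral; locus 6 carries A2->A and A4->B; one adaptive
  # allele at each of L7-L10
  expect_true(all(loci$adaptation[loci$locus <= 5] == "neutral"))
  l6 <- loci[loci$locus == 6, ]
  expect_equal(l6$adaptation, c("neutral", "A", "neutral", "B", "neutral"))
  n_adaptive <- tapply(loci$adaptation != "neutral", loci$locus, sum)
  expect_equal(as.integer(n_adaptive[6:10]), c(2L, 1L, 1L, 1L, 1L))
})

test_that("locus tables with invalid frequencies are rejected", {
  bad <- locus_table_default()
  bad$freq[1] <- 0.15 # locus 1 now sums to 0.95
  expect_error(sample_genotypes(10, bad), "sum to 1")
})

test_that("founder genotypes follow the initial allele frequencies", {
  set.seed(11)
  g <- sample_genotypes(50000)
  # locus 1: uniform profile
  expect_equal(allele_frequencies(g, 1), rep(0.2, 5), tolerance = 0.02)
  # locus 4: the rare allele appears at ~0.01
  f4 <- allele_frequencies(g, 4)
  expect_equal(f4[1], 0.01, tolerance = 0.15)
  expect_equal(f4, c(0.01, 0.04, 0.15, 0.30, 0.50), tolerance = 0.03)

  # a degenerate frequency profile fixes the genotype
  fixed <- locus_table_default()
  fixed$freq <- rep(c(1, 0, 0, 0, 0), 10)
  gf <- sample_genotypes(20, fixed)
  expect_true(all(gf == 1L))

  # determinism: the same seed yields the same genotype stream
  set.seed(99); g1 <- sample_genotypes(100)
  set.seed(99); g2 <- sample_genotypes(100)
  expect_identical(g1, g2)
})

test_that("Mendelian inheritance draws one allele per parent per locus", {
  mother <- matrix(rep(c(1L, 1L), 10), nrow = 1)
  father <- matrix(rep(c(2L, 2L), 10), nrow = 1)
  off <- mate_genotypes(mother, father)
  expect_true(all(off[, seq(1, 20, 2)] == 1L))
  expect_true(all(off[, seq(2, 20, 2)] == 2L))

  # offspring alleles are a subset of parental alleles at every locus
  set.seed(3)
  m <- sample_genotypes(500)
  f <- sample_genotypes(500)
  o <- mate_genotypes(m, f)
  for (l in c(1, 5, 10)) {
    i <- c(2 * l - 1, 2 * l)
    parental <- cbind(m[, i], f[, i])
    expect_true(all(rowSums(parental == o[, i[1]]) > 0))
    expect_true(all(rowSums(parental == o[, i[2]]) > 0))
  }
})

test_that("heterozygous parents transmit each allele with frequency 1/2", {
  n <- 100000
  mother <- matrix(rep(c(1L, 2L), 10), nrow = n, ncol = 20, byrow = TRUE)
  father <- matrix(3L, nrow = n, ncol = 20)
  set.seed(5)
  off <- mate_genotypes(mother, father)
  # maternal allele at locus 1 is the one that is not 3
  maternal <- ifelse(off[, 1] == 3L, off[, 2], off[, 1])
  expect_equal(mean(maternal == 1L), 0.5, tolerance = 0.01)

  # zero linkage: transmissions at different loci are uncorrelated
  m1 <- ifelse(off[, 1] == 3L, off[, 2], off[, 1]) == 1L
  m2 <- ifelse(off[, 3] == 3L, off[, 4], off[, 3]) == 1L
  expect_lt(abs(cor(m1, m2)), 0.02)
})

test_that("neutral allele frequencies are a martingale under random mating", {
  # mean per-generation drift across replicates is within 3 SE of zero
  set.seed(42)
  n <- 500; reps <- 100; gens <- 10
  drift <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- sample_genotypes(n)
    p0 <- allele_frequencies(g, 1)[1]
    for (t in seq_len(gens)) {
      mothers <- g[sample.int(n, n, replace = TRUE), , drop = FALSE]
      fathers <- g[sample.int(n, n, replace = TRUE), , drop = FALSE]
      g <- mate_genotypes(mothers, fathers)
    }
    drift[r] <- (allele_frequencies(g, 1)[1] - p0) / gens
  }
  se <- stats::sd(drift) / sqrt(reps)
  expect_lt(abs(mean(drift)), 3 * se + 1e-12)
})

test_that("adaptive allele copies are counted against the habitat type", {
  loci <- locus_table_default()
  g <- matrix(1L, nrow = 1, ncol = 20)
  g[, c(1, 3, 5, 7, 9) * 2 - 1] <- 1L
  # L6 homozygous for the A-adapted allele, all else neutral states
  g[, 11:12] <- 2L       # L6 = (2,2)
  g[, 13:14] <- c(1L, 2L) # L7 neutral alleles
  g[, 15:16] <- c(1L, 2L) # L8 neutral
  g[, 17:18] <- c(2L, 3L) # L9 neutral
  g[, 19:20] <- c(2L, 3L) # L10 neutral
  expect_equal(count_adaptive_alleles(g, "A", loci), 2L)
  expect_equal(count_adaptive_alleles(g, "B", loci), 0L)
  # one copy of each of L6's two adaptive alleles: one matches each habitat
  g2 <- g
  g2[, 11:12] <- c(2L, 4L)
  expect_equal(count_adaptive_alleles(g2, "B", loci), 1L)
  expect_equal(count_adaptive_alleles(g2, "A", loci), 1L)
  expect_error(count_adaptive_alleles(g, "none", loci), "habitat")
})

test_that("genotype homozygosity is the homozygous-locus fraction", {
  hom <- matrix(rep(c(2L, 2L), 10), nrow = 1)
  het <- matrix(rep(c(1L, 2L), 10), nrow = 1)
  half <- matrix(c(rep(c(1L, 1L), 5), rep(c(1L, 2L), 5)), nrow = 1)
  expect_equal(genotype_homozygosity(hom), 1)
  expect_equal(genotype_homozygosity(het), 0)
  expect_equal(genotype_homozygosity(half), 0.5)
})
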