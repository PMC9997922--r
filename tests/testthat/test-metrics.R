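test_that("per-capita homozygosity averages the genotype fractions", {
  hom <- matrix(rep(c(2L, 2L), 10), nrow = 3, ncol = 20, byrow = TRUE)
  het <- matrix(rep(c(1L, 2L), 10), nrow = 3, ncol = 20, byrow = TRUE)
  expect_equal(per_capita_homozygosity(hom), 1)
  expect_equal(per_capita_homozygosity(het), 0)
  g40 <- matrix(c(rep(c(1L, 1L), 4), rep(c(1L, 2L), 6)), nrow = 1)
  g60 <- matrix(c(rep(c(1L, 1L), 6), rep(c(1L, 2L), 4)), nrow = 1)
  expect_equal(per_capita_homozygosity(rbind(g40, g60)), 0.5)
  expect_error(per_capita_homozygosity(hom[0, ]), "Empty")
})

test_that("allele frequencies and richness count extant alleles", {
  g <- matrix(1L, nrow = 4, ncol = 20)
  expect_equal(allele_frequencies(g, 1), c(1, 0, 0, 0, 0))
  expect_equal(allelic_richness(g, 1), 1L)
  g1 <- matrix(rep(c(1L, 2L), 10), nrow = 1)
  expect_equal(allele_frequencies(g1, 1), c(0.5, 0.5, 0, 0, 0))
  g3 <- rbind(matrix(rep(c(1L, 2L), 10), 1, 20),
              matrix(rep(c(2L, 3L), 10), 1, 20))
  expect_equal(allelic_richness(g3, 1), 3L)
  expect_equal(sum(allele_frequencies(g3, 5)), 1)
})

test_that("allelic evenness matches the entropy anchors", {
  # frozen analytic values of -sum(p ln p)/ln 5 for the three initial
  # frequency profiles (equal / unequal / rare-dominated)
  expect_equal(allelic_evenness(rep(0.20, 5)), 1.0)
  expect_equal(allelic_evenness(c(0.30, 0.25, 0.20, 0.15, 0.10)), 0.95963908,
               tolerance = 1e-6)
  expect_equal(allelic_evenness(c(0.01, 0.04, 0.15, 0.30, 0.50)), 0.72518496,
               tolerance = 1e-6)
  expect_equal(allelic_evenness(c(1, 0, 0, 0, 0)), 0)
  expect_error(allelic_evenness(c(0.5, 0.3)), "sum to 1")

  # bounds and the uniform-maximum property over random profiles
  set.seed(10)
  for (i in 1:25) {
    p <- as.numeric(stats::rmultinom(1, 200, runif(5))) / 200
    e <- allelic_evenness(p)
    expect_gte(e, 0)
    expect_lte(e, 1 + 1e-12)
    if (sum(p > 0) == 5 && stats::sd(p) > 0) expect_lt(e, 1)
  }
})

test_that("heterozygosity deficit is zero under Hardy-Weinberg equilibrium", {
  # single extant allele: both terms vanish
  g <- matrix(1L, nrow = 5, ncol = 20)
  expect_equal(heterozygosity_deficit(g, 1), 0)
  # all homozygous, two alleles at 0.5: -0.5
  g2 <- rbind(matrix(1L, 2, 20), matrix(2L, 2, 20))
  expect_equal(heterozygosity_deficit(g2, 1), -0.5)
  # random-mating draws (independent alleles) sit at HWE
  set.seed(14)
  gh <- sample_genotypes(10000)
  for (l in c(1, 2, 4)) {
    expect_equal(heterozygosity_deficit(gh, l), 0, tolerance = 0.02)
  }
})

test_that("pairwise genetic distance counts differing unordered locus pairs", {
  a <- matrix(rep(c(1L, 2L), 10), nrow = 1)
  b <- a
  expect_equal(pairwise_genetic_distance(rbind(a, b))[1, 2], 0)
  c <- matrix(rep(c(3L, 4L), 10), nrow = 1)
  expect_equal(pairwise_genetic_distance(rbind(a, c))[1, 2], 1)
  d <- a
  d[, 1:6] <- rep(c(1L, 1L), 3) # differs at loci 1-3 only
  expect_equal(pairwise_genetic_distance(rbind(a, d))[1, 2], 0.3)
  # a heterozygote is the same unordered pair regardless of phase order
  e <- a
  expect_equal(pairwise_genetic_distance(rbind(a, e))[1, 2], 0)

  m <- pairwise_genetic_distance(sample_genotypes(20))
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("genetic distance agrees with ape::dist.gene on locus strings", {
  library(ape)
  set.seed(21)
  g <- sample_genotypes(40)
  ours <- pairwise_genetic_distance(g)
  df <- as.data.frame(sapply(1:10, function(l) {
    paste(g[, 2 * l - 1], g[, 2 * l], sep = "/")
  }))
  theirs <- as.matrix(ape::dist.gene(df, method = "percentage"))
  expect_equal(unname(ours), unname(theirs))
})

test_that("stratified distance sampling honors quotas and missing strata", {
  sim <- run_replicate(mini_config(horizon = 20), seed = 2)
  set.seed(1)
  out <- sample_for_distance_matrix(sim, per_patch_n = 5)
  expect_equal(nrow(out$sample), 15L)
  expect_equal(dim(out$dist), c(15L, 15L))
  expect_equal(as.integer(table(out$sample$patch)), rep(5L, 3))
  # per_patch_n = 1 degenerates to one individual per patch
  set.seed(1)
  out1 <- sample_for_distance_matrix(sim, per_patch_n = 1)
  expect_equal(dim(out1$dist), c(3L, 3L))
  # identical seeds give identical samples
  set.seed(7); s1 <- sample_for_distance_matrix(sim, per_patch_n = 4)
  set.seed(7); s2 <- sample_for_distance_matrix(sim, per_patch_n = 4)
  expect_identical(s1$sample, s2$sample)
})

test_that("correlograms are flat when genotypes are shuffled over space", {
  sim <- continuous_run("short", 1)
  set.seed(31)
  cg <- ibd_correlogram(sim, n_bins = 8, sample_n = 400)
  expect_s3_class(cg, "hexpop_correlogram")
  expect_equal(nrow(cg), 8L)
  expect_true(sum(cg$n_pairs) > 0)
  # permuting genotypes across locations kills the spatial signal
  snap <- get_snapshot(sim, 400)
  perm <- snap
  perm$geno <- snap$geno[sample(nrow(snap$geno)), ]
  sim_perm <- sim
  sim_perm$snapshots[["400"]] <- perm
  tst <- ibd_test(sim_perm, n_perm = 49, sample_n = 300)
  expect_gt(tst$p_value, 0.05)
})

test_that("migrant accounting follows the gap-crossing breeding definition", {
  fake <- list(
    first_breeding = tibble::tibble(
      step = c(5, 5, 6, 7, 8),
      natal_patch = c(1, 1, 2, 1, 3),
      bred_patch = c(2, 1, 2, 2, 1),
      crossed_gap = c(TRUE, TRUE, TRUE, FALSE, TRUE)
    ),
    landscape = list(cells = tibble::tibble(patch = rep(1:3, 10))),
    demography = tibble::tibble(step = 1:10, breeders = rep(2, 10),
                                breeder_age_sum = rep(10, 10))
  )
  ms <- migration_summary(fake, c(1, 10))
  # migrants: crossed AND first bred away from the natal patch (rows 1 and 5);
  # a crosser breeding at home (row 2) and a mover that never crossed (row 4)
  # are excluded
  expect_equal(ms$migrants, 2L)
  expect_equal(ms$generation_time, 5)
  expect_equal(ms$generations, 2)
  expect_equal(ms$migrants_per_generation, 1)
  expect_equal(ms$per_patch$emigrants, c(1L, 0L, 1L))
  expect_equal(ms$per_patch$immigrants, c(1L, 1L, 0L))
  expect_error(migration_summary(fake, c(20, 30)), "No breeding")
})

test_that("generation time is the mean maternal age over the window", {
  fake <- list(demography = tibble::tibble(
    step = 1:5, breeders = c(2, 3, 0, 1, 4),
    breeder_age_sum = c(4, 6, 0, 2, 8)
  ), steps = 5)
  expect_equal(generation_time(fake, c(1, 5)), 2)
  expect_error(generation_time(fake, c(3, 3)), "No births")
})

test_that("population trajectories partition the whole-population census", {
  sim <- run_replicate(mini_config(horizon = 25), seed = 9)
  tr <- population_trajectories(sim)
  tot <- tapply(tr$count, tr$step, sum)
  expect_equal(as.numeric(tot), as.numeric(sim$demography$n))
  # the extinction flag latches once a patch count first reaches zero
  for (p in unique(tr$patch)) {
    e <- tr[tr$patch == p, ]
    expect_equal(e$extinct, cumsum(e$count == 0) > 0)
  }
})
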