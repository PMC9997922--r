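# Observable responses: per-capita homozygosity, allele frequencies, allelic
# richness and evenness, heterozygosity deficit, pairwise genetic distance,
# isolation-by-distance correlograms, migration summaries, generation time,
# and per-patch population trajectories. Metric functions take genotype
# matrices / simulation objects and return plain values or tibbles.

#' Retrieve a stored genotype snapshot
#'
#' @param sim A `hexpop_sim`.
#' @param step Step of the snapshot (default: the latest stored).
#' @return A list with `step`, `id`, `cell`, `patch`, `age`, `sex`, `geno`.
#' @export
get_snapshot <- function(sim, step = NULL) {
  if (!length(sim$snapshots)) abort("This simulation stored no snapshots.")
  steps <- as.integer(names(sim$snapshots))
  if (is.null(step)) step <- max(steps)
  if (!step %in% steps) {
    abort(paste0("No snapshot at step ", step, "; available: ",
                 paste(steps, collapse = ", ")))
  }
  sim$snapshots[[as.character(step)]]
}

#' Per-capita homozygosity of a sample
#'
#' Fraction of homozygous genotypes across all loci and individuals:
#' homozygous-locus count / (n_loci x n).
#'
#' @param geno Genotype matrix of the sample.
#' @return A fraction in `[0, 1]`.
#' @export
per_capita_homozygosity <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (!nrow(geno)) abort("Empty sample.")
  mean(genotype_homozygosity(geno))
}

#' Allele frequencies at a locus
#'
#' @param geno Genotype matrix of the sample.
#' @param locus Locus index.
#' @param n_alleles Number of allele states (default 5).
#' @return Numeric vector of length `n_alleles`, summing to 1.
#' @export
allele_frequencies <- function(geno, locus, n_alleles = 5) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (!nrow(geno)) abort("Empty sample.")
  al <- c(geno[, 2L * locus - 1L], geno[, 2L * locus])
  tabulate(al, n_alleles) / (2 * nrow(geno))
}

#' Allelic richness at a locus
#'
#' Number of extant (nonzero-frequency) alleles.
#'
#' @inheritParams allele_frequencies
#' @return Integer count.
#' @export
allelic_richness <- function(geno, locus, n_alleles = 5) {
  sum(allele_frequencies(geno, locus, n_alleles) > 0)
}

#' Allelic evenness
#'
#' Shannon entropy of the extant allele frequencies normalized by the maximum
#' entropy for five alleles: `-sum(p * ln(p)) / ln(5)`, summing over extant
#' alleles only. Equals 1 for the uniform five-allele profile and 0 when a
#' single allele is extant.
#'
#' @param freqs Allele frequency vector (must sum to 1).
#' @param max_alleles Richness baseline for the normalization (default 5).
#' @return A value in `[0, 1]`.
#' @examples
#' allelic_evenness(rep(0.2, 5)) # 1
#' round(allelic_evenness(c(0.3, 0.25, 0.2, 0.15, 0.1)), 2) # 0.96
#' round(allelic_evenness(c(0.01, 0.04, 0.15, 0.3, 0.5)), 2) # 0.72
#' @export
allelic_evenness <- function(freqs, max_alleles = 5) {
  if (abs(sum(freqs) - 1) > 1e-6) abort("`freqs` must sum to 1.")
  p <- freqs[freqs > 0]
  -sum(p * log(p)) / log(max_alleles)
}

#' Heterozygosity deficit at a locus
#'
#' `H_obs - H_exp`, where `H_obs` is the observed heterozygote fraction and
#' `H_exp = 1 - sum(q_i^2)` over the extant alleles. The baseline shifts as
#' alleles are lost, unlike richness or evenness.
#'
#' @inheritParams allele_frequencies
#' @return A numeric value (near 0 under Hardy-Weinberg equilibrium).
#' @export
heterozygosity_deficit <- function(geno, locus, n_alleles = 5) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (!nrow(geno)) abort("Empty sample.")
  a <- geno[, 2L * locus - 1L]
  b <- geno[, 2L * locus]
  h_obs <- mean(a != b)
  q <- allele_frequencies(geno, locus, n_alleles)
  h_exp <- 1 - sum(q^2)
  h_obs - h_exp
}

#' Pairwise inter-individual genetic distance
#'
#' Fraction of loci at which two individuals' unordered allele pairs are not
#' identical: `{1,2}` vs `{1,1}` differs, `{1,2}` vs `{2,1}` does not.
#'
#' @param geno Genotype matrix (canonical sorted locus pairs).
#' @return A symmetric n x n matrix with zero diagonal, entries in `[0, 1]`.
#' @export
pairwise_genetic_distance <- function(geno) {
  if (is.null(dim(geno)) || nrow(geno) < 2) {
    abort("Need at least two genotypes.")
  }
  n <- nrow(geno)
  nl <- ncol(geno) %/% 2L
  d <- matrix(0, n, n)
  for (l in seq_len(nl)) {
    code <- geno[, 2L * l - 1L] * 8L + geno[, 2L * l]
    d <- d + outer(code, code, "!=")
  }
  d / nl
}

#' Patch-stratified sample with its genetic distance matrix
#'
#' Randomly selects `per_patch_n` individuals from each extant patch of a
#' genotype snapshot (with replacement only if a patch holds fewer) and
#' computes their pairwise genetic distance matrix. Extinct patches are
#' recorded as missing strata with a warning.
#'
#' @param sim A `hexpop_sim`.
#' @param step Snapshot step (default latest).
#' @param per_patch_n Individuals per patch (default 25).
#' @return A list with `sample` (tibble: `id`, `patch`, `cell`) and `dist`
#'   (the square distance matrix); missing patches in
#'   `attr(, "missing_patches")`.
#' @export
sample_for_distance_matrix <- function(sim, step = NULL, per_patch_n = 25) {
  snap <- get_snapshot(sim, step)
  patches <- sort(unique(sim$landscape$cells$patch))
  picks <- integer(0)
  missing <- integer(0)
  for (p in patches) {
    in_p <- which(snap$patch == p)
    if (!length(in_p)) {
      missing <- c(missing, p)
      next
    }
    replace <- length(in_p) < per_patch_n
    picks <- c(picks, sample(in_p, per_patch_n, replace = replace))
  }
  if (length(missing)) {
    warn(paste0("Extinct patch(es) at snapshot: ",
                paste(missing, collapse = ", "), "; stratum skipped."))
  }
  out <- list(
    sample = tibble(id = snap$id[picks], patch = snap$patch[picks],
                    cell = snap$cell[picks]),
    dist = pairwise_genetic_distance(snap$geno[picks, , drop = FALSE])
  )
  attr(out, "missing_patches") <- missing
  out
}

#' Isolation-by-distance correlogram
#'
#' Bins inter-individual geographic (hex) distances into equal-width classes
#' and reports the mean pairwise genetic distance and the pair count per
#' class (the counts diagnose spatial clumping).
#'
#' @param sim A `hexpop_sim`.
#' @param step Snapshot step (default latest).
#' @param n_bins Number of equal-width distance classes (default 10).
#' @param max_pairs Random pair subsample size for large snapshots.
#' @param sample_n Optional cap on the number of individuals used.
#' @return A tibble of class `hexpop_correlogram` with columns `bin`, `mid`,
#'   `mean_genetic_distance`, `n_pairs`.
#' @export
ibd_correlogram <- function(sim, step = NULL, n_bins = 10, max_pairs = 1e5,
                            sample_n = 2000) {
  pd <- ibd_pairs(sim, step, max_pairs, sample_n)
  rng <- range(pd$geo)
  if (rng[1] == rng[2]) {
    out <- tibble(bin = 1L, mid = rng[1],
                  mean_genetic_distance = mean(pd$gd), n_pairs = nrow(pd))
    class(out) <- c("hexpop_correlogram", class(out))
    return(out)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cls <- factor(findInterval(pd$geo, breaks, rightmost.closed = TRUE),
                levels = seq_len(n_bins))
  mean_gd <- as.numeric(tapply(pd$gd, cls, mean))
  counts <- as.integer(table(cls))
  out <- tibble(
    bin = seq_len(n_bins),
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_genetic_distance = mean_gd,
    n_pairs = counts
  )
  class(out) <- c("hexpop_correlogram", class(out))
  out
}

ibd_pairs <- function(sim, step = NULL, max_pairs = 1e5, sample_n = 2000) {
  snap <- get_snapshot(sim, step)
  n <- length(snap$id)
  if (n < 2) abort("Need at least two individuals.")
  use <- if (n > sample_n) sample.int(n, sample_n) else seq_len(n)
  nu <- length(use)
  npairs <- nu * (nu - 1) / 2
  if (npairs > max_pairs) {
    i <- sample.int(nu, max_pairs, replace = TRUE)
    j <- sample.int(nu, max_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
  } else {
    cmb <- utils::combn(nu, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
  }
  cells <- sim$landscape$cells
  ci <- snap$cell[use[i]]; cj <- snap$cell[use[j]]
  geo <- hex_distance(cells$q[ci], cells$r[ci], cells$q[cj], cells$r[cj])
  g <- snap$geno[use, , drop = FALSE]
  nl <- ncol(g) %/% 2L
  gd <- numeric(length(i))
  for (l in seq_len(nl)) {
    code <- g[, 2L * l - 1L] * 8L + g[, 2L * l]
    gd <- gd + (code[i] != code[j])
  }
  tibble(geo = geo, gd = gd / nl)
}

#' Test for isolation by distance against a permutation null
#'
#' Slope of genetic distance on geographic distance over sampled pairs,
#' compared with the distribution of slopes after randomly permuting
#' genotypes across locations.
#'
#' @inheritParams ibd_correlogram
#' @param n_perm Number of genotype permutations (default 99).
#' @return A list with `slope`, `perm_slopes`, and the upper-tail `p_value`.
#' @export
ibd_test <- function(sim, step = NULL, n_perm = 99, max_pairs = 2e4,
                     sample_n = 500) {
  snap <- get_snapshot(sim, step)
  n <- length(snap$id)
  use <- if (n > sample_n) sample.int(n, sample_n) else seq_len(n)
  nu <- length(use)
  cmb <- if (nu * (nu - 1) / 2 > max_pairs) {
    i <- sample.int(nu, max_pairs, replace = TRUE)
    j <- sample.int(nu, max_pairs, replace = TRUE)
    ok <- i != j
    rbind(i[ok], j[ok])
  } else {
    utils::combn(nu, 2)
  }
  i <- cmb[1, ]; j <- cmb[2, ]
  cells <- sim$landscape$cells
  ci <- snap$cell[use[i]]; cj <- snap$cell[use[j]]
  geo <- hex_distance(cells$q[ci], cells$r[ci], cells$q[cj], cells$r[cj])
  g <- snap$geno[use, , drop = FALSE]
  nl <- ncol(g) %/% 2L
  codes <- sapply(seq_len(nl), function(l) g[, 2L * l - 1L] * 8L + g[, 2L * l])
  gd_for <- function(perm) {
    gd <- numeric(length(i))
    for (l in seq_len(nl)) gd <- gd + (codes[perm[i], l] != codes[perm[j], l])
    gd / nl
  }
  slope_of <- function(gd) stats::cov(geo, gd) / stats::var(geo)
  obs <- slope_of(gd_for(seq_len(nu)))
  perm_slopes <- replicate(n_perm, slope_of(gd_for(sample.int(nu))))
  list(slope = obs, perm_slopes = perm_slopes,
       p_value = (1 + sum(perm_slopes >= obs)) / (n_perm + 1))
}

#' Migration summary over an epoch window
#'
#' A migrant is an individual that crossed a barrier gap and whose first
#' reproduction occurred outside its natal patch; non-breeders and gap
#' crossers that first bred in their natal patch are excluded. Rates are
#' stratified by sending (natal) and receiving patch, and migrants per
#' generation uses the window's own measured generation time.
#'
#' @param sim A `hexpop_sim`.
#' @param window Integer `c(start, end)` step window (inclusive).
#' @return A list of class `hexpop_migration`: per-patch tibble (`patch`,
#'   `first_breeders`, `emigrants`, `immigrants`, `philopatric`,
#'   `emigration_rate`, `immigration_rate`, `philopatric_fraction`), plus
#'   `migrants`, `generation_time`, `generations`, and
#'   `migrants_per_generation`.
#' @export
migration_summary <- function(sim, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  fb <- sim$first_breeding
  fb <- fb[fb$step >= window[1] & fb$step <= window[2], ]
  if (!nrow(fb)) abort("No breeding events in the window.")
  np <- max(sim$landscape$cells$patch)
  mig <- fb$crossed_gap & fb$natal_patch != fb$bred_patch
  per_patch <- tibble(
    patch = seq_len(np),
    first_breeders = tabulate(fb$natal_patch, np),
    emigrants = tabulate(fb$natal_patch[mig], np),
    immigrants = tabulate(fb$bred_patch[mig], np),
    philopatric = tabulate(fb$natal_patch[fb$natal_patch == fb$bred_patch], np)
  )
  per_patch$emigration_rate <- ifelse(per_patch$first_breeders > 0,
    per_patch$emigrants / per_patch$first_breeders, NA_real_)
  breeders_by_bred <- tabulate(fb$bred_patch, np)
  per_patch$immigration_rate <- ifelse(breeders_by_bred > 0,
    per_patch$immigrants / breeders_by_bred, NA_real_)
  per_patch$philopatric_fraction <- ifelse(per_patch$first_breeders > 0,
    per_patch$philopatric / per_patch$first_breeders, NA_real_)
  gt <- generation_time(sim, window)
  gens <- (window[2] - window[1] + 1) / gt
  structure(list(
    per_patch = per_patch,
    window = window,
    migrants = sum(mig),
    generation_time = gt,
    generations = gens,
    migrants_per_generation = sum(mig) / gens
  ), class = "hexpop_migration")
}

#' @export
print.hexpop_migration <- function(x, ...) {
  cat("<hexpop_migration> steps ", x$window[1], "-", x$window[2], ": ",
      x$migrants, " migrants over ", round(x$generations, 1),
      " generations (", round(x$migrants_per_generation, 3),
      " migrants/generation)\n", sep = "")
  print(x$per_patch)
  invisible(x)
}

#' Generation time over a window
#'
#' The observed mean age of reproducing females across all reproduction
#' events in the window.
#'
#' @param sim A `hexpop_sim`.
#' @param window Integer `c(start, end)` step window (inclusive); default the
#'   whole run after a 100-step burn-in.
#' @return Mean maternal age in years.
#' @export
generation_time <- function(sim, window = c(min(101, sim$steps), sim$steps)) {
  d <- sim$demography
  d <- d[d$step >= window[1] & d$step <= window[2], ]
  if (!sum(d$breeders)) abort("No births in the window.")
  sum(d$breeder_age_sum) / sum(d$breeders)
}

#' Per-patch population trajectories
#'
#' @param sim A `hexpop_sim`.
#' @return A tibble `step`, `patch`, `count`, `extinct` (count reached 0).
#' @export
population_trajectories <- function(sim) {
  out <- sim$census[c("step", "patch", "count")]
  out <- dplyr::group_by(out, .data$patch)
  out <- dplyr::mutate(out, extinct = cumsum(.data$count == 0) > 0)
  dplyr::ungroup(out)
}

#' Per-patch allele frequency trajectories
#'
#' Frequencies from the logged per-patch allele counts, joined with the
#' adaptation map so adaptive-allele dynamics can be tracked.
#'
#' @param sim A `hexpop_sim`.
#' @param loci Optional subset of locus indices.
#' @return A tibble `step`, `patch`, `locus`, `allele`, `freq`, `adaptation`.
#' @export
allele_trajectories <- function(sim, loci = NULL) {
  ac <- sim$allele_counts
  if (!is.null(loci)) ac <- ac[ac$locus %in% loci, ]
  ac <- dplyr::group_by(ac, .data$step, .data$patch, .data$locus)
  ac <- dplyr::mutate(ac, freq = .data$count / pmax(1, sum(.data$count)))
  ac <- dplyr::ungroup(ac)
  dplyr::left_join(ac, sim$config$loci[c("locus", "allele", "adaptation")],
                   by = c("locus", "allele"))
}
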