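# Diploid genetics: ten unlinked loci, five alleles each (coded 1-5).
# Genotypes are stored as an n x 2*n_loci integer matrix with columns
# L1a, L1b, ..., L10a, L10b; each locus pair is kept in canonical (sorted)
# order because phase is never distinguished. There is no mutation operator
# anywhere in the code path.

#' Default locus specification table
#'
#' Ten loci with five alleles each. Loci 1-5 are fully neutral with initial
#' frequency profiles that are equal, unequal (both orientations), or
#' dominated by a common allele with rare alternatives; loci 6-10 each carry
#' at least one locally adaptive allele (locus 6 carries two: allele 2 adapted
#' to habitat type A, allele 4 to type B).
#'
#' @return A tibble with columns `locus`, `allele`, `freq`, `adaptation`
#'   (`"neutral"`, `"A"`, or `"B"`).
#' @export
locus_table_default <- function() {
  freq <- c(
    0.20, 0.20, 0.20, 0.20, 0.20,
    0.30, 0.25, 0.20, 0.15, 0.10,
    0.10, 0.15, 0.20, 0.25, 0.30,
    0.01, 0.04, 0.15, 0.30, 0.50,
    0.50, 0.30, 0.15, 0.04, 0.01,
    0.20, 0.20, 0.20, 0.20, 0.20,
    0.30, 0.25, 0.20, 0.15, 0.10,
    0.10, 0.15, 0.20, 0.25, 0.30,
    0.01, 0.04, 0.15, 0.30, 0.50,
    0.50, 0.30, 0.15, 0.04, 0.01
  )
  adaptation <- rep("neutral", 50)
  adaptation[(6 - 1) * 5 + 2] <- "A"
  adaptation[(6 - 1) * 5 + 4] <- "B"
  adaptation[(7 - 1) * 5 + 5] <- "A"
  adaptation[(8 - 1) * 5 + 5] <- "B"
  adaptation[(9 - 1) * 5 + 1] <- "A"
  adaptation[(10 - 1) * 5 + 1] <- "B"
  tibble(
    locus = rep(1:10, each = 5),
    allele = rep(1:5, times = 10),
    freq = freq,
    adaptation = adaptation
  )
}

validate_loci <- function(loci) {
  need <- c("locus", "allele", "freq", "adaptation")
  if (!all(need %in% names(loci))) {
    abort(paste0("Locus table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(loci$freq < 0)) abort("Initial allele frequencies must be >= 0.")
  sums <- tapply(loci$freq, loci$locus, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    bad <- names(sums)[abs(sums - 1) > 1e-9]
    abort(paste0("Initial allele frequencies must sum to 1 at every locus; ",
                 "locus ", paste(bad, collapse = ", "), " does not."))
  }
  if (!all(loci$adaptation %in% c("neutral", "A", "B"))) {
    abort("`adaptation` must be \"neutral\", \"A\", or \"B\".")
  }
  invisible(loci)
}

n_loci <- function(loci) length(unique(loci$locus))

# n_loci x n_alleles matrices of initial frequencies / adaptation codes
# (0 = neutral, 1 = habitat A, 2 = habitat B)
loci_freq_matrix <- function(loci) {
  loci <- dplyr::arrange(loci, .data$locus, .data$allele)
  matrix(loci$freq, nrow = n_loci(loci), byrow = TRUE)
}

loci_adaptation_matrix <- function(loci) {
  loci <- dplyr::arrange(loci, .data$locus, .data$allele)
  matrix(match(loci$adaptation, c("A", "B"), nomatch = 3L) %% 3L,
         nrow = n_loci(loci), byrow = TRUE)
}

geno_colnames <- function(nl) {
  paste0("L", rep(seq_len(nl), each = 2), c("a", "b"))
}

#' Sample founder genotypes from initial allele frequencies
#'
#' Each of the two alleles at each locus is drawn independently from the
#' locus's initial frequency profile; there is no spatial stratification.
#'
#' @param n Number of individuals.
#' @param loci Locus specification table ([locus_table_default()]).
#' @return An `n` x `2 * n_loci` integer matrix (columns `L1a`, `L1b`, ...),
#'   each locus pair in canonical sorted order.
#' @export
sample_genotypes <- function(n, loci = locus_table_default()) {
  validate_loci(loci)
  fm <- loci_freq_matrix(loci)
  nl <- nrow(fm)
  geno <- matrix(0L, n, 2L * nl, dimnames = list(NULL, geno_colnames(nl)))
  for (l in seq_len(nl)) {
    a <- sample.int(ncol(fm), 2L * n, replace = TRUE, prob = fm[l, ])
    a1 <- a[seq_len(n)]
    a2 <- a[n + seq_len(n)]
    geno[, 2L * l - 1L] <- pmin(a1, a2)
    geno[, 2L * l] <- pmax(a1, a2)
  }
  geno
}

#' Mendelian inheritance with free recombination
#'
#' At each locus independently (zero linkage), one uniformly chosen allele
#' from each parent; no mutation, so offspring alleles are always a subset of
#' the parental alleles.
#'
#' @param mother,father Genotype matrices with matching dimensions; row i of
#'   each are the parents of offspring i.
#' @return Offspring genotype matrix, canonical locus order.
#' @export
mate_genotypes <- function(mother, father) {
  if (is.null(dim(mother))) mother <- matrix(mother, nrow = 1)
  if (is.null(dim(father))) father <- matrix(father, nrow = 1)
  stopifnot(identical(dim(mother), dim(father)))
  n <- nrow(mother)
  nl <- ncol(mother) %/% 2L
  off <- matrix(0L, n, 2L * nl, dimnames = list(NULL, geno_colnames(nl)))
  for (l in seq_len(nl)) {
    i <- 2L * l - 1L
    am <- ifelse(runif(n) < 0.5, mother[, i], mother[, i + 1L])
    af <- ifelse(runif(n) < 0.5, father[, i], father[, i + 1L])
    off[, i] <- pmin(am, af)
    off[, i + 1L] <- pmax(am, af)
  }
  off
}

#' Count locally adaptive allele copies for a habitat type
#'
#' Number of allele copies (0-2 per locus) whose adaptation type matches the
#' given habitat, over the loci that carry adaptive alleles.
#'
#' @param geno Genotype matrix (or a single genotype vector).
#' @param habitat `"A"` or `"B"` (or codes 1/2).
#' @param loci Locus specification table.
#' @return Integer vector, one count per individual.
#' @export
count_adaptive_alleles <- function(geno, habitat, loci = locus_table_default()) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  code <- if (is.numeric(habitat)) as.integer(habitat) else match(toupper(habitat), c("A", "B"))
  if (length(code) != 1 || is.na(code) || !code %in% 1:2) {
    abort("`habitat` must be a single \"A\" or \"B\" (untyped habitat has no adaptive match).")
  }
  adap <- loci_adaptation_matrix(loci)
  nl <- nrow(adap)
  counts <- integer(nrow(geno))
  for (l in seq_len(nl)) {
    if (!any(adap[l, ] == code)) next
    for (j in c(2L * l - 1L, 2L * l)) {
      counts <- counts + (adap[l, geno[, j]] == code)
    }
  }
  as.integer(counts)
}

#' Per-genotype homozygosity
#'
#' Fraction of loci at which the two alleles are identical.
#'
#' @param geno Genotype matrix (or single genotype vector).
#' @return Numeric vector in `[0, 1]`, one value per individual.
#' @export
genotype_homozygosity <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  nl <- ncol(geno) %/% 2L
  a <- geno[, 2L * seq_len(nl) - 1L, drop = FALSE]
  b <- geno[, 2L * seq_len(nl), drop = FALSE]
  rowMeans(a == b)
}
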