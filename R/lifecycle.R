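# Annual life cycle: (a) resource acquisition under scramble competition,
# (b) exclusive pair formation, (c) density-dependent reproduction,
# (d) correlated random-walk natal dispersal, (e) survival. Operations here
# are pure given the landscape and R's RNG state; the engine sequences them.

#' Demographic parameters
#'
#' @param s_juv,s_adult Annual survival probability by stage class.
#' @param resource_threshold,resource_penalty Individuals acquiring less than
#'   `resource_threshold` of their resource goal incur `resource_penalty`
#'   additional probability of mortality (additive on the mortality scale,
#'   floored at survival 0).
#' @param resource_goal Resource units an individual attempts to acquire per
#'   step; one habitat cell produces one unit per step. The default (2.5)
#'   places the stationary population density near the saturated initial
#'   density of one adult per cell.
#' @param fecundity_max Mean litter size at full resource acquisition; the
#'   realized litter is Normal(fecundity_max * resource_fraction,
#'   fecundity_sd), rounded and truncated at zero.
#' @param fecundity_sd Standard deviation of the reproductive-rate draw.
#' @param pairing_radius Hex-distance radius within which a female can pair
#'   with a male (reachable without crossing an impassable edge).
#' @return A list of class `hexpop_demography`.
#' @export
demography_params <- function(s_juv = 0.500, s_adult = 0.885,
                              resource_threshold = 0.20,
                              resource_penalty = 0.10,
                              resource_goal = 2.5,
                              fecundity_max = 1.2, fecundity_sd = 0.5,
                              pairing_radius = 3) {
  p <- list(s_juv = s_juv, s_adult = s_adult,
            resource_threshold = resource_threshold,
            resource_penalty = resource_penalty,
            resource_goal = resource_goal,
            fecundity_max = fecundity_max, fecundity_sd = fecundity_sd,
            pairing_radius = pairing_radius)
  probs <- c(p$s_juv, p$s_adult, p$resource_threshold, p$resource_penalty)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (p$fecundity_max <= 0) abort("`fecundity_max` must be positive.")
  if (p$fecundity_sd < 0) abort("`fecundity_sd` must be non-negative.")
  structure(p, class = "hexpop_demography")
}

#' Dispersal parameters
#'
#' @param range `"short"` (path lengths uniform on 1-5 hexagon steps),
#'   `"long"` (uniform on 5-25), or a length-2 integer vector `c(min, max)`.
#' @param autocorrelation Directional persistence on a 0 (uniformly random
#'   step directions) to 100 (perfectly linear paths) scale; the previous
#'   direction is kept with probability `autocorrelation / 100`.
#' @return A list of class `hexpop_dispersal`.
#' @export
dispersal_params <- function(range = "short", autocorrelation = 75) {
  if (is.character(range)) {
    range <- switch(match.arg(range, c("short", "long")),
                    short = c(1L, 5L), long = c(5L, 25L))
  }
  range <- as.integer(range)
  if (length(range) != 2 || any(range <= 0) || range[1] > range[2]) {
    abort("`range` must be \"short\", \"long\", or positive c(min, max).")
  }
  if (autocorrelation < 0 || autocorrelation > 100) {
    abort("`autocorrelation` must be in [0, 100].")
  }
  structure(list(range = range, autocorrelation = autocorrelation),
            class = "hexpop_dispersal")
}

#' Scramble-competition resource allocation
#'
#' Every habitat cell yields one resource unit per step, split equally among
#' all individuals whose reachable neighborhood contains it. An individual's
#' acquired total, divided by its resource goal and clipped to `[0, 1]`, is
#' its resource fraction.
#'
#' @param landscape A `hexpop_landscape` (the current epoch's reachability is
#'   used).
#' @param cells Integer vector: the occupied cell of each individual.
#' @param goal Resource goal per individual (units).
#' @return Numeric vector of resource fractions, one per individual.
#' @export
allocate_resources <- function(landscape, cells, goal = 1) {
  counts <- tabulate(cells, landscape$n)
  competitors <- as.numeric(landscape$M %*% counts)
  yield <- ifelse(competitors > 0, 1 / competitors, 0)
  acquired <- as.numeric(landscape$M %*% yield)
  pmin(1, acquired[cells] / goal)
}

#' Exclusive (monogamous) pair formation
#'
#' Adult females, processed in uniformly random order (so no age or id class
#' is systematically advantaged when local males are scarce), each pair with
#' the nearest unpaired adult male reachable within the pairing radius
#' without crossing an impassable edge; ties are broken by smallest male id.
#' Each adult joins at most one pair per step.
#'
#' @param landscape A `hexpop_landscape`.
#' @param adults A data frame with columns `id`, `sex` (`"F"`/`"M"` or 1/2),
#'   and `cell`.
#' @return A tibble with columns `female`, `male` (ids), one row per pair.
#' @export
form_pairs <- function(landscape, adults) {
  sx <- adults$sex
  if (!is.numeric(sx)) sx <- match(toupper(as.character(sx)), c("F", "M"))
  ord <- order(adults$id)
  f <- ord[sx[ord] == 1L]
  m <- ord[sx[ord] == 2L]
  if (!length(f) || !length(m)) {
    return(tibble(female = integer(0), male = integer(0)))
  }
  f <- f[sample.int(length(f))]
  pos <- pairs_cpp(adults$cell[f], adults$cell[m],
                   landscape$reach$off, landscape$reach$cell,
                   landscape$reach$dist, landscape$n)
  hit <- pos > 0L
  tibble(female = adults$id[f[hit]], male = adults$id[m[pos[hit]]])
}

#' Litter size for a paired female
#'
#' Draws Normal(`fecundity_max * resource_fraction`, `fecundity_sd`), rounds
#' to the nearest integer, and truncates at zero.
#'
#' @param resource_fraction Resource fractions of the paired females.
#' @param params A `hexpop_demography`.
#' @return Non-negative integer vector of offspring counts.
#' @export
offspring_number <- function(resource_fraction, params = demography_params()) {
  n <- length(resource_fraction)
  draw <- rnorm(n, params$fecundity_max * resource_fraction, params$fecundity_sd)
  pmax(0L, as.integer(round(draw)))
}

#' Correlated random-walk natal dispersal
#'
#' Each juvenile draws a path length uniformly from the configured integer
#' range and takes that many cell-to-cell steps. The previous direction is
#' kept with probability `autocorrelation / 100`; a proposed move across an
#' edge with permeability p succeeds with probability p per encounter, and a
#' failed crossing consumes the step at the barrier while redirecting the
#' walker uniformly among the currently passable edges. Matrix cells are
#' never entered.
#'
#' @param landscape A `hexpop_landscape`.
#' @param cells Natal cell of each disperser.
#' @param params A `hexpop_dispersal`.
#' @return A tibble with columns `cell` (settlement), `crossed_gap` (whether
#'   any successful crossing used an edge with 0 < p < 1), and `path_length`.
#' @export
disperse <- function(landscape, cells, params = dispersal_params()) {
  n <- length(cells)
  if (!n) {
    return(tibble(cell = integer(0), crossed_gap = logical(0),
                  path_length = integer(0)))
  }
  lo <- params$range[1]; hi <- params$range[2]
  len <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
  len[len > hi] <- hi
  res <- disperse_cpp(as.integer(cells), len, landscape$nbr, landscape$perm,
                      params$autocorrelation)
  tibble(cell = res$cell, crossed_gap = res$crossed, path_length = len)
}

#' Annual survival probability
#'
#' Base survival by stage class, minus the additional mortality for
#' individuals below the resource threshold, plus (for juveniles on typed
#' habitat) the additive survival benefit S per matching adaptive allele
#' copy; the result is clamped to `[0, 1]`.
#'
#' @param stage `"juvenile"`/`"adult"` (or 1/2), vectorized.
#' @param resource_fraction Resource fraction acquired this step.
#' @param params A `hexpop_demography`.
#' @param adaptive_copies Matching adaptive allele copies (juveniles only).
#' @param S Survival benefit per adaptive allele copy.
#' @return Numeric vector of survival probabilities.
#' @export
survival_probability <- function(stage, resource_fraction,
                                 params = demography_params(),
                                 adaptive_copies = 0, S = 0) {
  st <- if (is.numeric(stage)) as.integer(stage)
        else match(tolower(as.character(stage)), c("juvenile", "adult"))
  if (anyNA(st)) abort("`stage` must be \"juvenile\" or \"adult\".")
  p <- ifelse(st == 1L, params$s_juv, params$s_adult)
  p <- p - params$resource_penalty * (resource_fraction < params$resource_threshold)
  p <- p + S * adaptive_copies * (st == 1L)
  pmin(1, pmax(0, p))
}

#' Apply independent Bernoulli survival draws
#'
#' @param p Survival probability per individual.
#' @return Logical vector: `TRUE` for survivors.
#' @export
apply_survival <- function(p) {
  runif(length(p)) < p
}
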