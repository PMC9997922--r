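# broom-style accessors for simulation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation's per-patch time series
#'
#' @param x A `hexpop_sim`.
#' @param ... Unused.
#' @return A tibble `step`, `patch`, `count`, `homozygosity`.
#' @export
tidy.hexpop_sim <- function(x, ...) {
  as_tibble(x$census)
}

#' One-row summary of a simulation
#'
#' @param x A `hexpop_sim`.
#' @param ... Unused.
#' @return A tibble with `steps`, `seed`, `final_n`, `patches_extinct`,
#'   `generation_time` (mean maternal age after a 100-step burn-in), and
#'   `final_homozygosity` (population mean).
#' @export
glance.hexpop_sim <- function(x, ...) {
  last <- x$census[x$census$step == x$steps, ]
  gt <- tryCatch(generation_time(x), error = function(e) NA_real_)
  hom <- stats::weighted.mean(last$homozygosity, last$count, na.rm = TRUE)
  tibble(
    steps = x$steps,
    seed = x$seed,
    final_n = sum(last$count),
    patches_extinct = sum(last$count == 0),
    generation_time = gt,
    final_homozygosity = hom
  )
}

#' @rdname tidy.hexpop_sim
#' @export
tidy.hexpop_migration <- function(x, ...) {
  x$per_patch
}

#' @rdname glance.hexpop_sim
#' @export
glance.hexpop_migration <- function(x, ...) {
  tibble(
    window_start = x$window[1], window_end = x$window[2],
    migrants = x$migrants,
    generation_time = x$generation_time,
    generations = x$generations,
    migrants_per_generation = x$migrants_per_generation
  )
}

#' @rdname glance.hexpop_sim
#' @export
glance.hexpop_experiment <- function(x, ...) {
  dplyr::bind_cols(
    x$index,
    dplyr::bind_rows(lapply(x$sims, glance))
  )
}
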