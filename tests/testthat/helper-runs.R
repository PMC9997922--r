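# Shared fixtures: a small three-patch landscape for cheap unit tests, and
# lazily cached full-scenario runs reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# Three patches (8x10 large, 4x5 medium, 2x3 small); medium and small abut the
# large patch only, giving interfaces 1-2 and 1-3.
mini_layout <- function() {
  tibble::tibble(
    patch_id = 1:3,
    label = c("L", "M", "S"),
    cols = c(8L, 4L, 2L),
    rows = c(10L, 5L, 3L),
    col0 = c(0L, -4L, 8L),
    row0 = c(0L, 2L, 3L)
  )
}

mini_epochs <- function(horizon, names, bounds, barrier, gap_p = 0,
                        selection = 0, habitat = FALSE) {
  tibble::tibble(
    name = names,
    start = c(1, head(bounds, -1) + 1),
    end = bounds,
    barrier = barrier,
    gap_permeability = gap_p,
    selection = selection,
    habitat = habitat
  )
}

mini_config <- function(horizon = 40, ..., epochs = NULL) {
  if (is.null(epochs)) {
    epochs <- tibble::tibble(
      name = "continuous", start = 1, end = horizon, barrier = "none",
      gap_permeability = 0, selection = 0, habitat = FALSE
    )
  }
  sim_config(patches = mini_layout(), horizon = horizon, epochs = epochs,
             habitat_A = c(1), habitat_B = c(2, 3),
             snapshot_steps = max(epochs$end), ...)
}

# Full-scenario continuous-epoch run (default landscape), 400 steps.
continuous_run <- function(dispersal, seed) {
  cached_run(paste0("cont_", dispersal, "_", seed), {
    cfg <- sim_config(
      dispersal = dispersal, horizon = 400,
      epochs = tibble::tibble(
        name = "continuous", start = 1, end = 400, barrier = "none",
        gap_permeability = 0, selection = 0, habitat = FALSE),
      snapshot_steps = 400)
    run_replicate(cfg, seed = seed)
  })
}

# Burn-in (continuous, 150 steps) followed by 500 semi-connected steps.
migration_run <- function(dispersal, gap_p, seed) {
  cached_run(paste0("mig_", dispersal, "_", gap_p, "_", seed), {
    cfg <- sim_config(
      dispersal = dispersal, gap_permeability = gap_p, horizon = 650,
      epochs = tibble::tibble(
        name = c("continuous", "semi_connected"),
        start = c(1, 151), end = c(150, 650),
        barrier = c("none", "gapped"), gap_permeability = c(0, gap_p),
        selection = 0, habitat = FALSE),
      snapshot_steps = 650)
    run_replicate(cfg, seed = seed)
  })
}

# Continuous burn-in then a 300-step isolated epoch (drift only).
isolated_run <- function(seed) {
  cached_run(paste0("iso_", seed), {
    cfg <- sim_config(
      horizon = 400,
      epochs = tibble::tibble(
        name = c("continuous", "isolated"),
        start = c(1, 101), end = c(100, 400),
        barrier = c("none", "absolute"), gap_permeability = 0,
        selection = 0, habitat = FALSE),
      snapshot_steps = c(100, 400))
    run_replicate(cfg, seed = seed)
  })
}

# Continuous burn-in then a gapped epoch with strong local selection.
selection_run <- function(seed) {
  cached_run(paste0("sel_", seed), {
    cfg <- sim_config(
      selection = 0.10, gap_permeability = 0.70, horizon = 300,
      epochs = tibble::tibble(
        name = c("continuous", "semi_connected_selection"),
        start = c(1, 101), end = c(100, 300),
        barrier = c("none", "gapped"), gap_permeability = c(0, 0.70),
        selection = c(0, 0.10), habitat = c(FALSE, TRUE)),
      snapshot_steps = 300)
    run_replicate(cfg, seed = seed)
  })
}

mini_land <- function() {
  cached_run("mini_land", build_landscape(mini_layout(), gap_edges = 1))
}
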