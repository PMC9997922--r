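# Simulation engine: configuration, initialization, the per-step event
# sequence (epoch transition -> resources -> pairing -> reproduction ->
# juvenile dispersal -> survival -> aging/promotion), and replicate /
# treatment management. A single R RNG stream per replicate, with a fixed
# iteration order over individuals (ascending id), makes every output a
# deterministic function of (config, seed).

#' Default epoch schedule
#'
#' Four scheduled landscape epochs: continuous (free movement), isolated
#' (absolute inter-patch barriers), semi-connected (barrier gaps), and
#' semi-connected with local selection (gaps plus habitat typing). With the
#' standard 1000-step epochs the boundaries fall at steps 1001, 2001, and
#' 3001; a horizon beyond 4000 extends the final epoch.
#'
#' @param horizon Total number of simulation steps.
#' @param gap_permeability Per-encounter gap transmission probability for the
#'   gapped epochs.
#' @param selection Survival benefit S per adaptive allele copy in the
#'   selection epoch.
#' @param epoch_length Length of each scheduled epoch (default 1000).
#' @return A tibble with columns `name`, `start`, `end`, `barrier`,
#'   `gap_permeability`, `selection`, `habitat`.
#' @export
epoch_schedule <- function(horizon = 4000, gap_permeability = 0.70,
                           selection = 0.10, epoch_length = 1000) {
  sched <- tibble(
    name = c("continuous", "isolated", "semi_connected",
             "semi_connected_selection"),
    start = c(1, epoch_length + 1, 2 * epoch_length + 1, 3 * epoch_length + 1),
    end = c(epoch_length, 2 * epoch_length, 3 * epoch_length, 4 * epoch_length),
    barrier = c("none", "absolute", "gapped", "gapped"),
    gap_permeability = c(0, 0, gap_permeability, gap_permeability),
    selection = c(0, 0, 0, selection),
    habitat = c(FALSE, FALSE, FALSE, TRUE)
  )
  sched <- sched[sched$start <= horizon, ]
  sched$end[nrow(sched)] <- horizon
  sched
}

#' Simulation configuration
#'
#' Collects the full scenario: landscape layout and gap geometry, epoch
#' schedule, demographic and dispersal parameters, selection strength, gap
#' permeability, locus table, horizon, replication, and logging cadence. The
#' defaults are the built-in six-patch study scenario.
#'
#' @param dispersal `"short"`, `"long"`, or an integer `c(min, max)` range of
#'   dispersal path lengths.
#' @param selection Survival benefit S per adaptive allele copy (strong 0.10
#'   or weak 0.01 in the factorial design).
#' @param gap_permeability Barrier-gap transmission probability per encounter
#'   (high 0.70 or low 0.02 in the factorial design).
#' @param horizon Number of simulation steps (default 4000; 5000 extends the
#'   selection epoch).
#' @param epochs Epoch schedule tibble; defaults to
#'   [epoch_schedule()] built from the arguments above.
#' @param patches Landscape layout ([hex_layout_default()]).
#' @param gap_edges Gap edges per patch interface.
#' @param loci Locus specification table ([locus_table_default()]).
#' @param demography A [demography_params()] object.
#' @param autocorrelation Dispersal directional persistence (0-100).
#' @param habitat_A,habitat_B Patch ids assigned to habitat types A and B in
#'   epochs with habitat typing (defaults interleave types so every patch
#'   adjoins at least one patch of the opposite type).
#' @param snapshot_steps Steps at which full genotype snapshots are stored
#'   (default: the last step of every epoch).
#' @param allele_log_every Cadence (in steps) of per-patch allele-count
#'   logging; epoch-end steps are always logged.
#' @param replicates Replicates per treatment in [run_experiment()].
#' @param base_seed Base seed from which treatment/replicate seeds derive.
#' @return A list of class `hexpop_config`.
#' @export
sim_config <- function(dispersal = "short",
                       selection = 0.10,
                       gap_permeability = 0.70,
                       horizon = 4000,
                       epochs = NULL,
                       patches = hex_layout_default(),
                       gap_edges = 1,
                       loci = locus_table_default(),
                       demography = demography_params(),
                       autocorrelation = 75,
                       habitat_A = c(1, 4, 6),
                       habitat_B = c(2, 3, 5),
                       snapshot_steps = NULL,
                       allele_log_every = 50,
                       replicates = 10,
                       base_seed = 1) {
  if (is.null(epochs)) {
    epochs <- epoch_schedule(horizon, gap_permeability, selection)
  }
  need <- c("name", "start", "end", "barrier", "gap_permeability",
            "selection", "habitat")
  if (!all(need %in% names(epochs))) {
    abort(paste0("`epochs` must have columns: ", paste(need, collapse = ", ")))
  }
  epochs <- epochs[order(epochs$start), ]
  if (epochs$start[1] != 1 || epochs$end[nrow(epochs)] != horizon ||
      (nrow(epochs) > 1 &&
       any(epochs$start[-1] != epochs$end[-nrow(epochs)] + 1))) {
    abort("Epochs must tile steps 1..horizon without gaps or overlap.")
  }
  if (any(epochs$selection > 0 & !epochs$habitat)) {
    abort("An epoch with selection > 0 must assign habitat types.")
  }
  validate_loci(loci)
  if (length(intersect(habitat_A, habitat_B))) {
    abort("`habitat_A` and `habitat_B` must not share patch ids.")
  }
  structure(list(
    dispersal = dispersal_params(dispersal, autocorrelation),
    selection = selection,
    gap_permeability = gap_permeability,
    horizon = as.integer(horizon),
    epochs = epochs,
    patches = patches,
    gap_edges = gap_edges,
    loci = loci,
    demography = demography,
    habitat_A = habitat_A,
    habitat_B = habitat_B,
    snapshot_steps = if (is.null(snapshot_steps)) as.integer(epochs$end)
                     else as.integer(snapshot_steps),
    allele_log_every = as.integer(allele_log_every),
    replicates = as.integer(replicates),
    base_seed = as.integer(base_seed)
  ), class = "hexpop_config")
}

#' The factorial treatment grid
#'
#' Dispersal behavior (short vs long) x selection strength (0.10 vs 0.01) x
#' barrier gap permeability (0.02 vs 0.70): eight treatment combinations.
#'
#' @return A tibble with columns `treatment`, `dispersal`, `selection`,
#'   `gap_permeability`.
#' @export
treatment_grid <- function() {
  g <- tidyr::expand_grid(
    dispersal = c("short", "long"),
    selection = c(0.10, 0.01),
    gap_permeability = c(0.02, 0.70)
  )
  dplyr::bind_cols(tibble(treatment = seq_len(nrow(g))), g)
}

epoch_spec_from_row <- function(config, row) {
  habitat <- NULL
  if (isTRUE(row$habitat)) {
    habitat <- setNames(
      c(rep("A", length(config$habitat_A)), rep("B", length(config$habitat_B))),
      c(config$habitat_A, config$habitat_B)
    )
  }
  epoch_spec(row$name, barrier = row$barrier,
             gap_permeability = row$gap_permeability,
             selection = row$selection, habitat = habitat)
}

#' Initialize simulation state
#'
#' Saturates the landscape with adults: one age-1 adult per habitat cell, sex
#' assigned 50/50 at random, founder genotypes drawn from the initial allele
#' frequencies with no spatial stratification.
#'
#' @param config A `hexpop_config`.
#' @return An environment of class `hexpop_state`.
#' @export
initialize_state <- function(config) {
  stopifnot(inherits(config, "hexpop_config"))
  land <- build_landscape(config$patches, config$gap_edges)
  land <- apply_epoch(land, epoch_spec_from_row(config, config$epochs[1, ]))
  n <- land$n
  np <- max(land$cells$patch)
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$land <- land
  state$patchv <- land$cells$patch
  state$np <- np
  state$step <- 0L
  state$epoch_name <- config$epochs$name[1]
  state$next_id <- n + 1L
  state$pop <- list(
    id = seq_len(n),
    sex = ifelse(runif(n) < 0.5, 1L, 2L),
    age = rep(1L, n),
    cell = seq_len(n),
    natal = land$cells$patch,
    resource = rep(1, n),
    crossed = rep(FALSE, n),
    bred = rep(NA_integer_, n),
    geno = sample_genotypes(n, config$loci)
  )
  h <- config$horizon
  state$log <- list2env(list(
    census = matrix(0L, h, np),
    hom = matrix(NA_real_, h, np),
    born = matrix(0L, h, np),
    settled = matrix(0L, h, np),
    deaths_juv = matrix(0L, h, np),
    deaths_adult = matrix(0L, h, np),
    breed_n = integer(h),
    breed_agesum = numeric(h),
    gap_crossings = integer(h),
    firstbreed = vector("list", h),
    kernel = list(),
    allele_counts = list(),
    snapshots = list()
  ), parent = emptyenv())
  class(state) <- "hexpop_state"
  state
}

allele_count_array <- function(geno, patch, np, nl) {
  out <- array(0L, c(np, 5L, nl))
  for (l in seq_len(nl)) {
    al <- c(geno[, 2L * l - 1L], geno[, 2L * l])
    key <- (al - 1L) * np + rep(patch, 2L)
    out[, , l] <- tabulate(key, np * 5L)
  }
  out
}

#' Advance the simulation by one step
#'
#' Applies an epoch transition if the step crosses an epoch boundary, then
#' executes the life-cycle events in order: resource acquisition, pair
#' formation, reproduction, juvenile dispersal, survival of all individuals,
#' and finally age increment with juvenile-to-adult promotion. All events are
#' appended to the log.
#'
#' @param state A `hexpop_state`.
#' @return The state (invisibly; the environment is updated in place).
#' @export
sim_step <- function(state) {
  config <- state$config
  t <- state$step + 1L
  if (t > config$horizon) abort("Simulation horizon already reached.")
  ep <- config$epochs[findInterval(t, config$epochs$start), ]
  if (!identical(ep$name, state$epoch_name)) {
    state$land <- apply_epoch(state$land, epoch_spec_from_row(config, ep))
    state$epoch_name <- ep$name
  }
  land <- state$land
  pop <- state$pop
  demog <- config$demography
  log <- state$log
  np <- state$np
  patchv <- state$patchv
  n <- length(pop$id)

  # (a) resource acquisition
  if (n) {
    pop$resource <- allocate_resources(land, pop$cell, demog$resource_goal)
  }

  # (b) pair formation
  mothers <- integer(0); fathers <- integer(0)
  if (n) {
    f <- which(pop$sex == 1L)
    m <- which(pop$sex == 2L)
    if (length(f) && length(m)) {
      f <- f[sample.int(length(f))]
      pos <- pairs_cpp(pop$cell[f], pop$cell[m], land$reach$off,
                       land$reach$cell, land$reach$dist, land$n)
      hit <- pos > 0L
      mothers <- f[hit]
      fathers <- m[pos[hit]]
    }
  }

  # (c) reproduction
  K <- 0L
  if (length(mothers)) {
    litter <- offspring_number(pop$resource[mothers], demog)
    br <- litter > 0L
    log$breed_n[t] <- sum(br)
    log$breed_agesum[t] <- sum(pop$age[mothers[br]])
    newb <- c(mothers[br][is.na(pop$bred[mothers[br]])],
              fathers[br][is.na(pop$bred[fathers[br]])])
    if (length(newb)) {
      bp <- patchv[pop$cell[newb]]
      pop$bred[newb] <- bp
      log$firstbreed[[t]] <- list(natal = pop$natal[newb], bred = bp,
                                  crossed = pop$crossed[newb])
    }
    K <- sum(litter)
  }
  if (K) {
    mom <- rep(mothers, litter)
    dad <- rep(fathers, litter)
    geno_off <- mate_genotypes(pop$geno[mom, , drop = FALSE],
                               pop$geno[dad, , drop = FALSE])
    sex_off <- ifelse(runif(K) < 0.5, 1L, 2L)
    natal_cell <- pop$cell[mom]
    natal_off <- patchv[natal_cell]
    log$born[t, ] <- tabulate(natal_off, np)

    # (d) juvenile dispersal
    dsp <- disperse(land, natal_cell, config$dispersal)
    settle <- dsp$cell
    crossed_off <- dsp$crossed_gap
    log$settled[t, ] <- tabulate(patchv[settle], np)
    log$gap_crossings[t] <- sum(crossed_off)
    dd <- hex_distance(land$cells$q[natal_cell], land$cells$r[natal_cell],
                       land$cells$q[settle], land$cells$r[settle])
    kern <- log$kernel[[state$epoch_name]]
    if (is.null(kern)) kern <- integer(101)
    tb <- tabulate(pmin(dd, 100L) + 1L, 101L)
    log$kernel[[state$epoch_name]] <- kern + tb
  } else {
    geno_off <- pop$geno[integer(0), , drop = FALSE]
    sex_off <- integer(0); settle <- integer(0)
    crossed_off <- logical(0); natal_off <- integer(0)
  }

  # (e) survival: adults first, then this step's juveniles
  keep <- integer(0)
  if (n) {
    p_a <- demog$s_adult -
      demog$resource_penalty * (pop$resource < demog$resource_threshold)
    p_a <- pmin(1, pmax(0, p_a))
    sa <- runif(n) < p_a
    keep <- which(sa)
    log$deaths_adult[t, ] <- tabulate(patchv[pop$cell[!sa]], np)
  }
  jkeep <- integer(0)
  if (K) {
    p_j <- rep(demog$s_juv, K)
    if (ep$selection > 0 && any(land$habitat > 0L)) {
      h <- land$habitat[settle]
      copies <- integer(K)
      for (code in 1:2) {
        ii <- which(h == code)
        if (length(ii)) {
          copies[ii] <- count_adaptive_alleles(
            geno_off[ii, , drop = FALSE], code, config$loci)
        }
      }
      p_j <- p_j + ep$selection * copies
    }
    p_j <- pmin(1, pmax(0, p_j))
    sj <- runif(K) < p_j
    jkeep <- which(sj)
    log$deaths_juv[t, ] <- tabulate(patchv[settle[!sj]], np)
  }

  # aging and juvenile -> adult promotion at step end
  Kj <- length(jkeep)
  pop <- list(
    id = c(pop$id[keep], state$next_id + seq_len(Kj) - 1L),
    sex = c(pop$sex[keep], sex_off[jkeep]),
    age = c(pop$age[keep] + 1L, rep(1L, Kj)),
    cell = c(pop$cell[keep], settle[jkeep]),
    natal = c(pop$natal[keep], natal_off[jkeep]),
    resource = c(pop$resource[keep], rep(1, Kj)),
    crossed = c(pop$crossed[keep], crossed_off[jkeep]),
    bred = c(pop$bred[keep], rep(NA_integer_, Kj)),
    geno = rbind(pop$geno[keep, , drop = FALSE],
                 geno_off[jkeep, , drop = FALSE])
  )
  state$next_id <- state$next_id + Kj
  state$pop <- pop

  n2 <- length(pop$id)
  if (n2) {
    pp <- patchv[pop$cell]
    log$census[t, ] <- tabulate(pp, np)
    hom <- genotype_homozygosity(pop$geno)
    hs <- rowsum(hom, pp)
    log$hom[t, as.integer(rownames(hs))] <- hs / log$census[t, as.integer(rownames(hs))]
  }
  nl <- n_loci(config$loci)
  if (n2 && (t %% config$allele_log_every == 0L || t %in% config$epochs$end)) {
    log$allele_counts[[as.character(t)]] <-
      allele_count_array(pop$geno, patchv[pop$cell], np, nl)
  }
  if (t %in% config$snapshot_steps) {
    log$snapshots[[as.character(t)]] <- list(
      step = t, id = pop$id, cell = pop$cell, patch = patchv[pop$cell],
      age = pop$age, sex = pop$sex, natal = pop$natal,
      crossed = pop$crossed, geno = pop$geno
    )
  }
  state$step <- t
  invisible(state)
}

finalize_sim <- function(state) {
  config <- state$config
  log <- state$log
  h <- state$step
  np <- state$np
  idx <- seq_len(h)
  census <- tibble(
    step = rep(idx, each = np),
    patch = rep(seq_len(np), times = h),
    count = as.integer(t(log$census[idx, , drop = FALSE])),
    homozygosity = as.numeric(t(log$hom[idx, , drop = FALSE]))
  )
  events <- tibble(
    step = rep(idx, each = np),
    patch = rep(seq_len(np), times = h),
    born = as.integer(t(log$born[idx, , drop = FALSE])),
    settled = as.integer(t(log$settled[idx, , drop = FALSE])),
    deaths_juv = as.integer(t(log$deaths_juv[idx, , drop = FALSE])),
    deaths_adult = as.integer(t(log$deaths_adult[idx, , drop = FALSE])),
    count = as.integer(t(log$census[idx, , drop = FALSE]))
  )
  demog <- tibble(
    step = idx,
    n = as.integer(rowSums(log$census[idx, , drop = FALSE])),
    breeders = log$breed_n[idx],
    breeder_age_sum = log$breed_agesum[idx],
    births = as.integer(rowSums(log$born[idx, , drop = FALSE])),
    gap_crossings = log$gap_crossings[idx]
  )
  fb <- log$firstbreed[idx]
  got <- !vapply(fb, is.null, logical(1))
  first_breeding <- if (any(got)) {
    tibble(
      step = rep(idx[got], times = vapply(fb[got], function(x) length(x$natal), 0L)),
      natal_patch = unlist(lapply(fb[got], `[[`, "natal")),
      bred_patch = unlist(lapply(fb[got], `[[`, "bred")),
      crossed_gap = unlist(lapply(fb[got], `[[`, "crossed"))
    )
  } else {
    tibble(step = integer(0), natal_patch = integer(0),
           bred_patch = integer(0), crossed_gap = logical(0))
  }
  kernels <- dplyr::bind_rows(lapply(names(log$kernel), function(ep) {
    k <- log$kernel[[ep]]
    nz <- which(k > 0L)
    tibble(epoch = ep, distance = nz - 1L, n = k[nz])
  }))
  ac <- log$allele_counts
  allele_counts <- dplyr::bind_rows(lapply(names(ac), function(s) {
    a <- ac[[s]]
    nl <- dim(a)[3]
    tibble(
      step = as.integer(s),
      patch = rep(seq_len(np), times = 5L * nl),
      allele = rep(rep(1:5, each = np), times = nl),
      locus = rep(seq_len(nl), each = 5L * np),
      count = as.integer(a)
    )
  }))
  structure(list(
    config = config, seed = state$seed, steps = h,
    census = census, events = events, demography = demog,
    first_breeding = first_breeding, kernels = kernels,
    allele_counts = allele_counts,
    snapshots = log$snapshots,
    landscape = state$land
  ), class = "hexpop_sim")
}

#' Run a single simulation replicate
#'
#' Initializes the state from the configuration and advances it through the
#' full horizon; given the same seed, the returned logs are bit-identical
#' across runs.
#'
#' @param config A `hexpop_config`.
#' @param seed Integer seed for the replicate's RNG stream.
#' @return An object of class `hexpop_sim` with tibble logs (`census`,
#'   `events`, `demography`, `first_breeding`, `kernels`, `allele_counts`),
#'   genotype `snapshots`, and the final landscape.
#' @export
run_replicate <- function(config, seed = config$base_seed) {
  set.seed(as.integer(seed))
  state <- initialize_state(config)
  state$seed <- as.integer(seed)
  for (t in seq_len(config$horizon)) sim_step(state)
  finalize_sim(state)
}

#' Run the full factorial experiment
#'
#' Runs every treatment in the grid for the configured number of replicates,
#' with seeds derived from the base seed, treatment index, and replicate
#' index.
#'
#' @param config A `hexpop_config` (its dispersal/selection/permeability are
#'   overridden per treatment).
#' @param treatments Treatment tibble ([treatment_grid()] by default).
#' @param replicates Replicates per treatment.
#' @return An object of class `hexpop_experiment`: a list with the treatment
#'   `index` tibble (including the derived seed per run) and the list of
#'   `sims`.
#' @export
run_experiment <- function(config = sim_config(),
                           treatments = treatment_grid(),
                           replicates = config$replicates) {
  runs <- tidyr::expand_grid(treatment = treatments$treatment,
                             replicate = seq_len(replicates))
  runs <- dplyr::left_join(runs, treatments, by = "treatment")
  runs$seed <- config$base_seed + 1009L * (runs$treatment - 1L) +
    (runs$replicate - 1L)
  sims <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    tc <- sim_config(
      dispersal = runs$dispersal[i],
      selection = runs$selection[i],
      gap_permeability = runs$gap_permeability[i],
      horizon = config$horizon,
      patches = config$patches,
      gap_edges = config$gap_edges,
      loci = config$loci,
      demography = config$demography,
      autocorrelation = config$dispersal$autocorrelation,
      habitat_A = config$habitat_A, habitat_B = config$habitat_B,
      snapshot_steps = config$snapshot_steps,
      allele_log_every = config$allele_log_every,
      replicates = replicates, base_seed = config$base_seed
    )
    sims[[i]] <- run_replicate(tc, runs$seed[i])
  }
  names(sims) <- paste0("t", runs$treatment, "_r", runs$replicate)
  structure(list(index = runs, sims = sims), class = "hexpop_experiment")
}

#' @export
print.hexpop_sim <- function(x, ...) {
  cat("<hexpop_sim> ", x$steps, " steps, seed ", x$seed, "\n", sep = "")
  last <- x$census[x$census$step == x$steps, ]
  cat("  final census by patch: ", paste(last$count, collapse = ", "),
      " (total ", sum(last$count), ")\n", sep = "")
  cat("  snapshots at steps: ", paste(names(x$snapshots), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.hexpop_config <- function(x, ...) {
  cat("<hexpop_config> horizon ", x$horizon, ", dispersal ",
      paste(x$dispersal$range, collapse = "-"),
      ", S = ", x$selection, ", gap p = ", x$gap_permeability, "\n", sep = "")
  cat("  epochs: ", paste(x$epochs$name, collapse = " -> "), "\n", sep = "")
  invisible(x)
}
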