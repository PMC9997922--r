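# Landscape: habitat patches assembled from hexagonal cells, surrounded by
# impassable matrix. Movement constraints live in a per-cell x per-direction
# permeability matrix: 1 = free passage, 0 = absolute barrier (or matrix),
# intermediate values = barrier-gap transmission probability per encounter.

#' Default six-patch landscape layout
#'
#' Two large patches (26 x 51 cells) adjoin at the landscape center; two
#' medium (10 x 20) and two small (5 x 10) patches each abut one large patch
#' but never each other, giving five patch interfaces and 3152 habitat cells
#' in total.
#'
#' @return A tibble with one row per patch: `patch_id`, `label`, `cols`,
#'   `rows`, `col0`, `row0` (offset-grid origin of the patch rectangle).
#' @export
hex_layout_default <- function() {
  tibble(
    patch_id = 1:6,
    label = c("L1", "L2", "M1", "M2", "S1", "S2"),
    cols = c(26L, 26L, 10L, 10L, 5L, 5L),
    rows = c(51L, 51L, 20L, 20L, 10L, 10L),
    col0 = c(0L, 26L, -10L, 52L, -5L, 52L),
    row0 = c(0L, 0L, 15L, 15L, 40L, 0L)
  )
}

#' Build a hexagonal patch landscape
#'
#' Lays rectangular patches (columns x rows on an offset grid) onto a shared
#' hexagonal lattice, records every inter-patch interface, and pre-selects the
#' barrier-gap edges: each interface receives a contiguous, centered run of
#' `gap_edges` cell-to-cell edges, so the total gap size is identical across
#' interfaces.
#'
#' @param patches Patch layout tibble as returned by [hex_layout_default()].
#' @param gap_edges Number of gap edges per patch interface (default 1, a
#'   minimal single-edge opening).
#' @param radius Radius (in cells) of the resource/pairing neighborhood
#'   structure kept with the landscape (default 3, a 37-cell disk).
#' @return An object of class `hexpop_landscape`.
#' @examples
#' land <- build_landscape()
#' land$patch_sizes
#' @export
build_landscape <- function(patches = hex_layout_default(), gap_edges = 1,
                            radius = 3) {
  need <- c("patch_id", "cols", "rows", "col0", "row0")
  if (!all(need %in% names(patches))) {
    abort(paste0("`patches` must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(patches$cols <= 0 | patches$rows <= 0)) {
    abort("Patch dimensions must be positive (a patch with zero cells is not allowed).")
  }
  cells <- purrr::pmap_dfr(patches[need], function(patch_id, cols, rows, col0, row0) {
    col <- rep(col0 + seq_len(cols) - 1L, each = rows)
    row <- rep(row0 + seq_len(rows) - 1L, times = cols)
    ax <- offset_to_axial(col, row)
    tibble(q = ax$q, r = ax$r, col = as.integer(col), row = as.integer(row),
           patch = as.integer(patch_id))
  })
  if (anyDuplicated(cells[c("q", "r")])) {
    abort("Overlapping patch footprints: two patches claim the same cell.")
  }
  cells <- dplyr::arrange(cells, .data$patch, .data$col, .data$row)
  cells$cell <- seq_len(nrow(cells))
  n <- nrow(cells)

  # neighbour lookup via dense integer keys
  qmin <- min(cells$q); rmin <- min(cells$r)
  rspan <- max(cells$r) - rmin + 3L
  key <- (cells$q - qmin) * rspan + (cells$r - rmin)
  nbr <- matrix(0L, n, 6)
  for (k in 1:6) {
    nk <- (cells$q + HEX_DIRS[k, 1] - qmin) * rspan +
      (cells$r + HEX_DIRS[k, 2] - rmin)
    hit <- match(nk, key)
    nbr[, k] <- ifelse(is.na(hit), 0L, cells$cell[hit])
  }

  base_perm <- matrix(0, n, 6)
  base_perm[nbr > 0L] <- 1

  # directed inter-patch edges, with gap flags chosen on unordered edges
  from <- rep(seq_len(n), 6)
  dir <- rep(1:6, each = n)
  to <- as.vector(nbr)
  sel <- to > 0L & cells$patch[from] != cells$patch[pmax(to, 1L)]
  e_from <- from[sel]; e_to <- to[sel]; e_dir <- dir[sel]
  inter <- tibble(
    from = e_from, to = e_to, dir = e_dir,
    patch_from = cells$patch[e_from], patch_to = cells$patch[e_to]
  )
  inter$iface <- paste(pmin(inter$patch_from, inter$patch_to),
                       pmax(inter$patch_from, inter$patch_to), sep = "-")
  inter$ekey <- paste(pmin(inter$from, inter$to), pmax(inter$from, inter$to))
  und <- inter[!duplicated(inter$ekey), ]
  und$pos_row <- (cells$row[und$from] + cells$row[und$to]) / 2
  und$pos_col <- (cells$col[und$from] + cells$col[und$to]) / 2
  gap_keys <- unlist(lapply(split(und, und$iface), function(e) {
    e <- e[order(e$pos_row, e$pos_col, e$from), ]
    m <- nrow(e)
    g <- min(gap_edges, m)
    start <- (m - g) %/% 2 + 1L
    e$ekey[seq(start, length.out = g)]
  }), use.names = FALSE)
  inter$is_gap <- inter$ekey %in% gap_keys
  inter$ekey <- NULL

  land <- structure(list(
    cells = cells[c("cell", "q", "r", "col", "row", "patch")],
    n = n,
    patches = patches,
    patch_sizes = setNames(
      tabulate(cells$patch, max(patches$patch_id)),
      if ("label" %in% names(patches)) patches$label[order(patches$patch_id)]
      else paste0("P", sort(patches$patch_id))
    ),
    nbr = nbr,
    base_perm = base_perm,
    interpatch = inter,
    gap_edges = gap_edges,
    radius = radius,
    habitat = integer(n),
    epoch = NULL,
    perm = NULL,
    reach = NULL,
    M = NULL
  ), class = "hexpop_landscape")
  apply_epoch(land, epoch_spec("continuous"))
}

#' Describe one landscape epoch
#'
#' @param name One of `"continuous"`, `"isolated"`, `"semi_connected"`,
#'   `"semi_connected_selection"`, or any label.
#' @param barrier Inter-patch barrier mode: `"none"` (free passage),
#'   `"absolute"` (permeability 0), or `"gapped"` (gap edges carry
#'   `gap_permeability`, remaining interface edges 0). Defaults by name.
#' @param gap_permeability Per-encounter transmission probability of a gap
#'   edge (used when `barrier = "gapped"`).
#' @param selection Survival benefit S per locally adaptive allele copy
#'   (applies to juveniles; requires a habitat assignment).
#' @param habitat Named or positional vector mapping patch ids to habitat
#'   types `"A"`/`"B"`, or `NULL` for an untyped landscape.
#' @return A list of class `hexpop_epoch`.
#' @export
epoch_spec <- function(name,
                       barrier = switch(name,
                         continuous = "none", isolated = "absolute", "gapped"),
                       gap_permeability = 0,
                       selection = 0,
                       habitat = NULL) {
  barrier <- match.arg(barrier, c("none", "absolute", "gapped"))
  if (barrier == "gapped" && (is.na(gap_permeability) || gap_permeability < 0 ||
                              gap_permeability > 1)) {
    abort("A gapped epoch needs `gap_permeability` in [0, 1].")
  }
  if (selection > 0 && is.null(habitat)) {
    abort("`selection` > 0 requires a habitat assignment.")
  }
  structure(list(name = name, barrier = barrier,
                 gap_permeability = gap_permeability,
                 selection = selection, habitat = habitat),
            class = "hexpop_epoch")
}

#' Apply an epoch to a landscape
#'
#' Rewrites the edge permeabilities (and habitat typing) for the given epoch
#' and rebuilds the reachability structures. Idempotent for a fixed spec;
#' applying another spec and then the original restores the original edge set.
#'
#' @param landscape A `hexpop_landscape`.
#' @param spec A `hexpop_epoch` from [epoch_spec()].
#' @return The updated landscape.
#' @export
apply_epoch <- function(landscape, spec) {
  stopifnot(inherits(landscape, "hexpop_landscape"), inherits(spec, "hexpop_epoch"))
  perm <- landscape$base_perm
  ip <- landscape$interpatch
  if (nrow(ip)) {
    v <- switch(spec$barrier,
      none = rep(1, nrow(ip)),
      absolute = rep(0, nrow(ip)),
      gapped = ifelse(ip$is_gap, spec$gap_permeability, 0)
    )
    perm[cbind(ip$from, ip$dir)] <- v
  }
  habitat <- integer(landscape$n)
  if (!is.null(spec$habitat)) {
    hmap <- spec$habitat
    ids <- if (!is.null(names(hmap))) as.integer(names(hmap)) else seq_along(hmap)
    code <- match(toupper(as.character(hmap)), c("A", "B"))
    if (anyNA(code)) abort("Habitat types must be \"A\" or \"B\".")
    lut <- integer(max(landscape$cells$patch))
    lut[ids] <- code
    habitat <- lut[landscape$cells$patch]
  }
  reach <- reach_cpp(landscape$nbr, perm, landscape$radius)
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_len(landscape$n), diff(reach$off)),
    j = reach$cell, x = 1, dims = c(landscape$n, landscape$n)
  )
  landscape$perm <- perm
  landscape$habitat <- habitat
  landscape$reach <- reach
  landscape$M <- M
  landscape$epoch <- spec
  landscape
}

#' Edge permeability between two adjacent cells
#'
#' @param landscape A `hexpop_landscape`.
#' @param from,to Cell ids of two adjacent habitat cells, or `to = NA` to
#'   query a direction leaving the habitat (always 0: edges are reflective).
#' @return The current epoch's transmission probability for that edge.
#' @export
edge_permeability <- function(landscape, from, to) {
  cl <- landscape$cells
  if (is.na(to)) return(0)
  d <- which(landscape$nbr[from, ] == to)
  if (!length(d)) {
    if (hex_distance(cl$q[from], cl$r[from], cl$q[to], cl$r[to]) != 1) {
      abort("Cells are not adjacent.")
    }
    return(0) # adjacent through matrix is impossible; defensive
  }
  landscape$perm[from, d[1]]
}

#' Habitat cells reachable from a center without crossing impassable edges
#'
#' The hexagonal disk of the given radius, clipped to habitat and restricted
#' to cells connected to the center through edges of permeability > 0 by paths
#' of length at most `radius`.
#'
#' @param landscape A `hexpop_landscape`.
#' @param center Cell id of a habitat cell.
#' @param radius Non-negative integer.
#' @return A tibble with columns `cell`, `dist`.
#' @export
reachable_neighborhood <- function(landscape, center, radius = landscape$radius) {
  if (length(center) != 1 || is.na(center) || center < 1 || center > landscape$n) {
    abort("`center` must be a single habitat cell id.")
  }
  if (radius == landscape$radius) {
    off <- landscape$reach$off
    idx <- seq(off[center] + 1L, off[center + 1L])
    return(tibble(cell = landscape$reach$cell[idx],
                  dist = landscape$reach$dist[idx]))
  }
  # generic BFS for non-default radii
  dist <- rep(NA_integer_, landscape$n)
  dist[center] <- 0L
  frontier <- center
  d <- 0L
  while (length(frontier) && d < radius) {
    nxt <- integer(0)
    for (c0 in frontier) {
      pass <- which(landscape$perm[c0, ] > 0 & landscape$nbr[c0, ] > 0L)
      for (k in pass) {
        t0 <- landscape$nbr[c0, k]
        if (is.na(dist[t0])) {
          dist[t0] <- d + 1L
          nxt <- c(nxt, t0)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  found <- which(!is.na(dist))
  out <- tibble(cell = found, dist = dist[found])
  dplyr::arrange(out, .data$dist, .data$cell)
}

#' @export
print.hexpop_landscape <- function(x, ...) {
  cat("<hexpop_landscape> ", x$n, " habitat cells in ",
      nrow(x$patches), " patches\n", sep = "")
  cat("  patch sizes: ", paste(x$patch_sizes, collapse = ", "), "\n", sep = "")
  cat("  interfaces:  ",
      paste(unique(x$interpatch$iface), collapse = ", "), "\n", sep = "")
  if (!is.null(x$epoch)) {
    cat("  epoch:       ", x$epoch$name, " (barrier ", x$epoch$barrier,
        if (x$epoch$barrier == "gapped")
          paste0(", gap p = ", x$epoch$gap_permeability), ")\n", sep = "")
  }
  invisible(x)
}
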