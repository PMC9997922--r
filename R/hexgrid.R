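# Hexagonal lattice geometry: flat-top hexagons on axial coordinates (q, r).
# The six neighbour directions are ordered so that opposite(k) = (k + 3) mod 6,
# which lets edge permeabilities be mirrored cheaply.

HEX_DIRS <- matrix(
  c(1L, 0L,
    1L, -1L,
    0L, -1L,
    -1L, 0L,
    -1L, 1L,
    0L, 1L),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("q", "r"))
)

#' Hexagonal lattice distance
#'
#' Number of cell-to-cell steps between two hexagons on an axial-coordinate
#' lattice. Symmetric, and satisfies the triangle inequality.
#'
#' @param q1,r1 Axial coordinates of the first cell (vectors recycle).
#' @param q2,r2 Axial coordinates of the second cell.
#' @return Integer vector of distances.
#' @examples
#' hex_distance(0, 0, 3, -1)
#' @export
hex_distance <- function(q1, r1, q2, r2) {
  dq <- q2 - q1
  dr <- r2 - r1
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

#' Cells within a hexagonal disk
#'
#' All axial coordinates within `radius` lattice steps of a center cell. The
#' disk size is `1 + 3 * radius * (radius + 1)`; radius 3 gives the 37-cell
#' resource-acquisition neighborhood used by the default scenario.
#'
#' @param q,r Axial coordinates of the center.
#' @param radius Non-negative integer radius.
#' @return A tibble with columns `q`, `r`, `dist`.
#' @examples
#' nrow(hex_disk(0, 0, 3)) # 37
#' @export
hex_disk <- function(q, r, radius) {
  if (length(radius) != 1 || is.na(radius) || radius < 0) {
    abort("`radius` must be a single non-negative integer.")
  }
  radius <- as.integer(radius)
  dq <- rep(seq(-radius, radius), each = 2L * radius + 1L)
  dr <- rep(seq(-radius, radius), times = 2L * radius + 1L)
  keep <- abs(dq + dr) <= radius
  dq <- dq[keep]
  dr <- dr[keep]
  tibble(
    q = q + dq, r = r + dr,
    dist = hex_distance(q, r, q + dq, r + dr)
  )
}

#' Convert offset (column, row) grid positions to axial coordinates
#'
#' Rectangular patches are specified as columns x rows on a flat-top, odd-q
#' offset grid; this maps those positions onto the axial system used
#' internally.
#'
#' @param col,row Integer offset coordinates (vectors recycle).
#' @return A tibble with axial columns `q`, `r`.
#' @export
offset_to_axial <- function(col, row) {
  tibble(q = as.integer(col), r = as.integer(row - col %/% 2))
}
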