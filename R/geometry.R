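#' Minimum-image displacement under periodic boundary conditions
#'
#' Computes `p2 - p1` with each Cartesian component wrapped into
#' `(-box/2, +box/2]`, i.e. the displacement to the nearest periodic image
#' of `p2` in an orthorhombic box. All distance computations in the package
#' route through this convention, so coordinates may be supplied wrapped.
#'
#' @param p1,p2 Numeric 3-vectors, or n x 3 matrices of positions (nm).
#' @param box Numeric 3-vector of orthorhombic box edge lengths (nm).
#' @return A displacement of the same shape as the inputs (nm).
#' @examples
#' min_image_displacement(c(0.5, 0, 0), c(9.9, 0, 0), c(10, 10, 10))
#' @export
min_image_displacement <- function(p1, p2, box) {
  check_box(box)
  p1 <- to_xyz(p1)
  p2 <- to_xyz(p2)
  d <- p2 - p1
  out <- wrap_half_open(d, box)
  if (nrow(out) == 1L) drop(out) else out
}

#' Minimum-image distance
#'
#' Euclidean norm of [min_image_displacement()]. Never exceeds half the box
#' diagonal.
#'
#' @inheritParams min_image_displacement
#' @return Numeric scalar or vector of distances (nm).
#' @export
min_image_distance <- function(p1, p2, box) {
  check_box(box)
  d <- wrap_half_open(to_xyz(p2) - to_xyz(p1), box)
  sqrt(rowSums(d^2))
}

# wrap each column of an n x 3 displacement matrix into (-L/2, L/2]
wrap_half_open <- function(d, box) {
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    low <- d[, k] <= -box[k] / 2
    d[low, k] <- d[low, k] + box[k]
  }
  d
}

# wrap positions into [0, L)
wrap_into_box <- function(pos, box) {
  pos <- to_xyz(pos)
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  pos
}

to_xyz <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) abort("positions must have 3 columns")
    p
  } else {
    if (length(p) != 3L) abort("a position must be a 3-vector")
    matrix(p, nrow = 1L)
  }
}

check_box <- function(box) {
  if (length(box) != 3L || !is.numeric(box) || any(!is.finite(box)) ||
      any(box <= 0)) {
    abort("invalid geometry: box must be 3 strictly positive edge lengths",
          class = "cgagg_invalid_geometry")
  }
  invisible(box)
}

#' All bead pairs within a distance cutoff
#'
#' Periodic neighbor search over one set of positions using a cell-list
#' spatial index (falling back to an exact all-pairs scan for small systems).
#' Distances use the minimum-image convention; a bead pair exactly at the
#' cutoff counts as within it (closed interval).
#'
#' @param pos n x 3 matrix of positions (nm).
#' @param box Orthorhombic box edge lengths (nm).
#' @param cutoff Distance cutoff (nm); must not exceed half the smallest
#'   box edge (minimum image would be ambiguous beyond that).
#' @return A tibble with columns `i`, `j` (1-based row indices, `i < j`)
#'   and `dist` (nm).
#' @export
neighbor_pairs <- function(pos, box, cutoff) {
  check_box(box)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    abort("cutoff must be a positive scalar")
  if (cutoff > min(box) / 2)
    abort("cutoff exceeds half the smallest box edge; minimum image invalid",
          class = "cgagg_invalid_geometry")
  res <- neighbor_pairs_cpp(to_xyz(pos), as.numeric(box), cutoff)
  tibble::tibble(i = res$i, j = res$j, dist = res$dist)
}
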