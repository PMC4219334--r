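#' Construct a point set
#'
#' A point set is a light wrapper around an N x dim numeric matrix of
#' coordinates (2D or 3D), with an optional role label ("X" for the dependent
#' set, "Y" for the reference set). Coordinates are in pixels when points come
#' from images, or in the units of the coordinate file otherwise.
#'
#' @param coords numeric matrix (N x 2 or N x 3), or a data frame / vector
#'   coercible to one. A single point may be given as a plain numeric vector.
#' @param label free-text role label.
#' @return an object of class `point_set` (a numeric matrix with attributes).
#' @examples
#' point_set(cbind(runif(10), runif(10)), label = "X")
#' @export
point_set <- function(coords, label = "") {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1) stop("a point set needs at least one point")
  if (!ncol(coords) %in% c(2L, 3L)) stop("points must be 2D or 3D")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  dimnames(coords) <- NULL
  structure(coords, class = c("point_set", "matrix", "array"), label = label)
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("Point set%s: %d points in %dD\n",
              if (nzchar(attr(x, "label"))) paste0(" '", attr(x, "label"), "'") else "",
              nrow(x), ncol(x)))
  print(head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (inherits(x, "point_set")) return(unclass(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

#' Define a rectangular analysis region
#'
#' The region is the admissible space within which the dependent set can
#' distribute: a closed rectangular box, optionally restricted by a binary
#' raster mask aligned to the box. For objects detected in an L-pixel image
#' axis the convention is pixel centers at integer positions, so the bounds
#' are `c(0, L - 1)` (a 400-pixel image has bounds (0, 399)).
#'
#' @param bounds either a 2 x dim matrix (rows = lower, upper) or a numeric
#'   vector `c(xlo, xhi, ylo, yhi[, zlo, zhi])`.
#' @param mask optional logical/numeric array; nonzero cells are admissible.
#'   The raster is aligned to the bounds: cell `[i, j]` covers the point
#'   `lower + (c(i, j) - 1) * cell_size`. Membership of an arbitrary point is
#'   decided by nearest-cell lookup.
#' @param cell_size edge length of one mask cell, in coordinate units.
#' @return an object of class `region`.
#' @examples
#' region(c(0, 399, 0, 399))
#' @export
region <- function(bounds, mask = NULL, cell_size = 1) {
  if (is.null(dim(bounds))) {
    if (length(bounds) %% 2L != 0L) stop("bounds vector must have 2 entries per dimension")
    bounds <- matrix(as.numeric(bounds), nrow = 2L)
  }
  if (nrow(bounds) != 2L || !ncol(bounds) %in% c(2L, 3L)) {
    stop("bounds must be a 2 x dim matrix with dim 2 or 3")
  }
  if (any(bounds[2L, ] <= bounds[1L, ])) stop("upper bound must exceed lower bound in every dimension")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask != 0), dim = dim(mask) %||% c(length(mask), 1L))
    if (!any(mask)) stop("empty admissible region: mask excludes everything")
    if (length(dim(mask)) != ncol(bounds)) stop("mask dimensionality must match bounds")
    expect_cells <- floor((bounds[2L, ] - bounds[1L, ]) / cell_size) + 1
    if (any(abs(dim(mask) - expect_cells) > 1)) {
      stop(sprintf("mask shape (%s) does not match bounds/cell size (expected about %s)",
                   paste(dim(mask), collapse = "x"), paste(expect_cells, collapse = "x")))
    }
  }
  structure(list(bounds = bounds, mask = mask, cell_size = cell_size,
                 dim = ncol(bounds)),
            class = "region")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region <- function(x, ...) {
  b <- apply(x$bounds, 2L, function(v) sprintf("[%g, %g]", v[1L], v[2L]))
  cat("Region:", paste(b, collapse = " x "),
      if (!is.null(x$mask)) sprintf("with mask (%s cells admissible)",
                                    format(sum(x$mask), big.mark = ",")) else "",
      "\n")
  invisible(x)
}

region_contains <- function(region, coords) {
  coords <- as_coord_matrix(coords)
  ok <- rep(TRUE, nrow(coords))
  for (d in seq_len(region$dim)) {
    ok <- ok & coords[, d] >= region$bounds[1L, d] & coords[, d] <= region$bounds[2L, d]
  }
  if (!is.null(region$mask)) ok <- ok & mask_lookup(region, coords)
  ok
}

# Nearest-cell mask membership: round to the closest cell index, clamp to the
# raster so points on the boundary stay inside.
mask_lookup <- function(region, coords) {
  dm <- dim(region$mask)
  idx <- matrix(0L, nrow(coords), region$dim)
  for (d in seq_len(region$dim)) {
    i <- as.integer(round((coords[, d] - region$bounds[1L, d]) / region$cell_size)) + 1L
    idx[, d] <- pmin(pmax(i, 1L), dm[d])
  }
  region$mask[idx]
}

#' Nearest-neighbor distances between two point sets
#'
#' For each point of `x`, the Euclidean distance to its nearest neighbor in
#' the reference set `y`, computed with a kd-tree (expected cost
#' O(N log M)). Output order matches the point order of `x`.
#'
#' @param x,y point sets (matrices or [point_set()] objects) of equal
#'   dimensionality; `y` must be nonempty.
#' @return numeric vector of length `nrow(x)` of nonnegative distances.
#' @examples
#' nn_distances(rbind(c(0, 0)), rbind(c(3, 4), c(10, 10)))  # 5
#' @export
nn_distances <- function(x, y) {
  x <- as_coord_matrix(x)
  y <- as_coord_matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch between the two point sets")
  if (nrow(y) == 0L) stop("empty reference set")
  .nn_query_cpp(x, y)
}

#' Regular lattice covering a region
#'
#' All points of a Cartesian lattice with the given spacing, anchored at the
#' lower bound of every dimension; points exactly on the upper bound are
#' included (closed intervals). If the region carries a mask, only lattice
#' points whose nearest mask cell is admissible are returned.
#'
#' @param region a [region()].
#' @param spacing lattice constant, in coordinate units; must be positive and
#'   smaller than every bound extent.
#' @return a [point_set()] of lattice points.
#' @export
lattice_points <- function(region, spacing) {
  stopifnot(inherits(region, "region"))
  if (spacing <= 0) stop("spacing must be positive")
  ext <- region$bounds[2L, ] - region$bounds[1L, ]
  if (any(spacing >= ext)) stop("spacing must be smaller than every bound extent")
  axes <- lapply(seq_len(region$dim), function(d) {
    seq(region$bounds[1L, d], region$bounds[2L, d], by = spacing)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  if (!is.null(region$mask)) {
    keep <- mask_lookup(region, grid)
    if (!any(keep)) stop("mask excludes all lattice points")
    grid <- grid[keep, , drop = FALSE]
  }
  point_set(grid, label = "lattice")
}

#' Grid-sample the context distances
#'
#' Nearest-neighbor distance from every lattice point of the region to the
#' reference set `y`. These samples estimate the context q(d): the NN-distance
#' distribution a uniformly and independently placed point would see, given
#' the layout of `y` and the shape of the admissible region. The lattice
#' construction itself is the boundary correction; no edge correction is
#' applied to the distances.
#'
#' @inheritParams lattice_points
#' @param y reference point set.
#' @return numeric vector of context distance samples.
#' @export
sample_context <- function(y, region, spacing) {
  grid <- lattice_points(region, spacing)
  nn_distances(grid, y)
}
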