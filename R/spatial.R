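#' Distance from each spot to the nucleus
#'
#' Euclidean distance (micrometers) from each spot centroid to the nearest
#' nucleus *boundary* pixel center; spots whose position falls inside the
#' nucleus mask are assigned distance 0 (projected FISH signal can overlie
#' the nuclear edge).
#'
#' @param spots Spot table with `x_nm`, `y_nm`.
#' @param geometry [make_cell_geometry()] object with a nonempty nucleus
#'   mask.
#' @return Numeric vector of distances in micrometers, one per spot.
#' @export
distance_to_nucleus <- function(spots, geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  nuc <- geometry$nucleus_mask
  if (!any(nuc)) stop("empty nucleus mask")
  ny <- nrow(nuc); nx <- ncol(nuc)
  # boundary: nucleus pixels with at least one 4-neighbor outside the mask
  padded <- matrix(FALSE, ny + 2, nx + 2)
  padded[2:(ny + 1), 2:(nx + 1)] <- nuc
  inner <- padded[1:ny, 2:(nx + 1)] & padded[3:(ny + 2), 2:(nx + 1)] &
    padded[2:(ny + 1), 1:nx] & padded[2:(ny + 1), 3:(nx + 2)]
  boundary <- nuc & !inner
  bidx <- which(boundary)
  px <- geometry$pixel_size_nm
  bx <- (((bidx - 1L) %/% ny) + 0.5) * px   # boundary pixel centers, nm
  by <- (((bidx - 1L) %% ny) + 0.5) * px

  n <- nrow(spots)
  out <- numeric(n)
  col <- pmin(pmax(floor(spots$x_nm / px) + 1L, 1L), nx)
  row <- pmin(pmax(floor(spots$y_nm / px) + 1L, 1L), ny)
  inside <- nuc[cbind(row, col)]
  outside <- which(!inside)
  # chunked distance matrix keeps memory bounded for big spot tables
  chunk <- 2000L
  if (length(outside)) for (s in seq(1L, length(outside), by = chunk)) {
    ii <- outside[s:min(s + chunk - 1L, length(outside))]
    dx <- outer(spots$x_nm[ii], bx, "-")
    dy <- outer(spots$y_nm[ii], by, "-")
    out[ii] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  out / 1000
}

#' Radial distribution of spots relative to the nucleus
#'
#' Normalized histogram of distance-from-nucleus values in fixed-width bins
#' (5 um by default, the granularity at which perinuclear enrichment is
#' reported).
#'
#' @param distances_um Distances from [distance_to_nucleus()].
#' @param bin_um Bin width in micrometers.
#' @param max_um Upper edge; default covers the data.
#' @return Object of class `radial_profile`: `bin_edges_um`,
#'   `fraction_per_bin`, `n_spots`, and the raw `distances_um` (used by
#'   [fraction_within()]).
#' @export
radial_distribution <- function(distances_um, bin_um = 5, max_um = NULL) {
  if (any(distances_um < 0)) stop("distances must be non-negative")
  n <- length(distances_um)
  if (n == 0L) stop("no distances supplied")
  top <- max_um %||% (ceiling(max(distances_um, bin_um) / bin_um) * bin_um)
  edges <- seq(0, top, by = bin_um)
  if (max(distances_um) > top) stop("'max_um' smaller than largest distance")
  counts <- graphics::hist(distances_um, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  # hist(right = FALSE) drops values equal to the top edge; fold them in
  counts[length(counts)] <- counts[length(counts)] +
    sum(distances_um == top)
  structure(list(bin_edges_um = edges,
                 fraction_per_bin = counts / n,
                 n_spots = n,
                 distances_um = distances_um),
            class = "radial_profile")
}

#' Cumulative fraction of spots within a radius of the nucleus
#'
#' @param profile A [radial_distribution()] result (or a numeric vector of
#'   distances in um).
#' @param radius_um Query radius in micrometers.
#' @return Fraction of spots at distance `<= radius_um` (non-decreasing in
#'   the radius).
#' @export
fraction_within <- function(profile, radius_um) {
  d <- if (inherits(profile, "radial_profile")) profile$distances_um
       else profile
  vapply(radius_um, function(r) mean(d <= r), numeric(1))
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("<radial_profile>", x$n_spots, "spots,",
      length(x$fraction_per_bin), "bins of",
      diff(x$bin_edges_um[1:2]), "um\n")
  lab <- sprintf("[%g,%g)", head(x$bin_edges_um, -1), x$bin_edges_um[-1])
  print(stats::setNames(round(x$fraction_per_bin, 3), lab))
  invisible(x)
}
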