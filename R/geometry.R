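#' Build a synthetic single-cell geometry
#'
#' Constructs the raster geometry all downstream analyses assume: a cell mask
#' (an ellipse, lightly randomized in orientation and eccentricity so that no
#' two cells are identical), a circular nucleus mask fully contained in the
#' cell, and the analyzed area \eqn{A} in nm^2.  The defaults emulate a
#' cultured cardiomyocyte imaged at 106.3 nm/pixel on a 512 x 512 field.
#'
#' @param seed Integer seed; the geometry is bit-reproducible for a fixed seed.
#' @param shape_px Image shape as `c(ny, nx)` in pixels.
#' @param nucleus_radius_um Nucleus radius in micrometers.
#' @param pixel_size_nm Lateral pixel size in nanometers (must be positive).
#' @param z_step_nm Axial step in nanometers (metadata for stack-based input).
#' @param cell_radii_um Semi-axes of the cell ellipse in micrometers.
#' @param jitter Relative jitter (0-1) applied to the cell axes, orientation
#'   and nucleus offset.  `jitter = 0` gives a fully deterministic, axis
#'   aligned geometry regardless of seed.
#'
#' @return An object of class `cell_geometry`: a list with `pixel_size_nm`,
#'   `z_step_nm`, `shape_px`, `nucleus_mask`, `cell_mask` (logical matrices,
#'   rows = y), `area_A_nm2`, `center_px` and `seed`.
#'
#' @details Pixel `(ix, iy)` (column, row; 1-based) covers the square
#'   `[(ix-1), ix] x [(iy-1), iy]` in pixel units, so its center sits at
#'   `(ix - 0.5, iy - 0.5)` pixels, i.e. `(ix - 0.5) * pixel_size_nm` nm.
#'   All continuous coordinates in the package use this convention.
#'
#' @export
make_cell_geometry <- function(seed = 1L,
                               shape_px = c(512L, 512L),
                               nucleus_radius_um = 8,
                               pixel_size_nm = 106.3,
                               z_step_nm = 200,
                               cell_radii_um = c(25, 20),
                               jitter = 0.1) {
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("'pixel_size_nm' must be a single positive number")
  }
  if (length(shape_px) != 2L || any(shape_px < 8)) {
    stop("'shape_px' must be c(ny, nx) with both dimensions >= 8")
  }
  if (nucleus_radius_um <= 0) stop("'nucleus_radius_um' must be positive")

  ny <- as.integer(shape_px[1]); nx <- as.integer(shape_px[2])
  px_um <- pixel_size_nm / 1000

  geom <- withr::with_seed(as.integer(seed), {
    a <- cell_radii_um[1] * (1 + jitter * stats::runif(1, -1, 1))
    b <- cell_radii_um[2] * (1 + jitter * stats::runif(1, -1, 1))
    theta <- if (jitter > 0) stats::runif(1, 0, pi) else 0
    cx <- nx / 2 * px_um
    cy <- ny / 2 * px_um
    # nucleus offset from the cell center, kept well inside
    max_off <- max(0, min(a, b) - nucleus_radius_um) * 0.4 * jitter
    off_ang <- stats::runif(1, 0, 2 * pi)
    ncx <- cx + max_off * cos(off_ang)
    ncy <- cy + max_off * sin(off_ang)
    list(a = a, b = b, theta = theta, cx = cx, cy = cy, ncx = ncx, ncy = ncy)
  })

  xs <- ((seq_len(nx)) - 0.5) * px_um
  ys <- ((seq_len(ny)) - 0.5) * px_um
  X <- matrix(xs, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(ys, nrow = ny, ncol = nx)

  ct <- cos(geom$theta); st <- sin(geom$theta)
  U <- (X - geom$cx) * ct + (Y - geom$cy) * st
  V <- -(X - geom$cx) * st + (Y - geom$cy) * ct
  cell_mask <- (U / geom$a)^2 + (V / geom$b)^2 <= 1
  nucleus_mask <- (X - geom$ncx)^2 + (Y - geom$ncy)^2 <= nucleus_radius_um^2

  if (!all(cell_mask[nucleus_mask])) {
    stop("invalid geometry: nucleus does not fit inside the cell mask")
  }
  if (!any(cell_mask & !nucleus_mask)) {
    stop("invalid geometry: no cytoplasmic pixels available")
  }

  structure(list(
    pixel_size_nm = pixel_size_nm,
    z_step_nm = z_step_nm,
    shape_px = c(ny = ny, nx = nx),
    nucleus_mask = nucleus_mask,
    cell_mask = cell_mask,
    area_A_nm2 = sum(cell_mask) * pixel_size_nm^2,
    center_px = c(x = geom$cx / px_um, y = geom$cy / px_um),
    seed = as.integer(seed)
  ), class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry> ", x$shape_px["ny"], "x", x$shape_px["nx"],
      " px @ ", x$pixel_size_nm, " nm/px\n", sep = "")
  cat("  cell area A: ", format(x$area_A_nm2, digits = 4), " nm^2 (",
      format(x$area_A_nm2 / 1e6, digits = 4), " um^2); nucleus pixels: ",
      sum(x$nucleus_mask), "\n", sep = "")
  invisible(x)
}

# Per-pixel distance (in pixels) to the nearest nucleus pixel; 0 inside the
# nucleus.  Euclidean distance transform of the nucleus complement.
nucleus_distance_px <- function(geometry) {
  m <- matrix(1, nrow(geometry$nucleus_mask), ncol(geometry$nucleus_mask))
  m[geometry$nucleus_mask] <- 0
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}
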