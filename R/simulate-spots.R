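#' Default cluster-size distribution for simulated transcripts
#'
#' Probability vector over mRNA copies per spot (1..7) chosen so that about a
#' quarter of detected particles are single molecules and about a fifth sit in
#' clusters of six or more transcripts, the regime reported for cardiac
#' ion-channel transcripts in cardiomyocytes.
#'
#' @return Named numeric vector summing to 1; names are copy numbers.
#' @export
default_cluster_dist <- function() {
  c(`1` = 0.25, `2` = 0.22, `3` = 0.15, `4` = 0.10,
    `5` = 0.08, `6` = 0.10, `7` = 0.10)
}

# Precompute a categorical sampler over placeable pixels.  Placement weight
# decays exponentially with distance from the nucleus (perinuclear bias);
# lambda_um = Inf gives uniform placement over the cytoplasm.
placement_sampler <- function(geometry, lambda_um = 10) {
  allowed <- geometry$cell_mask & !geometry$nucleus_mask
  idx <- which(allowed)
  if (length(idx) == 0L) stop("no placeable pixels in geometry")
  if (is.finite(lambda_um)) {
    d_um <- nucleus_distance_px(geometry)[idx] * geometry$pixel_size_nm / 1000
    w <- exp(-d_um / lambda_um)
  } else {
    w <- rep(1, length(idx))
  }
  ny <- nrow(geometry$cell_mask)
  list(
    row = ((idx - 1L) %% ny) + 1L,
    col = ((idx - 1L) %/% ny) + 1L,
    cdf = cumsum(w) / sum(w),
    allowed = allowed
  )
}

# Draw n continuous positions (nm) uniformly within sampled pixels.  When
# min_sep_nm > 0 positions closer than that to an already-accepted position
# are redrawn (hard-core process for resolvable-spot fields).
draw_positions <- function(n, sampler, pixel_size_nm, min_sep_nm = 0) {
  draw <- function(k) {
    i <- findInterval(stats::runif(k), sampler$cdf) + 1L
    data.frame(
      x_nm = (sampler$col[i] - 1 + stats::runif(k)) * pixel_size_nm,
      y_nm = (sampler$row[i] - 1 + stats::runif(k)) * pixel_size_nm
    )
  }
  if (min_sep_nm <= 0 || n <= 1) return(draw(n))
  out <- draw(1)
  tries <- 0L
  while (nrow(out) < n) {
    p <- draw(1)
    if (min((out$x_nm - p$x_nm)^2 + (out$y_nm - p$y_nm)^2) >= min_sep_nm^2) {
      out <- rbind(out, p)
    } else {
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("placement error: cannot satisfy 'min_separation_nm'")
      }
    }
  }
  out
}

inside_allowed <- function(x_nm, y_nm, sampler, pixel_size_nm) {
  col <- floor(x_nm / pixel_size_nm) + 1L
  row <- floor(y_nm / pixel_size_nm) + 1L
  ny <- nrow(sampler$allowed); nx <- ncol(sampler$allowed)
  ok <- col >= 1L & col <= nx & row >= 1L & row <= ny
  ok[ok] <- sampler$allowed[cbind(row[ok], col[ok])]
  ok
}

#' Simulate a ground-truthed spot field for one cell
#'
#' Places diffraction-limited mRNA spots for one or more species inside the
#' cytoplasm of a synthetic cell, with a controlled colocalized fraction
#' between the first two species, a configurable cluster-size (copy number)
#' distribution, multiplicative lognormal intensity noise around a known
#' single-molecule intensity, and an exponential perinuclear density bias.
#'
#' A fraction `coloc_fraction` of the first species' spots receives a partner
#' of the second species placed uniformly within a disc of radius
#' `coloc_distance_nm` (default one pixel, the tightest association criterion
#' used downstream); all other spots are placed independently.
#'
#' @param geometry A [make_cell_geometry()] object.
#' @param counts Named integer vector of spots per species,
#'   e.g. `c(hERG1a = 100, SCN5A = 100)`.
#' @param cluster_dist Probability vector over copy numbers; names give the
#'   copy numbers (defaults to 1..length).  Must sum to 1.
#' @param coloc_fraction Fraction (0-1) of first-species spots given a
#'   second-species partner.
#' @param coloc_distance_nm Maximum partner displacement in nm.
#' @param single_intensity Fluorescence intensity of a single mRNA (arbitrary
#'   units).
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   lognormal intensity noise (0 = noiseless).
#' @param perinuclear_lambda_um Decay length of the placement density with
#'   distance from the nucleus; `Inf` places spots uniformly.
#' @param psf_sigma_nm Nominal spot Gaussian width recorded in `sigma_nm`
#'   (defaults to 1.3 pixels, a typical diffraction-limited width).
#' @param min_separation_nm Minimum within-channel center separation; 0
#'   (default) allows arbitrarily close spots, a positive value yields a
#'   hard-core field of individually resolvable spots (used for detection
#'   benchmarks).
#' @param seed Integer seed (bit-reproducible output).
#' @param cell_id Cell label written into the table.
#' @param sampler Optional precomputed [placement_sampler()]; pass one when
#'   simulating many cells on a shared geometry to avoid recomputing the
#'   distance transform.
#'
#' @return A list with `spots` (a spot table: `cell_id`, `channel`, `x_nm`,
#'   `y_nm`, `z_nm`, `intensity`, `sigma_nm`, `copies`, `spot_id`) and
#'   `truth` (class `spot_truth`): the true spot table, true single-molecule
#'   intensity, the planted pair list (`spot_id_a`, `spot_id_b`), the
#'   requested colocalized fraction and the seed.
#'
#' @export
simulate_spot_field <- function(geometry,
                                counts = c(hERG1a = 100, SCN5A = 100),
                                cluster_dist = default_cluster_dist(),
                                coloc_fraction = 0,
                                coloc_distance_nm = geometry$pixel_size_nm,
                                single_intensity = 1000,
                                intensity_cv = 0.15,
                                perinuclear_lambda_um = 10,
                                psf_sigma_nm = 1.3 * geometry$pixel_size_nm,
                                min_separation_nm = 0,
                                seed = 1L,
                                cell_id = "cell_1",
                                sampler = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (is.null(names(counts))) names(counts) <- paste0("species_", seq_along(counts))
  if (any(counts < 0)) stop("'counts' must be non-negative")
  if (abs(sum(cluster_dist) - 1) > 1e-8) stop("'cluster_dist' must sum to 1")
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("'coloc_fraction' must be in [0, 1]")
  }
  if (is.null(names(cluster_dist))) {
    names(cluster_dist) <- seq_along(cluster_dist)
  }
  copy_values <- as.integer(names(cluster_dist))

  if (is.null(sampler)) sampler <- placement_sampler(geometry, perinuclear_lambda_um)
  n_total <- sum(counts)
  if (n_total > length(sampler$row)) {
    stop("placement error: requested spot count exceeds placeable area")
  }

  px <- geometry$pixel_size_nm
  species <- names(counts)
  n_pairs <- if (length(counts) >= 2L && coloc_fraction > 0) {
    np <- round(coloc_fraction * counts[[1]])
    if (np > counts[[2]]) {
      stop("placement error: coloc_fraction requires more partners than ",
           "second-species spots available")
    }
    np
  } else 0L

  res <- withr::with_seed(as.integer(seed), {
    pos <- list()
    for (s in species) {
      pos[[s]] <- draw_positions(counts[[s]], sampler, px, min_separation_nm)
    }

    pair_idx_a <- integer(0)
    if (n_pairs > 0) {
      pair_idx_a <- seq_len(n_pairs)  # anchors are iid draws; first n suffice
      a <- pos[[1]][pair_idx_a, , drop = FALSE]
      for (j in seq_len(n_pairs)) {
        placed <- FALSE
        for (try in 1:200) {
          u <- stats::runif(1); ang <- stats::runif(1, 0, 2 * pi)
          rr <- coloc_distance_nm * sqrt(u)
          xx <- a$x_nm[j] + rr * cos(ang); yy <- a$y_nm[j] + rr * sin(ang)
          if (inside_allowed(xx, yy, sampler, px)) {
            pos[[2]]$x_nm[j] <- xx; pos[[2]]$y_nm[j] <- yy
            placed <- TRUE
            break
          }
        }
        if (!placed) {  # anchor is in a sliver; co-place exactly
          pos[[2]]$x_nm[j] <- a$x_nm[j]; pos[[2]]$y_nm[j] <- a$y_nm[j]
        }
      }
    }

    tabs <- vector("list", length(species))
    offset <- 0L
    for (k in seq_along(species)) {
      n <- counts[[k]]
      copies <- if (n > 0) {
        copy_values[sample.int(length(copy_values), n, replace = TRUE,
                               prob = cluster_dist)]
      } else integer(0)
      noise <- if (intensity_cv > 0 && n > 0) {
        s <- sqrt(log(1 + intensity_cv^2))
        stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
      } else rep(1, n)
      tabs[[k]] <- data.frame(
        cell_id = rep(cell_id, n),
        channel = rep(species[k], n),
        x_nm = pos[[k]]$x_nm, y_nm = pos[[k]]$y_nm, z_nm = rep(0, n),
        intensity = copies * single_intensity * noise,
        sigma_nm = rep(psf_sigma_nm, n),
        copies = copies,
        spot_id = offset + seq_len(n),
        stringsAsFactors = FALSE
      )
      offset <- offset + n
    }
    spots <- do.call(rbind, tabs)
    pairs <- if (n_pairs > 0) {
      data.frame(cell_id = cell_id,
                 spot_id_a = tabs[[1]]$spot_id[pair_idx_a],
                 spot_id_b = tabs[[2]]$spot_id[pair_idx_a])
    } else {
      data.frame(cell_id = character(0), spot_id_a = integer(0),
                 spot_id_b = integer(0))
    }
    list(spots = spots, pairs = pairs)
  })

  truth <- structure(list(
    true_spots = res$spots,
    true_single_intensity = single_intensity,
    true_coloc_pairs = res$pairs,
    true_coloc_fraction = coloc_fraction,
    seed = as.integer(seed)
  ), class = "spot_truth")
  list(spots = res$spots, truth = truth)
}

#' Simulate a multi-cell smFISH experiment
#'
#' Runs [simulate_spot_field()] across `n_cells` cells sharing one geometry,
#' deriving an independent sub-seed per cell from `seed`, and concatenates
#' spot tables and ground truth.
#'
#' @param n_cells Number of cells.
#' @param geometry Shared [make_cell_geometry()]; defaults to seed-matched
#'   geometry.
#' @param seed Master seed; per-cell seeds are drawn from it.
#' @param ... Passed to [simulate_spot_field()] (counts, coloc_fraction, ...).
#' @param perinuclear_lambda_um Placement decay length, shared across cells.
#' @param count_sampler Optional `function(i)` returning the named per-species
#'   count vector for cell `i`, overriding a fixed `counts`; use it to emulate
#'   the wide (roughly 5-200 transcripts) and possibly correlated per-cell
#'   pool sizes seen in real cells.
#'
#' @return List with `spots` (all cells), `truth` (concatenated pair list and
#'   per-cell truth tables) and `geometry`.
#' @export
simulate_experiment <- function(n_cells,
                                geometry = make_cell_geometry(seed = seed),
                                seed = 1L,
                                perinuclear_lambda_um = 10,
                                count_sampler = NULL,
                                ...) {
  sampler <- placement_sampler(geometry, perinuclear_lambda_um)
  cell_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max - 1L, n_cells))
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    extra <- list(...)
    if (!is.null(count_sampler)) extra$counts <- count_sampler(i)
    out[[i]] <- do.call(simulate_spot_field, c(list(
      geometry, seed = cell_seeds[i],
      cell_id = sprintf("cell_%03d", i), sampler = sampler,
      perinuclear_lambda_um = perinuclear_lambda_um), extra))
  }
  spots <- do.call(rbind, lapply(out, `[[`, "spots"))
  pairs <- do.call(rbind, lapply(out, function(o) o$truth$true_coloc_pairs))
  truth <- structure(list(
    true_spots = spots,
    true_single_intensity = out[[1]]$truth$true_single_intensity,
    true_coloc_pairs = pairs,
    true_coloc_fraction = out[[1]]$truth$true_coloc_fraction,
    seed = as.integer(seed)
  ), class = "spot_truth")
  list(spots = spots, truth = truth, geometry = geometry)
}
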