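#' Intersection area of two equal circles
#'
#' Area of overlap of two discs of radius `r` whose centers are `d` apart:
#' \deqn{I = 2 r^2 \cos^{-1}\!\left(\frac{d}{2r}\right)
#'   - \frac{d}{2}\sqrt{4r^2 - d^2}}
#' Disjoint discs (`d > 2r`) return 0.
#'
#' @param d_nm Center distance(s), nm (non-negative).
#' @param r_nm Disc radius, nm (positive).
#' @return Intersection area(s) in nm^2.
#' @export
circle_intersection <- function(d_nm, r_nm) {
  if (any(d_nm < 0)) stop("'d_nm' must be non-negative")
  if (any(r_nm <= 0)) stop("'r_nm' must be positive")
  dd <- pmin(d_nm, 2 * r_nm)
  ifelse(d_nm >= 2 * r_nm, 0,
         2 * r_nm^2 * acos(dd / (2 * r_nm)) -
           (dd / 2) * sqrt(pmax(4 * r_nm^2 - dd^2, 0)))
}

#' Expected chance associations between two spot populations
#'
#' Analytic chance-correction model for object-based colocalization: the
#' expected number of spot pairs that would satisfy a center-distance
#' criterion `d` under spatial randomness, for populations of `N_m1` and
#' `N_m2` spots of average radius `r` in an analyzed area `A`:
#' \deqn{E_m = \frac{N_{m1} N_{m2} (2\pi r^2 - I)}{A}}
#' with `I = circle_intersection(d, r)` (`model = "union"`, the default,
#' exactly as the source formula is printed).  `model = "distance"` uses the
#' classical geometric encounter area instead, \eqn{E_m = N_{m1} N_{m2} \pi
#' d^2 / A}: the exact expected number of pairs with centers closer than
#' `d` under uniform placement, provided for sensitivity analysis (see the
#' methods vignette for why the two differ).
#'
#' @param N_m1,N_m2 Spot counts of the two populations (in one cell).
#' @param r_nm Average spot radius, nm.
#' @param d_nm Distance criterion, nm (0 <= d <= 2r for the union model).
#' @param A_nm2 Analyzed area, nm^2 (positive).
#' @param model `"union"` (printed form) or `"distance"` (geometric null).
#' @return Expected pair count (vectorized over `d_nm`).
#' @export
expected_pair_count <- function(N_m1, N_m2, r_nm, d_nm, A_nm2,
                                model = c("union", "distance")) {
  model <- match.arg(model)
  if (any(A_nm2 <= 0)) stop("'A_nm2' must be positive")
  if (model == "union") {
    I <- circle_intersection(d_nm, r_nm)
    N_m1 * N_m2 * (2 * pi * r_nm^2 - I) / A_nm2
  } else {
    N_m1 * N_m2 * pi * d_nm^2 / A_nm2
  }
}

#' Expected chance triple associations
#'
#' Extends the pairwise chance model to triples (two mRNA species plus a
#' protein signal):
#' \deqn{E_p = \frac{N_p E_m (\pi r^2 - I)}{A}}
#' where `N_p` is the protein spot count and `E_m` the expected pair count.
#' `model = "distance"` substitutes the geometric encounter area
#' \eqn{\pi d^2}.
#'
#' @param N_p Protein spot count.
#' @param E_m Expected pair count from [expected_pair_count()].
#' @inheritParams expected_pair_count
#' @return Expected triple count.
#' @export
expected_triple_count <- function(N_p, E_m, r_nm, d_nm, A_nm2,
                                  model = c("union", "distance")) {
  model <- match.arg(model)
  if (any(A_nm2 <= 0)) stop("'A_nm2' must be positive")
  if (model == "union") {
    I <- circle_intersection(d_nm, r_nm)
    N_p * E_m * (pi * r_nm^2 - I) / A_nm2
  } else {
    N_p * E_m * pi * d_nm^2 / A_nm2
  }
}

# Greedy nearest-first one-to-one matching within one cell.
# Returns data.frame(ia, ib, distance_nm) with local (within-cell) indices.
greedy_match <- function(xa, ya, xb, yb, dmax_nm) {
  na <- length(xa); nb <- length(xb)
  if (na == 0L || nb == 0L) {
    return(data.frame(ia = integer(0), ib = integer(0),
                      distance_nm = numeric(0)))
  }
  dx <- outer(xa, xb, "-"); dy <- outer(ya, yb, "-")
  dmat <- sqrt(dx^2 + dy^2)
  cand <- which(dmat <= dmax_nm, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(ia = integer(0), ib = integer(0),
                      distance_nm = numeric(0)))
  }
  dd <- dmat[cand]
  ord <- order(dd, cand[, 1], cand[, 2])  # ties: A index, then B index
  cand <- cand[ord, , drop = FALSE]; dd <- dd[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(length(dd))
  for (i in seq_along(dd)) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE; keep[i] <- TRUE
    }
  }
  data.frame(ia = cand[keep, 1], ib = cand[keep, 2], distance_nm = dd[keep])
}

#' Match spots of two channels within a distance criterion
#'
#' One-to-one object-based matching: all cross-channel pairs with center
#' distance at or below the criterion are sorted by increasing distance
#' (ties broken by first-channel then second-channel spot index) and
#' accepted greedily, each spot used at most once.  Matching is performed
#' per cell.
#'
#' @param spots_a,spots_b Spot tables sharing `cell_id` and nm coordinates.
#' @param criterion_px Maximum center distance in pixels (1-4 in typical
#'   use).
#' @param pixel_size_nm Pixel size used to convert the criterion to nm.
#' @return List with `pairs` (`cell_id`, `spot_a`, `spot_b`, `distance_nm`
#'   using the tables' `spot_id` where present, else row index) and
#'   `per_cell` (`cell_id`, `n_a`, `n_b`, `observed`).
#' @export
match_pairs <- function(spots_a, spots_b, criterion_px = 2,
                        pixel_size_nm = 106.3) {
  dmax <- criterion_px * pixel_size_nm
  cells <- sort(unique(c(spots_a$cell_id, spots_b$cell_id)))
  ida <- spots_a$spot_id %||% seq_len(nrow(spots_a))
  idb <- spots_b$spot_id %||% seq_len(nrow(spots_b))
  pairs <- list(); per_cell <- list()
  for (cc in cells) {
    sa <- which(spots_a$cell_id == cc); sb <- which(spots_b$cell_id == cc)
    m <- greedy_match(spots_a$x_nm[sa], spots_a$y_nm[sa],
                      spots_b$x_nm[sb], spots_b$y_nm[sb], dmax)
    if (nrow(m)) {
      pairs[[cc]] <- data.frame(cell_id = cc,
                                spot_a = ida[sa][m$ia],
                                spot_b = idb[sb][m$ib],
                                distance_nm = m$distance_nm)
    }
    per_cell[[cc]] <- data.frame(cell_id = cc, n_a = length(sa),
                                 n_b = length(sb), observed = nrow(m))
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
            else data.frame(cell_id = character(0), spot_a = integer(0),
                            spot_b = integer(0), distance_nm = numeric(0)),
    per_cell = do.call(rbind, c(per_cell, make.row.names = FALSE))
  )
}

#' Triple association of two mRNA channels and a protein channel
#'
#' A triple is an accepted mRNA pair (from [match_pairs()]) whose first- or
#' second-channel centroid lies within the criterion distance of a protein
#' spot; protein spots are consumed greedily (nearest pair first, each
#' protein spot used at most once).  The default criterion is 2 px, the
#' physiologically motivated distance for triple analysis.
#'
#' @param spots_a,spots_b,spots_p mRNA and protein spot tables sharing
#'   `cell_id`.
#' @inheritParams match_pairs
#' @return List with `triples` (`cell_id`, `spot_a`, `spot_b`, `spot_p`,
#'   `distance_nm` of the pair-to-protein link) and `per_cell` (`cell_id`,
#'   `n_a`, `n_b`, `n_p`, `observed_pairs`, `observed_triples`).
#' @export
match_triples <- function(spots_a, spots_b, spots_p, criterion_px = 2,
                          pixel_size_nm = 106.3) {
  dmax <- criterion_px * pixel_size_nm
  pm <- match_pairs(spots_a, spots_b, criterion_px, pixel_size_nm)
  ida <- spots_a$spot_id %||% seq_len(nrow(spots_a))
  idb <- spots_b$spot_id %||% seq_len(nrow(spots_b))
  idp <- spots_p$spot_id %||% seq_len(nrow(spots_p))
  cells <- pm$per_cell$cell_id
  triples <- list(); per_cell <- list()
  for (cc in cells) {
    pr <- pm$pairs[pm$pairs$cell_id == cc, , drop = FALSE]
    sp <- which(spots_p$cell_id == cc)
    np <- length(sp)
    found <- data.frame(cell_id = character(0), spot_a = integer(0),
                        spot_b = integer(0), spot_p = integer(0),
                        distance_nm = numeric(0))
    if (nrow(pr) && np) {
      sa <- which(spots_a$cell_id == cc); sb <- which(spots_b$cell_id == cc)
      ax <- spots_a$x_nm[sa][match(pr$spot_a, ida[sa])]
      ay <- spots_a$y_nm[sa][match(pr$spot_a, ida[sa])]
      bx <- spots_b$x_nm[sb][match(pr$spot_b, idb[sb])]
      by <- spots_b$y_nm[sb][match(pr$spot_b, idb[sb])]
      px_ <- spots_p$x_nm[sp]; py_ <- spots_p$y_nm[sp]
      # link distance: nearer of (A-to-P, B-to-P)
      da <- sqrt(outer(ax, px_, "-")^2 + outer(ay, py_, "-")^2)
      db <- sqrt(outer(bx, px_, "-")^2 + outer(by, py_, "-")^2)
      dlink <- pmin(da, db)
      cand <- which(dlink <= dmax, arr.ind = TRUE)
      if (nrow(cand)) {
        dd <- dlink[cand]
        ord <- order(dd, cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]; dd <- dd[ord]
        used_pair <- logical(nrow(pr)); used_p <- logical(np)
        for (i in seq_along(dd)) {
          q <- cand[i, 1]; p <- cand[i, 2]
          if (!used_pair[q] && !used_p[p]) {
            used_pair[q] <- TRUE; used_p[p] <- TRUE
            found <- rbind(found, data.frame(
              cell_id = cc, spot_a = pr$spot_a[q], spot_b = pr$spot_b[q],
              spot_p = idp[sp][p], distance_nm = dd[i]))
          }
        }
      }
    }
    triples[[cc]] <- found
    per_cell[[cc]] <- data.frame(
      cell_id = cc,
      n_a = pm$per_cell$n_a[pm$per_cell$cell_id == cc],
      n_b = pm$per_cell$n_b[pm$per_cell$cell_id == cc],
      n_p = np,
      observed_pairs = nrow(pr),
      observed_triples = nrow(found))
  }
  list(triples = do.call(rbind, c(triples, make.row.names = FALSE)),
       per_cell = do.call(rbind, c(per_cell, make.row.names = FALSE)))
}

#' Paired test of observed vs expected association counts
#'
#' Two-tailed paired t-test of per-cell observed association counts against
#' the per-cell chance expectation, with Bonferroni correction over the
#' number of distance criteria tested.  If the per-cell differences are
#' exactly constant (zero variance) the test degenerates: all-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference gives
#' `t = +-Inf, p = 0`.
#'
#' @param observed,expected Per-cell counts (equal length, >= 3 cells).
#' @param n_criteria Number of criteria tested (Bonferroni factor).
#' @return List: `t`, `df`, `p_raw`, `p_bonferroni`, `mean_observed`,
#'   `mean_expected`, `n_cells`.
#' @export
association_test <- function(observed, expected, n_criteria = 1L) {
  if (length(observed) != length(expected)) stop("length mismatch")
  n <- length(observed)
  if (n < 3) stop("need at least 3 cells for the paired test")
  d <- observed - expected
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) { tt <- 0; p <- 1 } else { tt <- sign(mean(d)) * Inf; p <- 0 }
  } else {
    ht <- stats::t.test(observed, expected, paired = TRUE)
    tt <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = tt, df = n - 1L, p_raw = p,
       p_bonferroni = min(1, p * n_criteria),
       mean_observed = mean(observed), mean_expected = mean(expected),
       n_cells = n)
}

#' Fraction of each population that is associated
#'
#' Percentage of each species' spots that belong to a matched pair, pooled
#' across cells.
#'
#' @param n_pairs Matched pair count(s), summed if a vector.
#' @param total_a,total_b Total spot counts per species (summed if vectors).
#' @return Named vector `pct_a`, `pct_b` (0-100).
#' @export
association_fractions <- function(n_pairs, total_a, total_b) {
  ta <- sum(total_a); tb <- sum(total_b)
  if (ta <= 0 || tb <= 0) stop("totals must be positive")
  c(pct_a = 100 * sum(n_pairs) / ta, pct_b = 100 * sum(n_pairs) / tb)
}

#' Full pairwise association analysis across distance criteria
#'
#' For each criterion (1-4 px by default): per-cell one-to-one matching,
#' per-cell chance expectation from [expected_pair_count()] using that
#' cell's counts and the analyzed area, a paired t-test with Bonferroni
#' correction over criteria, and the associated fractions of each
#' population.
#'
#' @param spots_a,spots_b Spot tables sharing `cell_id`.
#' @param geometry Shared [make_cell_geometry()] (supplies `A` and the pixel
#'   size), or a named list of geometries keyed by `cell_id`.
#' @param criteria_px Integer vector of center-distance criteria in pixels.
#' @param r_nm Average spot radius; default derives from the tables' fitted
#'   widths via [mean_spot_radius_nm()].
#' @param expected_model Passed to [expected_pair_count()].
#' @return Object of class `association_result`: `per_cell` (rows cell x
#'   criterion with `observed` and `expected`), `summary` (per criterion:
#'   mean +- SE observed and expected, `t`, `p_raw`, `p_bonferroni`,
#'   `pct_a`, `pct_b`), `r_nm`, `criteria_px`, `expected_model`.
#' @export
analyze_association <- function(spots_a, spots_b, geometry,
                                criteria_px = 1:4, r_nm = NULL,
                                expected_model = c("union", "distance")) {
  expected_model <- match.arg(expected_model)
  geoms <- if (inherits(geometry, "cell_geometry")) NULL else geometry
  g1 <- if (is.null(geoms)) geometry else geoms[[1]]
  px <- g1$pixel_size_nm
  if (is.null(r_nm)) {
    r_nm <- mean_spot_radius_nm(rbind(spots_a[c("sigma_nm")],
                                      spots_b[c("sigma_nm")]))
  }
  nc <- length(criteria_px)
  per_cell <- list(); summary <- list()
  for (ci in seq_len(nc)) {
    cr <- criteria_px[ci]
    m <- match_pairs(spots_a, spots_b, cr, px)
    pc <- m$per_cell
    A <- vapply(pc$cell_id, function(cc) {
      if (is.null(geoms)) g1$area_A_nm2 else geoms[[cc]]$area_A_nm2
    }, numeric(1))
    pc$criterion_px <- cr
    pc$expected <- expected_pair_count(pc$n_a, pc$n_b, r_nm, cr * px, A,
                                       model = expected_model)
    ht <- association_test(pc$observed, pc$expected, n_criteria = nc)
    fr <- association_fractions(pc$observed, pc$n_a, pc$n_b)
    per_cell[[ci]] <- pc
    summary[[ci]] <- data.frame(
      criterion_px = cr,
      mean_observed = mean(pc$observed),
      se_observed = stats::sd(pc$observed) / sqrt(nrow(pc)),
      mean_expected = mean(pc$expected),
      se_expected = stats::sd(pc$expected) / sqrt(nrow(pc)),
      t = ht$t, p_raw = ht$p_raw, p_bonferroni = ht$p_bonferroni,
      pct_a = fr[["pct_a"]], pct_b = fr[["pct_b"]])
  }
  structure(list(per_cell = do.call(rbind, per_cell),
                 summary = do.call(rbind, summary),
                 r_nm = r_nm, criteria_px = criteria_px,
                 expected_model = expected_model),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> model:", x$expected_model,
      " r =", round(x$r_nm, 1), "nm\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Triple association analysis with chance correction
#'
#' Matches triples at one criterion (2 px default), computes the per-cell
#' expected triple count \eqn{E_p}, the paired test, the fraction of
#' first-species mRNA associated with protein (the actively translated
#' population) and the fraction of that population also associated with the
#' second mRNA species.
#'
#' @inheritParams analyze_association
#' @param spots_p Protein spot table.
#' @param criterion_px Single distance criterion in pixels.
#' @return Object of class `triple_result`: `per_cell`, `test`,
#'   `pct_a_with_protein`, `pct_translated_with_b`, `r_nm`, `criterion_px`.
#' @export
analyze_triple_association <- function(spots_a, spots_b, spots_p, geometry,
                                       criterion_px = 2, r_nm = NULL,
                                       expected_model = c("union", "distance")) {
  expected_model <- match.arg(expected_model)
  stopifnot(inherits(geometry, "cell_geometry"))
  px <- geometry$pixel_size_nm
  if (is.null(r_nm)) {
    r_nm <- mean_spot_radius_nm(rbind(spots_a[c("sigma_nm")],
                                      spots_b[c("sigma_nm")]))
  }
  mt <- match_triples(spots_a, spots_b, spots_p, criterion_px, px)
  pc <- mt$per_cell
  d_nm <- criterion_px * px
  Em <- expected_pair_count(pc$n_a, pc$n_b, r_nm, d_nm, geometry$area_A_nm2,
                            model = expected_model)
  pc$expected <- expected_triple_count(pc$n_p, Em, r_nm, d_nm,
                                       geometry$area_A_nm2,
                                       model = expected_model)
  ht <- association_test(pc$observed_triples, pc$expected)
  # translated population: first-species spots matched to a protein spot
  ap <- match_pairs(spots_a, spots_p, criterion_px, px)
  n_translated <- sum(ap$per_cell$observed)
  pct_a_with_protein <- 100 * n_translated / max(1, sum(pc$n_a))
  pct_translated_with_b <- if (n_translated > 0) {
    100 * sum(pc$observed_triples) / n_translated
  } else 0
  structure(list(per_cell = pc, triples = mt$triples, test = ht,
                 pct_a_with_protein = pct_a_with_protein,
                 pct_translated_with_b = pct_translated_with_b,
                 r_nm = r_nm, criterion_px = criterion_px,
                 expected_model = expected_model),
            class = "triple_result")
}

#' @export
print.triple_result <- function(x, ...) {
  cat("<triple_result> criterion:", x$criterion_px, "px; observed",
      sum(x$per_cell$observed_triples), "triples vs",
      round(sum(x$per_cell$expected), 2), "expected (p =",
      signif(x$test$p_raw, 3), ")\n")
  cat(sprintf("  %.1f%% of species A with protein; %.1f%% of those also with species B\n",
              x$pct_a_with_protein, x$pct_translated_with_b))
  invisible(x)
}
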