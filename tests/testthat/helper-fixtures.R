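# Shared fixtures: a small fast geometry and detection-vs-truth matching.

# 256 px cell used by most unit tests (cheap distance transform)
small_geom <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      g <<- make_cell_geometry(seed = 1, shape_px = c(256, 256),
                               nucleus_radius_um = 5,
                               cell_radii_um = c(12, 10))
    }
    g
  }
})

# match detected spots to true spots within tol_px; returns precision/recall
# and localization RMSE (px) over matched detections
score_detection <- function(detected, truth, pixel_size_nm, tol_px = 1) {
  if (nrow(detected) == 0L) {
    return(list(precision = 0, recall = 0, rmse_px = NA_real_))
  }
  dmat <- sqrt(outer(detected$x_nm, truth$x_nm, "-")^2 +
                 outer(detected$y_nm, truth$y_nm, "-")^2)
  nn_det <- apply(dmat, 1, min)
  nn_tru <- apply(dmat, 2, min)
  tol_nm <- tol_px * pixel_size_nm
  hit <- nn_det <= tol_nm
  list(precision = mean(hit),
       recall = mean(nn_tru <= tol_nm),
       rmse_px = sqrt(mean(nn_det[hit]^2)) / pixel_size_nm)
}

# photons per intensity unit so a single-copy spot peaks at snr * sqrt(bg)
photons_for_snr <- function(snr, background, psf_sigma_px, single_intensity) {
  snr * sqrt(background) * 2 * pi * psf_sigma_px^2 / single_intensity
}

# brute-force maximum one-to-one matching count under a distance cap
# (exhaustive search; only usable for <= ~8 spots per channel)
max_matching_count <- function(D, cap) {
  na <- nrow(D); nb <- ncol(D)
  best <- 0
  rec <- function(a, used_b, cnt) {
    if (cnt + (na - a + 1) <= best) return()
    if (a > na) { best <<- max(best, cnt); return() }
    rec(a + 1, used_b, cnt)
    for (b in seq_len(nb)) {
      if (!used_b[b] && D[a, b] <= cap) {
        ub <- used_b; ub[b] <- TRUE
        rec(a + 1, ub, cnt + 1)
      }
    }
  }
  rec(1, rep(FALSE, nb), 0)
  best
}
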