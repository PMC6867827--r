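test_that("maximum projection is a per-pixel max over planes", {
  one <- matrix(runif(64), 8, 8)
  expect_identical(project_max(one), one)
  stk <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  pm <- project_max(stk)
  # brute-force check against every plane
  for (p in 1:5) expect_true(all(pm >= stk[, , p]))
  expect_equal(pm, pmax(stk[, , 1], stk[, , 2], stk[, , 3],
                        stk[, , 4], stk[, , 5]))
  expect_error(project_max(list()), "empty")
})

test_that("background subtraction maps flat images to zero and is shift-invariant", {
  flat <- matrix(50, 64, 64)
  for (m in c("log", "rolling_ball")) {
    out <- subtract_background(flat, m, radius_px = 8)
    expect_true(all(abs(out) < 1e-8))
  }
  img <- matrix(rpois(64 * 64, 20), 64, 64)
  a <- subtract_background(img, "log", 8)
  b <- subtract_background(img + 100, "log", 8)
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(all(a >= 0))
  expect_error(subtract_background(img, "log", radius_px = 0), "positive")
  expect_error(subtract_background(img, "nonsense"), "arg")
})

test_that("background subtraction preserves a spot peak on a gradient", {
  g <- small_geom()
  sp <- data.frame(cell_id = "c", channel = "A",
                   x_nm = 128 * g$pixel_size_nm, y_nm = 128 * g$pixel_size_nm,
                   z_nm = 0, intensity = 1000, sigma_nm = NA)
  clean <- render_image(sp, g, psf_sigma_px = 1.3, background = 0,
                        noise = FALSE)
  grad <- matrix(rep(seq(0, 30, length.out = 256), each = 256), 256, 256)
  out <- subtract_background(clean + grad, "log", radius_px = 10)
  expect_equal(max(out[120:136, 120:136]), max(clean),
               tolerance = 0.1)
})

test_that("candidate detection finds separated peaks and nothing on blanks", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_candidates(blank, min_peak = 1)), 0)
  two <- matrix(0, 64, 64)
  two[20, 20] <- 100; two[20, 30] <- 80   # 10 px apart
  cand <- detect_candidates(two, blur_sigma_px = 1, min_peak = 5,
                            min_separation_px = 3)
  expect_equal(nrow(cand), 2)
  # closer than min_separation: brighter peak survives
  close2 <- matrix(0, 64, 64)
  close2[20, 20] <- 100; close2[20, 22] <- 60
  cand2 <- detect_candidates(close2, blur_sigma_px = 0, min_peak = 5,
                             min_separation_px = 3)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$x_px, 19.5)
})

test_that("noiseless spots localize to 0.05 px and conserve intensity to 1%", {
  g <- small_geom()
  sp <- data.frame(cell_id = "c", channel = "A",
                   x_nm = 100.0 * g$pixel_size_nm,
                   y_nm = 50.0 * g$pixel_size_nm,
                   z_nm = 0, intensity = 2000, sigma_nm = NA)
  img <- render_image(sp, g, psf_sigma_px = 1.3, background = 5,
                      noise = FALSE)
  det <- detect_spots(img, g, min_peak = 1)
  expect_equal(nrow(det$spots), 1)
  expect_lt(abs(det$spots$x_nm - sp$x_nm) / g$pixel_size_nm, 0.05)
  expect_lt(abs(det$spots$y_nm - sp$y_nm) / g$pixel_size_nm, 0.05)
  expect_equal(det$spots$intensity, 2000, tolerance = 0.01)
})

test_that("width thresholds move candidates to the rejects table", {
  g <- small_geom()
  sp <- data.frame(cell_id = "c", channel = "A",
                   x_nm = 100 * g$pixel_size_nm, y_nm = 100 * g$pixel_size_nm,
                   z_nm = 0, intensity = 2000, sigma_nm = NA)
  # render a wide blob, beyond the default sigma bounds
  img <- render_image(sp, g, psf_sigma_px = 3.5, background = 0,
                      noise = FALSE)
  cand <- data.frame(x_px = 99.5, y_px = 99.5, value = max(img))
  out <- fit_spots(img, cand, g, window_px = 17,
                   sigma_bounds_px = c(0.7, 2.5))
  expect_equal(nrow(out$spots), 0)
  expect_equal(nrow(out$rejects), 1)
  expect_false(out$rejects$fit_ok[1])
})

test_that("detection count is invariant under a constant offset", {
  g <- small_geom()
  f <- simulate_spot_field(g, counts = c(A = 40), cluster_dist = c(`1` = 1),
                           intensity_cv = 0, min_separation_nm = 600,
                           seed = 21)
  ppu <- photons_for_snr(8, 50, 1.3, 1000)
  img <- render_image(f$spots, g, psf_sigma_px = 1.3, photons_per_unit = ppu,
                      background = 50, seed = 21)
  d0 <- detect_spots(img, g)
  d1 <- detect_spots(img + 200, g)
  expect_equal(nrow(d0$spots), nrow(d1$spots))
})

test_that("fitted intensities scale linearly with rendered intensities", {
  g <- small_geom()
  f <- simulate_spot_field(g, counts = c(A = 30),
                           cluster_dist = c(`1` = .4, `2` = .3, `3` = .3),
                           intensity_cv = 0.2, min_separation_nm = 800,
                           seed = 13)
  img <- render_image(f$spots, g, psf_sigma_px = 1.3, photons_per_unit = 0.5,
                      background = 10, noise = FALSE)
  det <- detect_spots(img, g, min_peak = 2)
  dmat <- sqrt(outer(det$spots$x_nm, f$spots$x_nm, "-")^2 +
                 outer(det$spots$y_nm, f$spots$y_nm, "-")^2)
  idx <- apply(dmat, 1, which.min)
  fit <- stats::lm(det$spots$intensity ~ f$spots$intensity[idx])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("stack input yields axial positions near the truth", {
  g <- small_geom()
  sp <- data.frame(cell_id = "c", channel = "A",
                   x_nm = 80 * g$pixel_size_nm, y_nm = 90 * g$pixel_size_nm,
                   z_nm = 6.3 * g$z_step_nm, intensity = 3000, sigma_nm = NA)
  stk <- render_image(sp, g, planes = 12, background = 2, noise = FALSE)
  det <- detect_spots(stk, g, min_peak = 1)
  expect_equal(nrow(det$spots), 1)
  expect_lt(abs(det$spots$z_nm - sp$z_nm), g$z_step_nm / 2)
})
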