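test_that("circle intersection has its closed-form limits", {
  expect_equal(circle_intersection(2 * 200, 200), 0)            # touching
  expect_equal(circle_intersection(0, 200), pi * 200^2)         # coincident
  expect_equal(circle_intersection(500, 200), 0)                # disjoint
  # d = r, r = 1: lens area 2*pi/3 - sqrt(3)/2
  expect_equal(circle_intersection(1, 1), 2 * pi / 3 - sqrt(3) / 2,
               tolerance = 1e-12)
  expect_error(circle_intersection(-1, 1), "non-negative")
  expect_error(circle_intersection(1, 0), "positive")
})

test_that("circle intersection agrees with numerical integration", {
  # lens = twice the circular segment cut at x = d/2
  for (r in c(50, 163, 400)) for (d in c(0.2, 0.9, 1.7) * r) {
    seg <- stats::integrate(function(x) 2 * sqrt(pmax(r^2 - x^2, 0)),
                            d / 2, r, rel.tol = 1e-10)$value
    expect_equal(circle_intersection(d, r), 2 * seg,
                 tolerance = 1e-6 * r^2 / max(1, circle_intersection(d, r)))
  }
})

test_that("expected pair counts follow the printed formula and its limits", {
  # N1 = 0 gives 0; touching discs give N1 N2 2 pi r^2 / A
  expect_equal(expected_pair_count(0, 50, 200, 100, 1e9), 0)
  expect_equal(expected_pair_count(100, 100, 200, 400, 2e9),
               100 * 100 * 2 * pi * 200^2 / 2e9)
  # independent re-evaluation at the 2 px criterion
  r <- 200; d <- 212.6; A <- 2e9
  I <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expect_equal(expected_pair_count(100, 100, r, d, A),
               1e4 * (2 * pi * r^2 - I) / A, tolerance = 1e-12)
  # geometric-distance alternative
  expect_equal(expected_pair_count(100, 100, r, d, A, model = "distance"),
               1e4 * pi * d^2 / A, tolerance = 1e-12)
  expect_error(expected_pair_count(1, 1, 200, 100, 0), "positive")
})

test_that("expected counts increase with the distance criterion", {
  r <- 163
  d <- seq(0, 2 * r, length.out = 80)
  em <- expected_pair_count(100, 100, r, d, 2e9)
  expect_true(all(diff(em) > 0))
})

test_that("expected triple counts follow the printed formula", {
  expect_equal(expected_triple_count(0, 5, 200, 100, 1e9), 0)
  # d = 0: the pi r^2 - I factor vanishes
  expect_equal(expected_triple_count(50, 5, 200, 0, 1e9), 0)
  r <- 200; d <- 212.6; A <- 2e9
  Em <- expected_pair_count(100, 100, r, d, A)
  I <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expect_equal(expected_triple_count(50, Em, r, d, A),
               50 * Em * (pi * r^2 - I) / A, tolerance = 1e-12)
})

test_that("pair matching is greedy nearest-first and one-to-one", {
  px <- 106.3
  a <- data.frame(cell_id = "c", x_nm = 0, y_nm = 0)
  b <- data.frame(cell_id = "c", x_nm = c(1.0, 1.5) * px, y_nm = c(0, 0))
  m <- match_pairs(a, b, criterion_px = 2, pixel_size_nm = px)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$spot_b, 1)           # nearer B wins
  # coincident spots pair trivially
  m0 <- match_pairs(a, data.frame(cell_id = "c", x_nm = 0, y_nm = 0),
                    criterion_px = 2, pixel_size_nm = px)
  expect_equal(m0$per_cell$observed, 1)
  expect_equal(m0$pairs$distance_nm, 0)
})

test_that("greedy matching equals the exhaustive optimum on small instances", {
  set.seed(42)
  for (i in 1:60) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    ax <- runif(na, 0, 20); ay <- runif(na, 0, 20)
    bx <- runif(nb, 0, 20); by <- runif(nb, 0, 20)
    cap <- runif(1, 1, 4)
    sa <- data.frame(cell_id = "c", x_nm = ax, y_nm = ay)
    sb <- data.frame(cell_id = "c", x_nm = bx, y_nm = by)
    greedy <- match_pairs(sa, sb, criterion_px = cap,
                          pixel_size_nm = 1)$per_cell$observed
    D <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
    expect_equal(greedy, max_matching_count(D, cap))
  }
})

test_that("pair counts are symmetric in channel order", {
  g <- small_geom()
  f <- simulate_spot_field(g, counts = c(A = 60, B = 60),
                           coloc_fraction = 0.3, seed = 12)
  A <- f$spots[f$spots$channel == "A", ]
  B <- f$spots[f$spots$channel == "B", ]
  m1 <- match_pairs(A, B, 2, g$pixel_size_nm)$per_cell$observed
  m2 <- match_pairs(B, A, 2, g$pixel_size_nm)$per_cell$observed
  expect_equal(m1, m2)
})

test_that("triple matching finds planted triples and respects the criterion", {
  px <- 106.3
  a <- data.frame(cell_id = "c", x_nm = c(0, 10 * px), y_nm = c(0, 0))
  b <- data.frame(cell_id = "c", x_nm = c(0.5, 10.5) * px, y_nm = c(0, 0))
  p <- data.frame(cell_id = "c", x_nm = c(0, 13.1 * px), y_nm = c(0, 0))
  # first pair has a coincident protein spot; second pair's nearest P is 2.6 px
  mt <- match_triples(a, b, p, criterion_px = 2, pixel_size_nm = px)
  expect_equal(mt$per_cell$observed_pairs, 2)
  expect_equal(mt$per_cell$observed_triples, 1)
  expect_equal(mt$triples$spot_p, 1)
})

test_that("planted triples are all recovered with no extras", {
  g <- small_geom()
  px <- g$pixel_size_nm
  f <- simulate_spot_field(g, counts = c(A = 40, B = 40),
                           coloc_fraction = 0.5, coloc_distance_nm = px,
                           min_separation_nm = 5 * px, seed = 5)
  A <- f$spots[f$spots$channel == "A", ]
  B <- f$spots[f$spots$channel == "B", ]
  # protein spots planted on every paired A spot
  ia <- match(f$truth$true_coloc_pairs$spot_id_a, f$spots$spot_id)
  P <- data.frame(cell_id = "c", spot_id = seq_along(ia),
                  x_nm = f$spots$x_nm[ia], y_nm = f$spots$y_nm[ia])
  P$cell_id <- A$cell_id[1]
  mt <- match_triples(A, B, P, criterion_px = 2, pixel_size_nm = px)
  expect_equal(mt$per_cell$observed_triples, nrow(P))
})

test_that("association test handles degenerate and null inputs", {
  ht0 <- association_test(rep(4, 10), rep(4, 10))
  expect_equal(ht0$t, 0)
  expect_equal(ht0$p_raw, 1)
  ht5 <- association_test(rep(9, 10), rep(4, 10))
  expect_equal(ht5$t, Inf)
  expect_equal(ht5$p_raw, 0)
  expect_error(association_test(1:2, 2:3), "at least 3")
  # Bonferroni multiplies and caps at 1
  obs <- c(5, 6, 7, 9, 4, 6); exp <- c(4, 5, 6, 7, 5, 5)
  ht <- association_test(obs, exp, n_criteria = 4)
  expect_equal(ht$p_bonferroni, min(1, ht$p_raw * 4))
  ht1 <- association_test(obs, exp + 0.9, n_criteria = 1000)
  expect_equal(ht1$p_bonferroni, 1)
})

test_that("association fractions are exact on constructed counts", {
  fr <- association_fractions(25, 100, 100)
  expect_equal(unname(fr), c(25, 25))
  fr0 <- association_fractions(0, 50, 80)
  expect_equal(unname(fr0), c(0, 0))
  expect_error(association_fractions(5, 0, 10), "positive")
})

test_that("planted colocalized fractions are recovered within 3 points", {
  g <- small_geom()
  for (f in c(0, 0.25)) {
    ex <- simulate_experiment(10, g, seed = 31, counts = c(A = 80, B = 80),
                              coloc_fraction = f)
    A <- ex$spots[ex$spots$channel == "A", ]
    B <- ex$spots[ex$spots$channel == "B", ]
    m <- match_pairs(A, B, criterion_px = 1, pixel_size_nm = g$pixel_size_nm)
    fr <- association_fractions(m$per_cell$observed, m$per_cell$n_a,
                                m$per_cell$n_b)
    expect_lt(abs(fr[["pct_a"]] - 100 * f), 3)
  }
})

test_that("full association analysis is significant only for planted signal", {
  g <- small_geom()
  ex1 <- simulate_experiment(12, g, seed = 41, counts = c(A = 80, B = 80),
                             coloc_fraction = 0.25)
  A <- ex1$spots[ex1$spots$channel == "A", ]
  B <- ex1$spots[ex1$spots$channel == "B", ]
  res <- analyze_association(A, B, g, criteria_px = 1:4)
  expect_s3_class(res, "association_result")
  expect_equal(nrow(res$summary), 4)
  expect_true(all(res$summary$p_bonferroni ==
                    pmin(1, res$summary$p_raw * 4)))
  # planted signal: observed far exceeds chance at every criterion
  expect_true(all(res$summary$mean_observed > res$summary$mean_expected))
  expect_true(all(res$summary$p_bonferroni < 0.01))
})

test_that("removing planted triples drives the triple fraction to chance", {
  # mirrors a translation-inhibition contrast: same spot counts, planted
  # protein association removed
  g <- small_geom()
  px <- g$pixel_size_nm
  ex <- simulate_experiment(8, g, seed = 51, counts = c(A = 60, B = 60),
                            coloc_fraction = 0.4)
  A <- ex$spots[ex$spots$channel == "A", ]
  B <- ex$spots[ex$spots$channel == "B", ]
  # "control": protein planted on half of the paired A spots
  # (pair spot ids are unique within a cell, so match on both keys)
  key <- paste(ex$spots$cell_id, ex$spots$spot_id)
  ia <- match(paste(ex$truth$true_coloc_pairs$cell_id,
                    ex$truth$true_coloc_pairs$spot_id_a), key)
  ia <- ia[seq(1, length(ia), by = 2)]
  P_ctrl <- data.frame(cell_id = ex$spots$cell_id[ia],
                       x_nm = ex$spots$x_nm[ia], y_nm = ex$spots$y_nm[ia])
  # "treated": same number of protein spots placed independently
  ftr <- simulate_spot_field(g, counts = c(P = nrow(P_ctrl)), seed = 52)
  P_trt <- ftr$spots[c("cell_id", "x_nm", "y_nm")]
  P_trt$cell_id <- withr::with_seed(53, {
    sample(unique(A$cell_id), nrow(P_trt), replace = TRUE)
  })
  t_ctrl <- analyze_triple_association(A, B, P_ctrl, g, r_nm = 163)
  t_trt <- analyze_triple_association(A, B, P_trt, g, r_nm = 163)
  # planted association: strong signal, far above chance
  expect_lt(t_ctrl$test$p_raw, 0.01)
  expect_gt(sum(t_ctrl$per_cell$observed_triples),
            5 * max(1, sum(t_trt$per_cell$observed_triples)))
  # independent protein placement: no excess over chance
  expect_gt(t_trt$test$p_raw, 0.05)
})
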