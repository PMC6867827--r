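act_model <- list(G_max_nS = 10, V_rev_mV = -88, V_half_mV = -20, k_mV = -7,
                  tau_act_s = 0.15, tau_deact_s = 0.4)

test_that("drug subtraction is pointwise and validates protocols", {
  sw <- simulate_sweeps(protocol_activation(), act_model, noise_sd = 0)
  zero <- subtract_sensitive(sw, sw)
  expect_true(all(zero$current == 0))
  none <- sw; none$current[] <- 0
  expect_identical(subtract_sensitive(sw, none)$current, sw$current)
  short <- simulate_sweeps(protocol_activation(voltages_mV = c(-50, 0)),
                           act_model)
  expect_error(subtract_sensitive(sw, short), "mismatch")
  # hERG + linear leak; drug removes the hERG component
  leak <- sw
  leak$current <- matrix(rep(0.05 * (sw$voltage_mV + 50),
                             each = nrow(sw$current)),
                         nrow = nrow(sw$current))
  both <- sw; both$current <- sw$current + leak$current
  rec <- subtract_sensitive(both, leak)
  expect_equal(rec$current, sw$current, tolerance = 1e-12)
})

test_that("steady-state window measures the end-of-step mean", {
  sw <- simulate_sweeps(protocol_activation(voltages_mV = 0), act_model)
  sw$current[] <- 10   # constant trace
  expect_equal(measure_steady_state(sw)$current, 10)
  # linear ramp of slope m ending at v: window mean = v - m*w/2
  tt <- sw$time_s
  step <- sw$epochs$step
  m <- 4 / 1e-3  # 4 pA per ms
  sw$current[, 1] <- (tt - step[2]) * m + 100
  got <- measure_steady_state(sw, window_ms = 5)$current
  expect_equal(got, 100 - m * 0.005 / 2, tolerance = 0.01 * abs(got))
  expect_error(measure_steady_state(sw, window_ms = 1e6), "exceeds")
})

test_that("tail peaks capture the signed extremum of the tail epoch", {
  sw <- simulate_sweeps(protocol_activation(voltages_mV = c(-20, 20)),
                        act_model, noise_sd = 0)
  tp <- measure_tail_peak(sw)
  # monotone decaying tail: peak equals the first tail sample
  tail_start <- which(sw$time_s >= sw$epochs$tail[1])[1]
  expect_equal(tp$tail_peak, sw$current[tail_start, ], tolerance = 1e-6)
  flat <- sw; flat$current[] <- 0
  expect_equal(measure_tail_peak(flat)$tail_peak, c(0, 0))
})

test_that("noiseless Boltzmann data are recovered to 0.1%", {
  v <- seq(-50, 30, by = 10)
  iv <- data.frame(voltage_mV = v,
                   current = (v - -88) * 10 / (1 + exp((v - -20) / -7)))
  fit <- fit_activation(iv)
  expect_equal(fit$G_max, 10, tolerance = 1e-3)
  expect_equal(fit$V_rev, -88, tolerance = 1e-3)
  expect_equal(fit$V_half, -20, tolerance = 1e-3)
  expect_equal(fit$k, -7, tolerance = 1e-3)
  # midpoint identity: model at V_half is half the fully-open current
  at_half <- (fit$V_half - fit$V_rev) * fit$G_max /
    (1 + exp((fit$V_half - fit$V_half) / fit$k))
  expect_equal(at_half, 0.5 * (fit$V_half - fit$V_rev) * fit$G_max)
  # invariance to point order and current scaling
  sh <- sample(length(v))
  fit2 <- fit_activation(iv[sh, ])
  expect_equal(fit2$V_half, fit$V_half, tolerance = 1e-6)
  iv3 <- transform(iv, current = current * 3)
  fit3 <- fit_activation(iv3)
  expect_equal(fit3$V_half, fit$V_half, tolerance = 1e-4)
  expect_equal(fit3$G_max, 3 * fit$G_max, tolerance = 1e-3)
})

test_that("normalized-G mode fits tail-current activation curves", {
  v <- seq(-50, 30, by = 10)
  tails <- data.frame(voltage_mV = v,
                      tail_peak = 5 / (1 + exp((v - -15) / -6)))
  fit <- fit_activation(tails, mode = "normalized_g")
  expect_equal(fit$V_half, -15, tolerance = 1e-3)
  expect_equal(fit$abs_k, 6, tolerance = 1e-3)
  expect_equal(fit$G_max, 5, tolerance = 1e-3)
})

test_that("inactivation fits recover the printed equation exactly", {
  v <- seq(-140, 20, by = 10)
  m <- list(I_min = -50, I_max = -900, V_max = -80, k = 6)
  i <- (m$I_min - m$I_max) + m$I_max / (1 + exp((v - m$V_max) / m$k))
  fit <- fit_inactivation(data.frame(voltage_mV = v, current = i))
  expect_equal(fit$V_max, -80, tolerance = 1e-3)
  expect_equal(fit$k, 6, tolerance = 1e-3)
  expect_equal(fit$I_min, -50, tolerance = 0.1)
  expect_equal(fit$I_max, -900, tolerance = 0.5)
  expect_error(fit_inactivation(data.frame(voltage_mV = 1:3,
                                           current = 1:3)),
               "at least 5")
})

test_that("conductance curves are flat for ohmic data and logistic for gated", {
  v <- seq(-40, 40, by = 10)
  ohmic <- data.frame(voltage_mV = v, current = (v - -88) * 2)
  g <- conductance_curve(ohmic, V_rev = -88)
  expect_equal(g$G, rep(2, length(v)), tolerance = 1e-9)
  expect_equal(attr(g, "G_max"), 2, tolerance = 0.05)
  gated <- data.frame(voltage_mV = v,
                      current = (v - -88) * 10 / (1 + exp((v - 0) / -8)))
  gg <- conductance_curve(gated, V_rev = -88, normalize = TRUE)
  expect_equal(max(gg$G), 1, tolerance = 0.01)
  expect_warning(conductance_curve(data.frame(voltage_mV = c(-88, v),
                                              current = c(0, gated$current)),
                                   V_rev = -88), "V_rev")
})

test_that("the late integral is exact on closed forms, additive and linear", {
  tr <- list(time_s = seq(0, 0.9, by = 1e-3), current = rep(-2, 901))
  expect_equal(late_current_integral(tr, 50, 800), -2 * 750)
  tr0 <- list(time_s = tr$time_s, current = rep(0, 901))
  expect_equal(late_current_integral(tr0), 0)
  # additivity over subintervals and linearity in the trace
  set.seed(3)
  trn <- list(time_s = tr$time_s, current = rnorm(901))
  q_all <- late_current_integral(trn, 50, 800)
  q_sum <- late_current_integral(trn, 50, 300) +
    late_current_integral(trn, 300, 800)
  expect_equal(q_all, q_sum, tolerance = 1e-9)
  tr2 <- list(time_s = trn$time_s, current = 2.5 * trn$current)
  expect_equal(late_current_integral(tr2, 50, 800), 2.5 * q_all,
               tolerance = 1e-9)
  expect_error(late_current_integral(trn, 50, 2000), "cover")
})

test_that("pre-pulse baseline correction removes a holding offset", {
  sw <- simulate_sweeps(protocol_late(),
                        list(plateau_pA = -2), noise_sd = 0)
  sw$current <- sw$current + 11    # constant offset everywhere
  expect_equal(late_current_integral(sw), -2 * 750, tolerance = 1e-6)
})
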