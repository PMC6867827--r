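#' Drug-sensitive current by sweep subtraction
#'
#' Point-by-point difference between matched sweep families recorded before
#' and during a blocker (e.g. the E-4031-sensitive component isolating the
#' rapid delayed-rectifier current).
#'
#' @param sweeps_pre,sweeps_drug `sweep_set` objects with identical protocols
#'   and sampling.
#' @return A `sweep_set` holding the difference traces.
#' @export
subtract_sensitive <- function(sweeps_pre, sweeps_drug) {
  stopifnot(inherits(sweeps_pre, "sweep_set"), inherits(sweeps_drug, "sweep_set"))
  if (!isTRUE(all.equal(sweeps_pre$time_s, sweeps_drug$time_s)) ||
      !identical(dim(sweeps_pre$current), dim(sweeps_drug$current)) ||
      !isTRUE(all.equal(sweeps_pre$voltage_mV, sweeps_drug$voltage_mV))) {
    stop("protocol mismatch between pre and drug sweep sets")
  }
  out <- sweeps_pre
  out$current <- sweeps_pre$current - sweeps_drug$current
  out
}

#' Steady-state current at the end of each step
#'
#' Averages the current over the final `window_ms` of the depolarizing step
#' (5 ms by default) for each sweep and pairs it with the step voltage.
#'
#' @param sweeps A `sweep_set`.
#' @param window_ms Averaging window at the step end, in ms.
#' @return Data frame with `voltage_mV` and `current` (same units as traces).
#' @export
measure_steady_state <- function(sweeps, window_ms = 5) {
  stopifnot(inherits(sweeps, "sweep_set"))
  step <- sweeps$epochs$step
  if (window_ms / 1000 > diff(step)) {
    stop("'window_ms' exceeds the step duration")
  }
  sel <- sweeps$time_s >= (step[2] - window_ms / 1000) & sweeps$time_s < step[2]
  data.frame(voltage_mV = sweeps$voltage_mV,
             current = colMeans(sweeps$current[sel, , drop = FALSE]))
}

#' Peak tail current per sweep
#'
#' Signed extremum of the current within the tail epoch (following the
#' return to the tail potential), paired with the preceding step voltage.
#'
#' @param sweeps A `sweep_set` with a tail epoch.
#' @param polarity `"auto"` takes the sample of largest magnitude;
#'   `"positive"`/`"negative"` force the max/min.
#' @return Data frame with `voltage_mV` (prepulse) and `tail_peak`.
#' @export
measure_tail_peak <- function(sweeps, polarity = c("auto", "positive", "negative")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  polarity <- match.arg(polarity)
  if (is.null(sweeps$epochs$tail)) stop("sweep set has no tail epoch")
  tl <- sweeps$epochs$tail
  sel <- sweeps$time_s >= tl[1] & sweeps$time_s <= tl[2]
  pk <- apply(sweeps$current[sel, , drop = FALSE], 2, function(tr) {
    switch(polarity,
           auto = tr[which.max(abs(tr))],
           positive = max(tr),
           negative = min(tr))
  })
  data.frame(voltage_mV = sweeps$voltage_mV, tail_peak = pk)
}

#' Peak current per sweep near step onset
#'
#' Signed extremum within a search window after the step onset (defaults to
#' 1-10 ms), the conventional measurement for fast inward currents.
#'
#' @inheritParams measure_tail_peak
#' @param window_ms Two-element search window after step onset, in ms.
#' @return Data frame with `voltage_mV` and `peak`.
#' @export
measure_peak <- function(sweeps, window_ms = c(1, 10),
                         polarity = c("auto", "positive", "negative")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  polarity <- match.arg(polarity)
  on <- sweeps$epochs$step[1]
  sel <- sweeps$time_s >= on + window_ms[1] / 1000 &
    sweeps$time_s <= on + window_ms[2] / 1000
  pk <- apply(sweeps$current[sel, , drop = FALSE], 2, function(tr) {
    switch(polarity,
           auto = tr[which.max(abs(tr))],
           positive = max(tr),
           negative = min(tr))
  })
  data.frame(voltage_mV = sweeps$voltage_mV, peak = pk)
}

# Multi-start nonlinear least squares; returns best converged fit or NULL.
best_nls <- function(formula, data, starts, lower = NULL, upper = NULL) {
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  best
}

#' Fit a Boltzmann activation curve
#'
#' Nonlinear least-squares fit of the full current-voltage Boltzmann form
#' \deqn{I(V) = (V - V_{rev}) G_{max} / (1 + e^{(V - V_{1/2})/k})}
#' (`mode = "full_iv"`), or of the scaled logistic
#' \eqn{y(V) = G_{max} / (1 + e^{(V - V_{1/2})/k})} for tail-current or
#' conductance-voltage data (`mode = "normalized_g"`).  Initialization is
#' multi-start over slope factors `k` in {+-3, +-7, +-15} mV with the
#' midpoint seeded at the half-amplitude voltage.  In this parameterization
#' activation that grows with depolarization corresponds to `k < 0`; the
#' returned object carries `abs_k` and a direction flag so the sign is never
#' ambiguous.
#'
#' @param data Data frame with `voltage_mV` and a response column (`current`,
#'   `tail_peak`, `peak`, `G` or the second column).
#' @param mode `"full_iv"` or `"normalized_g"` (see above).
#' @param V_rev Fix the reversal potential at this value (mV); `NULL` fits it.
#' @return Object of class `boltzmann_fit`: `G_max`, `V_rev`, `V_half`, `k`,
#'   `abs_k`, `direction`, `rss`, `mode`, `fitted`.
#' @export
fit_activation <- function(data, mode = c("full_iv", "normalized_g"),
                           V_rev = NULL) {
  mode <- match.arg(mode)
  ycol <- intersect(c("current", "tail_peak", "peak", "G"), names(data))
  y <- if (length(ycol)) data[[ycol[1]]] else data[[2]]
  v <- data$voltage_mV
  if (length(v) < 5) stop("need at least 5 voltage points")
  ord <- order(v); v <- v[ord]; y <- y[ord]
  d <- data.frame(v = v, y = y)

  amp <- max(abs(y))
  if (amp == 0) amp <- 1
  # half-amplitude voltage as midpoint seed
  vh0 <- v[which.min(abs(abs(y) - amp / 2))]
  ks <- c(-15, -7, -3, 3, 7, 15)

  if (mode == "normalized_g") {
    gm0 <- y[which.max(abs(y))]
    starts <- lapply(ks, function(k) list(G = gm0, Vh = vh0, k = k))
    fit <- best_nls(y ~ G / (1 + exp((v - Vh) / k)), d, starts)
    if (is.null(fit)) stop("Boltzmann fit failed to converge (multi-start)")
    p <- stats::coef(fit)
    out <- list(G_max = unname(p["G"]), V_rev = V_rev %||% NA_real_,
                V_half = unname(p["Vh"]), k = unname(p["k"]))
  } else {
    vr0 <- V_rev %||% c(-90, -40, 0)
    starts <- list()
    for (k in ks) for (vr in vr0) {
      gm0 <- amp / max(abs(v - vr))
      starts[[length(starts) + 1L]] <-
        if (is.null(V_rev)) list(G = gm0, Vr = vr, Vh = vh0, k = k)
        else list(G = gm0, Vh = vh0, k = k)
    }
    fit <- if (is.null(V_rev)) {
      best_nls(y ~ (v - Vr) * G / (1 + exp((v - Vh) / k)), d, starts)
    } else {
      best_nls(stats::as.formula(
        sprintf("y ~ (v - (%.10g)) * G / (1 + exp((v - Vh) / k))", V_rev)),
        d, starts)
    }
    if (is.null(fit)) stop("Boltzmann fit failed to converge (multi-start)")
    p <- stats::coef(fit)
    out <- list(G_max = unname(p["G"]),
                V_rev = if (is.null(V_rev)) unname(p["Vr"]) else V_rev,
                V_half = unname(p["Vh"]), k = unname(p["k"]))
  }
  out$abs_k <- abs(out$k)
  out$direction <- if (out$k < 0) "increases with depolarization"
                   else "decreases with depolarization"
  out$rss <- sum(stats::residuals(fit)^2)
  out$mode <- mode
  out$fitted <- stats::fitted(fit)[order(ord)]
  structure(out, class = "boltzmann_fit")
}

#' Fit a Boltzmann availability (inactivation) curve
#'
#' Least-squares fit of the availability equation in its printed form
#' \deqn{I(V) = (I_{min} - I_{max}) + I_{max} / (1 + e^{(V - V_{max})/k})}
#' to test-pulse current vs conditioning voltage.  Note that as printed the
#' curve tends to \eqn{I_{min}} far below \eqn{V_{max}}; data recorded with
#' the conventional orientation can simply be fitted as-is since the signs
#' of \eqn{I_{max}} and `k` absorb the direction.
#'
#' @param data Data frame with `voltage_mV` (conditioning) and a response
#'   column (`current`, `tail_peak`, `peak` or the second column).
#' @return Object of class `inactivation_fit`: `I_min`, `I_max`, `V_max`,
#'   `k`, `rss`, `fitted`.
#' @export
fit_inactivation <- function(data) {
  ycol <- intersect(c("current", "tail_peak", "peak"), names(data))
  y <- if (length(ycol)) data[[ycol[1]]] else data[[2]]
  v <- data$voltage_mV
  if (length(v) < 5) stop("need at least 5 voltage points")
  ord <- order(v); v <- v[ord]; y <- y[ord]
  d <- data.frame(v = v, y = y)
  i_lo <- y[1]; i_hi <- y[length(y)]
  vh0 <- v[which.min(abs(y - (i_lo + i_hi) / 2))]
  starts <- list()
  for (k in c(-15, -7, -3, 3, 7, 15)) {
    starts[[length(starts) + 1L]] <-
      list(Imin = i_lo, Imax = i_lo - i_hi, Vmax = vh0, k = k)
    starts[[length(starts) + 1L]] <-
      list(Imin = i_hi, Imax = i_hi - i_lo, Vmax = vh0, k = k)
  }
  fit <- best_nls(y ~ (Imin - Imax) + Imax / (1 + exp((v - Vmax) / k)),
                  d, starts)
  if (is.null(fit)) stop("availability fit failed to converge (multi-start)")
  p <- stats::coef(fit)
  structure(list(I_min = unname(p["Imin"]), I_max = unname(p["Imax"]),
                 V_max = unname(p["Vmax"]), k = unname(p["k"]),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit)[order(ord)]),
            class = "inactivation_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> (", x$mode, ")\n", sep = "")
  cat(sprintf("  G_max = %.4g, V_rev = %.4g mV, V_half = %.4g mV, |k| = %.4g mV (%s)\n",
              x$G_max, x$V_rev, x$V_half, x$abs_k, x$direction))
  invisible(x)
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("<inactivation_fit> I_min = %.4g, I_max = %.4g, V_max = %.4g mV, k = %.4g mV\n",
              x$I_min, x$I_max, x$V_max, x$k))
  invisible(x)
}

#' Conductance-voltage curve from I-V points
#'
#' Chord conductance `G(V) = I / (V - V_rev)`; points at the reversal
#' potential are excluded with a warning.  `G_max` is estimated by fitting
#' the logistic Boltzmann to the G-V points.
#'
#' @param iv Data frame with `voltage_mV` and `current`.
#' @param V_rev Reversal potential in mV.
#' @param normalize Divide by the fitted `G_max`.
#' @return Data frame with `voltage_mV`, `G`; fitted `G_max` in
#'   `attr(, "G_max")`.
#' @export
conductance_curve <- function(iv, V_rev, normalize = FALSE) {
  keep <- iv$voltage_mV != V_rev
  if (!all(keep)) warning("excluding point(s) at V == V_rev")
  g <- data.frame(voltage_mV = iv$voltage_mV[keep],
                  G = iv$current[keep] / (iv$voltage_mV[keep] - V_rev))
  G_max <- g$G[which.max(abs(g$G))]
  if (nrow(g) >= 5) {
    fitted_G <- tryCatch(fit_activation(g, mode = "normalized_g")$G_max,
                         error = function(e) NA_real_)
    # keep the Boltzmann plateau only when it is identifiable in-range
    # (ohmic / non-saturating data otherwise inflate it without bound)
    if (is.finite(fitted_G) && abs(fitted_G) <= 1.5 * max(abs(g$G))) {
      G_max <- fitted_G
    }
  }
  if (normalize) g$G <- g$G / G_max
  attr(g, "G_max") <- G_max
  g
}

#' Late-current integral
#'
#' Trapezoidal integral of the baseline-corrected current between `t0_ms`
#' and `t1_ms` from the beginning of the pulse (defaults 50-800 ms, the
#' standard late sodium current window).  The baseline is the mean current
#' over the final 10 ms of the pre-pulse holding segment (`"pre_pulse"`),
#' zero (`"zero"`), or a user value.
#'
#' @param sweeps A `sweep_set` (first sweep is used unless `sweep` says
#'   otherwise), or a list/data frame with `time_s` and `current` where time
#'   zero is the pulse onset.
#' @param t0_ms,t1_ms Integration window, ms from pulse onset.
#' @param baseline `"pre_pulse"`, `"zero"`, or a numeric baseline current.
#' @param sweep Column index when `sweeps` holds several traces.
#' @return Charge in pA*ms (single number).
#' @export
late_current_integral <- function(sweeps, t0_ms = 50, t1_ms = 800,
                                  baseline = "pre_pulse", sweep = 1L) {
  if (inherits(sweeps, "sweep_set")) {
    onset <- sweeps$epochs$step[1]
    t_ms <- (sweeps$time_s - onset) * 1000
    cur <- sweeps$current[, sweep]
    base <- if (identical(baseline, "pre_pulse")) {
      pre <- t_ms < 0 & t_ms >= -10
      if (!any(pre)) 0 else mean(cur[pre])
    } else if (identical(baseline, "zero")) 0 else as.numeric(baseline)
  } else {
    t_ms <- sweeps$time_s * 1000
    cur <- sweeps$current
    base <- if (is.numeric(baseline)) as.numeric(baseline) else 0
  }
  tol <- 1e-6
  if (min(t_ms) > t0_ms + tol || max(t_ms) < t1_ms - tol) {
    stop("trace does not cover the integration window")
  }
  sel <- t_ms >= t0_ms - tol & t_ms <= t1_ms + tol
  pracma::trapz(t_ms[sel], cur[sel] - base)
}
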