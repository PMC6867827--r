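#' Voltage-clamp protocol descriptions
#'
#' Constructors for the three protocol families used by the simulator and the
#' sweep analysis: a delayed-rectifier activation protocol (depolarizing
#' steps followed by a tail at -40 mV), a sodium-channel availability
#' protocol (conditioning pulses followed by a fixed test pulse), and a
#' single-pulse late-current protocol.
#'
#' @param voltages_mV Step (or conditioning) voltages in mV.
#' @param step_s,tail_s,pre_s Durations in seconds of the step, tail, and
#'   pre-step holding segment.
#' @param tail_mV Tail / test-pulse voltage in mV.
#' @param holding_mV Holding potential in mV.
#' @param dt_s Sample interval in seconds.
#' @return A list of class `vc_protocol`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_activation <- function(voltages_mV = seq(-50, 30, by = 10),
                                step_s = 3, tail_s = 1.5, tail_mV = -40,
                                holding_mV = -50, pre_s = 0.05, dt_s = 0.001) {
  structure(list(type = "activation", voltages_mV = voltages_mV,
                 step_s = step_s, tail_s = tail_s, tail_mV = tail_mV,
                 holding_mV = holding_mV, pre_s = pre_s, dt_s = dt_s),
            class = "vc_protocol")
}

#' @rdname protocols
#' @export
protocol_inactivation <- function(voltages_mV = seq(-140, 20, by = 10),
                                  step_s = 0.5, tail_s = 0.05, tail_mV = -20,
                                  holding_mV = -120, pre_s = 0.02,
                                  dt_s = 0.0002) {
  structure(list(type = "inactivation", voltages_mV = voltages_mV,
                 step_s = step_s, tail_s = tail_s, tail_mV = tail_mV,
                 holding_mV = holding_mV, pre_s = pre_s, dt_s = dt_s),
            class = "vc_protocol")
}

#' @rdname protocols
#' @export
protocol_late <- function(voltages_mV = -30, step_s = 0.8,
                          holding_mV = -120, pre_s = 0.05, dt_s = 0.001) {
  structure(list(type = "late", voltages_mV = voltages_mV, step_s = step_s,
                 tail_s = 0, tail_mV = holding_mV, holding_mV = holding_mV,
                 pre_s = pre_s, dt_s = dt_s),
            class = "vc_protocol")
}

# Boltzmann steady-state current, the full I-V form:
# I(V) = (V - V_rev) * G_max / (1 + exp((V - V_half)/k))
boltzmann_iv <- function(V, G_max, V_rev, V_half, k) {
  (V - V_rev) * G_max / (1 + exp((V - V_half) / k))
}

# Open probability (logistic gate) of the same parameterization.
boltzmann_popen <- function(V, V_half, k) 1 / (1 + exp((V - V_half) / k))

# Availability curve exactly as the inactivation equation prints:
# I(V) = (I_min - I_max) + I_max / (1 + exp((V - V_max)/k))
boltzmann_avail <- function(V, I_min, I_max, V_max, k) {
  (I_min - I_max) + I_max / (1 + exp((V - V_max) / k))
}

#' Simulate voltage-clamp current sweeps
#'
#' Generates whole-cell current families from a Boltzmann gating model with
#' first-order activation/deactivation kinetics, optionally plus white noise.
#' For `activation` protocols the steady-state current at each step voltage
#' follows the full Boltzmann I-V form, approached mono-exponentially with
#' `tau_act_s`; tail currents deactivate exponentially at the tail potential
#' from the open fraction reached at the end of the step.  For
#' `inactivation` protocols the test-pulse current equals the printed
#' availability equation evaluated at the conditioning voltage.  For `late`
#' protocols the pulse current is a plateau plus an optional decaying
#' exponential component (a persistent "late" current riding on a decaying
#' one).
#'
#' @param protocol A [protocol_activation()], [protocol_inactivation()] or
#'   [protocol_late()] object.
#' @param model Named list of model parameters.  Activation:
#'   `G_max_nS`, `V_rev_mV`, `V_half_mV`, `k_mV`, `tau_act_s`, `tau_deact_s`.
#'   Inactivation: `I_min_pA`, `I_max_pA`, `V_max_mV`, `k_mV`.  Late:
#'   `plateau_pA`, `exp_amp_pA`, `exp_tau_s`.
#' @param noise_sd Gaussian current noise SD (pA) added per sample.
#' @param seed Integer seed for the noise.
#'
#' @return A `sweep_set`: list with `time_s`, `current` (matrix, time x
#'   sweep, pA), `voltage_mV` (per sweep), `epochs` (`pre`, `step`, `tail`
#'   time windows in s), `dt_s`, `protocol` and the generating `model`.
#' @export
simulate_sweeps <- function(protocol, model, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(protocol, "vc_protocol"))
  if (!all(is.finite(protocol$voltages_mV))) stop("protocol voltages must be finite")
  dt <- protocol$dt_s
  t_pre <- protocol$pre_s; t_step <- protocol$step_s; t_tail <- protocol$tail_s
  total <- t_pre + t_step + t_tail
  time_s <- seq(0, total, by = dt)
  in_pre <- time_s < t_pre
  in_step <- time_s >= t_pre & time_s < t_pre + t_step
  in_tail <- time_s >= t_pre + t_step
  V <- protocol$voltages_mV
  cur <- matrix(0, nrow = length(time_s), ncol = length(V))

  for (j in seq_along(V)) {
    v <- V[j]
    tr <- numeric(length(time_s))
    if (protocol$type == "activation") {
      tau_a <- model$tau_act_s %||% 0.15
      tau_d <- model$tau_deact_s %||% 0.4
      iss <- boltzmann_iv(v, model$G_max_nS, model$V_rev_mV,
                          model$V_half_mV, model$k_mV)
      ts <- time_s[in_step] - t_pre
      tr[in_step] <- iss * (1 - exp(-ts / tau_a))
      p_end <- boltzmann_popen(v, model$V_half_mV, model$k_mV) *
        (1 - exp(-t_step / tau_a))
      i_tail0 <- model$G_max_nS * p_end * (protocol$tail_mV - model$V_rev_mV)
      tt <- time_s[in_tail] - (t_pre + t_step)
      tr[in_tail] <- i_tail0 * exp(-tt / tau_d)
    } else if (protocol$type == "inactivation") {
      avail <- boltzmann_avail(v, model$I_min_pA, model$I_max_pA,
                               model$V_max_mV, model$k_mV)
      tr[in_step] <- 0
      tr[in_tail] <- avail
    } else if (protocol$type == "late") {
      ts <- time_s[in_step] - t_pre
      tr[in_step] <- (model$plateau_pA %||% 0) +
        (model$exp_amp_pA %||% 0) * exp(-ts / (model$exp_tau_s %||% 0.1))
    } else {
      stop("unknown protocol type: ", protocol$type)
    }
    cur[, j] <- tr
  }

  if (noise_sd > 0) {
    cur <- withr::with_seed(as.integer(seed), {
      cur + matrix(stats::rnorm(length(cur), 0, noise_sd),
                   nrow = nrow(cur))
    })
  }

  structure(list(
    time_s = time_s, current = cur, voltage_mV = V,
    epochs = list(pre = c(0, t_pre),
                  step = c(t_pre, t_pre + t_step),
                  tail = if (t_tail > 0) c(t_pre + t_step, total) else NULL),
    dt_s = dt, protocol = protocol, model = model
  ), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", ncol(x$current), " sweeps x ", nrow(x$current),
      " samples (dt ", x$dt_s * 1000, " ms), protocol: ",
      x$protocol$type, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
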