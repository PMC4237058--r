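# Tsodyks-Markram synapse dynamics: state evolution, effective weight,
# steady state, and fixed-point calibration of the scale constant A.

#' STP parameter set
#'
#' Bundle the three Tsodyks-Markram parameters of one synapse class together
#' with the optional scale constant `A`. `U` is the baseline release
#' probability, `tau_D` the depression (resource recovery) time constant and
#' `tau_F` the facilitation decay time constant, both in seconds. `A` scales
#' the effective weight `mu = A * x * u1`; it stays `NA` until calibrated
#' (see [calibrate_A()]), and every computation treats `NA` as `A = 1` so
#' that the analytic characterization is scale-free.
#'
#' @param U release probability, in (0, 1).
#' @param tau_D depression time constant in seconds, > 0.
#' @param tau_F facilitation time constant in seconds, > 0.
#' @param A optional positive scale constant; `NA` means uncalibrated.
#' @return An object of class `stp_params`.
#' @examples
#' p <- stp_params(U = 0.1, tau_D = 0.12, tau_F = 0.15)
#' r_crit(p$U, p$tau_D, p$tau_F)
#' @export
stp_params <- function(U, tau_D, tau_F, A = NA_real_) {
  stopifnot(is.numeric(U), length(U) == 1L, is.finite(U), U > 0, U < 1,
            is.numeric(tau_D), length(tau_D) == 1L, is.finite(tau_D), tau_D > 0,
            is.numeric(tau_F), length(tau_F) == 1L, is.finite(tau_F), tau_F > 0)
  if (!is.na(A)) stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0)
  structure(list(U = U, tau_D = tau_D, tau_F = tau_F, A = as.numeric(A)),
            class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  cat(sprintf("STP parameters: U = %g, tau_D = %g s, tau_F = %g s, A = %s\n",
              x$U, x$tau_D, x$tau_F,
              if (is.na(x$A)) "uncalibrated" else format(x$A)))
  invisible(x)
}

.stp_A <- function(params) if (is.na(params$A)) 1 else params$A

#' Dynamic state of one synapse
#'
#' Holds the utilization `u`, the availability `x`, the effective release
#' fraction `u1 = u (1 - U) + U` and the time of the last update (ms).
#' Between spikes `u` decays toward 0 with `tau_F` and `x` recovers toward 1
#' with `tau_D`; `u1` is the utilization the *next* spike would release.
#'
#' @param params an [stp_params()] object (needed to compute `u1`).
#' @param u,x initial utilization and availability, both in \[0, 1\].
#' @param t_last time of the last update in ms.
#' @return An object of class `stp_state`.
#' @export
stp_state <- function(params, u = 0, x = 1, t_last = 0) {
  stopifnot(inherits(params, "stp_params"),
            u >= 0, u <= 1, x >= 0, x <= 1, is.finite(t_last))
  structure(list(u = u, x = x, u1 = u * (1 - params$U) + params$U,
                 t_last = t_last),
            class = "stp_state")
}

#' Steady state of the Tsodyks-Markram synapse at a constant rate
#'
#' Closed-form fixed point of the rate-driven STP equations under a constant
#' presynaptic rate `r`:
#' `u* = tau_F U r / (1 + tau_F U r)`, `u1* = u*(1 - U) + U`,
#' `x* = 1 / (1 + tau_D u1* r)` and `mu* = A x* u1*`.
#'
#' @param params an [stp_params()] object; an unset `A` is taken as 1.
#' @param r presynaptic firing rate(s) in Hz, >= 0; vectorized.
#' @return A data frame with columns `r`, `u_star`, `x_star`, `u1_star`,
#'   `mu_star` (one row per rate).
#' @examples
#' stp_steady_state(stp_params(0.1, 0.12, 0.15), r = c(0, 10, 20))
#' @export
stp_steady_state <- function(params, r) {
  stopifnot(inherits(params, "stp_params"), is.numeric(r), length(r) >= 1L)
  if (any(!is.finite(r)) || any(r < 0))
    stop("`r` must be finite and non-negative")
  U <- params$U
  u_star <- params$tau_F * U * r / (1 + params$tau_F * U * r)
  u1_star <- u_star * (1 - U) + U
  x_star <- 1 / (1 + params$tau_D * u1_star * r)
  data.frame(r = r, u_star = u_star, x_star = x_star, u1_star = u1_star,
             mu_star = .stp_A(params) * x_star * u1_star)
}

#' Calibrate the STP scale constant against a static weight
#'
#' Fixed-point calibration: choose `A = W / (x*(r_star) u1*(r_star))` so the
#' effective weight of the dynamic synapse equals the static weight `W`
#' exactly when the presynaptic neuron fires steadily at `r_star`. A network
#' whose static weights produce a mean rate `r_star` then keeps that rate as
#' a fixed point when the synapses are made dynamic.
#'
#' @param W static weight in (0, 1).
#' @param params an [stp_params()] object (its `A`, if any, is ignored).
#' @param r_star calibration rate in Hz, >= 0.
#' @return The scale constant `A` (a positive number).
#' @examples
#' p <- stp_params(0.1, 0.12, 0.15)
#' A <- calibrate_A(0.04, p, r_star = 12)
#' p$A <- A
#' stp_steady_state(p, 12)$mu_star  # == 0.04
#' @export
calibrate_A <- function(W, params, r_star) {
  stopifnot(is.numeric(W), length(W) == 1L, is.finite(W), W > 0, W < 1,
            inherits(params, "stp_params"),
            is.numeric(r_star), length(r_star) == 1L,
            is.finite(r_star), r_star >= 0)
  base <- stp_params(params$U, params$tau_D, params$tau_F)  # force A = 1
  ss <- stp_steady_state(base, r_star)
  A <- W / (ss$x_star * ss$u1_star)
  if (!is.finite(A) || A <= 0) stop("calibration produced a non-finite A")
  A
}

#' One explicit Euler step of the rate-driven STP equations
#'
#' Integrates `du/dt = -u/tau_F + U (1 - u) r` and
#' `dx/dt = (1 - x)/tau_D - u1 x r` forward by `dt` milliseconds with a
#' smooth (non-spiking) presynaptic rate `r`. The scheme is first order;
#' `u` and `x` are clamped to \[0, 1\] to guard discretization overshoot,
#' and `u1` is recomputed from the updated `u`.
#'
#' @param state an [stp_state()] object.
#' @param params an [stp_params()] object.
#' @param r presynaptic rate in Hz, >= 0.
#' @param dt step size in ms, > 0.
#' @return The advanced `stp_state`.
#' @export
stp_ode_step <- function(state, params, r, dt) {
  stopifnot(inherits(state, "stp_state"), inherits(params, "stp_params"),
            is.numeric(r), length(r) == 1L, is.finite(r), r >= 0,
            is.numeric(dt), length(dt) == 1L, is.finite(dt))
  if (dt <= 0) stop("`dt` must be positive")
  dt_s <- dt / 1000
  U <- params$U
  u <- state$u; x <- state$x
  u1 <- u * (1 - U) + U
  u_new <- u + dt_s * (-u / params$tau_F + U * (1 - u) * r)
  x_new <- x + dt_s * ((1 - x) / params$tau_D - u1 * x * r)
  u_new <- min(max(u_new, 0), 1)
  x_new <- min(max(x_new, 0), 1)
  structure(list(u = u_new, x = x_new, u1 = u_new * (1 - U) + U,
                 t_last = state$t_last + dt),
            class = "stp_state")
}

#' Event-driven STP update at a presynaptic spike
#'
#' Advances the synapse to the spike time (exponential decay of `u` toward 0
#' with `tau_F` and relaxation of `x` toward 1 with `tau_D`), then applies
#' the spike: the released utilization is `u1 = u (1 - U) + U` (the
#' facilitation jump itself, so the first spike from rest releases exactly
#' `U`), the effective weight is `mu = A x u1` evaluated before depletion,
#' the resource is depleted to `x (1 - u1)` and the utilization jumps to
#' `u1`.
#'
#' @param state an [stp_state()] object.
#' @param params an [stp_params()] object; an unset `A` is taken as 1.
#' @param t_spike spike time in ms, `>= state$t_last`.
#' @return A list with elements `state` (the post-spike `stp_state`) and
#'   `mu` (the effective weight of this spike).
#' @examples
#' p <- stp_params(0.1, 0.12, 0.15)
#' stp_event_update(stp_state(p), p, t_spike = 0)$mu  # == 0.1
#' @export
stp_event_update <- function(state, params, t_spike) {
  stopifnot(inherits(state, "stp_state"), inherits(params, "stp_params"),
            is.numeric(t_spike), length(t_spike) == 1L, is.finite(t_spike))
  dt_ms <- t_spike - state$t_last
  if (dt_ms < 0) stop("`t_spike` precedes the state's last update")
  U <- params$U
  u <- state$u * exp(-dt_ms / (1000 * params$tau_F))
  x <- 1 - (1 - state$x) * exp(-dt_ms / (1000 * params$tau_D))
  u1 <- u * (1 - U) + U
  mu <- .stp_A(params) * x * u1
  list(state = structure(list(u = u1, x = x * (1 - u1), u1 = u1,
                              t_last = t_spike),
                         class = "stp_state"),
       mu = mu)
}

#' Run an event-driven synapse over a spike train
#'
#' Convenience wrapper iterating [stp_event_update()] over a sorted train of
#' presynaptic spike times.
#'
#' @param params an [stp_params()] object.
#' @param spike_times sorted spike times in ms.
#' @param state optional starting [stp_state()] (default: rest, `u = 0`,
#'   `x = 1`, `t_last` at the first spike minus nothing).
#' @return A data frame with one row per spike: `t` (ms), `u`, `x` (post-
#'   spike values), `u1` and `mu`.
#' @export
stp_run_train <- function(params, spike_times, state = NULL) {
  stopifnot(inherits(params, "stp_params"), is.numeric(spike_times))
  if (is.unsorted(spike_times)) stop("`spike_times` must be sorted")
  if (is.null(state)) state <- stp_state(params, t_last = spike_times[1])
  n <- length(spike_times)
  u <- x <- u1 <- mu <- numeric(n)
  for (i in seq_len(n)) {
    upd <- stp_event_update(state, params, spike_times[i])
    state <- upd$state
    u[i] <- state$u; x[i] <- state$x; u1[i] <- state$u1; mu[i] <- upd$mu
  }
  data.frame(t = spike_times, u = u, x = x, u1 = u1, mu = mu)
}

#' Steady synaptic efficacy across a staircase of presynaptic rates
#'
#' Drives one event-driven synapse with regular spike trains at each rate in
#' turn (the state carries over between steps, emulating a staircase
#' stimulation protocol) and reports the steady effective weight reached at
#' each rate, taken as the mean `mu` over the last fraction of each step.
#' A synapse with critical rate `r_crit` shows `mu` increasing across rates
#' below `r_crit` and decreasing across rates above it.
#'
#' @param params an [stp_params()] object.
#' @param rates vector of presynaptic rates in Hz, > 0.
#' @param step_duration duration of each rate step in ms.
#' @param tail_frac fraction of each step's spikes averaged for the steady
#'   value.
#' @return A data frame with columns `rate` and `mu_steady`.
#' @examples
#' dual_regime_trace(stp_params(0.1, 0.12, 0.15), rates = seq(1, 11, 2))
#' @export
dual_regime_trace <- function(params, rates, step_duration = 2000,
                              tail_frac = 0.5) {
  stopifnot(inherits(params, "stp_params"), is.numeric(rates), all(rates > 0),
            step_duration > 0, tail_frac > 0, tail_frac <= 1)
  state <- stp_state(params)
  t0 <- 0
  mu_steady <- numeric(length(rates))
  for (k in seq_along(rates)) {
    period <- 1000 / rates[k]
    times <- seq(t0 + period, t0 + step_duration, by = period)
    mus <- numeric(length(times))
    for (i in seq_along(times)) {
      upd <- stp_event_update(state, params, times[i])
      state <- upd$state
      mus[i] <- upd$mu
    }
    if (length(mus) == 0L)
      stop("step too short to contain a spike at rate ", rates[k])
    keep <- min(ceiling(length(mus) * (1 - tail_frac)), length(mus) - 1L)
    mu_steady[k] <- mean(mus[seq.int(keep + 1L, length(mus))])
    t0 <- t0 + step_duration
  }
  data.frame(rate = rates, mu_steady = mu_steady)
}
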