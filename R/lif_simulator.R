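# Conductance-based LIF network simulation: neuron parameters, the sparse
# 80/20 RAIN topology, Poisson spike sources and the clock-driven simulator
# (compiled core in src/lif_sim.cpp).

#' LIF neuron and synapse parameters
#'
#' Defaults are the standard operating point used throughout the package:
#' membrane capacitance 200 pF, leak conductance 10 nS (membrane time
#' constant 20 ms), reversal potentials 0 / -80 mV, threshold -54 mV, reset
#' -60 mV, rest -74 mV, conductance decay constants 5 ms (excitatory) and
#' 15 ms (inhibitory), maximum synaptic conductances 100 nS and a 2 ms
#' refractory period.
#'
#' @param C_m membrane capacitance (pF).
#' @param g_leak leak conductance (nS).
#' @param E_exc,E_inh excitatory/inhibitory reversal potentials (mV).
#' @param V_thresh,V_reset,V_rest threshold, reset and resting potentials (mV).
#' @param tau_exc,tau_inh conductance decay constants (ms).
#' @param g_max_exc,g_max_inh maximum synaptic conductances (nS).
#' @param t_ref refractory period (ms).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 200, g_leak = 10, E_exc = 0, E_inh = -80,
                          V_thresh = -54, V_reset = -60, V_rest = -74,
                          tau_exc = 5, tau_inh = 15,
                          g_max_exc = 100, g_max_inh = 100, t_ref = 2) {
  stopifnot(C_m > 0, g_leak > 0, tau_exc > 0, tau_inh > 0,
            g_max_exc > 0, g_max_inh > 0, t_ref >= 0,
            V_reset < V_thresh)
  structure(list(C_m = C_m, g_leak = g_leak, E_exc = E_exc, E_inh = E_inh,
                 V_thresh = V_thresh, V_reset = V_reset, V_rest = V_rest,
                 tau_exc = tau_exc, tau_inh = tau_inh,
                 g_max_exc = g_max_exc, g_max_inh = g_max_inh, t_ref = t_ref),
            class = "neuron_params")
}

#' Build a sparse 80/20 random network
#'
#' Erdos-Renyi directed topology: every ordered pair of distinct neurons is
#' connected independently with probability `p_connect` (no autapses, at
#' most one synapse per ordered pair). Neurons `1..n_exc` are excitatory,
#' the rest inhibitory. Every synapse leaving an excitatory neuron carries
#' the static weight `W_exc`, every synapse leaving an inhibitory neuron
#' `W_inh`; connection types are labelled EE, EI, IE, II with the
#' presynaptic population first (EI = excitatory source onto inhibitory
#' target).
#'
#' @param n_exc,n_inh population sizes, > 0.
#' @param p_connect connection probability in (0, 1).
#' @param W_exc,W_inh static weights in (0, 1).
#' @param seed optional integer seed; the topology is deterministic given it.
#' @return An object of class `rain_topology`: a list with `n_exc`, `n_inh`,
#'   and `edges`, a data frame with columns `pre`, `post`, `w`, `type`.
#' @examples
#' top <- build_rain_topology(80, 20, 0.05, 0.04, 0.12, seed = 1)
#' nrow(top$edges)
#' @export
build_rain_topology <- function(n_exc, n_inh, p_connect, W_exc, W_inh,
                                seed = NULL) {
  stopifnot(is.numeric(n_exc), n_exc >= 1, is.numeric(n_inh), n_inh >= 1,
            p_connect > 0, p_connect < 1,
            W_exc > 0, W_exc < 1, W_inh > 0, W_inh < 1)
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  n <- n_exc + n_inh
  if (!is.null(seed)) set.seed(seed)
  k <- rbinom(n, n - 1L, p_connect)  # out-degree per presynaptic neuron
  posts <- vector("list", n)
  for (j in seq_len(n)) {
    if (k[j] == 0L) { posts[[j]] <- integer(0); next }
    tgt <- sample.int(n - 1L, k[j])
    tgt[tgt >= j] <- tgt[tgt >= j] + 1L  # skip the self index
    posts[[j]] <- tgt
  }
  pre <- rep.int(seq_len(n), lengths(posts))
  post <- unlist(posts, use.names = FALSE)
  pre_exc <- pre <= n_exc
  post_exc <- post <= n_exc
  type <- ifelse(pre_exc, ifelse(post_exc, "EE", "EI"),
                          ifelse(post_exc, "IE", "II"))
  edges <- data.frame(pre = pre, post = post,
                      w = ifelse(pre_exc, W_exc, W_inh),
                      type = type)
  structure(list(n_exc = n_exc, n_inh = n_inh, p_connect = p_connect,
                 W_exc = W_exc, W_inh = W_inh, seed = seed, edges = edges),
            class = "rain_topology")
}

#' @export
print.rain_topology <- function(x, ...) {
  cat(sprintf("RAIN topology: %d exc + %d inh neurons, p = %g, %d synapses\n",
              x$n_exc, x$n_inh, x$p_connect, nrow(x$edges)))
  invisible(x)
}

#' Topology with no synapses
#'
#' A degenerate network of unconnected neurons, mainly useful for
#' single-neuron experiments driven by `I_ext` or external stimulus.
#'
#' @param n_exc,n_inh population sizes (either may be 0, not both).
#' @return A `rain_topology` with an empty edge list.
#' @export
empty_topology <- function(n_exc = 1, n_inh = 0) {
  stopifnot(n_exc >= 0, n_inh >= 0, n_exc + n_inh >= 1)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 p_connect = 0, W_exc = NA_real_, W_inh = NA_real_,
                 seed = NULL,
                 edges = data.frame(pre = integer(0), post = integer(0),
                                    w = numeric(0), type = character(0))),
            class = "rain_topology")
}

#' Replace the static weights of a topology
#'
#' Keeps the adjacency fixed and rewrites the per-edge weights from the
#' presynaptic population; used by the static-weight sweep so that every
#' grid point is evaluated on the same graph.
#'
#' @param topology a [build_rain_topology()] object.
#' @param W_exc,W_inh new static weights in (0, 1).
#' @return The modified topology.
#' @export
set_weights <- function(topology, W_exc, W_inh) {
  stopifnot(inherits(topology, "rain_topology"),
            W_exc > 0, W_exc < 1, W_inh > 0, W_inh < 1)
  pre_exc <- topology$edges$pre <= topology$n_exc
  topology$edges$w <- ifelse(pre_exc, W_exc, W_inh)
  topology$W_exc <- W_exc
  topology$W_inh <- W_inh
  topology
}

#' Spike raster container
#'
#' A set of `(neuron, time)` spike events over a run of known duration,
#' stored sorted by time.
#'
#' @param neuron integer neuron ids (1-based).
#' @param time spike times in ms.
#' @param n_neurons number of neurons the raster covers.
#' @param duration run duration in ms.
#' @param dt integration step of the producing run (ms), if any.
#' @return An object of class `spike_raster`: a data frame with columns
#'   `neuron` and `time` and attributes `n_neurons`, `duration`, `dt`.
#' @export
spike_raster <- function(neuron, time, n_neurons, duration, dt = NA_real_) {
  stopifnot(length(neuron) == length(time), n_neurons >= 1, duration >= 0)
  o <- order(time, neuron)
  structure(data.frame(neuron = as.integer(neuron)[o], time = time[o]),
            n_neurons = as.integer(n_neurons), duration = duration, dt = dt,
            class = c("spike_raster", "data.frame"))
}

#' Independent Poisson spike trains
#'
#' @param rate rate per source in Hz, >= 0.
#' @param duration train duration in ms.
#' @param n_sources number of independent sources.
#' @param seed optional integer seed.
#' @return A [spike_raster()] with `n_sources` neurons.
#' @export
poisson_spikes <- function(rate, duration, n_sources, seed = NULL) {
  stopifnot(rate >= 0, duration >= 0, n_sources >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(n_sources, rate * duration / 1000)
  neuron <- rep.int(seq_len(n_sources), counts)
  time <- runif(sum(counts), 0, duration)
  spike_raster(neuron, time, n_sources, duration)
}

#' Simulate a conductance-based LIF network
#'
#' Clock-driven integration at resolution `dt`: synaptic conductances decay
#' exponentially and are incremented by `g_max * W / tau` (static synapses)
#' or `g_max * mu / tau` (dynamic synapses, with `mu` from the event-driven
#' Tsodyks-Markram update of that edge and `tau` the receptor's decay
#' constant in ms) one step after each presynaptic spike; the membrane
#' follows the current-balance equation under forward
#' Euler; a threshold crossing emits a spike, clamps the membrane at the
#' reset potential for the refractory period, and the conductances keep
#' integrating throughout.
#'
#' When `stp` is given (see [stp_config()]), every synapse of a connection
#' type shares that type's `(U, tau_D, tau_F)` and a scale constant `A`
#' calibrated per edge against the edge's static weight at the
#' configuration's `r_star`, so the dynamic network reduces to the static
#' one when the whole population fires at `r_star`.
#'
#' @param topology a [build_rain_topology()] object.
#' @param params a [neuron_params()] object.
#' @param stp an [stp_config()] or `NULL` for static synapses.
#' @param stimulus `NULL`, or a list with elements `time` (ms), `target`
#'   (neuron ids) and `weight` (dimensionless, scalar or per event):
#'   external spikes delivered through the excitatory conductance as
#'   increments of `g_max_exc * weight`.
#' @param duration run duration in ms.
#' @param dt integration step in ms, default 0.1.
#' @param seed optional integer seed (used only for the initial voltages
#'   under `init_v = "uniform"`).
#' @param init_v `"uniform"` (default): initial membrane potentials drawn
#'   uniformly in `[V_reset, V_thresh)`; `"rest"`: all at `V_rest`.
#' @param I_ext constant external current in pA, scalar or per neuron.
#' @param record_v neuron ids whose membrane trace to record (every step).
#' @param delay synaptic transmission delay in ms; rounded to a whole
#'   number of steps, minimum one step. Default: one step (`dt`).
#' @param early_stop `NULL`, or a list with any of `dead_window` (ms; stop
#'   once a trailing window contains no spike network-wide -- with no
#'   external input the network is then silent forever), `rate_limit` (Hz)
#'   and `rate_window` (ms; stop when the windowed network mean rate
#'   exceeds the limit), and `check_after` (ms, default: end of stimulus).
#' @return A [spike_raster()] with extra attributes `v_trace` (matrix, one
#'   column per recorded neuron), `stopped_early`, `stop_reason`,
#'   `sim_duration`.
#' @export
simulate_network <- function(topology, params = neuron_params(), stp = NULL,
                             stimulus = NULL, duration, dt = 0.1, seed = NULL,
                             init_v = c("uniform", "rest"), I_ext = 0,
                             record_v = integer(0), early_stop = NULL,
                             delay = dt) {
  stopifnot(inherits(topology, "rain_topology"),
            inherits(params, "neuron_params"),
            is.numeric(duration), duration > 0, is.numeric(dt), dt > 0)
  init_v <- match.arg(init_v)
  n <- topology$n_exc + topology$n_inh

  # CSR by presynaptic neuron
  e <- topology$edges
  o <- order(e$pre)
  e <- e[o, , drop = FALSE]
  ptr <- c(0L, cumsum(tabulate(e$pre, nbins = n)))

  if (!is.null(seed)) set.seed(seed)
  V0 <- if (init_v == "uniform")
    runif(n, params$V_reset, params$V_thresh) else rep(params$V_rest, n)

  I_ext <- rep_len(as.numeric(I_ext), n)

  if (is.null(stimulus)) {
    stim_step <- integer(0); stim_target <- integer(0); stim_jump <- numeric(0)
    stim_end <- 0
  } else {
    stopifnot(is.list(stimulus), all(c("time", "target") %in% names(stimulus)))
    w <- rep_len(if (is.null(stimulus$weight)) 0.5 else stimulus$weight,
                 length(stimulus$time))
    so <- order(stimulus$time)
    stim_step <- as.integer(floor(stimulus$time[so] / dt))
    stim_step[stim_step >= duration / dt] <- as.integer(duration / dt) - 1L
    stim_target <- as.integer(stimulus$target[so]) - 1L
    stim_jump <- params$g_max_exc / params$tau_exc * w[so]
    stim_end <- if (length(stimulus$time)) max(stimulus$time) else 0
  }

  use_stp <- !is.null(stp)
  if (use_stp) {
    stopifnot(inherits(stp, "stp_config"))
    pe <- calibrate_stp_edges(stp, e)
    stp_U <- pe$U; stp_tauF <- pe$tauF_ms; stp_tauD <- pe$tauD_ms; stp_A <- pe$A
  } else {
    stp_U <- stp_tauF <- stp_tauD <- stp_A <- numeric(0)
  }

  es <- list(dead_window = NA_real_, rate_limit = Inf, rate_window = 100,
             check_after = stim_end + 50)
  if (!is.null(early_stop)) es <- modifyList(es, early_stop)

  res <- .lif_sim_cpp(n, topology$n_exc, ptr, e$post - 1L, e$w,
                      unclass(params), V0, I_ext,
                      stim_step, stim_target, stim_jump,
                      duration, dt, use_stp,
                      stp_U, stp_tauF, stp_tauD, stp_A,
                      as.integer(record_v) - 1L,
                      !is.na(es$dead_window),
                      ifelse(is.na(es$dead_window), 0, es$dead_window),
                      es$rate_limit, es$rate_window, es$check_after,
                      max(1L, as.integer(round(delay / dt))))

  out <- spike_raster(res$neuron, res$time, n, duration, dt)
  attr(out, "v_trace") <- res$v_trace
  attr(out, "stopped_early") <- res$stopped_early
  attr(out, "stop_reason") <- res$stop_reason
  attr(out, "sim_duration") <- res$sim_duration
  out
}

#' STP configuration for a network
#'
#' One Tsodyks-Markram parameter triple per connection type, plus the
#' calibration rate `r_star` at which each type's scale constant `A` is
#' fixed against that type's static weight (see [calibrate_A()]).
#'
#' @param ee,ei,ie,ii [stp_params()] objects for the four connection types
#'   (presynaptic population first).
#' @param r_star calibration rate in Hz, default 12.
#' @return An object of class `stp_config`.
#' @export
stp_config <- function(ee, ei, ie, ii, r_star = 12) {
  for (p in list(ee, ei, ie, ii)) stopifnot(inherits(p, "stp_params"))
  stopifnot(is.numeric(r_star), r_star >= 0)
  structure(list(ee = ee, ei = ei, ie = ie, ii = ii, r_star = r_star),
            class = "stp_config")
}

# Per-edge STP arrays with A calibrated at r_star against the edge weight.
# Time constants are converted to ms for the simulator core.
calibrate_stp_edges <- function(stp, edges) {
  types <- c("EE", "EI", "IE", "II")
  key <- match(edges$type, types)
  par <- list(stp$ee, stp$ei, stp$ie, stp$ii)
  U <- vapply(par, `[[`, numeric(1), "U")
  tauD <- vapply(par, `[[`, numeric(1), "tau_D")
  tauF <- vapply(par, `[[`, numeric(1), "tau_F")
  # denominator x* u1* at r_star, per type
  denom <- vapply(par, function(p) {
    ss <- stp_steady_state(stp_params(p$U, p$tau_D, p$tau_F), stp$r_star)
    ss$x_star * ss$u1_star
  }, numeric(1))
  list(U = U[key], tauD_ms = 1000 * tauD[key], tauF_ms = 1000 * tauF[key],
       A = edges$w / denom[key])
}
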