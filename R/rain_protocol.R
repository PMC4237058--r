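# The jump-start RAIN trial protocol: brief Poisson bombardment, free run,
# terminal-window activity metrics and the success criterion; plus the
# static-weight sweep.

#' RAIN trial protocol configuration
#'
#' The jump-start protocol: `n_stim` randomly chosen neurons (from both
#' populations) receive independent Poisson spike trains at `stim_rate` for
#' `stim_duration` ms, all external input is then removed and the network
#' runs freely until `run_duration`. The mean firing rate is measured over
#' the final `rate_window` ms; the inter-spike-interval coefficient of
#' variation over the final `cv_window` ms (wider, so that neurons firing
#' near the target rate contribute at least two intervals). A trial
#' succeeds when the terminal rate lies in `[r_min, r_max]` and, if
#' `cv_min` is set, the mean ISI CV exceeds it.
#'
#' @param n_stim number of stimulated neurons.
#' @param stim_duration stimulus duration in ms.
#' @param stim_rate Poisson rate per stimulated neuron in Hz.
#' @param stim_weight dimensionless injection weight (conductance increment
#'   `g_max_exc * stim_weight` per stimulus spike).
#' @param run_duration total run length in ms.
#' @param rate_window terminal window for the rate, ms.
#' @param cv_window terminal window for the ISI CV, ms.
#' @param r_min,r_max success band in Hz.
#' @param cv_min minimum mean ISI CV for success, or `NULL` to judge on
#'   rate alone.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_stim = 200, stim_duration = 50, stim_rate = 200,
                            stim_weight = 0.5, run_duration = 2000,
                            rate_window = 100, cv_window = 500,
                            r_min = 10, r_max = 20, cv_min = NULL) {
  stopifnot(n_stim >= 1, stim_duration >= 0, stim_rate >= 0, stim_weight > 0,
            run_duration > 0, rate_window > 0, rate_window <= run_duration,
            cv_window > 0, cv_window <= run_duration, r_min < r_max)
  if (!is.null(cv_min)) stopifnot(is.numeric(cv_min), length(cv_min) == 1L)
  structure(list(n_stim = as.integer(n_stim), stim_duration = stim_duration,
                 stim_rate = stim_rate, stim_weight = stim_weight,
                 run_duration = run_duration, rate_window = rate_window,
                 cv_window = cv_window, r_min = r_min, r_max = r_max,
                 cv_min = cv_min),
            class = "protocol_config")
}

#' Mean network firing rate over a time window
#'
#' Per-neuron spike count in the window divided by the window length,
#' averaged over all neurons of the raster (silent neurons included).
#'
#' @param raster a [spike_raster()].
#' @param window `c(t0, t1)` in ms, `t0 < t1`.
#' @return Mean rate in Hz.
#' @export
mean_firing_rate <- function(raster, window) {
  stopifnot(inherits(raster, "spike_raster"),
            is.numeric(window), length(window) == 2L)
  if (window[1] >= window[2]) stop("empty window: t0 must be < t1")
  n <- attr(raster, "n_neurons")
  in_win <- raster$time > window[1] & raster$time <= window[2]
  sum(in_win) / n / ((window[2] - window[1]) / 1000)
}

#' Mean inter-spike-interval coefficient of variation
#'
#' For each neuron, the CV (sd/mean) of the inter-spike intervals whose
#' both spikes fall in the window; averaged over neurons contributing at
#' least two intervals. Returns `NA` when no neuron qualifies -- that is a
#' value (undefined irregularity), not an error.
#'
#' @inheritParams mean_firing_rate
#' @return Mean CV (dimensionless), or `NA_real_`.
#' @export
isi_cv <- function(raster, window) {
  stopifnot(inherits(raster, "spike_raster"),
            is.numeric(window), length(window) == 2L)
  if (window[1] >= window[2]) stop("empty window: t0 must be < t1")
  keep <- raster$time > window[1] & raster$time <= window[2]
  if (!any(keep)) return(NA_real_)
  sub <- raster[keep, , drop = FALSE]
  sub <- sub[order(sub$neuron, sub$time), , drop = FALSE]
  cvs <- vapply(split(sub$time, sub$neuron), function(ts) {
    if (length(ts) < 3L) return(NA_real_)  # need >= 2 ISIs
    isi <- diff(ts)
    sd(isi) / mean(isi)
  }, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0L) NA_real_ else mean(cvs)
}

#' Run one jump-start RAIN trial
#'
#' Stimulates `n_stim` neurons sampled uniformly from the whole network
#' with Poisson trains for the stimulus period, lets the network run freely
#' to `run_duration`, and scores the terminal activity: mean rate over the
#' final `rate_window`, mean ISI CV over the final `cv_window`, success
#' per the protocol's band (and `cv_min` when set).
#'
#' @param topology a [build_rain_topology()] object.
#' @param params a [neuron_params()] object.
#' @param stp an [stp_config()] or `NULL` for static synapses.
#' @param protocol a [protocol_config()].
#' @param seed optional integer master seed; stimulated-neuron choice,
#'   stimulus trains and initial voltages are derived from it through named
#'   streams, so a trial is fully reproducible.
#' @param early_stop passed to [simulate_network()]; `TRUE` enables the
#'   dead-network stop with defaults, a list gives full control, `NULL`
#'   (default) disables early termination.
#' @param keep_raster keep the spike raster in the outcome (default TRUE).
#' @return An object of class `sim_outcome`: list with `mean_rate` (Hz),
#'   `mean_isi_cv`, `success`, `stopped_early`, `stop_reason`, `seed` and
#'   (optionally) `raster`.
#' @export
run_rain_trial <- function(topology, params = neuron_params(), stp = NULL,
                           protocol = protocol_config(), seed = NULL,
                           early_stop = NULL, keep_raster = TRUE) {
  stopifnot(inherits(topology, "rain_topology"),
            inherits(protocol, "protocol_config"))
  n <- topology$n_exc + topology$n_inh
  if (protocol$n_stim > n) stop("more stimulated neurons than neurons")

  if (!is.null(seed)) set.seed(derive_seed(seed, "stim-targets"))
  targets <- sample.int(n, protocol$n_stim)
  stim <- poisson_spikes(protocol$stim_rate, protocol$stim_duration,
                         protocol$n_stim,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, "stim-trains"))
  stimulus <- list(time = stim$time, target = targets[stim$neuron],
                   weight = protocol$stim_weight)

  if (isTRUE(early_stop)) early_stop <- list(dead_window = 100)
  raster <- simulate_network(
    topology, params, stp = stp, stimulus = stimulus,
    duration = protocol$run_duration, seed = if (is.null(seed)) NULL
                                             else derive_seed(seed, "init-v"),
    init_v = "uniform", early_stop = early_stop)

  stopped <- isTRUE(attr(raster, "stopped_early"))
  reason <- attr(raster, "stop_reason")
  if (stopped && identical(reason, "saturated")) {
    # terminal window never reached; the trial cannot be a success
    rate <- NA_real_; cv <- NA_real_; success <- FALSE
  } else {
    t1 <- protocol$run_duration
    rate <- mean_firing_rate(raster, c(t1 - protocol$rate_window, t1))
    cv <- isi_cv(raster, c(t1 - protocol$cv_window, t1))
    success <- rate >= protocol$r_min && rate <= protocol$r_max &&
      (is.null(protocol$cv_min) || (!is.na(cv) && cv > protocol$cv_min))
  }
  out <- list(mean_rate = rate, mean_isi_cv = cv, success = success,
              stopped_early = stopped, stop_reason = reason, seed = seed)
  if (keep_raster) out$raster <- raster
  structure(out, class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("RAIN trial: mean rate %s Hz, ISI CV %s, %s%s\n",
              format(x$mean_rate, digits = 4),
              format(x$mean_isi_cv, digits = 3),
              if (isTRUE(x$success)) "SUCCESS" else "failure",
              if (isTRUE(x$stopped_early))
                paste0(" (stopped early: ", x$stop_reason, ")") else ""))
  invisible(x)
}

#' Static-weight parameter sweep
#'
#' Runs one jump-start trial per `(W_exc, W_inh)` grid point on a shared
#' topology (adjacency fixed, weights rewritten per point) and tabulates
#' the terminal metrics. The canonical fine grid spans
#' `(0, 0.1) x (0, 1)` with steps 0.001 and 0.01 (about 10,000 points);
#' the default here is much coarser.
#'
#' @param W_exc,W_inh vectors of weights to cross.
#' @param topology a [build_rain_topology()] object whose weights are
#'   overwritten point by point.
#' @param params a [neuron_params()] object.
#' @param protocol a [protocol_config()]; the sweep judges success on rate
#'   and irregularity, so `cv_min = 1` is the conventional choice.
#' @param seed optional integer; each grid point derives its own trial seed.
#' @param early_stop passed to [run_rain_trial()].
#' @return A data frame with columns `w_exc`, `w_inh`, `rate_hz`, `isi_cv`,
#'   `success`.
#' @export
static_weight_sweep <- function(W_exc = seq(0.02, 0.06, by = 0.01),
                                W_inh = seq(0.04, 0.20, by = 0.04),
                                topology, params = neuron_params(),
                                protocol = protocol_config(cv_min = 1),
                                seed = NULL, early_stop = TRUE) {
  stopifnot(is.numeric(W_exc), is.numeric(W_inh),
            inherits(topology, "rain_topology"))
  grid <- expand.grid(w_exc = W_exc, w_inh = W_inh, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    top <- set_weights(topology, grid$w_exc[i], grid$w_inh[i])
    tr <- run_rain_trial(top, params, stp = NULL, protocol = protocol,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, paste0("sweep-", i)),
                         early_stop = early_stop, keep_raster = FALSE)
    data.frame(w_exc = grid$w_exc[i], w_inh = grid$w_inh[i],
               rate_hz = tr$mean_rate, isi_cv = tr$mean_isi_cv,
               success = tr$success)
  })
  do.call(rbind, res)
}
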