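# Characterization-guided STP parameter search over WXYZ network
# signatures, with the unrestricted RAND baseline.

#' Enumerate all WXYZ network signatures
#'
#' A network signature assigns one rhythm class to each connection type, in
#' the order EE, EI, IE, II; with six classes there are `6^4 = 1296`
#' signatures. The enumeration is lexicographic in the class order
#' `N < D < T < A < B < G` with the leftmost (EE) letter most significant,
#' so it starts `NNNN, NNND, NNNT, ...`.
#'
#' @return A character vector of length 1296.
#' @export
enumerate_signatures <- function() {
  keys <- rhythm_classes()$key
  g <- expand.grid(ii = keys, ie = keys, ei = keys, ee = keys,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$ee, g$ei, g$ie, g$ii)
}

#' Draw calibrated STP parameters for one network signature
#'
#' For each connection type, rejection-samples a `(U, tau_D, tau_F)` triple
#' from the rhythm class named by the signature letter (or uniformly on
#' `(0, 1)^3` for `"RAND"`), redrawing until the slow-moving filter
#' [small_dmu_ok()] passes, then calibrates the scale constant `A` against
#' that type's static weight at `r_star`.
#'
#' @param signature four class letters, e.g. `"GGGT"` (EE, EI, IE, II), or
#'   `"RAND"` for the unrestricted baseline.
#' @param r_star calibration and filter-evaluation rate in Hz, default 12.
#' @param dmu_threshold slow-moving filter bound, default 0.01; `NULL`
#'   disables the filter.
#' @param W_exc,W_inh static weights the excitatory- and inhibitory-source
#'   synapses are calibrated against.
#' @param seed optional integer seed.
#' @return An [stp_config()] whose four parameter sets carry calibrated `A`.
#' @examples
#' cfg <- draw_network_stp("GGGT", seed = 1)
#' classify_rhythm(r_crit(cfg$ee$U, cfg$ee$tau_D, cfg$ee$tau_F))  # "G"
#' @export
draw_network_stp <- function(signature, r_star = 12, dmu_threshold = 0.01,
                             W_exc = 0.04, W_inh = 0.12, seed = NULL) {
  stopifnot(is.character(signature), length(signature) == 1L)
  keys <- if (identical(signature, "RAND")) rep("RAND", 4)
          else strsplit(signature, "")[[1]]
  if (length(keys) != 4L || !all(keys %in% c(rhythm_classes()$key, "RAND")))
    stop("`signature` must be four class letters (N/D/T/A/B/G) or \"RAND\"")
  if (!is.null(seed)) set.seed(seed)
  W <- c(EE = W_exc, EI = W_exc, IE = W_inh, II = W_inh)
  draw_one <- function(key, w) {
    repeat {
      s <- sample_udf_class(key, 1L)
      if (is.null(dmu_threshold) ||
          small_dmu_ok(s$U, s$tau_D, s$tau_F, r_eval = r_star,
                       threshold = dmu_threshold)) {
        p <- stp_params(s$U, s$tau_D, s$tau_F)
        p$A <- calibrate_A(w, p, r_star)
        return(p)
      }
    }
  }
  stp_config(ee = draw_one(keys[1], W[["EE"]]),
             ei = draw_one(keys[2], W[["EI"]]),
             ie = draw_one(keys[3], W[["IE"]]),
             ii = draw_one(keys[4], W[["II"]]),
             r_star = r_star)
}

#' Search configuration
#'
#' @param signatures character vector of signatures to test (may include
#'   `"RAND"`); default: all 1296 plus the baseline.
#' @param trials trials per signature, >= 1.
#' @param r_star calibration rate in Hz.
#' @param dmu_threshold slow-moving filter bound (`NULL` disables).
#' @param r_min,r_max success band in Hz (search convention: 1 and 50, rate
#'   only -- no CV requirement).
#' @param n_exc,n_inh,p_connect,W_exc,W_inh base network specification.
#' @param run_duration trial length in ms.
#' @param seed master seed; every topology, draw and trial derives from it.
#' @param early_stop early-termination spec for the trials (default: dead-
#'   network stop plus a 250 Hz saturation guard); `NULL` disables.
#' @param fresh_topology build a new topology for every trial instead of
#'   reusing one per search (default FALSE, isolating STP effects).
#' @return An object of class `search_config`.
#' @export
search_config <- function(signatures = c("RAND", enumerate_signatures()),
                          trials = 100, r_star = 12, dmu_threshold = 0.01,
                          r_min = 1, r_max = 50,
                          n_exc = 8000, n_inh = 2000, p_connect = 0.015,
                          W_exc = 0.04, W_inh = 0.12, run_duration = 2000,
                          seed = 1,
                          early_stop = list(dead_window = 100,
                                            rate_limit = 250,
                                            rate_window = 100),
                          fresh_topology = FALSE) {
  stopifnot(is.character(signatures), length(signatures) >= 1L,
            trials >= 1, r_min < r_max)
  structure(list(signatures = signatures, trials = as.integer(trials),
                 r_star = r_star, dmu_threshold = dmu_threshold,
                 r_min = r_min, r_max = r_max,
                 n_exc = n_exc, n_inh = n_inh, p_connect = p_connect,
                 W_exc = W_exc, W_inh = W_inh, run_duration = run_duration,
                 seed = seed, early_stop = early_stop,
                 fresh_topology = fresh_topology),
            class = "search_config")
}

#' Run the characterization-guided STP parameter search
#'
#' For every signature in the configuration and every trial: draw fresh
#' STP parameters for the four connection types from the signature's
#' classes (with the slow-moving filter and fixed-point calibration), run
#' one jump-start RAIN trial with dynamic synapses on the base network, and
#' record whether the terminal rate fell inside the success band. Trials
#' that error are logged and counted as failures. The whole result is a
#' deterministic function of the configuration, including its seed.
#'
#' @param config a [search_config()].
#' @param verbose print per-signature progress.
#' @return A data frame with columns `signature`, `successes`, `trials`,
#'   `percent`, carrying the configuration as attribute `config`.
#' @export
run_search <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "search_config"))
  protocol <- protocol_config(run_duration = config$run_duration,
                              rate_window = min(100, config$run_duration),
                              cv_window = min(500, config$run_duration),
                              r_min = config$r_min, r_max = config$r_max,
                              cv_min = NULL)
  topo <- build_rain_topology(config$n_exc, config$n_inh, config$p_connect,
                              config$W_exc, config$W_inh,
                              seed = derive_seed(config$seed, "topology"))
  rows <- lapply(config$signatures, function(sig) {
    succ <- 0L
    for (tr in seq_len(config$trials)) {
      tag <- paste0(sig, "-", tr)
      if (config$fresh_topology)
        topo <- build_rain_topology(config$n_exc, config$n_inh,
                                    config$p_connect, config$W_exc,
                                    config$W_inh,
                                    seed = derive_seed(config$seed,
                                                       paste0("topo-", tag)))
      ok <- tryCatch({
        stp <- draw_network_stp(sig, r_star = config$r_star,
                                dmu_threshold = config$dmu_threshold,
                                W_exc = config$W_exc, W_inh = config$W_inh,
                                seed = derive_seed(config$seed,
                                                   paste0("draw-", tag)))
        out <- run_rain_trial(topo, stp = stp, protocol = protocol,
                              seed = derive_seed(config$seed,
                                                 paste0("trial-", tag)),
                              early_stop = config$early_stop,
                              keep_raster = FALSE)
        isTRUE(out$success)
      }, error = function(e) {
        warning("trial ", tag, " failed: ", conditionMessage(e))
        FALSE
      })
      if (ok) succ <- succ + 1L
    }
    if (verbose)
      message(sprintf("%s: %d/%d successes", sig, succ, config$trials))
    data.frame(signature = sig, successes = succ, trials = config$trials,
               percent = 100 * succ / config$trials)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Tabulate search results
#'
#' Sorts signatures by success percentage (descending) and, when a `RAND`
#' baseline row is present with at least one success, adds the fold change
#' `fold_vs_rand = percent / percent[RAND]` (1 for the baseline itself).
#'
#' @param results the data frame from [run_search()].
#' @return The sorted table, with a `fold_vs_rand` column when applicable.
#' @export
tabulate_search <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("signature", "successes", "trials", "percent")
                %in% names(results)))
  out <- results[order(-results$percent, results$signature), , drop = FALSE]
  rand <- out$percent[out$signature == "RAND"]
  if (length(rand) == 1L && rand > 0)
    out$fold_vs_rand <- out$percent / rand
  rownames(out) <- NULL
  out
}
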