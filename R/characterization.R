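# Analytic characterization of the STP parameter space: the rate derivative
# of the steady effective weight, the critical firing rate, brain-rhythm
# classification, P/N volumes, class-restricted sampling and the
# linear-response expressions.

#' Rate derivative of the steady-state effective weight
#'
#' Derivative of the (scale-free, `A = 1`) steady effective weight `mu*(r)`
#' of a Tsodyks-Markram synapse with respect to the presynaptic steady rate:
#' \deqn{d\mu/dr = U (F - D F^2 U r^2 - 2 D F U r - F U - D U) /
#'                 (D F U r^2 + D U r + F U r + 1)^2}
#' with `D = tau_D`, `F = tau_F` in seconds and `r` in Hz. Its sign decides
#' whether the synapse is facilitating (positive) or depressing (negative)
#' at that rate; the sign change is at [r_crit()].
#'
#' @param U release probability in (0, 1); vectorized.
#' @param tau_D,tau_F depression and facilitation time constants in seconds.
#' @param r presynaptic rate(s) in Hz, >= 0.
#' @return The derivative in units of 1/Hz (per unit `A`).
#' @examples
#' dmu_dr(0.1, 0.12, 0.15, r = 10)   # > 0: facilitating at 10 Hz
#' dmu_dr(0.1, 0.12, 0.15, r = 30)   # < 0: depressing at 30 Hz
#' @export
dmu_dr <- function(U, tau_D, tau_F, r) {
  .check_udf(U, tau_D, tau_F)
  stopifnot(is.numeric(r), all(is.finite(r)), all(r >= 0))
  D <- tau_D; F_ <- tau_F
  num <- U * (F_ - D * F_^2 * U * r^2 - 2 * D * F_ * U * r - F_ * U - D * U)
  den <- (D * F_ * U * r^2 + D * U * r + F_ * U * r + 1)^2
  num / den
}

.check_udf <- function(U, tau_D, tau_F) {
  stopifnot(is.numeric(U), is.numeric(tau_D), is.numeric(tau_F),
            all(is.finite(U)), all(is.finite(tau_D)), all(is.finite(tau_F)),
            all(U > 0), all(U < 1), all(tau_D > 0), all(tau_F > 0))
  invisible(TRUE)
}

#' Critical firing rate of a Tsodyks-Markram synapse
#'
#' The presynaptic steady rate at which the synapse switches from
#' facilitating to depressing:
#' \deqn{r_{crit} = -1/\tau_F + \sqrt{(1 - U) / (U \tau_D \tau_F)}}
#' (the potentially positive branch of the root of the numerator of
#' [dmu_dr()]). A non-positive value means the synapse is depressing at
#' every positive rate; for a positive value the synapse facilitates below
#' `r_crit` and depresses above it.
#'
#' @inheritParams dmu_dr
#' @return The critical rate in Hz (may be <= 0); vectorized.
#' @examples
#' r_crit(0.1, 0.12, 0.15)  # 15.69 Hz
#' @export
r_crit <- function(U, tau_D, tau_F) {
  .check_udf(U, tau_D, tau_F)
  -1 / tau_F + sqrt((1 - U) / (U * tau_D * tau_F))
}

#' The brain-rhythm partition of critical rates
#'
#' The six half-open classes used to partition the STP parameter space by
#' critical rate: Null (`r_crit <= 0`), delta `(0, 4]`, theta `(4, 8]`,
#' alpha `(8, 12]`, beta `(12, 30]` and gamma `(30, Inf)` Hz.
#'
#' @return A data frame with columns `key` (N, D, T, A, B, G), `rhythm`,
#'   `lo` and `hi` (interval `(lo, hi]` in Hz).
#' @export
rhythm_classes <- function() {
  data.frame(key = c("N", "D", "T", "A", "B", "G"),
             rhythm = c("null", "delta", "theta", "alpha", "beta", "gamma"),
             lo = c(-Inf, 0, 4, 8, 12, 30),
             hi = c(0, 4, 8, 12, 30, Inf))
}

#' Classify a critical rate into its brain-rhythm class
#'
#' @param r_crit_value critical rate(s) in Hz (any finite value).
#' @return A character vector of class keys in `{N, D, T, A, B, G}`.
#' @examples
#' classify_rhythm(c(-3, 4, 15.7))  # "N" "D" "B"
#' @export
classify_rhythm <- function(r_crit_value) {
  stopifnot(is.numeric(r_crit_value), all(is.finite(r_crit_value)))
  cls <- rhythm_classes()
  as.character(cut(r_crit_value, breaks = c(cls$lo[1], cls$hi),
                   labels = cls$key, right = TRUE))
}

#' Facilitating (P) and depressing (N) volumes of the STP parameter space
#'
#' Labels every point of a regular grid over `(0, 1)^3` in
#' `(U, tau_D, tau_F)` (time constants in seconds): `P` if the synapse is
#' facilitating at every steady rate up to `r_hi` (i.e. `r_crit >= r_hi`),
#' `N` if it is depressing at every rate from `r_lo` up
#' (`r_crit <= r_lo`), and `neither` otherwise. The closed-form critical
#' rate makes the scan a direct threshold test instead of a sign scan of
#' the derivative over the whole probe band.
#'
#' @param grid_step grid spacing in each dimension, in (0, 1); the grid is
#'   `grid_step, 2 grid_step, ...` strictly inside (0, 1). Default 0.014
#'   gives 71 points per axis (357,911 combinations).
#' @param r_lo,r_hi probe band in Hz, default 10 and 100.
#' @return A data frame with columns `U`, `tau_D`, `tau_F`, `r_crit` and
#'   `label` (one of `"P"`, `"N"`, `"neither"`).
#' @examples
#' v <- pn_volumes(grid_step = 0.2)
#' table(v$label)
#' @export
pn_volumes <- function(grid_step = 0.014, r_lo = 10, r_hi = 100) {
  stopifnot(is.numeric(grid_step), length(grid_step) == 1L,
            grid_step > 0, grid_step < 1,
            is.numeric(r_lo), is.numeric(r_hi), r_lo > 0, r_lo < r_hi)
  ax <- grid_step * seq_len(floor((1 - 1e-12) / grid_step))
  ax <- ax[ax < 1]
  if (length(ax) == 0L) stop("empty grid: `grid_step` leaves no points in (0, 1)")
  g <- expand.grid(U = ax, tau_D = ax, tau_F = ax,
                   KEEP.OUT.ATTRS = FALSE)
  rc <- r_crit(g$U, g$tau_D, g$tau_F)
  label <- rep("neither", nrow(g))
  label[rc >= r_hi] <- "P"
  label[rc <= r_lo] <- "N"
  data.frame(g, r_crit = rc, label = label)
}

#' Sample STP triples uniformly from one rhythm class
#'
#' Rejection sampling: draw `(U, tau_D, tau_F)` uniformly on `(0, 1)^3`
#' (time constants in seconds) and accept a draw iff its critical rate
#' falls in the requested class. `class_key = "RAND"` accepts every draw
#' (the unrestricted baseline). Sampling aborts with a diagnostic if the
#' acceptance rate over the probe batches falls below `1e-6`, which guards
#' against practically empty classes.
#'
#' @param class_key one of `"N"`, `"D"`, `"T"`, `"A"`, `"B"`, `"G"` or
#'   `"RAND"`.
#' @param n number of accepted triples to return, >= 1.
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with `n` rows and columns `U`, `tau_D`, `tau_F`.
#' @examples
#' s <- sample_udf_class("B", 5, seed = 1)
#' classify_rhythm(r_crit(s$U, s$tau_D, s$tau_F))  # all "B"
#' @export
sample_udf_class <- function(class_key, n, seed = NULL) {
  stopifnot(length(class_key) == 1L,
            class_key %in% c(rhythm_classes()$key, "RAND"),
            is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(numeric(0), ncol = 3)
  tried <- 0L
  batch <- max(1000L, 4L * n)
  while (nrow(out) < n) {
    draws <- matrix(runif(3L * batch), ncol = 3)
    # open-interval contract: exact 0/1 draws (measure zero) are rejected
    ok <- draws[, 1] > 0 & draws[, 1] < 1 &
          draws[, 2] > 0 & draws[, 2] < 1 &
          draws[, 3] > 0 & draws[, 3] < 1
    if (class_key != "RAND") {
      rc <- r_crit(draws[ok, 1], draws[ok, 2], draws[ok, 3])
      keep <- which(ok)[classify_rhythm(rc) == class_key]
    } else keep <- which(ok)
    out <- rbind(out, draws[keep, , drop = FALSE])
    tried <- tried + batch
    if (tried >= 1e6 && nrow(out) / tried < 1e-6)
      stop("acceptance rate below 1e-6 for class ", class_key,
           " after ", tried, " draws; the class is practically empty")
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(U = out[, 1], tau_D = out[, 2], tau_F = out[, 3])
}

#' Slow-moving synapse filter
#'
#' Tests whether the magnitude of the (A-normalized) rate derivative of the
#' steady effective weight at the operating rate is below a threshold:
#' `|dmu/dr(r_eval)| < threshold`. The guided parameter search keeps only
#' such "slow moving" dynamic synapses.
#'
#' @inheritParams dmu_dr
#' @param r_eval evaluation rate in Hz; default 12, the calibration target.
#' @param threshold strict positive bound, default 0.01 per Hz.
#' @return Logical, vectorized over the parameter arguments.
#' @export
small_dmu_ok <- function(U, tau_D, tau_F, r_eval = 12, threshold = 0.01) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  abs(dmu_dr(U, tau_D, tau_F, r_eval)) < threshold
}

#' First-order firing-rate response of a two-population network
#'
#' Evaluates the mean-field linear-response expressions for the change in
#' the excitatory population rate with respect to small perturbations of
#' the excitatory (`dre_dve`) and inhibitory (`dre_dvi`) input currents, in
#' a recurrent excitatory/inhibitory network with dynamic synapses. The
#' derivatives `d_mn` of the mean dynamic weight from population `n` to `m`
#' with respect to the steady rate enter linearly; all other constants are
#' positive.
#'
#' @param c a list with elements `beta_e`, `beta_i` (rate-transfer
#'   derivatives), `W_ee`, `W_ei`, `W_ie`, `W_ii` (mean static weights,
#'   first index postsynaptic), `n_e`, `n_i` (presynaptic counts), `r_e`,
#'   `r_i` (steady rates, Hz), `alpha` (positive constant) and `d_ee`,
#'   `d_ei`, `d_ie`, `d_ii` (rate derivatives of the mean dynamic weights,
#'   any sign).
#' @return A named numeric vector with elements `dre_dve` and `dre_dvi`.
#' @export
linear_response <- function(c) {
  need <- c("beta_e", "beta_i", "W_ee", "W_ei", "W_ie", "W_ii",
            "n_e", "n_i", "r_e", "r_i", "alpha",
            "d_ee", "d_ei", "d_ie", "d_ii")
  missing <- setdiff(need, names(c))
  if (length(missing)) stop("missing constants: ", paste(missing, collapse = ", "))
  for (nm in need) stopifnot(is.numeric(c[[nm]]), is.finite(c[[nm]]))
  if (c$alpha <= 0) stop("`alpha` must be positive")
  with(c, {
    K <- 1 + beta_i * n_i * W_ii
    dre_dve <- beta_e * K / alpha *
      (1 +
       d_ee * beta_e * n_e * r_e * K / alpha -
       d_ie * beta_e * beta_i * n_i * n_e * r_e * W_ei / alpha -
       d_ei * beta_i * beta_e * n_e * n_i * r_i * W_ie / alpha +
       d_ii * beta_i^2 * beta_e * n_i^2 * n_e * r_i * W_ei * W_ie /
         (alpha * K))
    dre_dvi <- -beta_i * beta_e * n_i * W_ei / alpha *
      (1 +
       d_ee * beta_e * n_e * r_e * K / alpha -
       d_ii * beta_i * n_i * r_i * (1 - beta_e * n_e * W_ee) / alpha -
       d_ie * beta_e * beta_i * n_i * n_e * r_e * W_ei / alpha +
       d_ei * r_i * K * (1 - beta_e * n_e * W_ee) / (alpha * W_ei))
    c(dre_dve = dre_dve, dre_dvi = dre_dvi)
  })
}
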