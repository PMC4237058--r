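# Independent oracles used across the suite. These deliberately do not call
# the package's own closed forms or update routines.

# Mean-field steady effective weight (A = 1) written out afresh.
oracle_mu_star <- function(U, D, F_, r) {
  u <- F_ * U * r / (1 + F_ * U * r)
  u1 <- u * (1 - U) + U
  x <- 1 / (1 + D * u1 * r)
  x * u1
}

# Exact fixed point of the event-driven synapse under regular spiking at
# rate r (Hz): closed form of the per-spike map (decay, facilitate via
# u1 = u(1-U)+U, release u1*x, deplete).
oracle_map_mu <- function(U, D, F_, r) {
  eF <- exp(-1 / (r * F_))
  eD <- exp(-1 / (r * D))
  u_post <- U / (1 - (1 - U) * eF)
  x_pre <- (1 - eD) / (1 - (1 - u_post) * eD)
  x_pre * u_post
}

# Brute-force integration of the rate-driven synapse equations with a tiny
# Euler step, independent of stp_ode_step.
oracle_ode_integrate <- function(U, D, F_, r, t_end_s, dt_s = 1e-5) {
  u <- 0; x <- 1
  for (i in seq_len(round(t_end_s / dt_s))) {
    u1 <- u * (1 - U) + U
    du <- -u / F_ + U * (1 - u) * r
    dx <- (1 - x) / D - u1 * x * r
    u <- u + dt_s * du
    x <- x + dt_s * dx
  }
  list(u = u, x = x, u1 = u * (1 - U) + U, mu = x * (u * (1 - U) + U))
}

# Central finite difference of the mean-field steady weight.
oracle_fd_dmu <- function(U, D, F_, r, h = 1e-4) {
  (oracle_mu_star(U, D, F_, r + h) - oracle_mu_star(U, D, F_, r - h)) / (2 * h)
}

# Sign-scan classification of a parameter point over an integer-Hz band:
# "P" if facilitating at every probed rate, "N" if depressing at every one.
# An exact zero at a band edge (measure-zero tie) is tolerated either way,
# matching the inclusive closed-form thresholds.
oracle_sign_scan <- function(U, D, F_, rates = 10:100, eps = 1e-9) {
  d <- vapply(rates, function(r) oracle_fd_dmu(U, D, F_, r), numeric(1))
  pos <- all(d > -eps); neg <- all(d < eps)
  if (pos && !neg) "P" else if (neg && !pos) "N" else "neither"
}

# Closed-form LIF inter-spike interval under constant current (no noise):
# refractory period plus the exponential charge-up time.
oracle_lif_isi <- function(I, params = neuron_params()) {
  v_inf <- params$V_rest + I / params$g_leak
  tau_m <- params$C_m / params$g_leak
  params$t_ref + tau_m * log((v_inf - params$V_reset) / (v_inf - params$V_thresh))
}

# A small shared topology for protocol-level tests (cheap to simulate).
small_topology <- function(seed = 7) {
  build_rain_topology(400, 100, 0.05, 0.04, 0.12, seed = seed)
}
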