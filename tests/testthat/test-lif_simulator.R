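# Topology generation, Poisson sources and the clock-driven LIF core.

test_that("topology edge counts are binomial and types follow the
           populations", {
  top <- build_rain_topology(2000, 500, 0.015, 0.04, 0.12, seed = 3)
  n <- 2500
  mean_edges <- 0.015 * n * (n - 1)
  sd_edges <- sqrt(n * (n - 1) * 0.015 * 0.985)
  expect_lt(abs(nrow(top$edges) - mean_edges), 4 * sd_edges)
  expect_false(any(top$edges$pre == top$edges$post))

  pre_exc <- top$edges$pre <= 2000
  expect_true(all(top$edges$w[pre_exc] == 0.04))
  expect_true(all(top$edges$w[!pre_exc] == 0.12))
  expect_true(all(top$edges$type[pre_exc] %in% c("EE", "EI")))
  expect_true(all(top$edges$type[!pre_exc] %in% c("IE", "II")))
  post_exc <- top$edges$post <= 2000
  expect_equal(top$edges$type,
               ifelse(pre_exc, ifelse(post_exc, "EE", "EI"),
                      ifelse(post_exc, "IE", "II")))

  expect_identical(top$edges,
                   build_rain_topology(2000, 500, 0.015, 0.04, 0.12,
                                       seed = 3)$edges)
  # vanishing connection probability: a valid (near-)empty topology
  tiny <- build_rain_topology(20, 5, 1e-6, 0.04, 0.12, seed = 1)
  expect_true(nrow(tiny$edges) %in% 0:2)
  expect_error(build_rain_topology(0, 100, 0.1, 0.04, 0.12))
})

test_that("Poisson sources have the right counts and exponential intervals", {
  expect_equal(nrow(poisson_spikes(0, 1000, 10, seed = 1)), 0L)

  r <- poisson_spikes(100, 1000, 100, seed = 2)
  expect_lt(abs(nrow(r) - 1e4), 4 * sqrt(1e4))
  isis <- unlist(lapply(split(r$time, r$neuron), function(t) diff(sort(t))))
  ks <- suppressWarnings(stats::ks.test(isis, "pexp", rate = 100 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("an unperturbed neuron stays at rest and sub-rheobase current
           never fires", {
  top <- empty_topology(1, 0)
  r0 <- simulate_network(top, duration = 300, init_v = "rest")
  expect_equal(nrow(r0), 0L)
  v <- attr(simulate_network(top, duration = 100, init_v = "rest",
                             record_v = 1), "v_trace")
  expect_true(all(abs(v + 74) < 1e-9))

  # rheobase = g_leak (V_thresh - V_rest) = 200 pA
  r_sub <- simulate_network(top, duration = 1000, I_ext = 199,
                            init_v = "rest")
  expect_equal(nrow(r_sub), 0L)
  r_supra <- simulate_network(top, duration = 1000, I_ext = 201,
                              init_v = "rest")
  expect_gt(nrow(r_supra), 0L)
})

test_that("constant-current firing matches the closed-form LIF interval", {
  top <- empty_topology(1, 0)
  r <- simulate_network(top, duration = 500, I_ext = 400, init_v = "rest",
                        dt = 0.1)
  isis <- diff(r$time)
  expect_equal(oracle_lif_isi(400), 7.25, tolerance = 1e-3)
  expect_true(all(abs(isis - oracle_lif_isi(400)) <= 2 * 0.1 + 1e-9))
})

test_that("refractoriness, voltage bounds and determinism hold in a driven
           network", {
  top <- small_topology()
  stim <- poisson_spikes(200, 50, 50, seed = 1)
  stimulus <- list(time = stim$time, target = stim$neuron, weight = 0.5)
  r1 <- simulate_network(top, stimulus = stimulus, duration = 400, seed = 5,
                         record_v = c(1, 250))
  r2 <- simulate_network(top, stimulus = stimulus, duration = 400, seed = 5,
                         record_v = c(1, 250))
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  isis <- unlist(lapply(split(r1$time, r1$neuron), diff))
  if (length(isis)) expect_true(all(isis >= 2 - 1e-9))

  v <- attr(r1, "v_trace")
  expect_true(all(v <= 0 + 1e-6) && all(v >= -80 - 1e-6))
})

test_that("a subthreshold voltage trace converges at first order in dt", {
  top <- empty_topology(1, 0)
  trace <- function(dt) {
    r <- simulate_network(top, duration = 100, I_ext = 150, init_v = "rest",
                          dt = dt, record_v = 1)
    v <- attr(r, "v_trace")[, 1]
    v[seq(1, length(v), by = round(0.4 / dt))]  # sample every 0.4 ms
  }
  e1 <- max(abs(trace(0.4) - trace(0.05)))
  e2 <- max(abs(trace(0.2) - trace(0.05)))
  expect_lt(e2 / e1, 0.75)
})

test_that("calibrated dynamic synapses release the static weight at the
           operating rate on average", {
  p <- stp_params(0.05, 0.25, 0.3)
  p$A <- calibrate_A(0.04, p, 12)
  set.seed(13)
  times <- cumsum(rexp(30000, 12 / 1000))
  tr <- stp_run_train(p, times)
  mu_bar <- mean(tr$mu[-(1:3000)])
  expect_lt(abs(mu_bar - 0.04) / 0.04, 0.05)
})

test_that("the compiled dynamic-synapse path matches an R-level replay of
           the same edge", {
  # one excitatory synapse 1 -> 2; neuron 1 fires tonically under constant
  # current; neuron 2 stays subthreshold. The C++ per-edge STP updates and
  # conductance bookkeeping must reproduce an independent R replay built
  # from stp_event_update.
  top <- empty_topology(2, 0)
  top$edges <- data.frame(pre = 1L, post = 2L, w = 0.04, type = "EE")
  p <- stp_params(0.15, 0.2, 0.25)
  stp <- stp_config(ee = p, ei = p, ie = p, ii = p, r_star = 12)
  dt <- 0.1
  ras <- simulate_network(top, stp = stp, duration = 200, dt = dt,
                          I_ext = c(400, 0), init_v = "rest", record_v = 2)
  v_cpp <- attr(ras, "v_trace")[, 1]
  spikes <- ras$time[ras$neuron == 1]
  expect_gt(length(spikes), 10)

  p$A <- calibrate_A(0.04, p, 12)
  mu <- stp_run_train(p, spikes, state = stp_state(p, t_last = 0))$mu
  np <- neuron_params()
  n_steps <- round(200 / dt)
  jump_step <- round(spikes / dt) + 1  # one-step transmission delay
  v <- numeric(n_steps + 1); v[1] <- np$V_rest
  g <- 0; dec <- exp(-dt / np$tau_exc)
  for (m in seq_len(n_steps)) {
    g <- g * dec
    hit <- which(jump_step == m)
    if (length(hit)) g <- g + np$g_max_exc / np$tau_exc * sum(mu[hit])
    vv <- v[m] + (np$g_leak * (np$V_rest - v[m]) + g * (0 - v[m])) *
      (dt / np$C_m)
    v[m + 1] <- vv
  }
  expect_lt(max(abs(v - v_cpp)), 1e-8)
})
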