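# Critical-rate characterization, rhythm classes, volumes, sampling and the
# linear-response expressions.

test_that("the rate derivative matches finite differences of the steady
           weight and vanishes at the critical rate", {
  expect_equal(dmu_dr(0.1, 0.12, 0.15, 10),
               oracle_fd_dmu(0.1, 0.12, 0.15, 10), tolerance = 1e-6)
  expect_equal(dmu_dr(0.1, 0.12, 0.15, 10), 0.00285, tolerance = 2e-3)
  expect_gt(dmu_dr(0.1, 0.12, 0.15, 10), 0)     # facilitating below r_crit
  expect_lt(dmu_dr(0.1, 0.12, 0.15, 1e4), 0)    # depressing as r -> infinity

  rc <- r_crit(0.1, 0.12, 0.15)
  expect_lt(abs(dmu_dr(0.1, 0.12, 0.15, rc)), 1e-12)

  set.seed(41)
  U <- runif(200, 0.02, 0.98); D <- runif(200, 0.02, 0.98)
  F_ <- runif(200, 0.02, 0.98); r <- runif(200, 0, 100)
  fd <- mapply(oracle_fd_dmu, U, D, F_, r)
  expect_equal(dmu_dr(U, D, F_, r), fd, tolerance = 1e-4)
})

test_that("the critical rate is the root and sign change of the derivative", {
  expect_equal(r_crit(0.1, 0.12, 0.15), 15.7, tolerance = 0.005)
  expect_equal(r_crit(0.5, 1, 1), 0, tolerance = 1e-12)

  # independent root by bisection of the derivative's sign on (0, 1000)
  f <- function(r) dmu_dr(0.2, 0.2, 0.5, r)
  lo <- 1e-6; hi <- 1000
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(r_crit(0.2, 0.2, 0.5), lo, tolerance = 1e-9)
  expect_equal(r_crit(0.2, 0.2, 0.5), 4.32, tolerance = 2e-3)

  set.seed(42)
  n <- 1e4
  U <- runif(n, 0.01, 0.99); D <- runif(n, 0.01, 0.99); F_ <- runif(n, 0.01, 0.99)
  rc <- r_crit(U, D, F_)
  pos <- rc > 0.1
  expect_true(all(abs(dmu_dr(U[pos], D[pos], F_[pos], rc[pos])) < 1e-9))
  expect_true(all(dmu_dr(U[pos], D[pos], F_[pos], 0.9 * rc[pos]) > 0))
  expect_true(all(dmu_dr(U[pos], D[pos], F_[pos], 1.1 * rc[pos]) < 0))
})

test_that("rhythm classification follows the half-open band partition", {
  expect_equal(classify_rhythm(15.7), "B")
  expect_equal(classify_rhythm(-3), "N")
  expect_equal(classify_rhythm(c(0, 4, 8, 12, 30)), c("N", "D", "T", "A", "B"))
  expect_equal(classify_rhythm(c(4.0001, 30.0001, 1e6)), c("T", "G", "G"))
  # every finite value maps to exactly one class
  x <- c(-1e6, rnorm(1000, 10, 20), 1e6)
  cls <- classify_rhythm(x)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% rhythm_classes()$key))
})

test_that("P/N volume labels agree with the brute-force sign scan", {
  v1 <- pn_volumes(grid_step = 0.5)
  expect_equal(nrow(v1), 1L)
  expect_equal(v1$U, 0.5)
  expect_equal(v1$label,
               if (r_crit(0.5, 0.5, 0.5) >= 100) "P"
               else if (r_crit(0.5, 0.5, 0.5) <= 10) "N" else "neither")

  v <- pn_volumes(grid_step = 0.095)
  expect_equal(nrow(v), 10^3)
  scan <- mapply(oracle_sign_scan, v$U, v$tau_D, v$tau_F)
  expect_equal(v$label, unname(scan))
  expect_error(pn_volumes(grid_step = 1))
})

test_that("class-restricted sampling honors its class, its seed, and the
           class volume", {
  s <- sample_udf_class("B", 50, seed = 1)
  expect_equal(nrow(s), 50L)
  expect_true(all(classify_rhythm(r_crit(s$U, s$tau_D, s$tau_F)) == "B"))
  expect_identical(s, sample_udf_class("B", 50, seed = 1))

  # acceptance fraction of class G equals its volume fraction (3 SE)
  ax <- seq(0.005, 0.995, by = 0.01)
  g <- expand.grid(U = ax, D = ax, F_ = ax)
  vol_G <- mean(classify_rhythm(r_crit(g$U, g$D, g$F_)) == "G")
  n_draw <- 40000
  set.seed(77)
  d <- matrix(runif(3 * n_draw), ncol = 3)
  acc <- mean(classify_rhythm(r_crit(d[, 1], d[, 2], d[, 3])) == "G")
  se <- sqrt(vol_G * (1 - vol_G) / n_draw)
  expect_lt(abs(acc - vol_G), 3 * se + 0.002)  # grid discretization slack
})

test_that("the slow-moving filter is a strict bound on the derivative", {
  expect_true(small_dmu_ok(0.1, 0.12, 0.15, r_eval = 12, threshold = 0.01))
  rc <- r_crit(0.3, 0.4, 0.5)
  expect_true(small_dmu_ok(0.3, 0.4, 0.5, r_eval = rc, threshold = 1e-12))
  expect_false(small_dmu_ok(0.1, 0.12, 0.15, r_eval = 12, threshold = 0))
})

test_that("linear response reduces to its leading factors and responds to
           the derivative signs as expected", {
  base <- list(beta_e = 0.4, beta_i = 0.3, W_ee = 0.04, W_ei = 0.12,
               W_ie = 0.04, W_ii = 0.12, n_e = 120, n_i = 30,
               r_e = 12, r_i = 12, alpha = 50,
               d_ee = 0, d_ei = 0, d_ie = 0, d_ii = 0)
  lr0 <- linear_response(base)
  K <- 1 + base$beta_i * base$n_i * base$W_ii
  expect_equal(unname(lr0["dre_dve"]), base$beta_e * K / base$alpha)
  expect_equal(unname(lr0["dre_dvi"]),
               -base$beta_i * base$beta_e * base$n_i * base$W_ei / base$alpha)

  stab <- modifyList(base, list(d_ee = -0.005, d_ii = -0.005,
                                d_ei = 0.005, d_ie = 0.005))
  expect_lt(linear_response(stab)["dre_dve"], lr0["dre_dve"])

  # independent transcription of the response expressions
  oracle_lr <- function(c) with(c, {
    K <- 1 + beta_i * n_i * W_ii
    ve <- beta_e * K / alpha *
      (1 + d_ee * beta_e * n_e * r_e * K / alpha
         - d_ie * beta_e * beta_i * n_i * n_e * r_e * W_ei / alpha
         - d_ei * beta_i * beta_e * n_e * n_i * r_i * W_ie / alpha
         + d_ii * beta_i^2 * beta_e * n_i^2 * n_e * r_i * W_ei * W_ie /
             (alpha * K))
    vi <- -beta_i * beta_e * n_i * W_ei / alpha *
      (1 + d_ee * beta_e * n_e * r_e * K / alpha
         - d_ii * beta_i * n_i * r_i * (1 - beta_e * n_e * W_ee) / alpha
         - d_ie * beta_e * beta_i * n_i * n_e * r_e * W_ei / alpha
         + d_ei * r_i * K * (1 - beta_e * n_e * W_ee) / (alpha * W_ei))
    c(ve, vi)
  })
  set.seed(9)
  for (i in 1:20) {
    cs <- list(beta_e = runif(1, 0.1, 1), beta_i = runif(1, 0.1, 1),
               W_ee = runif(1), W_ei = runif(1), W_ie = runif(1),
               W_ii = runif(1), n_e = sample(500, 1), n_i = sample(200, 1),
               r_e = runif(1, 1, 50), r_i = runif(1, 1, 50),
               alpha = runif(1, 1, 100),
               d_ee = rnorm(1, 0, 0.01), d_ei = rnorm(1, 0, 0.01),
               d_ie = rnorm(1, 0, 0.01), d_ii = rnorm(1, 0, 0.01))
    expect_equal(unname(linear_response(cs)), oracle_lr(cs), tolerance = 1e-12)
  }
  expect_error(linear_response(modifyList(base, list(alpha = 0))), "alpha")
  expect_error(linear_response(base[-1]), "missing")
})
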