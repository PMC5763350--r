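expect_theta_close <- function(theta_hat, theta_true, tol = 1e-6) {
  scale <- pmax(abs(theta_true), 1)
  expect_lt(max(abs(theta_hat - theta_true) / scale), tol)
}

test_that("noiseless joint fits recover the truth from the fixed default init", {
  p <- baseline_protocol()
  th <- theta_vector(10, 0, 900, 50, 0)
  y <- jsr_forward(th, p)
  fit <- fit_jsr(y, p)
  expect_true(fit$converged)
  expect_theta_close(fit$theta_hat, th)
  # determinism
  fit2 <- fit_jsr(y, p)
  expect_identical(fit2$theta_hat, fit$theta_hat)
  # and across 50 random brain-grid states with off-resonance and kappa != 1
  set.seed(99)
  for (i in 1:50) {
    st <- random_brain_state(rho = 10 * exp(1i * stats::runif(1, -pi, pi)))
    tht <- theta_from_state(st)
    yy <- jsr_forward(tht, p, kappa = 1.05)
    ft <- fit_jsr(yy, p, kappa = 1.05)
    expect_true(ft$converged)
    expect_theta_close(ft$theta_hat, tht)
  }
})

test_that("degenerate data vectors are flagged, not fatal", {
  p <- baseline_protocol()
  z <- fit_jsr(rep(0, 10), p)
  expect_false(z$converged)
  expect_match(z$failure_reason, "zero")
  z2 <- fit_jsr(c(rep(1, 9), NaN), p)
  expect_false(z2$converged)
  expect_error(fit_jsr(rep(1, 7), p), "length")
  p_small <- protocol(lapply(1:4, function(i)
    sequence_spec("bssfp", 10 * i, 4.2, phi_rf_deg = 90 * i)))
  expect_error(fit_jsr(rep(1, 8), p_small), "at least 5")
})

test_that("DESPOT1 linearisation recovers T1 exactly from two noiseless points", {
  t1 <- 900; tr <- 6.2
  st <- voxel_state(rho = 10, t1 = t1, t2 = 50)
  flips <- c(4, 18)
  mags <- vapply(flips, function(fa)
    10 * Mod(spgr_signal(st, sequence_spec("spgr", fa, tr, te_ms = 2.1))),
    numeric(1))
  d1 <- fit_despot1(mags, flips, tr)
  expect_true(d1$valid)
  expect_equal(d1$t1, t1, tolerance = 1e-10)
  # a common multiplicative factor (e.g. echo-time decay) leaves T1 untouched
  d1b <- fit_despot1(mags * exp(-2.1 / 185), flips, tr)
  expect_equal(d1b$t1, t1, tolerance = 1e-10)
  # non-physical signal patterns give a slope outside (0,1): flagged
  expect_false(fit_despot1(c(1, 5), flips, tr)$valid)          # slope > 1
  expect_false(fit_despot1(sin(flips * pi / 180), flips, tr)$valid)  # slope 0
  # kappa scales the actual flips
  mags_k <- vapply(flips, function(fa) {
    stk <- voxel_state(rho = 10, t1 = t1, t2 = 50, kappa = 1.1)
    10 * Mod(spgr_signal(stk, sequence_spec("spgr", fa, tr, te_ms = 2.1)))
  }, numeric(1))
  expect_equal(fit_despot1(mags_k, flips, tr, kappa = 1.1)$t1, t1,
               tolerance = 1e-10)
})

test_that("DESPOT2-FM recovers T2 and the field map with the true T1, and inherits T1 bias", {
  p <- baseline_protocol()
  th <- theta_vector(10, 0, 900, 50, 20)
  y <- jsr_forward(th, p)
  z <- complex(real = y[seq(3, 9, 2)], imaginary = y[seq(4, 10, 2)])
  fm <- fit_despot2fm(z, t1_fixed = 900, protocol = p)
  expect_true(fm$converged)
  expect_equal(fm$t2, 50, tolerance = 1e-6)
  expect_equal(fm$d_omega, 20, tolerance = 1e-6)
  expect_equal(Mod(fm$rho2), 10, tolerance = 1e-6)
  # an inflated T1 propagates into a biased T2: the two-step weakness
  fm_biased <- fit_despot2fm(z, t1_fixed = 1.2 * 900, protocol = p)
  expect_gt(abs(fm_biased$t2 - 50) / 50, 1e-3)
  # single phase increment: off-resonance unidentifiable
  p1 <- protocol(sequence_spec("spgr", 4, 6.2), sequence_spec("spgr", 18, 6.2),
                 sequence_spec("bssfp", 15, 4.2, phi_rf_deg = 0),
                 sequence_spec("bssfp", 65, 4.2, phi_rf_deg = 0))
  expect_error(fit_despot2fm(z[1:2], 900, p1), "phase increment")
})

test_that("spin-echo reference fits recover mono-exponential constants", {
  tis <- seq(107, 1857, by = 125)
  t1 <- 2058
  s <- abs(8 * (1 - 2 * exp(-tis / t1)))
  ir <- fit_reference_se(s, tis, "inversion_recovery_t1")
  expect_true(ir$converged)
  expect_equal(ir$time_constant, t1, tolerance = 1e-6)
  tes <- seq(15, 480, by = 15)
  t2 <- 185
  dec <- 6 * exp(-tes / t2)
  me <- fit_reference_se(dec, tes, "multiecho_t2")
  expect_equal(me$time_constant, t2, tolerance = 1e-6)
  ev <- fit_reference_se(dec, tes, "even_echoes_only")
  expect_equal(ev$time_constant, t2, tolerance = 1e-6)
  flat <- fit_reference_se(rep(0, 32), tes, "multiecho_t2")
  expect_false(flat$converged)
})

test_that("joint estimates are unbiased at low noise", {
  set.seed(2024)
  p <- baseline_protocol()
  th <- theta_vector(10, 0, 900, 50, 0)
  y0 <- jsr_forward(th, p)
  sigma <- 0.002 * 10
  n <- 600
  est <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    y <- y0 + stats::rnorm(length(y0), sd = sigma)
    ft <- fit_jsr(y, p)
    if (ft$converged) est[i, ] <- ft$theta_hat
  }
  est <- est[stats::complete.cases(est), ]
  expect_gt(nrow(est), 0.99 * n)
  bias <- colMeans(est) - th
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 3.5 * se + 1e-9))
})
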