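test_that("finite RF correction reduces to plain decay and matches its closed form", {
  # no pulse duration: plain exp(-TR/T2)
  z <- finite_rf_correction(t1 = 900, t2 = 50, t_rf = 0, tr = 4.2, beta = 1.3)
  expect_equal(z$e2, exp(-4.2 / 50), tolerance = 1e-14)
  # on-resonance with zero phase increment: cos^2(0) = 1 so zeta_beta = zeta
  z <- finite_rf_correction(900, 50, t_rf = 1.0, tr = 4.2, beta = 0)
  expect_equal(z$zeta_beta, z$zeta, tolerance = 1e-14)
  # direct evaluation of the printed form at T_RF/TR = 0.2
  z <- finite_rf_correction(900, 50, t_rf = 0.2 * 4.2, tr = 4.2, beta = 0.7)
  expect_equal(z$zeta, 0.68 - 0.125 * 1.2 * (50 / 900), tolerance = 1e-14)
  expect_error(finite_rf_correction(900, 50, t_rf = 5, tr = 4.2, beta = 0),
               "t_rf")
})

test_that("SPGR closed form has the right limits and matches Bloch propagation", {
  st <- voxel_state(rho = 1, t1 = 900, t2 = 50)
  # vanishing flip: no signal
  tiny <- sequence_spec("spgr", flip_deg = 1e-6, tr_ms = 6.2, te_ms = 2.1)
  expect_lt(Mod(spgr_signal(st, tiny)), 1e-7)
  # full recovery at TR = 10 T1, 90 degrees, TE ~ 0
  full <- sequence_spec("spgr", 90, tr_ms = 9000, te_ms = 1e-9)
  expect_equal(Mod(spgr_signal(st, full)), 1, tolerance = 5e-5)
  # Bloch steady-state oracle at a typical white-matter point
  sq <- sequence_spec("spgr", 18, tr_ms = 6.2, te_ms = 2.1)
  expect_equal(spgr_signal(st, sq), oracle_spgr(st, sq), tolerance = 1e-9)
  # T2' factor engages only when finite
  st2 <- voxel_state(rho = 1, t1 = 900, t2 = 50, t2prime = 285)
  expect_equal(Mod(spgr_signal(st2, sq)),
               Mod(spgr_signal(st, sq)) * exp(-2.1 / 285), tolerance = 1e-12)
})

test_that("bSSFP closed form collapses correctly at beta = pi and matches Bloch propagation", {
  st <- voxel_state(rho = 1, t1 = 900, t2 = 50, d_omega = 0)
  sq <- sequence_spec("bssfp", 65, tr_ms = 4.2, te_ms = 2.1, phi_rf_deg = 180)
  s <- bssfp_signal(st, sq)
  e1 <- exp(-4.2 / 900); e2 <- finite_rf_correction(900, 50, 0, 4.2, pi)$e2
  expect_equal(Re(s), 0, tolerance = 1e-15)
  expect_equal(Mod(s),
               (1 - e1) * sin(65 * pi / 180) * exp(-2.1 / 50) /
                 (1 - e1 * cos(65 * pi / 180) - e2 * (e1 - cos(65 * pi / 180))),
               tolerance = 1e-12)
  st30 <- voxel_state(rho = 1, t1 = 900, t2 = 50, d_omega = 30)
  sq0 <- sequence_spec("bssfp", 65, tr_ms = 4.2, te_ms = 2.1, phi_rf_deg = 0)
  expect_equal(bssfp_signal(st30, sq0), oracle_bssfp(st30, sq0), tolerance = 1e-9)
})

test_that("both signal models track the Bloch oracle over random states", {
  set.seed(41)
  for (i in 1:25) {
    st <- random_brain_state(rho = 1, kappa = stats::runif(1, 0.85, 1.15))
    sp <- random_sequence("spgr")
    bs <- random_sequence("bssfp")
    expect_equal(spgr_signal(st, sp), oracle_spgr(st, sp), tolerance = 1e-9)
    s <- bssfp_signal(st, bs)
    expect_lt(Mod(s - oracle_bssfp(st, bs)) / Mod(s), 1e-9)
  }
})

test_that("|bSSFP| is periodic in off-resonance with period 1/TR", {
  set.seed(7)
  for (i in 1:10) {
    bs <- random_sequence("bssfp")
    st <- random_brain_state(rho = 1)
    st2 <- st; st2$d_omega <- st$d_omega + 1000 / bs$tr
    expect_lt(abs(Mod(bssfp_signal(st, bs)) - Mod(bssfp_signal(st2, bs))), 1e-12)
  }
})

test_that("SPGR magnitude peaks at the Ernst angle", {
  st <- voxel_state(rho = 1, t1 = 900, t2 = 50)
  tr <- 6.2
  flips <- seq(0.01, 90, by = 0.01)
  p <- protocol(lapply(flips, function(fa)
    sequence_spec("spgr", fa, tr_ms = tr, te_ms = 2.1)))
  mags <- jsr_forward_grid(matrix(theta_from_state(st), nrow = 1), p)
  a_star <- flips[which.max(mags)]
  ernst <- acos(exp(-tr / 900)) * 180 / pi
  expect_lt(abs(a_star - ernst), 0.011)
})

test_that("the concatenated forward model has the stated layout and symmetries", {
  p <- baseline_protocol()
  expect_equal(n_spgr(p), 2)
  expect_equal(n_bssfp(p), 4)
  expect_equal(total_tr(p), 29.2, tolerance = 1e-12)
  th <- theta_vector(10, 0, 900, 50, 0)
  y <- jsr_forward(th, p)
  expect_length(y, 10)
  expect_true(all(y[1:2] >= 0))  # SPGR channels are magnitudes
  # zero proton density: all channels vanish
  expect_equal(jsr_forward(theta_vector(0, 0, 900, 50, 0), p), rep(0, 10))
  # homogeneity of degree 1 in |rho|
  expect_equal(jsr_forward(theta_vector(30, 0, 900, 50, 0), p), 3 * y,
               tolerance = 1e-12)
  set.seed(13)
  for (c in stats::runif(3, 0.2, 5)) {
    th2 <- theta_vector(c * 3, c * 4, 800, 60, 20)
    expect_equal(jsr_forward(th2, p),
                 c * jsr_forward(theta_vector(3, 4, 800, 60, 20), p),
                 tolerance = 1e-12)
  }
})

test_that("flipping the sign of rho_i reflects the on-resonance pi-cycled bSSFP channels", {
  # with dOmega = 0 and phi_rf = pi the normalised bSSFP signal is purely
  # imaginary, so rho_i -> -rho_i negates the real channel, keeps the
  # imaginary channel, and leaves SPGR magnitudes untouched
  p <- protocol(
    sequence_spec("spgr", 4, 6.2), sequence_spec("spgr", 18, 6.2),
    sequence_spec("bssfp", 15, 4.2, phi_rf_deg = 180),
    sequence_spec("bssfp", 65, 4.2, phi_rf_deg = 180),
    sequence_spec("bssfp", 40, 4.2, phi_rf_deg = 180))
  y1 <- jsr_forward(theta_vector(3, 4, 900, 50, 0), p)
  y2 <- jsr_forward(theta_vector(3, -4, 900, 50, 0), p)
  expect_equal(y2[1:2], y1[1:2], tolerance = 1e-14)
  re_idx <- 2 + c(1, 3, 5); im_idx <- 2 + c(2, 4, 6)
  expect_equal(y2[re_idx], -y1[re_idx], tolerance = 1e-12)
  expect_equal(y2[im_idx], y1[im_idx], tolerance = 1e-12)
})

test_that("constructors reject out-of-domain inputs and flag T2 > T1", {
  expect_error(voxel_state(rho = 1, t1 = -5, t2 = 50), "positive")
  expect_error(sequence_spec("spgr", 18, tr_ms = 6.2, te_ms = 6.3), "te_ms")
  expect_error(sequence_spec("spgr", 190, tr_ms = 6.2), "flip")
  expect_warning(voxel_state(rho = 1, t1 = 50, t2 = 900), "t2 > t1")
  expect_error(protocol(), "at least one")
  p4 <- protocol(lapply(1:4, function(i)
    sequence_spec("bssfp", 10 * i, 4.2, phi_rf_deg = 90 * i)))
  expect_error(validate_protocol(p4), "at least 5")
  p5 <- protocol(lapply(1:5, function(i) sequence_spec("spgr", 5 * i, 6.2, te_ms = 2.1)))
  expect_error(validate_protocol(p5), "bSSFP")
})
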