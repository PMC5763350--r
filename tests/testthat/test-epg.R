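wm_state <- function() voxel_state(rho = 1, t1 = 850, t2 = 50)

test_that("ideal spoiling reproduces the Ernst regime exactly", {
  st <- voxel_state(rho = 1, t1 = 900, t2 = 50)
  sq <- sequence_spec("spgr", 18, 6.2, te_ms = 3.1)
  cfg <- epg_config(ideal_spoiling = TRUE, convergence_tol = 1e-13,
                    max_reps = 20000)
  r <- epg_spgr_steady(st, sq, cfg)
  e1 <- exp(-6.2 / 900)
  ernst <- sin(18 * pi / 180) * (1 - e1) / (1 - e1 * cos(18 * pi / 180)) *
    exp(-3.1 / 50)
  expect_true(r$converged)
  expect_equal(r$signal, ernst, tolerance = 1e-10)
})

test_that("transverse coherences vanish to second order at small flip angles", {
  st <- wm_state()
  sq <- sequence_spec("spgr", 0.1, 6.2, te_ms = 3.1)
  r <- epg_spgr_steady(st, sq, epg_config(diffusivity = 0))
  e1 <- exp(-6.2 / 850)
  a <- 0.1 * pi / 180
  ernst <- sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-3.1 / 50)
  expect_lt(abs(r$signal - ernst) / ernst, 1e-3)
})

test_that("EPG steady state matches the isochromat-ensemble oracle", {
  st <- voxel_state(rho = 1, t1 = 900, t2 = 50)
  sq <- sequence_spec("spgr", 18, 6.2, te_ms = 3.1)
  r <- epg_spgr_steady(st, sq, epg_config(diffusivity = 0))
  iso <- oracle_isochromat_spgr(st, sq)
  expect_true(r$converged)
  expect_lt(abs(r$signal - iso) / iso, 0.005)
  # random draws over TR, FA, phase increment, relaxation times
  set.seed(23)
  for (i in 1:6) {
    t1 <- stats::runif(1, 600, 1400); t2 <- stats::runif(1, 30, 90)
    tr <- stats::runif(1, 4, 10); fa <- stats::runif(1, 3, 30)
    phi0 <- sample(c(50, 117, 150), 1)
    sti <- voxel_state(rho = 1, t1 = t1, t2 = t2)
    sqi <- sequence_spec("spgr", fa, tr, te_ms = tr / 2)
    ri <- epg_spgr_steady(sti, sqi,
                          epg_config(phase_increment = phi0, diffusivity = 0))
    isoi <- oracle_isochromat_spgr(sti, sqi, phi0_deg = phi0)
    expect_lt(abs(ri$signal - isoi) / isoi, 0.005)
  }
})

test_that("spoiling error maps behave like the Ernst-deviation analysis", {
  st <- wm_state()
  # perfect spoiling: zero error everywhere
  m0 <- spoiling_error_map(st, c(4.2, 6.2), c(5, 15),
                           epg_config(ideal_spoiling = TRUE,
                                      convergence_tol = 1e-12))
  expect_true(all(abs(m0$epsilon) < 1e-9))
  # small-angle cells are unbiased
  msmall <- spoiling_error_map(st, 6.2, 0.1, epg_config())
  expect_lt(abs(msmall$epsilon), 0.001)
  # continuity in FA at 0.5 degree resolution (no jump above 5 points)
  mfa <- spoiling_error_map(st, 6.2, seq(10, 20, by = 0.5), epg_config())
  expect_true(all(mfa$converged))
  expect_lt(max(abs(diff(mfa$epsilon))), 0.05)
  # spot cells cross-checked against the isochromat oracle (no diffusion)
  cfg0 <- epg_config(diffusivity = 0)
  for (cell in list(c(4.2, 8), c(6.2, 18), c(10, 25))) {
    sq <- sequence_spec("spgr", cell[2], cell[1], te_ms = cell[1] / 2)
    r <- epg_spgr_steady(st, sq, cfg0)
    iso <- oracle_isochromat_spgr(st, sq)
    expect_lt(abs(r$signal - iso) / iso, 0.005)
  }
})

test_that("stronger diffusion moves the spoiled sequence toward the ideal regime", {
  st <- wm_state()
  eps <- vapply(c(0.2, 0.8, 2.4), function(D) {
    m <- spoiling_error_map(st, 6.2, 18, epg_config(diffusivity = D))
    abs(m$epsilon)
  }, numeric(1))
  expect_true(all(diff(eps) <= 1e-12))
})

test_that("the flip-angle cap tracks the error threshold", {
  st <- wm_state()
  grid <- seq(1, 30, by = 0.5)
  # no error: cap at the scan bound
  ideal <- max_flip_for_error(st, 6.2, 0.05,
                              epg_config(ideal_spoiling = TRUE),
                              fa_grid = grid)
  expect_equal(ideal$max_flip, 30)
  inf_thr <- max_flip_for_error(st, 6.2, Inf, epg_config(), fa_grid = grid)
  expect_equal(inf_thr$max_flip, 30)
  # 5% white-matter threshold: a cap in the mid-to-high teens, consistent
  # with its own scan table
  mf <- max_flip_for_error(st, 6.2, 0.05, epg_config(), fa_grid = grid)
  expect_true(mf$feasible)
  expect_gt(mf$max_flip, 10)
  expect_lt(mf$max_flip, 25)
  scan <- mf$scan
  expect_lte(abs(scan$epsilon[scan$fa == mf$max_flip]), 0.05)
  expect_gt(abs(scan$epsilon[scan$fa == mf$max_flip + 0.5]), 0.05)
})
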