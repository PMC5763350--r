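# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form/EPG code paths: they propagate the per-TR
# rotation/relaxation recursion of the Bloch equations directly.
#
# Conventions (fixed by the closed-form component signs): free precession
# multiplies Mxy by exp(-i * 2*pi*dOmega*TR); an RF pulse of flip `a` about
# an axis at phase `psi` maps
#   mxy' = cos^2(a/2) mxy + sin^2(a/2) e^{2i psi} conj(mxy) + i e^{i psi} sin(a) mz
#   mz'  = (i/2) sin(a) (e^{-i psi} mxy - e^{i psi} conj(mxy)) + cos(a) mz
# and the receiver demodulates with the pulse phase.

oracle_pulse <- function(mxy, mz, a, psi = 0) {
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a)
  mxy_new <- ca2 * mxy + sa2 * exp(2i * psi) * Conj(mxy) +
    1i * exp(1i * psi) * sa * mz
  mz_new <- Re((1i / 2) * sa * (exp(-1i * psi) * mxy - exp(1i * psi) * Conj(mxy))) +
    cos(a) * mz
  list(mxy = mxy_new, mz = mz_new)
}

# Ideal-spoiling SPGR steady state by propagating n_reps repetitions:
# transverse magnetization is zeroed before every pulse.
oracle_spgr <- function(state, seq, n_reps = 1e4) {
  a <- state$kappa * seq$flip * pi / 180
  e1 <- exp(-seq$tr / state$t1)
  mz <- 1
  for (i in seq_len(n_reps)) mz <- 1 - e1 + e1 * mz * cos(a)
  s <- sin(a) * mz * exp(-seq$te / state$t2) * exp(-seq$te / state$t2prime)
  s * exp(1i * 2 * pi * (state$d_omega / 1000) * seq$te)
}

# bSSFP steady state by physical propagation: precession from dOmega only,
# RF pulse phase incremented by phi_rf every TR, receiver demodulated with
# the pulse phase. Runs until the post-pulse magnetization change per TR
# drops below tol. Instantaneous pulses (t_rf = 0).
oracle_bssfp <- function(state, seq, tol = 1e-13, max_reps = 2e5) {
  a <- state$kappa * seq$flip * pi / 180
  gamma <- -2 * pi * (state$d_omega / 1000) * seq$tr
  e1 <- exp(-seq$tr / state$t1); e2 <- exp(-seq$tr / state$t2)
  mxy <- 0 + 0i; mz <- 1
  prev <- c(0, 0, 0)
  for (n in 0:max_reps) {
    psi <- n * seq$phi_rf
    p <- oracle_pulse(mxy, mz, a, psi)
    demod <- p$mxy * exp(-1i * psi)
    cur <- c(Re(demod), Im(demod), p$mz)
    if (n > 0 && sqrt(sum((cur - prev)^2)) < tol * max(1, sqrt(sum(cur^2)))) {
      prev <- cur
      break
    }
    prev <- cur
    mxy <- p$mxy * exp(1i * gamma) * e2
    mz <- 1 - e1 + e1 * p$mz
  }
  s <- complex(real = prev[1], imaginary = prev[2])
  s * exp(-seq$te / state$t2) * exp(1i * 2 * pi * (state$d_omega / 1000) * seq$te)
}

# Isochromat-ensemble simulation of the RF- and gradient-spoiled SPGR
# sequence: n_iso spins spread evenly across one cycle of gradient
# dephasing per TR, quadratic RF phase schedule psi_n = phi0 n(n+1)/2.
# Returns the demodulated echo magnitude at TE (no diffusion).
oracle_isochromat_spgr <- function(state, seq, phi0_deg = 50, n_iso = 4096,
                                   tol = 1e-8, max_reps = 5000) {
  a <- state$kappa * seq$flip * pi / 180
  phi0 <- phi0_deg * pi / 180
  e1 <- exp(-seq$tr / state$t1); e2 <- exp(-seq$tr / state$t2)
  theta <- 2 * pi * ((seq_len(n_iso) - 0.5) / n_iso)
  deph <- exp(1i * theta)
  mxy <- rep(0 + 0i, n_iso); mz <- rep(1, n_iso)
  prev_mag <- Inf; mag <- NA_real_
  for (n in 0:max_reps) {
    psi <- phi0 * n * (n + 1) / 2
    p <- oracle_pulse(mxy, mz, a, psi)
    mag <- Mod(mean(p$mxy * exp(-1i * psi)))
    if (n > 0 && abs(mag - prev_mag) < tol * max(mag, 1e-12)) break
    prev_mag <- mag
    mxy <- p$mxy * deph * e2
    mz <- 1 - e1 + e1 * p$mz
  }
  mag * exp(-seq$te / state$t2)
}

# Richardson-extrapolated central-difference Jacobian: 4 step sizes,
# three extrapolation sweeps. f maps a length-m vector to a length-n vector.
oracle_richardson_jacobian <- function(f, x, rel_h = 1e-4) {
  n <- length(f(x)); m <- length(x)
  J <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    h0 <- max(abs(x[j]) * rel_h, 1e-7)
    D <- vector("list", 4)
    for (k in 1:4) {
      h <- h0 / 2^(k - 1)
      xp <- x; xm <- x
      xp[j] <- x[j] + h; xm[j] <- x[j] - h
      D[[k]] <- (f(xp) - f(xm)) / (2 * h)
    }
    for (lev in 1:3) {
      fac <- 4^lev
      for (k in 1:(4 - lev)) D[[k]] <- (fac * D[[k + 1]] - D[[k]]) / (fac - 1)
    }
    J[, j] <- D[[1]]
  }
  J
}
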