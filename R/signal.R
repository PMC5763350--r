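#' Finite RF pulse correction of the bSSFP transverse decay
#'
#' During a pulse of duration `t_rf` the magnetization partially relaxes
#' under a mixture of T1 and T2; the effective transverse decay over one
#' TR is corrected by shortening the decay interval by a fraction
#' `zeta_beta` of the pulse duration:
#' \deqn{\zeta = 0.68 - 0.125 (1 + T_{RF}/TR)\, T_2/T_1}
#' \deqn{\zeta_\beta = \zeta \cos^2\!\big[\tfrac{\beta}{2}\,(1 - (1-\zeta) T_{RF}/TR)\big]}
#' \deqn{E_2 = \exp(-(TR - \zeta_\beta T_{RF})/T_2)}
#' With `t_rf = 0` this reduces exactly to `exp(-tr/t2)`.
#'
#' @param t1,t2 relaxation times (ms).
#' @param t_rf RF pulse duration (ms, `0 <= t_rf < tr`).
#' @param tr repetition time (ms).
#' @param beta off-resonance dephasing angle per TR (radians).
#' @return List with `zeta`, `zeta_beta` and the corrected `e2`.
#'   All arguments recycle to a common length.
#' @export
finite_rf_correction <- function(t1, t2, t_rf, tr, beta) {
  if (any(t_rf < 0) || any(t_rf >= tr))
    stop("t_rf must satisfy 0 <= t_rf < tr")
  f <- t_rf / tr
  zeta <- 0.68 - 0.125 * (1 + f) * (t2 / t1)
  zeta_beta <- zeta * cos((beta / 2) * (1 - (1 - zeta) * f))^2
  shortened <- tr - zeta_beta * t_rf
  if (any(shortened <= 0))
    stop("finite-RF correction exceeds the repetition interval (zeta_beta * t_rf >= tr)")
  list(zeta = zeta, zeta_beta = zeta_beta, e2 = exp(-shortened / t2))
}

#' Steady-state SPGR signal (Ernst regime)
#'
#' Ideally spoiled gradient-echo steady state, normalised by the weighted
#' proton density:
#' \deqn{S = \frac{(1-E_1)\sin(\kappa\alpha)}{1-E_1\cos(\kappa\alpha)}
#'   \; e^{-TE/T_2} e^{-TE/T_2'} e^{i 2\pi \Delta\Omega TE}}
#' with \eqn{E_1 = e^{-TR/T_1}}. An infinite `t2prime` in the state drops
#' the reversible-decay factor. Validity of the perfect-spoiling
#' assumption for a given TR/flip combination is quantified separately by
#' [epg_spgr_steady()].
#'
#' @param state a [voxel_state()].
#' @param seq a [sequence_spec()] of kind `"spgr"` (its `te` must be set,
#'   or the sequence be part of a [protocol()] that filled it).
#' @return A complex scalar (magnitude at most 1).
#' @export
spgr_signal <- function(state, seq) {
  stopifnot(inherits(state, "jsr_voxel_state"), inherits(seq, "jsr_sequence"))
  if (seq$kind != "spgr") stop("spgr_signal needs a sequence of kind 'spgr'")
  te <- sequence_te(seq)
  a <- state$kappa * seq$flip * pi / 180
  e1 <- exp(-seq$tr / state$t1)
  s <- sin(a) * (1 - e1) / (1 - e1 * cos(a)) *
    exp(-te / state$t2) * exp(-te / state$t2prime)
  s * exp(1i * 2 * pi * (state$d_omega / 1000) * te)
}

#' Steady-state bSSFP signal
#'
#' Balanced steady-state free precession signal immediately after the
#' excitation pulse, propagated to the echo time, normalised by the
#' weighted proton density:
#' \deqn{S = (M_x^{SS} + i M_y^{SS})\, e^{-TE/T_2} e^{i 2\pi \Delta\Omega TE}}
#' \deqn{M_x^{SS} = (1-E_1) E_2 \sin(\kappa\alpha) \sin\beta / d, \quad
#'       M_y^{SS} = (1-E_1) (1 - E_2\cos\beta) \sin(\kappa\alpha) / d}
#' \deqn{d = (1 - E_1\cos\kappa\alpha)(1 - E_2\cos\beta)
#'         - E_2 (E_1 - \cos\kappa\alpha)(E_2 - \cos\beta)}
#' where \eqn{\beta = 2\pi\Delta\Omega\,TR + \phi_{RF}} is the dephasing
#' per TR and \eqn{E_2} carries the finite-RF correction of
#' [finite_rf_correction()]. No reversible (T2') decay enters: the bSSFP
#' echo refocuses static dephasing (spin-echo-like behaviour).
#'
#' @inheritParams spgr_signal
#' @param seq a [sequence_spec()] of kind `"bssfp"`.
#' @return A complex scalar (magnitude at most 1).
#' @export
bssfp_signal <- function(state, seq) {
  stopifnot(inherits(state, "jsr_voxel_state"), inherits(seq, "jsr_sequence"))
  if (seq$kind != "bssfp") stop("bssfp_signal needs a sequence of kind 'bssfp'")
  te <- sequence_te(seq)
  a <- state$kappa * seq$flip * pi / 180
  beta <- 2 * pi * (state$d_omega / 1000) * seq$tr + seq$phi_rf
  e1 <- exp(-seq$tr / state$t1)
  e2 <- finite_rf_correction(state$t1, state$t2, seq$t_rf, seq$tr, beta)$e2
  d <- (1 - e1 * cos(a)) * (1 - e2 * cos(beta)) -
    e2 * (e1 - cos(a)) * (e2 - cos(beta))
  if (any(abs(d) < 1e-300))
    stop("degenerate bSSFP denominator (d = 0); inputs are outside the valid domain")
  mx <- (1 - e1) * e2 * sin(a) * sin(beta) / d
  my <- (1 - e1) * (1 - e2 * cos(beta)) * sin(a) / d
  complex(real = mx, imaginary = my) * exp(-te / state$t2) *
    exp(1i * 2 * pi * (state$d_omega / 1000) * te)
}

sequence_te <- function(seq) {
  if (is.null(seq$te))
    stop("sequence has no echo time; set te_ms or build it into a protocol()")
  seq$te
}

# Precompute per-protocol constants once so that repeated forward-model
# evaluation (fitting, Fisher matrices, Monte Carlo) stays cheap.
compile_protocol <- function(p) {
  stopifnot(inherits(p, "jsr_protocol"))
  kinds <- vapply(p, `[[`, character(1), "kind")
  get <- function(seqs, f) vapply(seqs, `[[`, numeric(1), f)
  sp <- p[kinds == "spgr"]; bs <- p[kinds == "bssfp"]
  list(
    ns = length(sp), nb = length(bs),
    sp_flip = get(sp, "flip") * pi / 180, sp_tr = get(sp, "tr"), sp_te = get(sp, "te"),
    bs_flip = get(bs, "flip") * pi / 180, bs_tr = get(bs, "tr"), bs_te = get(bs, "te"),
    bs_phi = get(bs, "phi_rf"), bs_trf = get(bs, "t_rf"))
}

#' Concatenated real-valued JSR forward model
#'
#' The joint data vector a protocol predicts for one voxel: the SPGR
#' entries are signal magnitudes (the SPGR image phase carries incidental
#' contributions and is discarded, so these channels contain no
#' off-resonance information), and each bSSFP acquisition contributes its
#' real and imaginary parts as two consecutive entries. SPGR entries come
#' first, then the bSSFP pairs, each block in protocol order. Keeping the
#' bSSFP channels complex-valued (rather than magnitudes) keeps the model
#' differentiable through the stop bands and makes the off-resonance
#' directly estimable.
#'
#' @param theta estimation vector ([theta_vector()]): rho_r, rho_i (a.u.),
#'   t1, t2 (ms), d_omega (Hz).
#' @param protocol a [protocol()].
#' @param kappa transmit-field scale applied to every flip angle.
#' @param t2prime reversible decay constant for the SPGR factor
#'   (`Inf` = neglected).
#' @return Numeric vector of length `n_spgr + 2 * n_bssfp`.
#' @export
jsr_forward <- function(theta, protocol, kappa = 1, t2prime = Inf) {
  theta <- check_theta(theta)
  cp <- compile_protocol(protocol)
  if (cp$ns + cp$nb == 0) stop("empty protocol")
  drop(forward_core(matrix(theta, nrow = 1), cp, kappa, t2prime))
}

#' @description `jsr_forward_grid()` evaluates the same model for many
#' parameter vectors at once (one row of `theta_mat` per tissue state),
#' which the Fisher/CRLB grid machinery relies on.
#' @rdname jsr_forward
#' @param theta_mat numeric matrix with 5 columns, one row per state.
#' @export
jsr_forward_grid <- function(theta_mat, protocol, kappa = 1, t2prime = Inf) {
  theta_mat <- as.matrix(theta_mat)
  if (ncol(theta_mat) != 5) stop("theta_mat must have 5 columns")
  cp <- compile_protocol(protocol)
  forward_core(theta_mat, cp, kappa, t2prime)
}

# Scalar fast path used inside fitting loops: same model as forward_core
# but with plain vectors over sequences, no matrix allocation.
forward_scalar <- function(theta, cp, kappa = 1, t2prime = Inf) {
  t1 <- theta[3]; t2 <- theta[4]; dom <- theta[5] / 1000
  rho <- complex(real = theta[1], imaginary = theta[2])
  out <- numeric(cp$ns + 2L * cp$nb)
  if (cp$ns > 0) {
    a <- kappa * cp$sp_flip
    e1 <- exp(-cp$sp_tr / t1)
    dec <- exp(-cp$sp_te / t2)
    if (is.finite(t2prime)) dec <- dec * exp(-cp$sp_te / t2prime)
    out[seq_len(cp$ns)] <- Mod(rho) * abs(sin(a) * (1 - e1) / (1 - e1 * cos(a)) * dec)
  }
  if (cp$nb > 0) {
    a <- kappa * cp$bs_flip
    e1 <- exp(-cp$bs_tr / t1)
    beta <- 2 * pi * dom * cp$bs_tr + cp$bs_phi
    f <- cp$bs_trf / cp$bs_tr
    zeta <- 0.68 - 0.125 * (1 + f) * (t2 / t1)
    zeta_beta <- zeta * cos((beta / 2) * (1 - (1 - zeta) * f))^2
    e2 <- exp(-(cp$bs_tr - zeta_beta * cp$bs_trf) / t2)
    cb <- cos(beta); ca <- cos(a); sa <- sin(a)
    d <- (1 - e1 * ca) * (1 - e2 * cb) - e2 * (e1 - ca) * (e2 - cb)
    mx <- (1 - e1) * e2 * sa * sin(beta) / d
    my <- (1 - e1) * (1 - e2 * cb) * sa / d
    z <- rho * complex(real = mx, imaginary = my) *
      (exp(-cp$bs_te / t2) * complex(argument = 2 * pi * dom * cp$bs_te))
    out[cp$ns + 2L * seq_len(cp$nb) - 1L] <- Re(z)
    out[cp$ns + 2L * seq_len(cp$nb)] <- Im(z)
  }
  out
}

# theta_mat: P x 5. Returns P x (ns + 2 nb). kappa scalar or length P.
forward_core <- function(theta_mat, cp, kappa = 1, t2prime = Inf) {
  P <- nrow(theta_mat)
  kappa <- rep(kappa, length.out = P)
  t1 <- theta_mat[, 3]; t2 <- theta_mat[, 4]
  if (any(t1 <= 0) || any(t2 <= 0)) stop("t1 and t2 must be positive")
  rho <- complex(real = theta_mat[, 1], imaginary = theta_mat[, 2])
  dom <- theta_mat[, 5] / 1000            # cycles per ms
  out <- matrix(0, P, cp$ns + 2 * cp$nb)
  if (cp$ns > 0) {
    a <- kappa %o% cp$sp_flip             # P x ns
    e1 <- exp(-(1 / t1) %o% cp$sp_tr)
    dec <- exp(-(1 / t2) %o% cp$sp_te)
    if (is.finite(t2prime)) dec <- dec * exp(-rep(1, P) %o% (cp$sp_te / t2prime))
    s <- sin(a) * (1 - e1) / (1 - e1 * cos(a)) * dec
    out[, seq_len(cp$ns)] <- Mod(rho) * abs(s)
  }
  if (cp$nb > 0) {
    a <- kappa %o% cp$bs_flip             # P x nb
    e1 <- exp(-(1 / t1) %o% cp$bs_tr)
    beta <- 2 * pi * dom %o% cp$bs_tr + rep(1, P) %o% cp$bs_phi
    f <- cp$bs_trf / cp$bs_tr
    zeta <- 0.68 - 0.125 * ((t2 / t1) %o% (1 + f))
    zeta_beta <- zeta * cos((beta / 2) * (1 - (1 - zeta) * (rep(1, P) %o% f)))^2
    e2 <- exp(-(rep(1, P) %o% cp$bs_tr - zeta_beta * (rep(1, P) %o% cp$bs_trf)) / t2)
    cb <- cos(beta)
    d <- (1 - e1 * cos(a)) * (1 - e2 * cb) - e2 * (e1 - cos(a)) * (e2 - cb)
    mx <- (1 - e1) * e2 * sin(a) * sin(beta) / d
    my <- (1 - e1) * (1 - e2 * cb) * sin(a) / d
    ph <- 2 * pi * dom %o% cp$bs_te
    s <- complex(real = mx, imaginary = my) * exp(-(1 / t2) %o% cp$bs_te) *
      complex(argument = ph)
    z <- rho * s
    out[, cp$ns + 2 * seq_len(cp$nb) - 1] <- Re(z)
    out[, cp$ns + 2 * seq_len(cp$nb)] <- Im(z)
  }
  out
}
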