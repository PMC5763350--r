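#' Configuration of the extended-phase-graph SPGR simulation
#'
#' Settings of the RF- and gradient-spoiled steady-state simulation used
#' to quantify how far a given TR/flip combination departs from the
#' ideal (perfectly spoiled) Ernst regime.
#'
#' The gradient spoiler advances every transverse configuration by one
#' order per TR; the physical intra-voxel dephasing (`spoiler_dephasing`
#' radians across `voxel_size` mm) enters only through the per-order
#' diffusion b-values, which attenuate high-order coherences.
#'
#' @param phase_increment quadratic RF phase increment (degrees); the
#'   pulse phase follows `phi0 * n(n+1)/2`.
#' @param spoiler_dephasing transverse dephasing per TR across one voxel
#'   (radians).
#' @param voxel_size voxel extent along the spoiling direction (mm).
#' @param diffusivity apparent diffusion coefficient (um^2/ms).
#' @param max_order highest configuration order retained.
#' @param convergence_tol relative tolerance on the echo magnitude
#'   between successive repetitions.
#' @param max_reps repetition cap before the result is flagged
#'   non-converged.
#' @param ideal_spoiling zero all transverse states before each pulse
#'   (reproduces the Ernst regime exactly).
#' @return An object of class `jsr_epg_config`.
#' @export
epg_config <- function(phase_increment = 50, spoiler_dephasing = 7,
                       voxel_size = 0.8, diffusivity = 0.8,
                       max_order = 100, convergence_tol = 1e-8,
                       max_reps = 5000, ideal_spoiling = FALSE) {
  stopifnot(max_order >= 1, convergence_tol > 0, max_reps >= 2)
  if (!ideal_spoiling && spoiler_dephasing <= 0)
    stop("spoiler_dephasing must be positive unless ideal_spoiling is set")
  structure(list(phase_increment = phase_increment,
                 spoiler_dephasing = spoiler_dephasing,
                 voxel_size = voxel_size, diffusivity = diffusivity,
                 max_order = as.integer(max_order),
                 convergence_tol = convergence_tol,
                 max_reps = as.integer(max_reps),
                 ideal_spoiling = isTRUE(ideal_spoiling)),
            class = "jsr_epg_config")
}

#' Extended-phase-graph SPGR steady state
#'
#' Simulates the RF- and gradient-spoiled SPGR sequence with the
#' configuration-state (EPG) recursion: each repetition applies the RF
#' pulse with quadratically incremented phase (mixing transverse and
#' longitudinal configuration orders), relaxation with per-order
#' diffusion attenuation from the configured gradient moment, and a
#' one-order gradient shift. The demodulated echo magnitude is tracked
#' until its relative change per TR falls below the configured tolerance.
#'
#' @param state a [voxel_state()].
#' @param seq a [sequence_spec()] of kind `"spgr"` with its echo time set.
#' @param config an [epg_config()].
#' @return List with `signal` (echo magnitude at TE, rho-normalised),
#'   `converged`, and `n_reps`.
#' @export
epg_spgr_steady <- function(state, seq, config = epg_config()) {
  stopifnot(inherits(state, "jsr_voxel_state"), inherits(seq, "jsr_sequence"),
            inherits(config, "jsr_epg_config"))
  if (seq$kind != "spgr") stop("epg_spgr_steady needs a sequence of kind 'spgr'")
  te <- sequence_te(seq)
  a <- state$kappa * seq$flip * pi / 180
  phi0 <- config$phase_increment * pi / 180
  e1 <- exp(-seq$tr / state$t1); e2 <- exp(-seq$tr / state$t2)
  K <- config$max_order
  # signed transverse orders -K..K; longitudinal 0..K (Hermitian symmetry)
  nF <- 2L * K + 1L
  Fs <- complex(nF)                       # index k + K + 1
  Z <- complex(K + 1L); Z[1] <- 1
  ks <- -K:K
  # per-TR diffusion attenuation; dk in rad/mm, D in mm^2/ms
  dk <- config$spoiler_dephasing / config$voxel_size
  D <- config$diffusivity * 1e-6
  att_t <- exp(-(dk^2 * (ks^2 + ks + 1 / 3) * seq$tr) * D)
  att_l <- exp(-(dk^2 * (0:K)^2 * seq$tr) * D)
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  mag_prev <- Inf; mag <- NA_real_; converged <- FALSE; n <- 0L
  zfull <- function(Z) c(Conj(rev(Z[-1])), Z)      # signed -K..K
  for (n in 0:config$max_reps) {
    psi <- if (config$ideal_spoiling) 0 else phi0 * n * (n + 1) / 2
    if (config$ideal_spoiling) Fs[] <- 0
    Zs <- zfull(Z)
    Fc <- Conj(rev(Fs))                            # conj(F_{-k})
    Fnew <- ca2 * Fs + sa2 * exp(2i * psi) * Fc + 1i * exp(1i * psi) * sa * Zs
    Znew <- (1i / 2) * sa * (exp(-1i * psi) * Fs - exp(1i * psi) * Fc) + ca * Zs
    Fs <- Fnew
    Z <- Znew[(K + 1L):nF]                         # orders 0..K
    mag <- Mod(Fs[K + 1L] * exp(-1i * psi))
    if (n > 0 && abs(mag - mag_prev) < config$convergence_tol * max(mag, 1e-12)) {
      converged <- TRUE
      break
    }
    mag_prev <- mag
    # relaxation + diffusion over TR, then the gradient shift by one order
    Fs <- Fs * e2 * att_t
    Z <- Z * e1 * att_l
    Z[1] <- Z[1] + (1 - e1)
    Fs <- c(0 + 0i, Fs[-nF])                       # F_k <- F_{k-1}
  }
  list(signal = mag * exp(-te / state$t2), converged = converged, n_reps = n)
}

ernst_signal <- function(state, seq) {
  a <- state$kappa * seq$flip * pi / 180
  e1 <- exp(-seq$tr / state$t1)
  sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-sequence_te(seq) / state$t2)
}

#' Spoiling error relative to the ideal Ernst regime
#'
#' Tabulates `epsilon = (S_Ernst - S_EPG) / S_EPG` over a grid of
#' repetition times and flip angles: the fractional signal bias incurred
#' by assuming perfect spoiling when fitting data acquired with RF and
#' gradient spoiling.
#'
#' @param state a [voxel_state()] (e.g. white matter, T1 = 850 ms,
#'   T2 = 50 ms).
#' @param tr_values repetition times (ms).
#' @param fa_values flip angles (degrees).
#' @param config an [epg_config()].
#' @return Data frame with columns `tr`, `fa`, `epsilon`, `converged`;
#'   also a matrix form in attribute `matrix` (rows TR, columns FA).
#' @export
spoiling_error_map <- function(state, tr_values, fa_values,
                               config = epg_config()) {
  stopifnot(all(tr_values > 0), all(fa_values > 0))
  grid <- expand.grid(tr = tr_values, fa = fa_values, KEEP.OUT.ATTRS = FALSE)
  eps <- numeric(nrow(grid)); conv <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sq <- sequence_spec("spgr", grid$fa[i], grid$tr[i], te_ms = grid$tr[i] / 2)
    r <- epg_spgr_steady(state, sq, config)
    eps[i] <- (ernst_signal(state, sq) - r$signal) / r$signal
    conv[i] <- r$converged
  }
  out <- data.frame(grid, epsilon = eps, converged = conv)
  m <- matrix(eps, length(tr_values), length(fa_values),
              dimnames = list(tr = tr_values, fa = fa_values))
  attr(out, "matrix") <- m
  out
}

#' Largest flip angle keeping the spoiling error below a threshold
#'
#' Scans flip angles upward on a regular grid and returns the last value
#' before `|epsilon|` first exceeds the threshold - the flip-angle cap
#' imposed on SPGR entries during protocol design so that imperfect
#' spoiling cannot bias the fitted maps beyond the stated level.
#'
#' @param state a [voxel_state()].
#' @param tr repetition time (ms).
#' @param threshold allowed `|epsilon|` (fraction, e.g. 0.05).
#' @param config an [epg_config()].
#' @param fa_grid flip angles scanned (degrees; default 0.5 to 90 in
#'   0.5 steps).
#' @return List with `max_flip` (degrees; `NA` with `feasible = FALSE`
#'   when even the smallest scanned flip exceeds the threshold) and the
#'   scan table.
#' @export
max_flip_for_error <- function(state, tr, threshold, config = epg_config(),
                               fa_grid = seq(0.5, 90, by = 0.5)) {
  stopifnot(threshold > 0, tr > 0)
  map <- spoiling_error_map(state, tr, fa_grid, config)
  over <- which(abs(map$epsilon) > threshold)
  if (length(over) == 0)
    return(list(max_flip = max(fa_grid), feasible = TRUE, scan = map))
  if (over[1] == 1)
    return(list(max_flip = NA_real_, feasible = FALSE, scan = map))
  list(max_flip = fa_grid[over[1] - 1L], feasible = TRUE, scan = map)
}
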