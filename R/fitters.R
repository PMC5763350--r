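#' Options for the nonlinear least-squares fits
#'
#' @param theta0 initial estimation vector, or `NULL` to derive the
#'   default initialisation from the data: T1 = 1000 ms, T2 = 60 ms,
#'   zero off-resonance, and a real proton density scaled so that the
#'   model at the initial relaxation times matches the mean magnitude of
#'   the data. The initialisation is kept fixed across voxels.
#' @param lower,upper parameter bounds (fixed ordering). `NULL` uses the
#'   defaults: T1 in \[50, 7000\] ms, T2 in \[5, 3000\] ms, off-resonance
#'   within one half-period of the (smallest) bSSFP TR so that the
#'   periodic bSSFP profile has a unique optimum, proton-density
#'   components unbounded.
#' @param cost_tol stopping tolerance on the cost function value.
#' @param max_iter iteration cap.
#' @return An object of class `jsr_fit_options`.
#' @export
fit_options <- function(theta0 = NULL, lower = NULL, upper = NULL,
                        cost_tol = 1e-15, max_iter = 500) {
  stopifnot(cost_tol > 0, max_iter >= 1)
  if (!is.null(theta0)) theta0 <- check_theta(theta0)
  structure(list(theta0 = theta0, lower = lower, upper = upper,
                 cost_tol = cost_tol, max_iter = max_iter),
            class = "jsr_fit_options")
}

default_bounds <- function(protocol) {
  kinds <- vapply(protocol, `[[`, character(1), "kind")
  trb <- vapply(protocol[kinds == "bssfp"], `[[`, numeric(1), "tr")
  dom_max <- if (length(trb)) 1000 / (2 * min(trb)) else Inf
  list(lower = c(-Inf, -Inf, 50, 5, -dom_max),
       upper = c(Inf, Inf, 7000, 3000, dom_max))
}

fit_failure <- function(reason, n_par = 5) {
  structure(list(theta_hat = rep(NA_real_, n_par), residual_norm = NA_real_,
                 n_iter = 0L, converged = FALSE, failure_reason = reason),
            class = "jsr_fit")
}

#' @export
print.jsr_fit <- function(x, ...) {
  if (!is.null(x$failure_reason)) {
    cat("<fit> FAILED:", x$failure_reason, "\n")
  } else {
    cat(sprintf("<fit> %s after %d iterations, ssq %.4g%s\n",
                if (x$converged) "converged" else "NOT converged",
                x$n_iter, x$residual_norm,
                if (x$converged) "" else " (best iterate returned)"))
    print(x$theta_hat)
  }
  invisible(x)
}

#' Single-step joint relaxometry fit
#'
#' Least-squares fit of the concatenated forward model to one voxel's
#' data vector, estimating all five parameters (complex weighted proton
#' density, T1, T2, off-resonance) in a single step. Uses
#' Levenberg-Marquardt within box bounds; deterministic given the data
#' and options.
#'
#' @param y real data vector of length `n_spgr + 2 * n_bssfp` (SPGR
#'   magnitudes, then bSSFP real/imaginary pairs, blocks in protocol
#'   order).
#' @param protocol a [protocol()] passing [validate_protocol()].
#' @param kappa transmit-field scale of this voxel (actual flip =
#'   `kappa` times prescribed).
#' @param options a [fit_options()].
#' @param t2prime reversible decay constant assumed in the SPGR factor.
#' @return An object of class `jsr_fit`: `theta_hat`, `residual_norm`,
#'   `n_iter`, `converged`, `failure_reason`.
#' @export
fit_jsr <- function(y, protocol, kappa = 1, options = fit_options(),
                    t2prime = Inf) {
  validate_protocol(protocol)
  cp <- compile_protocol(protocol)
  n <- cp$ns + 2L * cp$nb
  if (length(y) != n)
    stop(sprintf("y has length %d but the protocol predicts %d channels",
                 length(y), n))
  if (any(!is.finite(y))) return(fit_failure("non-finite data"))
  if (all(y == 0)) return(fit_failure("all-zero data vector"))
  b <- default_bounds(protocol)
  lower <- options$lower %||% b$lower
  upper <- options$upper %||% b$upper
  theta0 <- options$theta0 %||% default_init(y, cp, kappa, t2prime)
  theta0 <- pmin(pmax(theta0, lower), upper)
  res_fn <- function(par) y - forward_scalar(par, cp, kappa, t2prime)
  # non-convergence is reported through the returned flag, not a warning
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = theta0, lower = lower, upper = upper, fn = res_fn,
    control = minpack.lm::nls.lm.control(
      ftol = options$cost_tol, ptol = 1e-10,
      maxiter = min(options$max_iter, 1024), maxfev = 100000)))
  theta_hat <- stats::setNames(fit$par, theta_names)
  structure(list(theta_hat = theta_hat, residual_norm = fit$deviance,
                 n_iter = fit$niter, converged = fit$info %in% 1:4,
                 failure_reason = NULL),
            class = "jsr_fit")
}

default_init <- function(y, cp, kappa, t2prime) {
  th <- c(1, 0, 1000, 60, 0)
  x <- forward_scalar(th, cp, kappa, t2prime)
  scale <- mean(abs(y)) / mean(abs(x))
  c(scale, 0, 1000, 60, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linearised variable-flip-angle T1 fit (DESPOT1)
#'
#' The classical two-step baseline's first stage: SPGR magnitudes at
#' several flip angles and a common TR are linearised as
#' `S/sin(k a) = E1 * S/tan(k a) + rho1 (1 - E1)` and fitted by ordinary
#' least squares; the slope gives `T1 = -TR / log(E1)`.
#'
#' @param spgr_mags SPGR magnitude signals (>= 2).
#' @param flips_deg prescribed flip angles (degrees), same length.
#' @param tr common repetition time (ms).
#' @param kappa transmit-field scale.
#' @return List with `rho1` (apparent SPGR proton density, echo-time
#'   decay absorbed), `t1` (ms), `slope`, and `valid` (`FALSE` when the
#'   slope falls outside (0, 1), i.e. a non-physical T1).
#' @export
fit_despot1 <- function(spgr_mags, flips_deg, tr, kappa = 1) {
  stopifnot(length(spgr_mags) == length(flips_deg), length(spgr_mags) >= 2,
            tr > 0)
  a <- kappa * flips_deg * pi / 180
  x <- spgr_mags / tan(a)
  yy <- spgr_mags / sin(a)
  m <- stats::cov(x, yy) / stats::var(x)
  b <- mean(yy) - m * mean(x)
  if (!is.finite(m) || m <= 0 || m >= 1)
    return(list(rho1 = NA_real_, t1 = NA_real_, slope = m, valid = FALSE))
  list(rho1 = b / (1 - m), t1 = -tr / log(m), slope = m, valid = TRUE)
}

#' Phase-cycled bSSFP T2 and field-map fit (DESPOT2-FM style)
#'
#' The two-step baseline's second stage: with T1 fixed at the DESPOT1
#' estimate, complex bSSFP data at two or more RF phase increments are
#' fitted by nonlinear least squares for an apparent complex proton
#' density, T2, and the off-resonance frequency. The finite-RF
#' correction of the transverse decay is applied. A magnitude-only
#' variant is available for data without reliable phase.
#'
#' @param bssfp_data complex bSSFP signals, one per bSSFP acquisition in
#'   protocol order (magnitude-only mode accepts real magnitudes).
#' @param t1_fixed fixed T1 (ms).
#' @param protocol a [protocol()] whose bSSFP entries describe the data.
#' @param kappa transmit-field scale.
#' @param options a [fit_options()] (only tolerances/iterations used).
#' @param magnitude fit magnitudes instead of complex data.
#' @return List with `rho2` (complex apparent proton density), `t2`,
#'   `d_omega`, `converged` and `n_iter`.
#' @export
fit_despot2fm <- function(bssfp_data, t1_fixed, protocol, kappa = 1,
                          options = fit_options(), magnitude = FALSE) {
  stopifnot(t1_fixed > 0)
  kinds <- vapply(protocol, `[[`, character(1), "kind")
  bs <- protocol[kinds == "bssfp"]
  if (length(bs) < 2) stop("at least 2 bSSFP acquisitions are required")
  if (length(bssfp_data) != length(bs))
    stop("bssfp_data must hold one value per bSSFP acquisition")
  phis <- vapply(bs, `[[`, numeric(1), "phi_rf")
  if (!magnitude && length(unique(round(phis %% (2 * pi), 10))) < 2)
    stop("off-resonance is unidentifiable from a single RF phase increment")
  cpb <- compile_protocol(protocol(bs))
  dom_max <- 1000 / (2 * min(cpb$bs_tr))
  model <- function(par) {
    # par = (rho_r, rho_i, t2, d_omega); t1 clamped
    forward_scalar(c(par[1], par[2], t1_fixed, par[3], par[4]), cpb, kappa)
  }
  z <- as.complex(bssfp_data)
  if (magnitude) {
    dat <- Mod(z)
    res_fn <- function(par) {
      m <- model(par)
      pred <- sqrt(m[seq(1, length(m), 2)]^2 + m[seq(2, length(m), 2)]^2)
      dat - pred
    }
  } else {
    dat <- as.vector(rbind(Re(z), Im(z)))
    res_fn <- function(par) dat - model(par)
  }
  scale0 <- mean(Mod(z)) / mean(Mod(complex(
    real = model(c(1, 0, 60, 0))[seq(1, 2 * length(bs), 2)],
    imaginary = model(c(1, 0, 60, 0))[seq(2, 2 * length(bs), 2)])))
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = c(scale0, 0, 60, 0),
    lower = c(-Inf, -Inf, 5, -dom_max), upper = c(Inf, Inf, 3000, dom_max),
    fn = res_fn,
    control = minpack.lm::nls.lm.control(
      ftol = options$cost_tol, ptol = 1e-10,
      maxiter = min(options$max_iter, 1024), maxfev = 100000)))
  list(rho2 = complex(real = fit$par[1], imaginary = fit$par[2]),
       t2 = fit$par[3], d_omega = fit$par[4],
       converged = fit$info %in% 1:4, n_iter = fit$niter)
}

#' Mono-exponential spin-echo reference fits
#'
#' Reference relaxometry from spin-echo data, fitted against the
#' expected mono-exponential curves: inversion recovery
#' `|a (1 - 2 exp(-TI/T1))|` for T1 (magnitude-aware, so the sign flip
#' at the null point needs no special handling), and multi-echo decay
#' `a exp(-TE/T2)` for T2. `mode = "even_echoes_only"` first restricts
#' the echo train to even-numbered echoes (discarding odd echoes
#' suppresses imperfect-refocusing contributions) and then fits the
#' decay.
#'
#' @param signals measured magnitudes.
#' @param times inversion times or echo times (ms), strictly increasing.
#' @param mode one of `"inversion_recovery_t1"`, `"multiecho_t2"`,
#'   `"even_echoes_only"`.
#' @return List with `time_constant` (ms), `amplitude`, `converged`,
#'   and `failure_reason` (`NULL` on success).
#' @export
fit_reference_se <- function(signals, times,
                             mode = c("inversion_recovery_t1", "multiecho_t2",
                                      "even_echoes_only")) {
  mode <- match.arg(mode)
  stopifnot(length(signals) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (mode == "even_echoes_only") {
    keep <- seq_along(signals) %% 2 == 0
    signals <- signals[keep]; times <- times[keep]
    mode <- "multiecho_t2"
  }
  if (length(signals) < 3) stop("at least 3 samples are required")
  if (all(signals == 0) || max(abs(signals)) == 0)
    return(list(time_constant = NA_real_, amplitude = NA_real_,
                converged = FALSE, failure_reason = "zero signal"))
  if (mode == "inversion_recovery_t1") {
    t0 <- times[which.min(abs(signals))] / log(2)   # null-point heuristic
    res_fn <- function(par) signals - abs(par[1] * (1 - 2 * exp(-times / par[2])))
    par0 <- c(max(abs(signals)), max(t0, times[1]))
  } else {
    pos <- signals > 0
    if (sum(pos) >= 2) {
      lf <- stats::lm.fit(cbind(1, times[pos]), log(signals[pos]))
      t0 <- if (lf$coefficients[2] < 0) -1 / lf$coefficients[2] else diff(range(times))
      a0 <- exp(lf$coefficients[1])
    } else {
      t0 <- diff(range(times)); a0 <- max(abs(signals))
    }
    res_fn <- function(par) signals - par[1] * exp(-times / par[2])
    par0 <- c(a0, t0)
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par0, lower = c(0, 1e-3), upper = c(Inf, 1e5), fn = res_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-12,
                                         maxiter = 500)))
  ok <- fit$info %in% 1:4 && is.finite(fit$par[2])
  list(time_constant = unname(fit$par[2]), amplitude = unname(fit$par[1]),
       converged = ok,
       failure_reason = if (ok) NULL else "no mono-exponential fit found")
}
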