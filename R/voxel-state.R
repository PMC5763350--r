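#' Tissue/voxel parameter state
#'
#' Bundles the unknowns of a single voxel: the complex weighted proton
#' density `rho` (receive gain, incidental phase and true proton density
#' are not separable from image data and are absorbed into one complex
#' scale), the relaxation times, an optional reversible decay constant
#' T2', the off-resonance frequency, and the transmit-field scale kappa
#' that multiplies every prescribed flip angle.
#'
#' @param rho complex weighted proton density (arbitrary units); a real
#'   number is taken as zero-phase.
#' @param t1 longitudinal relaxation time (ms, > 0).
#' @param t2 transverse relaxation time (ms, > 0).
#' @param t2prime reversible transverse decay constant (ms, > 0).
#'   `Inf` (the default) drops the associated SPGR decay factor.
#' @param d_omega off-resonance frequency (Hz).
#' @param kappa transmit field scale (dimensionless, > 0); the actual
#'   flip angle is `kappa` times the prescribed one.
#' @return An object of class `jsr_voxel_state`.
#' @examples
#' wm <- voxel_state(rho = 10, t1 = 900, t2 = 50)
#' @export
voxel_state <- function(rho = 1, t1, t2, t2prime = Inf, d_omega = 0, kappa = 1) {
  rho <- as.complex(rho)
  stopifnot(length(rho) == 1, length(t1) == 1, length(t2) == 1,
            is.finite(t1), is.finite(t2), is.finite(d_omega))
  if (t1 <= 0 || t2 <= 0) stop("t1 and t2 must be positive")
  if (t2prime <= 0) stop("t2prime must be positive (use Inf to neglect it)")
  if (kappa <= 0) stop("kappa must be positive")
  if (t2 > t1) warning("t2 > t1: physically unusual for tissue", call. = FALSE)
  structure(list(rho = rho, t1 = t1, t2 = t2, t2prime = t2prime,
                 d_omega = d_omega, kappa = kappa),
            class = "jsr_voxel_state")
}

#' @export
print.jsr_voxel_state <- function(x, ...) {
  cat(sprintf(
    "<voxel state>  |rho| = %.4g (phase %.3f rad)\n  T1 = %g ms, T2 = %g ms, T2' = %g ms\n  dOmega = %g Hz, kappa = %g\n",
    Mod(x$rho), Arg(x$rho), x$t1, x$t2, x$t2prime, x$d_omega, x$kappa))
  invisible(x)
}

theta_names <- c("rho_r", "rho_i", "t1", "t2", "d_omega")

#' Estimation vector of the joint model
#'
#' The five jointly estimated parameters in their fixed order:
#' `rho_r`, `rho_i` (a.u.), `t1`, `t2` (ms), `d_omega` (Hz). All fitting,
#' Fisher-information and Monte-Carlo code uses this ordering.
#'
#' @param rho_r,rho_i real and imaginary part of the weighted proton density.
#' @param t1,t2 relaxation times (ms).
#' @param d_omega off-resonance (Hz).
#' @return Named numeric vector of length 5.
#' @export
theta_vector <- function(rho_r, rho_i, t1, t2, d_omega) {
  stats::setNames(c(rho_r, rho_i, t1, t2, d_omega), theta_names)
}

#' @rdname theta_vector
#' @param state a [voxel_state()] object.
#' @export
theta_from_state <- function(state) {
  stopifnot(inherits(state, "jsr_voxel_state"))
  theta_vector(Re(state$rho), Im(state$rho), state$t1, state$t2, state$d_omega)
}

#' @rdname theta_vector
#' @param theta numeric vector of length 5 in the fixed ordering.
#' @param t2prime,kappa carried-over fields not part of the estimation vector.
#' @export
state_from_theta <- function(theta, t2prime = Inf, kappa = 1) {
  theta <- check_theta(theta)
  voxel_state(rho = complex(real = theta[1], imaginary = theta[2]),
              t1 = theta[3], t2 = theta[4], d_omega = theta[5],
              t2prime = t2prime, kappa = kappa)
}

check_theta <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) != 5 || any(!is.finite(theta)))
    stop("theta must be 5 finite numbers (rho_r, rho_i, t1, t2, d_omega)")
  if (theta[3] <= 0 || theta[4] <= 0)
    stop("theta: t1 and t2 must be positive")
  stats::setNames(theta, theta_names)
}
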