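#' Measurement noise model
#'
#' Zero-mean Gaussian noise of equal standard deviation on every data
#' channel (SPGR magnitudes, bSSFP real and imaginary parts). Either a
#' constant `sigma` in the arbitrary units of the images, or the relative
#' rule `sigma = rel * |rho|` tied to the weighted proton density of the
#' state under consideration (the rule used for design-time bound
#' calculations and Monte-Carlo validation; `rel = 0.02` by default).
#'
#' @param sigma constant standard deviation (a.u.), or `NULL` to use the
#'   relative rule.
#' @param rel relative noise level applied to `|rho|` when `sigma` is `NULL`.
#' @return An object of class `jsr_noise`.
#' @export
noise_model <- function(sigma = NULL, rel = 0.02) {
  if (!is.null(sigma)) {
    if (sigma <= 0) stop("sigma must be positive")
    structure(list(type = "constant", sigma = sigma), class = "jsr_noise")
  } else {
    if (rel <= 0) stop("rel must be positive")
    structure(list(type = "relative", rel = rel), class = "jsr_noise")
  }
}

noise_sigma <- function(noise, theta) {
  stopifnot(inherits(noise, "jsr_noise"))
  if (noise$type == "constant") return(rep(noise$sigma, NROW(theta)))
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  s <- noise$rel * sqrt(th[, 1]^2 + th[, 2]^2)
  if (any(s <= 0)) stop("relative noise rule needs |rho| > 0")
  s
}

#' Tissue-parameter grid for design and validation
#'
#' The set of parameter vectors over which bounds are evaluated. The
#' default [brain_grid()] covers brain tissue: T1 from 600 to 1200 ms in
#' 25 ms steps, T2 from 25 to 80 ms in 5 ms steps, and off-resonance
#' from -125 to 125 Hz (1 Hz steps in the full-resolution version; the
#' default uses 5 Hz steps to keep design runs desk-scale, a coarsening
#' the bound is insensitive to at the percent level). The weighted
#' proton density is fixed at 10 a.u. with zero phase.
#'
#' @param t1_values,t2_values relaxation-time grid values (ms).
#' @param d_omega_values off-resonance grid values (Hz).
#' @param rho fixed complex weighted proton density.
#' @return An object of class `jsr_grid`.
#' @export
grid_spec <- function(t1_values, t2_values, d_omega_values = 0, rho = 10 + 0i) {
  stopifnot(length(t1_values) > 0, length(t2_values) > 0,
            length(d_omega_values) > 0, all(t1_values > 0), all(t2_values > 0))
  structure(list(t1 = as.numeric(t1_values), t2 = as.numeric(t2_values),
                 d_omega = as.numeric(d_omega_values), rho = as.complex(rho)),
            class = "jsr_grid")
}

#' @rdname grid_spec
#' @param d_omega_step off-resonance step (Hz); 1 reproduces the
#'   full-resolution grid.
#' @export
brain_grid <- function(d_omega_step = 5) {
  grid_spec(t1_values = seq(600, 1200, by = 25),
            t2_values = seq(25, 80, by = 5),
            d_omega_values = seq(-125, 125, by = d_omega_step))
}

#' @export
print.jsr_grid <- function(x, ...) {
  cat(sprintf("<grid> %d T1 x %d T2 x %d dOmega = %d states, rho = %g%+gi\n",
              length(x$t1), length(x$t2), length(x$d_omega),
              length(x$t1) * length(x$t2) * length(x$d_omega),
              Re(x$rho), Im(x$rho)))
  invisible(x)
}

grid_theta_matrix <- function(grid) {
  stopifnot(inherits(grid, "jsr_grid"))
  g <- expand.grid(t1 = grid$t1, t2 = grid$t2, d_omega = grid$d_omega,
                   KEEP.OUT.ATTRS = FALSE)
  cbind(rho_r = Re(grid$rho), rho_i = Im(grid$rho),
        t1 = g$t1, t2 = g$t2, d_omega = g$d_omega)
}

# Central-difference Jacobians of the forward model for a batch of states.
# Relative step 1e-6 per parameter with an absolute floor of 1e-9.
# Returns a list of length 5 of P x N matrices (one per parameter).
forward_jacobian_grid <- function(theta_mat, cp, kappa = 1, t2prime = Inf,
                                  rel_step = 1e-6, abs_floor = 1e-9) {
  lapply(seq_len(5), function(j) {
    h <- pmax(abs(theta_mat[, j]) * rel_step, abs_floor)
    up <- theta_mat; dn <- theta_mat
    up[, j] <- up[, j] + h
    dn[, j] <- dn[, j] - h
    (forward_core(up, cp, kappa, t2prime) -
       forward_core(dn, cp, kappa, t2prime)) / (2 * h)
  })
}

#' Fisher information matrix of the joint model
#'
#' For independent Gaussian channels of standard deviation
#' \eqn{\sigma_i}, \eqn{F_{jk} = \sum_i \sigma_i^{-2}
#' (\partial g_i/\partial\theta_j)(\partial g_i/\partial\theta_k)} over
#' the entries \eqn{g_i} of [jsr_forward()]. Derivatives are central
#' finite differences with relative step `1e-6` (absolute floor `1e-9`).
#'
#' @param theta estimation vector ([theta_vector()]).
#' @param protocol a [protocol()].
#' @param noise a [noise_model()].
#' @param kappa transmit-field scale.
#' @param t2prime reversible decay constant (`Inf` = neglected).
#' @return Symmetric positive semidefinite 5 x 5 matrix with
#'   dimnames in the fixed parameter ordering.
#' @export
fisher_matrix <- function(theta, protocol, noise = noise_model(),
                          kappa = 1, t2prime = Inf) {
  theta <- check_theta(theta)
  cp <- compile_protocol(protocol)
  if (cp$ns + cp$nb == 0) stop("empty protocol")
  J <- forward_jacobian_grid(matrix(theta, nrow = 1), cp, kappa, t2prime)
  J <- do.call(cbind, lapply(J, drop))       # N x 5
  bad <- which(!is.finite(J), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite derivative of data entry %d with respect to %s",
                 bad[1, 1], theta_names[bad[1, 2]]))
  sigma <- noise_sigma(noise, theta)
  F <- crossprod(J) / sigma^2
  dimnames(F) <- list(theta_names, theta_names)
  (F + t(F)) / 2
}

#' Covariance lower bound from the Fisher matrix
#'
#' Inverts the Fisher information (the equality case of the Cramer-Rao
#' inequality). An ill-conditioned information matrix means some
#' parameter combination is essentially unconstrained by the protocol;
#' in that case an identifiability error names the combination via the
#' near-null eigenvector.
#'
#' @param fisher symmetric 5 x 5 (or M x M) information matrix.
#' @param cond_threshold condition number beyond which the matrix is
#'   treated as singular.
#' @return The inverse of `fisher`, symmetrised.
#' @export
crlb_covariance <- function(fisher, cond_threshold = 1e12) {
  fisher <- as.matrix(fisher)
  if (max(abs(fisher - t(fisher))) > 1e-10 * max(abs(fisher), 1))
    stop("fisher matrix must be symmetric")
  ev <- eigen(fisher, symmetric = TRUE)
  lmax <- max(ev$values)
  lmin <- min(ev$values)
  if (lmin <= 0 || lmax / lmin > cond_threshold) {
    v <- ev$vectors[, which.min(ev$values)]
    nm <- rownames(fisher)
    if (is.null(nm)) nm <- paste0("theta", seq_len(nrow(fisher)))
    comb <- paste(sprintf("%+.2f %s", v[abs(v) > 0.1], nm[abs(v) > 0.1]),
                  collapse = " ")
    stop("unidentifiable model: the parameter combination ", comb,
         " is unconstrained by this protocol (condition number ",
         format(if (lmin > 0) lmax / lmin else Inf, digits = 3), ")")
  }
  cov <- ev$vectors %*% (t(ev$vectors) / ev$values)
  dimnames(cov) <- dimnames(fisher)
  (cov + t(cov)) / 2
}

subset_indices <- function(subset) {
  if (is.character(subset)) {
    idx <- match(subset, theta_names)
    if (anyNA(idx)) stop("unknown parameter name(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(subset)
}

#' Relative precision and its root-mean-square over a parameter subset
#'
#' Per-parameter relative precision \eqn{p_m = \Sigma_{mm}/\theta_m^2}
#' (the bound on the squared relative standard deviation), its square
#' root `p` (directly comparable with a Monte-Carlo relative standard
#' deviation), and the root-mean-square precision
#' \eqn{P_{rms} = \sqrt{\sum_{m \in L} p_m}} over the subset `L` of
#' parameters being optimised (`t1` and `t2` by default).
#'
#' @param covariance covariance bound from [crlb_covariance()].
#' @param theta the parameter vector at which the bound was computed.
#' @param subset parameter names (or indices) forming the subset L.
#' @return List with `p_rel` (squared relative precisions), `p` (their
#'   square roots), and the scalar `p_rms`.
#' @export
rms_precision <- function(covariance, theta, subset = c("t1", "t2")) {
  theta <- check_theta(theta)
  idx <- subset_indices(subset)
  if (any(theta[idx] == 0))
    stop("relative precision undefined: theta is zero for ",
         paste(theta_names[idx][theta[idx] == 0], collapse = ", "))
  d <- diag(as.matrix(covariance))
  if (any(d[idx] < 0)) stop("negative variance bound; fisher matrix invalid")
  p_rel <- d[idx] / theta[idx]^2
  names(p_rel) <- theta_names[idx]
  list(p_rel = p_rel, p = sqrt(p_rel), p_rms = sqrt(sum(p_rel)))
}

#' One-stop CRLB evaluation at a single state
#'
#' @inheritParams fisher_matrix
#' @inheritParams rms_precision
#' @return An object of class `jsr_crlb`: fisher matrix, covariance
#'   bound, per-parameter relative precisions and `p_rms`.
#' @export
crlb <- function(theta, protocol, noise = noise_model(),
                 subset = c("t1", "t2"), kappa = 1, t2prime = Inf) {
  F <- fisher_matrix(theta, protocol, noise, kappa, t2prime)
  cov <- crlb_covariance(F)
  pr <- rms_precision(cov, theta, subset)
  structure(c(list(fisher = F, covariance = cov, subset = subset), pr),
            class = "jsr_crlb")
}

#' @export
print.jsr_crlb <- function(x, ...) {
  cat("<CRLB> relative sd bounds:",
      paste(sprintf("%s %.3g", names(x$p), x$p), collapse = ", "),
      sprintf("\n  P_rms(%s) = %.4g\n", paste(x$subset, collapse = ","), x$p_rms))
  invisible(x)
}

#' Worst-case relative precision over a tissue grid
#'
#' The design cost: the maximum over every grid state of the
#' root-mean-square relative precision bound. Conservative by
#' construction - a protocol is scored by the worst tissue/off-resonance
#' combination it would have to measure.
#'
#' @param protocol a [protocol()].
#' @param grid a [grid_spec()].
#' @param noise a [noise_model()].
#' @param subset parameter subset L entering the rms.
#' @param kappa transmit-field scale.
#' @param cond_threshold passed to the per-point inversion; a grid point
#'   whose information matrix is beyond it makes the cost infinite.
#' @param details if `TRUE` also return the per-point table.
#' @return List with `cf` (the worst-case `p_rms`), `argmax` (the grid
#'   point attaining it), and with `details = TRUE` a data frame
#'   `table` of per-point precisions.
#' @export
cf_grid <- function(protocol, grid, noise = noise_model(),
                    subset = c("t1", "t2"), kappa = 1,
                    cond_threshold = 1e12, details = FALSE) {
  theta_mat <- grid_theta_matrix(grid)
  idx <- subset_indices(subset)
  cp <- compile_protocol(protocol)
  if (cp$ns + cp$nb == 0) stop("empty protocol")
  J <- forward_jacobian_grid(theta_mat, cp, kappa)
  sigma <- noise_sigma(noise, theta_mat)
  P <- nrow(theta_mat)
  prms <- numeric(P)
  vars <- matrix(NA_real_, P, 5, dimnames = list(NULL, theta_names))
  nchan <- cp$ns + 2 * cp$nb
  for (p in seq_len(P)) {
    Jp <- vapply(J, function(m) m[p, ], numeric(nchan))
    if (any(!is.finite(Jp))) stop("non-finite derivative at grid point ", p)
    F <- crossprod(Jp) / sigma[p]^2
    # fast path: Cholesky inversion with a pivot-based conditioning proxy;
    # degenerate points fall back to the eigen route for a proper diagnosis
    ch <- tryCatch(chol(F), error = function(e) NULL)
    ok <- !is.null(ch) && (max(diag(ch)) / min(diag(ch)))^2 < cond_threshold
    if (ok) {
      vars[p, ] <- diag(chol2inv(ch))
    } else {
      dimnames(F) <- list(theta_names, theta_names)
      cov <- tryCatch(crlb_covariance(F, cond_threshold), error = function(e) e)
      if (inherits(cov, "error")) {
        return(list(cf = Inf,
                    argmax = theta_mat[p, ],
                    failure = conditionMessage(cov)))
      }
      vars[p, ] <- diag(cov)
    }
    prms[p] <- sqrt(sum(vars[p, idx] / theta_mat[p, idx]^2))
  }
  imax <- which.max(prms)
  out <- list(cf = prms[imax], argmax = theta_mat[imax, ])
  if (details) {
    rho_sq <- theta_mat[, 1]^2 + theta_mat[, 2]^2
    out$table <- data.frame(
      theta_mat,
      p_rho = sqrt((vars[, 1] + vars[, 2]) / rho_sq),
      p_t1 = sqrt(vars[, "t1"]) / theta_mat[, "t1"],
      p_t2 = sqrt(vars[, "t2"]) / theta_mat[, "t2"],
      sd_domega_hz = sqrt(vars[, "d_omega"]),
      p_rms = prms)
  }
  out
}
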