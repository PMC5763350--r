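with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Monte-Carlo precision experiment
#'
#' A seeded, reproducible experiment: repeated noisy realizations of one
#' state's data vector under a protocol, each fitted by the joint
#' estimator, with the spread of the estimates compared against the
#' covariance bound.
#'
#' @param theta_true true parameter vector ([theta_vector()]).
#' @param protocol a [protocol()].
#' @param noise a [noise_model()].
#' @param n_trials number of independent realizations (>= 2).
#' @param seed integer seed; runs are bit-reproducible given it.
#' @param kappa transmit-field scale.
#' @return An object of class `jsr_mc_experiment`.
#' @export
mc_experiment <- function(theta_true, protocol, noise = noise_model(),
                          n_trials = 1000, seed = 1, kappa = 1) {
  theta_true <- check_theta(theta_true)
  stopifnot(n_trials >= 2)
  structure(list(theta_true = theta_true, protocol = protocol, noise = noise,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 kappa = kappa),
            class = "jsr_mc_experiment")
}

#' Simulate noisy data realizations
#'
#' Every trial is the noiseless forward-model vector plus independent
#' zero-mean Gaussian noise of the model's standard deviation on each
#' channel: on real and imaginary bSSFP parts, and on the SPGR magnitude
#' value directly (the high-SNR regime in which the magnitude noise is
#' Gaussian to good approximation; a Rician option exists for
#' sensitivity checks).
#'
#' @param exp an [mc_experiment()].
#' @param rician add Rician-distributed (rather than Gaussian) noise on
#'   the SPGR magnitude channels.
#' @return Matrix `n_trials` x `n_channels` of noisy data vectors.
#' @export
simulate_trials <- function(exp, rician = FALSE) {
  stopifnot(inherits(exp, "jsr_mc_experiment"))
  y0 <- jsr_forward(exp$theta_true, exp$protocol, exp$kappa)
  sigma <- noise_sigma(exp$noise, exp$theta_true)
  ns <- n_spgr(exp$protocol)
  with_seed(exp$seed, {
    n <- exp$n_trials * length(y0)
    trials <- matrix(rep(y0, each = exp$n_trials) +
                       stats::rnorm(n, sd = sigma),
                     nrow = exp$n_trials)
    if (rician && ns > 0) {
      for (i in seq_len(ns)) {
        re <- y0[i] + stats::rnorm(exp$n_trials, sd = sigma)
        im <- stats::rnorm(exp$n_trials, sd = sigma)
        trials[, i] <- sqrt(re^2 + im^2)
      }
    }
    trials
  })
}

#' Fit every Monte-Carlo trial
#'
#' @param trials matrix from [simulate_trials()].
#' @param protocol the protocol the trials were simulated under.
#' @param kappa transmit-field scale.
#' @param options a [fit_options()].
#' @return Matrix of estimates (one row per trial; non-converged rows NA),
#'   with attribute `n_excluded`.
#' @export
mc_fit_trials <- function(trials, protocol, kappa = 1, options = fit_options()) {
  est <- matrix(NA_real_, nrow(trials), 5, dimnames = list(NULL, theta_names))
  for (i in seq_len(nrow(trials))) {
    ft <- fit_jsr(trials[i, ], protocol, kappa, options)
    if (isTRUE(ft$converged)) est[i, ] <- ft$theta_hat
  }
  attr(est, "n_excluded") <- sum(!stats::complete.cases(est))
  est
}

#' Monte-Carlo relative precision
#'
#' The observed counterpart of the bound: per-parameter
#' `p = sd(theta_hat) / |theta|` (the relative standard deviation over
#' converged trials). Non-converged trials are excluded and counted; an
#' exclusion fraction above `max_exclusion_frac` aborts, since it would
#' invalidate the precision estimate.
#'
#' @param fit_results estimate matrix from [mc_fit_trials()] (rows with
#'   `NA` mark non-converged trials), or a list of `jsr_fit` objects.
#' @param theta_true true parameter vector.
#' @param max_exclusion_frac largest tolerated exclusion fraction.
#' @return List with `p` (named, `NA` where the true value is zero),
#'   `sd` (absolute standard deviations), `n_used`, `n_excluded`.
#' @export
mc_precision <- function(fit_results, theta_true, max_exclusion_frac = 0.01) {
  theta_true <- check_theta(theta_true)
  if (is.list(fit_results) && !is.matrix(fit_results)) {
    fit_results <- do.call(rbind, lapply(fit_results, function(f)
      if (isTRUE(f$converged)) f$theta_hat else rep(NA_real_, 5)))
  }
  ok <- stats::complete.cases(fit_results)
  n_excl <- sum(!ok)
  if (sum(ok) < 2) stop("fewer than 2 converged fits")
  if (n_excl > max_exclusion_frac * nrow(fit_results))
    stop(sprintf("%d of %d trials failed to converge (> %.0f%%): precision estimate invalid",
                 n_excl, nrow(fit_results), 100 * max_exclusion_frac))
  sds <- apply(fit_results[ok, , drop = FALSE], 2, stats::sd)
  p <- ifelse(theta_true != 0, sds / abs(theta_true), NA_real_)
  list(p = stats::setNames(p, theta_names), sd = stats::setNames(sds, theta_names),
       n_used = sum(ok), n_excluded = n_excl)
}

#' Compare Monte-Carlo precision against the covariance bound on a grid
#'
#' For every grid state, simulates `n_trials` noisy realizations, fits
#' them with the joint estimator, and tabulates the relative percentage
#' difference `epsilon = (p_MC - p_CRLB)/p_CRLB * 100` for T1 and T2.
#' The per-point seeds derive deterministically from `seed`, so the
#' whole table is bit-reproducible.
#'
#' @param grid a [grid_spec()].
#' @param protocol a [protocol()].
#' @param noise a [noise_model()].
#' @param n_trials trials per grid point.
#' @param seed base seed.
#' @param kappa transmit-field scale.
#' @param options a [fit_options()].
#' @return Data frame with columns `t1`, `t2`, `d_omega`, `parameter`,
#'   `p_crlb`, `p_mc`, `epsilon_percent`, `n_excluded`; attribute
#'   `max_abs_epsilon` (%) and `mc_error_bar` (the relative sampling
#'   error of a standard deviation at `n_trials`, `1/sqrt(2 n)`).
#' @export
compare_mc_crlb <- function(grid, protocol, noise = noise_model(),
                            n_trials = 1000, seed = 1, kappa = 1,
                            options = fit_options()) {
  theta_mat <- grid_theta_matrix(grid)
  rows <- vector("list", nrow(theta_mat))
  for (i in seq_len(nrow(theta_mat))) {
    th <- theta_vector(theta_mat[i, 1], theta_mat[i, 2], theta_mat[i, 3],
                       theta_mat[i, 4], theta_mat[i, 5])
    bound <- crlb(th, protocol, noise, subset = c("t1", "t2"), kappa = kappa)
    ex <- mc_experiment(th, protocol, noise, n_trials,
                        seed = seed + i - 1L, kappa = kappa)
    est <- mc_fit_trials(simulate_trials(ex), protocol, kappa, options)
    mc <- mc_precision(est, th)
    eps <- (mc$p[c("t1", "t2")] - bound$p) / bound$p * 100
    rows[[i]] <- data.frame(
      t1 = th["t1"], t2 = th["t2"], d_omega = th["d_omega"],
      parameter = c("t1", "t2"),
      p_crlb = unname(bound$p), p_mc = unname(mc$p[c("t1", "t2")]),
      epsilon_percent = unname(eps), n_excluded = mc$n_excluded,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "max_abs_epsilon") <- max(abs(out$epsilon_percent))
  attr(out, "mc_error_bar") <- 1 / sqrt(2 * n_trials)
  out
}
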