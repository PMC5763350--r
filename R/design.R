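#' Constraints of the protocol-design search
#'
#' The feasibility rules under which acquisition protocols are designed:
#' a fixed scan-time budget expressed as the sum of repetition times,
#' a minimum TR (set by resolution and hardware), the bSSFP TR pinned to
#' that minimum (exploratory optimisation converges there, so it is
#' fixed for simplicity), a cap on SPGR flip angles that keeps imperfect
#' spoiling below the accepted signal bias, and the identifiability
#' minima (five measurements overall, two of them bSSFP).
#'
#' @param t_total scan-time budget: largest allowed sum of TRs (ms).
#' @param tr_min minimum repetition time (ms).
#' @param max_spgr_flip flip-angle cap for SPGR entries (degrees); see
#'   [max_flip_for_error()].
#' @param flip_bounds_bssfp allowed bSSFP flip range (degrees).
#' @param min_measurements,min_bssfp identifiability minima.
#' @param feasibility_tol slack on the budget (ms). The default 0.2 ms
#'   admits seven-acquisition combinations (7 x 4.2 = 29.4 ms against a
#'   29.2 ms budget), matching the published design-space table.
#' @return An object of class `jsr_design_constraints`.
#' @export
design_constraints <- function(t_total = 29.2, tr_min = 4.2,
                               max_spgr_flip = 15,
                               flip_bounds_bssfp = c(1, 90),
                               min_measurements = 5, min_bssfp = 2,
                               feasibility_tol = 0.2) {
  stopifnot(tr_min > 0, t_total > 0, max_spgr_flip > 0,
            length(flip_bounds_bssfp) == 2,
            flip_bounds_bssfp[1] < flip_bounds_bssfp[2], feasibility_tol >= 0)
  if (t_total < min_measurements * tr_min - feasibility_tol)
    stop("budget cannot accommodate the minimum number of measurements")
  structure(list(t_total = t_total, tr_min = tr_min,
                 max_spgr_flip = max_spgr_flip,
                 flip_bounds_bssfp = flip_bounds_bssfp,
                 min_measurements = as.integer(min_measurements),
                 min_bssfp = as.integer(min_bssfp),
                 feasibility_tol = feasibility_tol),
            class = "jsr_design_constraints")
}

#' Enumerate feasible acquisition-count combinations
#'
#' All (N_SPGR, N_bSSFP) pairs satisfying the identifiability minima and
#' the time budget when every acquisition runs at the minimum TR. The
#' enumeration box defaults to the published design-space table
#' (N_SPGR 1-4, N_bSSFP 1-5) and can be widened.
#'
#' @param constraints a [design_constraints()].
#' @param max_n_spgr,max_n_bssfp enumeration bounds.
#' @return Data frame with columns `n_spgr`, `n_bssfp` (feasible pairs
#'   only, ordered).
#' @export
enumerate_designs <- function(constraints = design_constraints(),
                              max_n_spgr = 4, max_n_bssfp = 5) {
  g <- expand.grid(n_spgr = seq_len(max_n_spgr), n_bssfp = seq_len(max_n_bssfp),
                   KEEP.OUT.ATTRS = FALSE)
  ok <- (g$n_spgr + g$n_bssfp >= constraints$min_measurements) &
    (g$n_bssfp >= constraints$min_bssfp) & (g$n_spgr >= 1) &
    ((g$n_spgr + g$n_bssfp) * constraints$tr_min <=
       constraints$t_total + constraints$feasibility_tol + 1e-9)
  out <- g[ok, , drop = FALSE]
  out[order(out$n_spgr, out$n_bssfp), , drop = FALSE]
}

# ---- pattern search ---------------------------------------------------------

# Projection of SPGR repetition times onto {tr_i >= tr_min, sum <= budget}:
# clamp at the floor, then shrink the excess above the floor uniformly.
project_spgr_tr <- function(tr, tr_min, budget) {
  tr <- pmax(tr, tr_min)
  total <- sum(tr)
  if (total <= budget) return(tr)
  excess <- tr - tr_min
  avail <- budget - length(tr) * tr_min
  if (avail < 0) return(rep(tr_min, length(tr)))  # infeasible; caller checks
  tr_min + excess * (avail / sum(excess))
}

build_design_protocol <- function(x, n_spgr, n_bssfp, constraints, t_rf = 0) {
  sf <- x[seq_len(n_spgr)]
  st <- x[n_spgr + seq_len(n_spgr)]
  bf <- x[2 * n_spgr + seq_len(n_bssfp)]
  bp <- x[2 * n_spgr + n_bssfp + seq_len(n_bssfp)]
  seqs <- c(
    lapply(seq_len(n_spgr), function(i)
      sequence_spec("spgr", sf[i], st[i], t_rf_ms = t_rf)),
    lapply(seq_len(n_bssfp), function(i)
      sequence_spec("bssfp", bf[i], constraints$tr_min,
                    phi_rf_deg = bp[i] * 180 / pi, t_rf_ms = t_rf)))
  protocol(seqs)
}

#' Optimise a protocol's free parameters against the worst-case bound
#'
#' For a fixed acquisition-count combination, minimises [cf_grid()] over
#' the free variables - SPGR flip angles (capped), SPGR repetition times
#' (floored at the minimum TR, jointly bounded by the scan-time budget),
#' bSSFP flip angles and RF phase increments (bSSFP TRs stay pinned at
#' the minimum) - with a bound-constrained coordinate pattern search
#' (mesh halving from 2 ms / 8 deg / 45 deg down to 0.01 ms / 0.1 deg /
#' 0.5 deg; budget violations resolved by projecting the SPGR TRs onto
#' the budget simplex), restarted from seeded uniform draws over the
#' constraint box. Ties in the cost are broken toward the smallest total
#' flip-angle sum, then lexicographically, making the result
#' deterministic for a given seed.
#'
#' @param n_spgr,n_bssfp acquisition counts (must be feasible under the
#'   constraints).
#' @param constraints a [design_constraints()].
#' @param grid a [grid_spec()] over which the worst case is taken.
#' @param noise a [noise_model()].
#' @param n_restarts random restarts (10 by default).
#' @param seed integer seed; the whole search is reproducible given it.
#' @param subset parameter subset entering the rms precision.
#' @param t_rf RF pulse duration attached to designed sequences (ms).
#' @return List with `protocol`, `cf`, `argmax` (worst grid point of the
#'   returned protocol) and `trace` (per-restart starting and final CF).
#' @export
optimize_protocol <- function(n_spgr, n_bssfp,
                              constraints = design_constraints(),
                              grid, noise = noise_model(),
                              n_restarts = 10, seed = 1,
                              subset = c("t1", "t2"), t_rf = 0) {
  feas <- enumerate_designs(constraints,
                            max_n_spgr = max(4, n_spgr),
                            max_n_bssfp = max(5, n_bssfp))
  if (!any(feas$n_spgr == n_spgr & feas$n_bssfp == n_bssfp))
    stop(sprintf("(%d SPGR, %d bSSFP) is infeasible under the constraints",
                 n_spgr, n_bssfp))
  spgr_budget <- constraints$t_total - n_bssfp * constraints$tr_min +
    constraints$feasibility_tol
  nv <- 2 * n_spgr + 2 * n_bssfp
  idx_sf <- seq_len(n_spgr)
  idx_st <- n_spgr + seq_len(n_spgr)
  idx_bf <- 2 * n_spgr + seq_len(n_bssfp)
  idx_bp <- 2 * n_spgr + n_bssfp + seq_len(n_bssfp)
  lower <- c(rep(0.5, n_spgr), rep(constraints$tr_min, n_spgr),
             rep(constraints$flip_bounds_bssfp[1], n_bssfp),
             rep(0, n_bssfp))
  upper <- c(rep(constraints$max_spgr_flip, n_spgr),
             rep(spgr_budget - (n_spgr - 1) * constraints$tr_min, n_spgr),
             rep(constraints$flip_bounds_bssfp[2], n_bssfp),
             rep(2 * pi, n_bssfp))
  steps0 <- c(rep(8, n_spgr), rep(2, n_spgr), rep(8, n_bssfp),
              rep(45 * pi / 180, n_bssfp))
  steps_min <- c(rep(0.1, n_spgr), rep(0.01, n_spgr), rep(0.1, n_bssfp),
                 rep(0.5 * pi / 180, n_bssfp))
  project <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    x[idx_st] <- project_spgr_tr(x[idx_st], constraints$tr_min, spgr_budget)
    x[idx_bp] <- x[idx_bp] %% (2 * pi)
    x
  }
  cost <- function(x) {
    p <- build_design_protocol(x, n_spgr, n_bssfp, constraints, t_rf)
    cf_grid(p, grid, noise, subset = subset)$cf
  }
  better <- function(cf_a, x_a, cf_b, x_b) {
    # is a strictly preferable to b? cost first, then flip-sum, then lex order
    if (cf_a < cf_b - 1e-12) return(TRUE)
    if (cf_a > cf_b + 1e-12) return(FALSE)
    fa <- sum(x_a[c(idx_sf, idx_bf)]); fb <- sum(x_b[c(idx_sf, idx_bf)])
    if (fa != fb) return(fa < fb)
    diff_idx <- which(x_a != x_b)
    length(diff_idx) > 0 && x_a[diff_idx[1]] < x_b[diff_idx[1]]
  }
  search_one <- function(x0) {
    x <- project(x0)
    f <- cost(x)
    steps <- steps0
    repeat {
      improved <- FALSE
      for (j in seq_len(nv)) {
        for (s in c(+1, -1)) {
          xt <- x
          xt[j] <- xt[j] + s * steps[j]
          xt <- project(xt)
          ft <- cost(xt)
          if (better(ft, xt, f, x)) {
            x <- xt; f <- ft; improved <- TRUE
          }
        }
      }
      if (!improved) {
        if (all(steps <= steps_min)) break
        steps <- pmax(steps / 2, steps_min)
      }
    }
    list(x = x, cf = f)
  }
  runs <- with_seed(seed, {
    starts <- lapply(seq_len(n_restarts), function(i)
      stats::runif(nv, lower, upper))
    lapply(starts, function(x0) {
      r <- search_one(x0)
      r$cf0 <- cost(project(x0))
      r
    })
  })
  best <- runs[[1]]
  for (r in runs[-1]) if (better(r$cf, r$x, best$cf, best$x)) best <- r
  proto <- build_design_protocol(best$x, n_spgr, n_bssfp, constraints, t_rf)
  res <- cf_grid(proto, grid, noise, subset = subset)
  list(protocol = proto, cf = res$cf, argmax = res$argmax,
       trace = data.frame(restart = seq_along(runs),
                          cf_start = vapply(runs, `[[`, numeric(1), "cf0"),
                          cf_final = vapply(runs, `[[`, numeric(1), "cf")))
}
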