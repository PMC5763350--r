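# Shared fixtures: all generated in code, seeded by the caller.

# Random tissue states spanning the brain grid (T1 600-1200 ms,
# T2 25-80 ms) with off-resonance in +/-100 Hz.
random_brain_state <- function(rho = 10, d_omega_range = c(-100, 100),
                               kappa = 1) {
  voxel_state(rho = rho,
              t1 = stats::runif(1, 600, 1200),
              t2 = stats::runif(1, 25, 80),
              d_omega = stats::runif(1, d_omega_range[1], d_omega_range[2]),
              kappa = kappa)
}

random_sequence <- function(kind = c("spgr", "bssfp")) {
  kind <- match.arg(kind)
  tr <- stats::runif(1, 3, 12)
  sequence_spec(kind, flip_deg = stats::runif(1, 2, 80), tr_ms = tr,
                te_ms = 0.5 * tr,
                phi_rf_deg = if (kind == "bssfp") stats::runif(1, 0, 360) else 0)
}

# Small design grid used where full brain-grid resolution is not the point.
coarse_grid <- function(d_omega_step = 25) {
  grid_spec(t1_values = seq(600, 1200, by = 200),
            t2_values = c(25, 50, 80),
            d_omega_values = seq(-125, 125, by = d_omega_step))
}
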