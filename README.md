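# jsrelax — joint system relaxometry for SPGR/bSSFP quantitative MRI

`jsrelax` estimates quantitative relaxation maps — T1, T2, off-resonance
ΔΩ and a complex weighted proton density ρ — from steady-state
gradient-echo data, and designs the acquisition protocols that make
those estimates as precise as a scan-time budget allows. It is aimed at
quantitative-MRI researchers who work with variable-flip-angle SPGR and
phase-cycled bSSFP acquisitions (the DESPOT family) and want the
precision of a single-step joint fit plus a principled way to choose
flip angles, repetition times and RF phase increments.

## What it computes

**Joint system relaxometry (JSR).** All acquisitions are described by
closed-form steady-state models — the Ernst SPGR signal and the full
bSSFP steady state

$$S_\mathrm{bSSFP} = (M_x^{SS} + i M_y^{SS})\,e^{-TE/T_2} e^{i2\pi\Delta\Omega TE},\qquad
M_{x,y}^{SS} = f(E_1, E_2, \kappa\alpha, \beta)/d,$$

with $\beta = 2\pi\Delta\Omega TR + \phi_{RF}$ and a finite-RF-pulse
correction of $E_2$ — concatenated into one real data vector (SPGR
magnitudes, bSSFP real/imaginary pairs). A single bounded
Levenberg-Marquardt fit per voxel estimates
$\theta = (\rho_r, \rho_i, T_1, T_2, \Delta\Omega)$, instead of the
conventional two-step DESPOT1 → DESPOT2-FM cascade that lets first-step
noise propagate into T2.

**Precision bounds and protocol design.** For Gaussian channel noise,
the Fisher matrix $F_{jk} = \sum_i \sigma_i^{-2}\,\partial_j g_i\,
\partial_k g_i$ gives the Cramér–Rao covariance bound $F^{-1}$;
protocols are scored by the *worst-case* root-mean-square relative
precision $P_\mathrm{rms} = \sqrt{p_{T_1} + p_{T_2}}$ over a brain
tissue grid, and a seeded pattern search optimises the free acquisition
parameters under a fixed sum-of-TRs budget.

**Supporting machinery.** An extended-phase-graph simulator (RF phase
spoiling, gradient spoiler, diffusion attenuation) quantifies
imperfect-spoiling bias and sets the SPGR flip-angle cap; Monte-Carlo
experiments validate the bound; reference DESPOT1/DESPOT2-FM and
spin-echo mono-exponential fitters provide baselines; a digital-phantom
generator and voxelwise NIfTI map fitting close the loop from protocol
to parameter maps.

## Worked example

```r
library(jsrelax)

p <- baseline_protocol()   # 2 SPGR (4/18 deg, TR 6.2) + 4 bSSFP (15/65 deg, TR 4.2, phi_rf 180/0)
p
#> <protocol> 2 SPGR + 4 bSSFP, sum of TRs 29.2 ms

# precision bound for white-matter-like tissue at 2% relative noise
crlb(theta_vector(10, 0, 900, 50, 0), p, noise_model(rel = 0.02))
#> <CRLB> relative sd bounds: t1 0.646, t2 0.614
#>   P_rms(t1,t2) = 0.8911

# simulate one voxel at 0.2% noise and fit it jointly
set.seed(1)
y <- jsr_forward(theta_vector(10, 0, 900, 50, 0), p) + rnorm(10, sd = 0.02)
fit_jsr(y, p)
#> <fit> converged after 9 iterations, ssq 0.001328
#>        rho_r        rho_i           t1           t2      d_omega
#>  10.33872319   0.01361882 928.15643553  48.73467295   0.24202674

# optimise a 2 SPGR + 4 bSSFP protocol under the same 29.2 ms budget
g <- grid_spec(c(600, 900, 1200), c(25, 50, 80), seq(-125, 125, 25))
opt <- optimize_protocol(2, 4, design_constraints(), g, n_restarts = 2, seed = 1)
round(c(optimised = opt$cf, baseline = cf_grid(p, g)$cf), 3)
#> optimised  baseline
#>     0.968     1.505
```

The fitted vector recovers the simulated voxel (T1 928 ms vs 900 true,
T2 48.7 ms vs 50 true at this noise level), and the bound-optimised
protocol reduces the worst-case relative precision cost by about a
third relative to the published baseline at identical scan time — the
optimiser spends the SPGR budget near the 15-degree spoiling-safe flip
cap and spreads the bSSFP phase increments instead of using only
180/0 degrees.

A command-line interface wraps the same functions:

```sh
jsr design --nspgr 2 --nbssfp 4 --restarts 10 --seed 1 --out design.json
jsr phantom --protocol protocol.yaml --out phantom/
jsr fit --images img1.nii.gz,...,img10.nii.gz --protocol protocol.yaml --b1map kappa.nii.gz --out-prefix maps/
```

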