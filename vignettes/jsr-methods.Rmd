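---
title: "Joint system relaxometry: models, bounds and protocol design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint system relaxometry: models, bounds and protocol design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsrelax)
```

## The estimation problem

Steady-state gradient-echo relaxometry measures a handful of spoiled
gradient-echo (SPGR) and balanced steady-state free precession (bSSFP)
images at different flip angles, repetition times and RF phase
increments, and infers per voxel the longitudinal and transverse
relaxation times $T_1$ and $T_2$, the off-resonance frequency
$\Delta\Omega$, and a complex *weighted proton density*
$\rho = A e^{-i\phi_A} M_0$. Receive gain $A$, incidental phase
$\phi_A$ and the true proton density $M_0$ cannot be separated from
image data, so they are absorbed into the single complex scale $\rho$
that every signal is proportional to.

The classical two-step pipeline (DESPOT1, then DESPOT2-FM) first fits
$T_1$ from a linearised SPGR relation and then feeds that $T_1$, fixed,
into a bSSFP fit for $T_2$ and the field map. Any noise or bias in the
first step propagates undamped into the second, and the $T_1$
information carried by the bSSFP data is discarded. *Joint system
relaxometry* (JSR) instead fits all five parameters
$\theta = (\rho_r, \rho_i, T_1, T_2, \Delta\Omega)$ to every
acquisition simultaneously, in a single nonlinear least-squares step.

## Signal models

The ideally spoiled SPGR steady state, normalised by $\rho$, is

$$S_\mathrm{SPGR} = \frac{(1 - E_1)\sin\kappa\alpha}{1 - E_1\cos\kappa\alpha}
  \, e^{-TE/T_2}\, e^{-TE/T_2'}\, e^{i 2\pi \Delta\Omega\, TE},
  \qquad E_1 = e^{-TR/T_1},$$

where $\kappa$ is the transmit-field scale (the actual flip angle is
$\kappa$ times the prescribed one; $\kappa$ maps are measured
separately, e.g. by actual-flip-angle imaging, and enter every fit as
known constants). The reversible decay constant $T_2'$ (defined by
$1/T_2^* = 1/T_2 + 1/T_2'$) is neglected by default: at the working
echo time of 2.1 ms and a typical frontal white-matter $T_2' = 285$ ms
the neglected factor deviates from unity by under 1%, and
`test-acceptance.R` verifies this bound against the implemented model.
A finite `t2prime` in [voxel_state()] switches the factor on.

The bSSFP steady state immediately after the excitation pulse,
propagated to the echo, is

$$S_\mathrm{bSSFP} = (M_x^{SS} + i M_y^{SS})\, e^{-TE/T_2}\,
   e^{i 2\pi \Delta\Omega\, TE}$$

with the standard single-pool components

$$M_x^{SS} = \frac{(1-E_1) E_2 \sin\kappa\alpha \sin\beta}{d}, \quad
  M_y^{SS} = \frac{(1-E_1)(1 - E_2\cos\beta) \sin\kappa\alpha}{d},$$

$$d = (1 - E_1\cos\kappa\alpha)(1 - E_2\cos\beta)
    - E_2 (E_1 - \cos\kappa\alpha)(E_2 - \cos\beta),$$

where $\beta = 2\pi\Delta\Omega\,TR + \phi_{RF}$ is the off-resonance
dephasing per repetition including the phase-cycling increment
$\phi_{RF}$. No $T_2'$ factor appears here: the balanced sequence
refocuses static dephasing at the echo (spin-echo-like behaviour).

**Finite RF pulses.** During a pulse of duration $T_{RF}$ the
magnetization relaxes under a tip-angle-dependent mixture of $T_1$ and
$T_2$; the transverse decay per TR is corrected by shortening the decay
interval, $E_2 = \exp(-(TR - \zeta_\beta T_{RF})/T_2)$ with
$\zeta = 0.68 - 0.125 (1 + T_{RF}/TR)\, T_2/T_1$ and
$\zeta_\beta = \zeta \cos^2[\tfrac{\beta}{2}(1 - (1-\zeta) T_{RF}/TR)]$.
The grouping of the exponent was a genuinely open reading of the
correction as typeset in the literature; the interpretation adopted —
$TR$ shortened by the fraction $\zeta_\beta$ of the pulse duration — is
the only one that is dimensionally consistent and reduces exactly to
$\exp(-TR/T_2)$ at $T_{RF}=0$.

**The concatenated data vector.** SPGR image phase carries incidental
contributions that would need a nuisance parameter, so SPGR channels
enter the fit as magnitudes $|\rho|\,|S_\mathrm{SPGR}|$; consequently
SPGR channels carry no off-resonance information. Each bSSFP
acquisition contributes its real and imaginary parts as two channels,
$\mathrm{Re}(\rho S)$ and $\mathrm{Im}(\rho S)$ — keeping the complex
values (rather than magnitudes) keeps the model differentiable through
the bSSFP stop bands and makes $\Delta\Omega$ directly estimable.
`jsr_forward()` assembles the vector with SPGR entries first, then the
bSSFP pairs, each block in protocol order.

**Units.** Milliseconds for all times, Hz for $\Delta\Omega$, degrees
for flip angles and phase increments at every user interface (radians
internally); $\beta$ is computed as
$2\pi(\Delta\Omega/1000)\,TR_\mathrm{ms} + \phi_{RF}$. Unset echo times
default to half the bSSFP repetition time, a convention that keeps
sampling bandwidth and distortion equal across acquisitions.

Both closed forms are validated in the test suite against an
independent Bloch-propagation oracle (the exact per-TR
rotation/relaxation/spoiling recursion, iterated to convergence) to
$10^{-9}$ relative accuracy over random tissue states.

## Imperfect spoiling and the flip-angle cap

The SPGR closed form assumes perfect spoiling. Real sequences use RF
spoiling (quadratic phase schedule $\phi_n = \phi_0\, n(n+1)/2$, with
the conventional "stable" increment $\phi_0 = 50^\circ$) plus a
gradient spoiler; the resulting steady state deviates from the Ernst
regime in a $TR$-, flip-, $T_1$- and $T_2$-dependent way.
`epg_spgr_steady()` quantifies this with the extended-phase-graph (EPG)
recursion: RF mixing of transverse/longitudinal configuration orders,
relaxation, per-order diffusion attenuation, and a one-order gradient
shift per TR.

Numerical choices worth stating:

* **Gradient shift.** The spoiler disperses approximately 7 radians
  across a 0.8 mm voxel per TR. EPG requires integer configuration
  shifts, and 7 rad exceeds $2\pi$, so one full cycle per TR is the
  adopted integer interpretation; the physical gradient moment enters
  only the per-order diffusion b-values
  ($b_T \propto \Delta k^2 (k^2 + k + 1/3)\,TR$ for transverse,
  $b_L \propto \Delta k^2 k^2\,TR$ for longitudinal states).
* **Truncation.** Orders above `max_order = 100` are dropped; at the
  default diffusivity (0.8 um^2/ms) the attenuation leaves truncated
  amplitudes far below $10^{-12}$.
* **Convergence.** The demodulated echo magnitude is tracked between
  successive repetitions; relative changes below $10^{-8}$ (default)
  define the steady state, and hitting the repetition cap flags the
  result instead of failing silently.
* **Reference tissues.** The representative white/grey-matter states
  used for error maps (WM $T_1/T_2$ = 850/50 ms, GM 1200/70 ms), the
  diffusivity, and the voxel geometry are configurable defaults — the
  exact values behind this kind of error analysis are rarely published,
  so all correctness claims about this module are oracle-based (a
  4096-isochromat ensemble simulation with the same phase schedule
  agrees within 0.5%), not value-based.

The spoiling error $\epsilon = (S_\mathrm{Ernst} - S_\mathrm{EPG})/S_\mathrm{EPG}$
grows with flip angle; `max_flip_for_error()` scans a 0.5 degree grid
and returns the last flip angle below a bias threshold. At a 5%
white-matter threshold and TR 6.2 ms the cap lands in the mid-to-high
teens of degrees with the default configuration, which motivates the
15 degree SPGR flip cap used as the design default.

## The precision bound and the design cost

For Gaussian channel noise of standard deviation $\sigma_i$ the Fisher
information of the data vector $g(\theta)$ is
$F_{jk} = \sum_i \sigma_i^{-2} \partial_j g_i\, \partial_k g_i$, and the
covariance of any unbiased estimator satisfies
$\Sigma \succeq F^{-1}$. Relative precisions
$p_m = \Sigma_{mm}/\theta_m^2$ are aggregated over the parameter subset
of interest $L$ (default $\{T_1, T_2\}$) into
$P_\mathrm{rms} = \sqrt{\sum_{m\in L} p_m}$, and a protocol is scored by
the *worst case* of $P_\mathrm{rms}$ over a tissue grid
(`cf_grid()`) — conservative by construction.

Numerical choices:

* Derivatives are central finite differences with per-parameter
  relative step $10^{-6}$ (absolute floor $10^{-9}$), validated against
  Richardson-extrapolated derivatives to $10^{-6}$ relative in the
  suite; analytic derivatives would be a later optimisation only.
* $F$ is inverted through its symmetric eigendecomposition; a condition
  number above $10^{12}$ (or a non-positive eigenvalue) raises an
  identifiability error that names the unconstrained parameter
  combination via the near-null eigenvector.
* The design noise model is $\sigma = 0.02\,|\rho|$ on every channel
  (any constant $\sigma$ may be supplied); with that relative rule the
  relative precisions of $T_1$, $T_2$, $\Delta\Omega$ are invariant to
  rescaling $|\rho|$, which the suite checks.
* The brain design grid is $T_1$ 600–1200 ms in 25 ms steps and $T_2$
  25–80 ms in 5 ms steps with $\rho = 10$ a.u.; the off-resonance axis
  spans ±125 Hz. The full 1 Hz off-resonance resolution is available
  (`brain_grid(d_omega_step = 1)`), but 5 Hz is the default and 25 Hz
  is used in the design examples — the worst-case cost is insensitive
  to this coarsening at the percent level because the bSSFP profile
  varies smoothly between the sampled offsets.
* Whether the proton-density components belong in $L$ is not fixed by
  the methodology; the default excludes them and a switch includes
  them.

## Protocol design

Scan time at fixed resolution is proportional to the sum of repetition
times, so designs are compared under a fixed budget
$\sum TR \le T_\mathrm{total} = 29.2$ ms (the baseline protocol's
total). Acquisition counts $(N_\mathrm{SPGR}, N_\mathrm{bSSFP})$ are
enumerated under the identifiability minima (five measurements overall
— five unknowns — and two bSSFP measurements for the field map, since
all acquisitions share one echo time) and the budget at the minimum
TR of 4.2 ms. A 0.2 ms feasibility slack is the default: the published
design-space table treats seven-acquisition combinations
(7 × 4.2 = 29.4 ms) as feasible against the 29.2 ms budget, and the
slack reproduces exactly that pattern; the enumeration box defaults to
the same table's 1–4 SPGR × 1–5 bSSFP range.

Within a count combination, the free variables are the SPGR flip
angles (capped at 15 degrees by the spoiling analysis), the SPGR
repetition times (floored at 4.2 ms, jointly budget-limited), and the
bSSFP flip angles and phase increments; bSSFP TRs stay pinned at the
minimum (exploratory optimisation converges there). The bSSFP flip
upper bound is 90 degrees — no principled cap is published, and the
baseline's 65 degrees sits comfortably inside. `optimize_protocol()`
minimises the worst-case cost with an in-package bound-constrained
coordinate pattern search: mesh halving from 2 ms / 8 deg / 45 deg
down to 0.01 ms / 0.1 deg / 0.5 deg, budget violations resolved by
projecting the SPGR TRs onto the budget simplex, phase increments
wrapped modulo $2\pi$. Pattern search is derivative-free and matches
the published methodology; any such method satisfying the monotonicity
invariants would do. The search restarts from 10 seeded uniform draws
by default, and cost ties are broken toward the smallest total flip sum
and then lexicographically, so results are bit-reproducible per seed.

## Fitting

`fit_jsr()` minimises the sum of squared residuals with
Levenberg-Marquardt inside box bounds: $T_1 \in [50, 7000]$ ms,
$T_2 \in [5, 3000]$ ms, and $\Delta\Omega$ within one half-period of
the bSSFP TR (±119 Hz at 4.2 ms) — the bSSFP profile is periodic in
$\Delta\Omega$, so restricting to one period makes the optimum unique.
Stopping criteria are a $10^{-15}$ tolerance on the cost or 500
iterations. The initialisation is fixed across voxels ($T_1 = 1000$ ms,
$T_2 = 60$ ms, $\Delta\Omega = 0$, real $\rho$ scaled to the data); the
published pipeline fixed its initial values to unprinted pilot-data
averages, so the defaults here are package choices and overridable.
Noiseless recovery from this fixed initialisation is exact to
$10^{-6}$ relative over the brain grid, which the suite verifies.

The comparison baselines are implemented as used in practice:
`fit_despot1()` (ordinary least squares on the linearised Ernst
relation), `fit_despot2fm()` (nonlinear fit of the phase-cycled
complex bSSFP data with $T_1$ clamped; complex-valued by default, with
a magnitude-only switch, since published descriptions do not fix the
choice), and `fit_reference_se()` (mono-exponential inversion-recovery
and multi-echo fits, with an even-echoes-only mode that suppresses
imperfect-refocusing contributions).

## Monte-Carlo validation and what it shows

`simulate_trials()` adds independent zero-mean Gaussian noise to every
channel; SPGR channels receive Gaussian noise on the magnitude value —
the high-SNR approximation of magnitude statistics — with a Rician
option for sensitivity checks. `compare_mc_crlb()` fits every trial
and tabulates $\epsilon = (p^{MC} - p^{CRLB})/p^{CRLB}$.

Two regimes matter, and the suite tests them separately:

* In the near-linear regime (noise well below the image signals, e.g.
  $\sigma = 0.002\,|\rho|$) the estimator attains the bound and
  $|\epsilon|$ sits within the Monte-Carlo sampling error
  ($\approx 1/\sqrt{2n}$ per standard-deviation estimate).
* At image-level noise ($\sigma = 0.02\,|\rho|$, per-image SNR of only
  2–5 under the baseline protocol with $\rho = 10$) the least-squares
  estimator is strongly nonlinear: a few percent of fits pile up at the
  $T_1$ bound, the estimate distribution is heavily right-skewed, and
  the observed spread exceeds the bound by a large, noise-dependent
  factor. The universal inequality — the estimator never *beats* the
  bound — still holds and is tested at both noise levels.

The acceptance suite and `scripts/acceptance.R` evaluate the
MC-vs-bound discrepancy at the image-level noise with $2\times 10^4$
trials per grid point (a desk-scale reduction of a $10^5$-trial
validation), reporting the maximum $|\epsilon|$ honestly; at that noise
level it is large for the reason above, not because of a defect in
either the bound or the fitter — the same code path passes the
sub-percent check in the near-linear regime.

## The digital phantom

`make_phantom()` emulates multi-class piecewise-constant
$T_1/T_2/\rho/\Delta\Omega$ maps (default classes at the agarose
phantom-like point 2058/185 ms and a brain point 900/50 ms), a smooth
multiplicative transmit-field map spanning 0.85–1.15, and per-channel
Gaussian noise with a recorded seed; complex bSSFP volumes persist as
paired `_re`/`_im` NIfTI files because complex NIfTI support is patchy
across readers. It emulates *noise and transmit-field structure only*:
no partial volume, no magnetization-transfer effects, no motion, no
spatial noise correlation from parallel imaging, and no imperfect
spoiling (images follow the ideal forward model). Passing phantom tests
therefore demonstrates estimator correctness and precision behaviour,
not robustness to the systematic effects that dominate in vivo
discrepancies — magnetization transfer in particular is known to bias
bSSFP-based estimates and is outside the single-pool model throughout.

`voxelwise_fit()` processes voxels independently (order- and
chunking-invariant, hence bit-identical under any partition), and the
`jsr` executable exposes the whole pipeline (`crlb`, `design`,
`phantom`, `fit`, `mc-validate`) for shell use.

## Problem sizes used in the checks

The shipped tests run desk-scale versions of every experiment: 25–100
random states for the oracle comparisons, $1.5\times 10^3$–$2\times
10^4$ Monte-Carlo trials per grid point, three-point design grids with
25 Hz off-resonance steps for the optimisation examples, and phantoms
of a few hundred voxels. Full-resolution configurations (the 25 × 12
tissue grid at 1 Hz off-resonance, $10^5$ trials) are reachable through
the same interfaces.

## Known limitations

Single-compartment model only; Gaussian-likelihood bound (no Rician
Fisher information); no magnetization-transfer or multicomponent
extensions; no correction of the imperfect-spoiling $T_1$ bias (the
flip cap merely limits it); $T_2'$ estimable only in principle (echo
times are tied to half the bSSFP TR by default); and the transmit-field
map is consumed as a known input, never jointly estimated.
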