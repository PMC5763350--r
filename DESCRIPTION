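Package: jsrelax
Title: Joint System Relaxometry for SPGR/bSSFP Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-step joint estimation of proton density, T1, T2 and
    off-resonance from spoiled gradient-echo (SPGR) and balanced
    steady-state free precession (bSSFP) image data, together with a
    Cramer-Rao lower bound framework for designing acquisition protocols
    (flip angles, repetition times, RF phase increments) that minimise
    the worst-case relative estimation variance under a scan-time budget.
    Includes closed-form steady-state signal models with a finite RF
    pulse correction, an extended-phase-graph simulator of imperfect
    SPGR spoiling with diffusion attenuation, conventional DESPOT1 and
    DESPOT2-FM reference fitters, mono-exponential spin-echo reference
    fits, Monte-Carlo validation of the bound, and a digital-phantom
    generator with voxelwise map fitting over NIfTI volumes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
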