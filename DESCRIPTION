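Package: levyswitch
Title: Noise-Induced Transitions in a Bistable Genetic Switch under
    Levy and Gaussian Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how Gaussian (Brownian) and heavy-tailed
    alpha-stable Levy fluctuations drive transitions between the low and
    high expression states of a transcription-factor autoregulation
    (TF-A) switch. Provides the deterministic kinetic model with
    equilibrium and stability analysis, sampling of symmetric
    alpha-stable variables, Euler-Maruyama simulation of the
    jump-diffusion model with Monte Carlo estimators of first-exit
    statistics, a finite-difference solver for the nonlocal
    integro-differential equations satisfied by the mean first exit time
    (MFET) and the first escape probability (FEP) under Balayage-Dirichlet
    exterior conditions, relative-contribution-factor sweeps, and a
    quantification of the stochastic basin of attraction (SBA) of the
    low-concentration state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
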