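Package: fndmc
Title: Fixed-Node Diffusion Monte Carlo for Small Atoms and Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational and fixed-node diffusion Monte Carlo (FN-DMC) for
    molecular ground-state energies at desk scale, with pluggable analytic and
    lightweight parametric trial wavefunctions.  Implements importance-sampled
    drift-diffusion with Umrigar-style time-step corrections, a
    constant-population branch-merge strategy, Zen-style local-energy clipping
    for size consistency, mixed-estimator energy evaluation with
    Flyvbjerg-Petersen reblocking, a VMC-DMC linear extrapolation scheme for
    relative energies, and a Monte-Carlo divergence measuring the difference
    between two nodal surfaces.  Everything runs in Hartree atomic units on a
    single process and is reproducible given a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
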