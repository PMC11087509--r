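Package: ensemblefit
Title: Cryo-EM Map-Guided Analysis of Molecular Dynamics Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Ensemblefit", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing molecular dynamics (MD) conformational
    ensembles against experimental cryo-EM density maps. Synthesizes density
    maps from atomic coordinates by Gaussian spreading, calibrates the atomic
    spread width against a reference map, fits nonnegative unit-sum mixture
    weights of per-ensemble maps to a target map by maximizing Pearson
    correlation over a masked reference region, and selects minimal
    correlation-optimal structure sets from a trajectory frame pool by
    iterative stochastic replacement with multi-replica convergence.
    Includes rigid-body (Kabsch) superposition, principal component analysis
    of conformational modes, readers and writers for PDB and MRC/CCP4 formats,
    a synthetic-data generator with known ground truth, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
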