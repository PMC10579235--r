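Package: popdyn
Title: Population Dynamics of Premotor Decision Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing neural population dynamics during perceptual
    decisions: event-aligned firing-rate tensors with movement masking,
    soft-normalized PCA with signal-versus-noise dimensionality estimation,
    kinematic analysis of neural trajectories (KiNeT), choice-selectivity
    latency and slope fitting, reaction-time and choice decoders with shuffle
    nulls, single-trial linear dynamical-system fits, reduced-rank regression,
    and subspace alignment indices. Includes a synthetic neural-population
    simulator (inhomogeneous Poisson spiking via the time-rescaling theorem)
    implementing three hypotheses about prestimulus covariation with choice
    and reaction time, so every stage of the pipeline can be exercised
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
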