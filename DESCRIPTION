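Package: pkcdesens
Title: Modeling Desensitization of PKC Apl II Translocation Under Spaced and
    Massed Serotonin Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a delay integro-differential model of serotonin-receptor
    trafficking, PKA signaling and activity-dependent protein synthesis that
    reproduces the differential desensitization of PKC Apl II membrane
    translocation in Aplysia sensory neurons under massed versus spaced
    serotonin application. Provides the receptor-state network with homologous
    and PKA-mediated desensitization, synthesis and degradation of the
    anti-desensitizer (AD) and desensitizer (D) proteins gated by windowed
    integrals of kinase activity, a fixed-step fourth-order Runge-Kutta
    integrator with trapezoid-rule history integrals, a library of stimulation
    and drug protocols, translocation readouts, a synthetic-measurement
    generator emulating confocal imaging data, staged least-squares parameter
    estimation, and local parameter-sensitivity classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
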