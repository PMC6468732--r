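Package: opncircuit
Title: Extracellular Proteasome-Osteopontin Circuit Dynamics in
    Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the extracellular proteasome-osteopontin (OPN)
    inflammatory circuit of relapsing-remitting multiple sclerosis as a
    system of ordinary differential equations, derives circuit parameters
    in closed form from paired remission/relapse serum measurements,
    infers Michaelis-Menten degradation kinetics of OPN species by 20S
    standard- and immuno-proteasomes from in vitro digestion time courses
    with a Metropolis-Hastings sampler, converts Boyden-chamber migration
    readouts into per-species chemotactic indices, and predicts
    MSSS-based relapse-severity scores from simulated circuit components
    with cross-validated linear models. Includes seeded synthetic-data
    generators for every input table so the full pipeline runs without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
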