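Package: sirsdtv
Title: Deterministic and Stochastic SIRS+DTV Epidemic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for the SIRS family of compartmental epidemic models
    extended with disease-induced death (D), capacity-limited treatment (T)
    and regimen-limited vaccination (V). Provides a continuous-time
    deterministic engine (fixed-step fourth-order Runge-Kutta) and a
    discrete-time stochastic chain-binomial engine sharing one
    parameterization, prevalence-adaptive contact rates, competing-risk
    rate-to-probability transforms, Erlang (boxcar) waiting-time extensions,
    parameter sweeps, stochastic ensembles with minor/major outbreak
    classification, outbreak-probability estimation, scenario configuration
    files, CSV trajectory export and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
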