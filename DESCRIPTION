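Package: nephroNN
Title: Neural-Network Surrogates for Renal Epithelial Transport Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic steady-state models of renal epithelial cells
    (proximal convoluted tubule and medullary thick ascending limb variants)
    with Goldman-Hodgkin-Katz electrodiffusion, carrier-mediated transport,
    and a damped Newton solver; parameter-sweep dataset generation with
    continuation (warm starts); and small feed-forward neural-network
    surrogates that learn the forward map from transport parameters to
    cellular state and the inverse map from observables back to transport
    parameters.  Includes sex-specific model variants, transporter-inhibition
    scenarios, and identifiability experiments, with fractional mean-square
    error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
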