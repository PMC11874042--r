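Package: pvolr
Title: Pressure-Volume Enthalpy Terms from Smooth Solvent-Accessible Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the solvent-accessible volume (SAV) of a molecule by
    Lebedev-Laikov quadrature of a smooth, switching-function-based
    solvent-accessible surface, together with its analytical gradient, an
    approximate surface-force (X-HCFF) gradient mode, and a numerical PV
    Hessian.  The pressure-times-volume term extends any electronic-energy
    backend to a constant-pressure enthalpy, enabling geometry optimization
    and conformational analysis on pressure-modified potential energy
    surfaces in the GPa regime.  Includes XYZ input/output, Bondi van der
    Waals radii, Monte-Carlo and closed-form volume oracles, synthetic
    geometry builders, a TOML-configurable command-line interface, and
    torsion-scan diagnostics for quadrature noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
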