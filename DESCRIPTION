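Package: terndiff
Title: Thermodynamically Consistent Diffusive Mixing in Ternary
    Antisolvent Crystallization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates diffusive mixing of a solute/solvent/antisolvent
    liquid (exemplified by glycine/water/ethanol) in a closed
    one-dimensional channel.  A nonideal extended Scatchard-Hildebrand
    (Flory-Huggins) free-energy model supplies activity coefficients,
    supersaturation and the thermodynamic factor matrix; species
    transport is solved with Maxwell-Stefan diffusion in the volume
    reference frame by a conservative finite-volume scheme.  Includes
    ternary phase-diagram construction (solubility curve, spinodal,
    binodal tie lines), detection of localized liquid-liquid spinodal
    demixing during mixing, peak-supersaturation trajectory analysis,
    diffusivity sweeps, an ideal/Fickian contrast mode, and
    least-squares calibration of the thermodynamic parameters against
    solubility and binary activity tables (with a seeded synthetic-data
    generator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
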