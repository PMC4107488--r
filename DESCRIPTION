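Package: hisscan
Title: Histidine-Scanning Library Design and Screening Analysis for
    pH-Sensitive Affinity Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering pH-sensitive protein ligands by
    histidine scanning, modelled on the workflow used to derive mild-elution
    Staphylococcal protein A variants for IgG affinity chromatography.
    Covers structure-guided mutation-site selection (minimum contact
    distances to positively charged residues, fractional solvent-accessible
    surface area by the Shrake-Rupley method), degenerate mixed-codon
    library construction and diversity accounting, stochastic simulation of
    multi-round phage-display panning, per-position enrichment analysis
    with effective/essential site calling, two-state thermal-unfolding fits
    of circular-dichroism melting curves, global 1:1 kinetic fits of
    surface-plasmon-resonance sensorgrams, and pH-gradient elution
    chromatogram simulation with elution-peak pH detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve
Config/testthat/edition: 3
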