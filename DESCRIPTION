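Package: ProbeSpectra
Title: Membrane Probe Orientation and Nuclear-Ensemble Fluorescence Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how the orientation and membrane-penetration
    depth of a solvatochromic fluorescent probe (such as Laurdan) embedded in a
    phospholipid bilayer shape its simulated absorption and emission spectra.
    Provides geometric observables on bilayer trajectories (fluorophore tilt
    angle, penetration depth, acyl-chain tilt, leaflet assignment), a
    hierarchical snapshot-sampling protocol for building excitation ensembles,
    construction of electrostatic-embedding point-charge environments around a
    methyl-truncated quantum fragment, nuclear-ensemble spectrum synthesis with
    Lorentzian broadening, permutation tests relating emission energy to probe
    geometry, a pluggable interface to external TD-DFT engines with packaged
    vertical-excitation benchmark tables, and a synthetic trajectory/excitation
    generator with known ground truth so the whole pipeline is testable without
    molecular dynamics or quantum chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'ProbeSpectra-package.R'
    'AllGenerics.R'
    'utils.R'
    'accessors.R'
    'io-trajectory.R'
    'synthetic-data.R'
    'geometry.R'
    'histogram.R'
    'sampling.R'
    'embedding.R'
    'spectra.R'
    'correlation.R'
    'qm-interface.R'
    'pipeline.R'
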