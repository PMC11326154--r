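Package: allomap
Title: Allosteric Network Mapping from Difference Density, HDX-MS and
    Enzyme Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring allosteric residue networks in proteins
    from complementary perturbation experiments. Implements weighted
    isomorphous (Fo-Fo) difference electron-density analysis with
    per-residue integration of absolute difference density above a noise
    threshold (IADDAT), residue-level difference analysis of
    hydrogen-deuterium exchange mass spectrometry (HDX-MS) uptake data
    with back-exchange correction, Michaelis-Menten kinetics fitting for
    mutant-vs-wild-type comparison, and thresholded pooling of residue
    sets with Jaccard and hypergeometric overlap statistics against
    externally defined residue sectors. A synthetic-data module generates
    toy crystals, structure factors, peptide uptake tables and
    plate-reader kinetics with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
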