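Package: excitonring
Title: Exciton Models of Light-Harvesting Pigment Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frenkel exciton Hamiltonians for bacteriochlorophyll rings of
    LH2-type antenna complexes, optionally augmented with charge-transfer
    states between adjacent B850 pigments. Builds idealized Cn-symmetric
    ring geometries or extracts them from PDB structures, samples Gaussian
    static-disorder ensembles emulating MD/QM site-energy fluctuations,
    computes absorption and circular dichroism spectra with second-order
    cumulant homogeneous lineshapes, and decomposes spectral shifts between
    ring variants (site energies, couplings, ring size, charge-transfer
    mixing) with mixed-model substitution analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
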