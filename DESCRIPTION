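Package: dynimpact
Title: Multi-Layer Structural and Dynamic Impact Assessment of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assesses the functional impact of protein missense variants by
    combining static-structure and molecular-dynamics-derived evidence layers:
    local and global backbone perturbation, solvent-accessible and buried
    surface decomposition, per-replicate trajectory metrics (RMSD drift,
    per-residue RMSF) with outlier-replicate exclusion, essential-dynamics
    principal component analysis with porcupine vectors and free-energy
    landscapes, nonbonded interaction energies under a distance-dependent
    dielectric, and aggregate pKa-shift profiles. Per-metric scores are
    calibrated against benign-control variants and combined into per-layer
    labels and an overall benign/VUS/damaging call. A synthetic-data module
    generates conformational ensembles, pKa tables and score tables with
    planted effects and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
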