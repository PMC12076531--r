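Package: anchorQuant
Title: Absolute Proteome Quantification by Anchor-Protein Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns label-free protein-groups reports from MaxQuant,
    MSFragger/FragPipe, DIA-NN and Spectronaut into absolute protein
    abundances (total fmol, ng per ug of protein extract, molecules per
    cell). Spiked anchor proteins of known amount (e.g. the UPS2 dynamic
    range standard) are fitted by log-log regression against measured
    intensities; the inverted calibration converts every protein's
    intensity into fmol at the injection scale, and an experimental
    parameters table (extract volumes, protein concentrations, cell
    counts, enrichment standards) scales those to the sample and the
    cell. Includes report ingestion with intensity-method detection,
    replicate-group inference from sample names, contaminant removal,
    validity filtering, median/quantile/total-sum normalization,
    Gaussian-downshift imputation of left-censored missing values,
    enrichment-factor estimation for subproteome fractions, and a
    synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
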