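Package: lensmech
Title: Biophysical Profiling of Lens Epithelial Cells from AFM and Raman Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of single-cell biophysical measurements:
    atomic force microscopy (AFM) topography flattening, cross-section cell
    height and Ra/Rq surface roughness; spherical Hertz contact-model fitting
    of force-indentation curves to estimate reduced and sample Young's moduli;
    asymmetric-least-squares baseline correction of Raman spectra and
    computation of the lipid-chain order parameters S_l and S_t used as
    membrane-fluidity readouts. Includes synthetic-data generators for height
    maps, force curves, Raman spectra and full three-group treatment cohorts
    so every stage of the pipeline is testable without instrument data, plus
    plain-text readers/writers, group statistics (t-test, one-way ANOVA) and
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
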