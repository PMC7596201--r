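Package: tspopet
Title: TSPO PET Kinetic Modeling and Immunohistochemistry Quantification
    for Small Vessel Disease White Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies [11C]PBR28 TSPO PET data in white-matter regions of
    interest with the standard two-tissue compartment model (2TCM) and its
    extension with an irreversible vascular-binding compartment (2TCM-1K),
    driven by a metabolite-corrected arterial plasma input function.
    Provides arterial input construction with Hill-type parent-fraction
    modeling, weighted nonlinear least-squares fitting with AIC model
    comparison, the outlier and plausibility exclusion rules used in small
    vessel disease studies, group statistics (paired and Levene-gated
    independent t-tests, Pearson correlations, two-way fixed-effects ANOVA),
    and H-DAB color-deconvolution percent-area quantification of Iba1 and
    TSPO immunostains.  A synthetic-data module generates blood curves,
    dynamic PET phantoms, CBF maps and stained-tissue images with known
    ground truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    car,
    RNifti,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
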