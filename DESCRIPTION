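Package: cardrisk
Title: Predicted Cardiac Toxicity Risk from Photon and Proton Radiotherapy
    Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing predicted radiogenic cardiac toxicity
    between photon and proton radiotherapy plans of the same patient.
    Implements dose-volume histogram (DVH) containers with plain-text I/O,
    differential/cumulative conversion and conservative rebinning,
    fractionation correction to 2 Gy-per-fraction equivalents via the
    linear-quadratic model, equivalent-dose bookkeeping including stray
    neutron contributions, a linear relative-risk model for cardiac
    mortality, relative-seriality and Lyman normal tissue complication
    probability (NTCP) models with effective-volume reduction, ratio
    summaries (RRR and RNTCP) for plan comparison, parameter and
    neutron-weighting sensitivity sweeps, and a deterministic synthetic DVH
    generator so the whole pipeline can be exercised without
    treatment-planning-system exports.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Encoding: UTF-8
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
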