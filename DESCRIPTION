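Package: pocketflex
Title: Differential Conformational Flexibility Analysis for Selective
    Binding-Site Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating selectivity-conferring small-molecule binding
    sites on proteins that exist in two forms (for example soluble versus
    membrane-tethered RANKL) by contrasting the conformational flexibility of
    the two forms.  Reads and writes multi-model PDB ensembles, computes
    residue-pair distance series, exceedance probabilities and the
    sum-of-distances (SDRP) pocket-breathing statistic with modal-bin
    representative-conformer selection, runs an auditable differential
    virtual-screening triage cascade over docking-score tables, and provides
    the small closed-form assay statistics used downstream (inhibition ratios,
    KD from kinetic rates, selectivity index, organ coefficients, and a
    four-parameter logistic dose-response fitter).  A seeded
    Ornstein-Uhlenbeck synthetic-ensemble generator supplies ground-truth
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
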