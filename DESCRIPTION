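Package: quenchbind
Title: Ligand-Protein Binding Analysis from Fluorescence Quenching Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of small-molecule binding to proteins from
    fluorescence quenching titration data. Implements Stern-Volmer and
    double-logarithmic binding fits with static/dynamic quenching
    classification, the model-independent interaction density function (IDF)
    procedure with Scatchard regression for site number and binding constant,
    van't Hoff enthalpy-entropy decomposition with Gibbs free energy and
    binding-force classification, multiexponential TCSPC lifetime fitting
    with intensity-weighted average lifetimes, inner-filter correction,
    mean residue ellipticity conversion, and docking-score to binding-constant
    conversion. A forward simulator with exact mass-balance ground truth
    (n-site independent identical sites, static quenching signal model,
    Poisson-noised decays) supports parameter-recovery testing of every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
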