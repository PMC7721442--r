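Package: flexiquantLF
Title: Label-Free Indirect Quantification of Peptide Modification Extent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies differentially modified peptides and quantifies their
    modification extent from label-free peptide intensities, without measuring
    the modified species directly. For each sample, a robust linear regression
    through the origin (RANSAC consensus over random peptide subsets, best of
    several initiations by coefficient of determination) is fitted against a
    reference sample; vertical distances to the regression line are converted
    into raw scores, high-side outliers are removed with a median + 3*MAD gate,
    and remaining scores are scaled by the median of the three highest raw
    scores to give RM (relative modification) scores, equal to one minus the
    modification extent. Peptides are classified as likely, possibly, or likely
    not differentially modified. A "superprotein" mode pools peptides of
    co-stoichiometric proteins so that proteins with too few peptides become
    analyzable. Includes a synthetic-data generator, an in-silico modification
    benchmark (correlation, per-class sensitivity/precision, quantification
    error), and a RANSAC-initiation reproducibility harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
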