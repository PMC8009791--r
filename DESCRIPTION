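Package: cranioquant
Title: Radial Outline Curve Quantification of Scaphocephaly Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the severity of scaphocephaly (sagittal
    craniosynostosis) from a cranial cross-section outline. A reference
    plane is placed 40 mm above three external landmarks (left porion and
    both exocanthia), the skull outline on that plane is converted into a
    normalized radial curve around its centre of mass, and the curve's
    peaks (forehead, occiput), troughs (left and right sides) and
    transition slopes are extracted. From these the package computes a
    cohort rank-sum severity score, an explicit severity index with
    mild/moderate/severe cut-offs, and the cranial index in both its
    traditional and curve-derived forms. Intracranial volume is estimated
    from binary masks by slice-area summation and classified against a
    user-supplied normative table in standard-deviation bands. The
    statistical layer provides visual-score aggregation, two-way random
    absolute-agreement average-measures intraclass correlation, and
    Pearson correlation with conventional interpretation scales. A
    parametric phantom generator produces synthetic outlines, head
    volumes, rater tables and normative tables for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
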