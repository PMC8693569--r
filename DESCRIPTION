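Package: deview
Title: Interactive Linked Views for Differential Expression Results
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Portable interactive dashboards for bulk and single-cell RNA-seq
    exploration: multidimensional scaling (MDS) plots based on leading
    log2-fold-change distances, and linked summary-expression views (MA,
    volcano, XY) with searchable gene tables. Widgets are declarative JSON
    documents rendered into fully self-contained HTML files or embeddable
    fragments, viewable without any analysis environment. The numeric
    substrate (log-CPM, leading-logFC distances, classical MDS,
    Benjamini-Hochberg adjustment, differential-expression status calling)
    is implemented in the package, and a negative-binomial count simulator
    provides reproducible fixtures end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
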