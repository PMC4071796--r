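Package: pepmapr
Title: Peptide Mapping and Topographical Annotation of Quantitative
    Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantified tryptic peptides from protXML output of the
    Trans Proteomic Pipeline (ProteinProphet with ASAPRatio/XPRESS
    stable-isotope quantitation) onto linear protein sequences annotated
    with membrane topology (signal peptides, transmembrane segments,
    cytoplasmic and extra-cytoplasmic domains).  Computes per-domain
    average log2 light:heavy fold changes, screens for candidate
    substrates of intramembrane proteases (type 2 single-pass proteins
    with an accumulating cytoplasmic tail), and renders a shareable
    static HTML report bundle.  Includes a synthetic-data generator that
    produces matched protXML and annotation fixtures with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    glue,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
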