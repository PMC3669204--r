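Package: hrss
Title: Hybrid Relative Specificity Similarity for Ontology Terms and Gene
    Products
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semantic similarity of Gene Ontology terms and gene products.
    Implements the hybrid relative specificity similarity (HRSS) measure,
    which combines the information content of the most informative common
    ancestor with term generality and the information-content distance of
    the two terms from that ancestor, alongside the edge-based RSS measure
    and the classical Resnik, Lin and Jiang term measures.  Gene-product
    similarity is obtained through maximum (MAX) and best-match-average
    (BMA) aggregation or the groupwise simUI and simGIC measures.  Includes
    parsers for OBO 1.2/1.4 ontologies and GAF 2.x annotation files with
    evidence-code filtering and true-path-rule propagation, corpus-based
    information content, ROC/AUC evaluation with Youden and F1 threshold
    selection, confidence binning of similarity scores, permutation
    Z-scores for ortholog functional conservation, deterministic fixture
    generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
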