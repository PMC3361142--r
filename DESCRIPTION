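Package: GOuniversal
Title: Topology-Based Semantic Similarity for Gene Ontology Terms and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the GO-universal metric, a topology-only semantic
    similarity measure for Gene Ontology terms in which each term carries a
    topological position characteristic mu (the recursive product over its
    parents of mu(parent)/children(parent)) and a topological information
    content IC = -ln(mu), computed in underflow-safe mantissa/exponent form.
    Term similarity is the shared information of the most informative common
    ancestor normalised by the larger of the two term ICs, and induces a
    distance metric 1 - S. Also provides the Wang and Zhang topological
    comparators, annotation-frequency information content, protein-level
    functional similarity (best-match average, average, maximum,
    Czekanowski-Dice, SimGIC/SimUIC/SimUI/SimDIC/SimUIX), OBO 1.2 and GAF 2.x
    ingestion with evidence-code filtering, seeded generators for random
    ontology DAGs and annotation corpora, an exact big-integer oracle for mu,
    and ROC/AUC/precision/accuracy/Pearson evaluation statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pROC, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
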