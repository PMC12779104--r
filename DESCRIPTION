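Package: kgqc
Title: Staged Data-Quality Validation for Patient Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying dynamic, rule-based data-quality
    assessment of integrated electronic health records. Generates clean,
    internally consistent MIMIC-like patient/admission/procedure/diagnosis
    tables, corrupts them with a two-parameter noise model (consistency and
    completeness operators with a ground-truth injection ledger), maps the
    tables to per-patient knowledge graphs aligned to a mini reference
    ontology, integrates staged sources into a unified patient graph, validates
    the graphs against SHACL-style shapes in eight completeness and consistency
    categories, and reports category-wise quality scores (1 - error rate)
    across the integration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
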