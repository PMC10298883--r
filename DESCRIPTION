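Package: orfsub
Title: Subinteractome Analysis of Uncharacterized ORF Proteins in Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to prioritize uncharacterized chromosome-specific
    open-reading-frame (CxORFx) proteins by the cancer-hallmark density of
    their physical protein-protein interaction neighborhoods
    (subinteractomes). Aggregates interaction records from PSI-MITAB and
    edge-list sources into a deduplicated network, extracts per-protein
    subinteractomes and runs partner censuses, computes cancer-hallmark
    scores (hallmark-associated partners per 10 partners) with percentile
    prioritization and hypergeometric over-representation analysis,
    classifies interactions as cancer-dependent or cancer-perturbed from
    normal/tumor Spearman co-expression sign shifts, evaluates multi-gene
    expression signatures by Kaplan-Meier/log-rank survival analysis with
    observed/expected hazard ratios and decisive-subset ablation, and
    groups differential-expression calls across cancers with
    SVD-with-imputation principal component analysis. A seeded synthetic
    data generator emulates every input so the whole pipeline is testable
    without external cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Survival,
    GeneExpression, PrincipalComponent
RoxygenNote: 7.3.3
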