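Package: cernatriad
Title: Competing Endogenous RNA (lncRNA-mRNA) Network Inference from
    Three-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) lncRNA-mRNA pairs from
    matched mRNA, miRNA and lncRNA expression profiles measured on the same
    samples under a two-group design. Provides RPKM/TPM quantification,
    fold-change and differential classification, Pearson correlation
    filtering of miRNA-target and lncRNA-mRNA pairs, intersection with
    sequence-predicted miRNA recognition element (MRE) pair lists, a ceRNA
    score with a hypergeometric shared-miRNA significance test, bipartite
    and tripartite network export, a reproducible pipeline driver, and a
    synthetic three-class data generator with planted ceRNA triplets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
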