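Package: ironvirt
Title: Cross-Study Meta-Analysis of Iron-Deficiency Regulated Genes and
    FIT-Dependence Filtering in Arabidopsis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying genes regulated by the Arabidopsis iron
    uptake regulator FIT from multi-line, multi-condition differential
    expression experiments, and for ranking iron-deficiency marker genes by
    their cross-study consistency. Converts per-comparison log2 fold change
    and p-value tables into ternary regulation calls, applies four-step
    sign-pattern filter cascades to classify robustly and tissue-specifically
    FIT-induced or FIT-repressed genes, aggregates gene-by-study ternary
    regulation matrices into ABS/SUM/RAT/VIRT consistency scores with
    threshold-based filtering and marker ranking, clusters fold-change
    profiles around designated marker genes, and simulates all inputs with
    planted gene classes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
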