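Package: saemir
Title: Smoking-Dependent miRNA Differential Expression and Cessation Reversibility in the Small Airway Epithelium
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for analysing microRNA expression in the small airway
    epithelium across nonsmokers, current smokers and the same smokers after
    smoking cessation. Implements per-miRNA two-factor (group + gender) ANOVA
    with Fisher's least-significant-difference contrasts, signed fold-change
    selection of smoking-dependent miRNAs, classification of those miRNAs as
    cessation-reversible or cessation-persistent, a per-subject quartile
    exceedance index with Kruskal-Wallis/Dunn group comparison, the percent
    change reversibility statistic, hypergeometric miRNA-category and
    target-gene pathway enrichment, comparative-CT relative quantification,
    and a synthetic cohort generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
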