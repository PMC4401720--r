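#!/usr/bin/env Rscript
# Per-miRNA two-factor (group + gender) ANOVA with Fisher LSD contrasts for
# smokers vs nonsmokers, selection of the smoking-dependent signature at
# p < 0.01 and |fold-change| > 1.5, and unsupervised hierarchical
# clustering of the signature (1 - Pearson correlation, average linkage).

library(saemir)

indir <- "results/cohort"
expr <- read_expression_matrix(file.path(indir, "expression_log2.tsv"))
meta <- read_sample_metadata(file.path(indir, "sample_metadata.tsv"))
truth <- read_results_table(file.path(indir, "truth.tsv"))

de <- run_diffexp(expr, meta, "smoker_vs_nonsmoker")
signature <- select_smoking_dependent(de)
write_results_table(de, "results/diffexp_smoker_vs_nonsmoker.tsv")
write_results_table(signature, "results/signature.tsv")

planted <- truth$mirna_id[truth$direction != "null"]
cat(sprintf("signature: %d miRNAs (%d up, %d down); %.0f%% of the %d planted recovered\n",
            nrow(signature), sum(signature$direction == "up"),
            sum(signature$direction == "down"),
            100 * mean(planted %in% signature$mirna_id), length(planted)))

hc <- cluster_signature(expr[signature$mirna_id,
                             meta$sample_id[meta$group != "quitter"]])
grp2 <- stats::cutree(hc$samples, 2)
split_purity <- max(mean(grp2[meta$sample_id[meta$group == "nonsmoker"]] == 1),
                    mean(grp2[meta$sample_id[meta$group == "nonsmoker"]] == 2))
cat(sprintf("clustering: cutting the sample dendrogram in two keeps %.0f%% of nonsmokers together\n",
            100 * split_purity))
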