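#!/usr/bin/env Rscript
# miRNA functional-category enrichment of the signature (hypergeometric
# upper tail over the category collection) and pathway enrichment of the
# expression-filtered (> 0.125 RPKM) target genes of the persistent miRNAs.

library(saemir)

indir <- "results/cohort"
signature <- read_results_table("results/signature.tsv")
ces <- read_results_table("results/cessation.tsv")
categories <- read_gene_sets(file.path(indir, "mirna_categories.gmt"),
                             universe_size = 1100)
pathways <- read_gene_sets(file.path(indir, "pathways.gmt"),
                           universe_size = 2000)
target_map <- read_target_map(file.path(indir, "target_map.tsv"))
rpkm <- read_rpkm_table(file.path(indir, "gene_rpkm.tsv"))

cat_enr <- category_enrichment(signature$mirna_id, categories)
write_results_table(cat_enr, "results/category_enrichment.tsv")
cat(sprintf("top category: %s (fold %.1f, p = %.2g)\n",
            cat_enr$set_name[1], cat_enr$fold_enrichment[1], cat_enr$p_value[1]))

filtered <- filter_targets_by_expression(target_map, rpkm)
cat(sprintf("target map: %d pairs, %d after the RPKM > 0.125 filter\n",
            nrow(target_map), nrow(filtered)))

ts <- collect_persistent_targets(ces, filtered, pathways)
write_results_table(ts$per_mirna, "results/persistent_target_counts.tsv")
write_results_table(ts$pathway, "results/pathway_enrichment.tsv")
cat(sprintf("pooled persistent targets: %d genes (deduplicated)\n",
            length(ts$pooled_targets)))
cat(sprintf("top pathway: %s (coverage %.2f, fold %.1f, p = %.2g)\n",
            ts$pathway$set_name[1], ts$pathway$coverage_ratio[1],
            ts$pathway$fold_enrichment[1], ts$pathway$p_value[1]))
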