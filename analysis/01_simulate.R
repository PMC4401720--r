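#!/usr/bin/env Rscript
# Generate a study-scale synthetic cessation cohort and matching annotation
# resources, and write them in the exchange formats the rest of the
# workflow reads back (expression/metadata/target-map/RPKM TSVs, GMTs).
#
# Design mirrors the study cohort: 9 nonsmokers, 10 smokers sampled again
# after 3 months of cessation, 1100 miRNAs with 25 up- and 9 down-regulated
# by smoking, 12 of the 34 persisting after cessation.

library(saemir)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- cohort_design(effect_log2 = 2.0, noise_sd_log2 = 0.5, seed = 2026L)
cohort <- generate_cohort(design)
ann <- generate_annotation_resources(cohort$truth, seed = 2026L)

write_expression_matrix(cohort$expr, file.path(out, "expression_log2.tsv"))
write_results_table(cohort$meta, file.path(out, "sample_metadata.tsv"))
write_results_table(cohort$truth, file.path(out, "truth.tsv"))
write_gene_sets(ann$categories$sets, file.path(out, "mirna_categories.gmt"))
write_gene_sets(ann$pathways$sets, file.path(out, "pathways.gmt"))
write_results_table(ann$target_map, file.path(out, "target_map.tsv"))
write_results_table(data.frame(gene_id = names(ann$rpkm), rpkm = ann$rpkm),
                    file.path(out, "gene_rpkm.tsv"))

cat(sprintf("cohort: %d miRNAs x %d samples (%s)\n",
            nrow(cohort$expr), ncol(cohort$expr),
            paste(table(cohort$meta$group), collapse = "/")))
cat(sprintf("planted: %d up, %d down, %d persistent\n",
            sum(cohort$truth$direction == "up"),
            sum(cohort$truth$direction == "down"),
            sum(cohort$truth$persistence == "persistent")))
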