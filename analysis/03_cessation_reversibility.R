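#!/usr/bin/env Rscript
# Classify the smoking-dependent signature as cessation-persistent
# (quitter vs nonsmoker p < 0.05, |FC| > 1.5) or reversible, quantify per-
# miRNA reversibility (% change on linear-scale means), and compare the
# quartile-based smoking-dependent miRNA index across the three groups
# (Kruskal-Wallis followed by Dunn's test).

library(saemir)

indir <- "results/cohort"
expr <- read_expression_matrix(file.path(indir, "expression_log2.tsv"))
meta <- read_sample_metadata(file.path(indir, "sample_metadata.tsv"))
truth <- read_results_table(file.path(indir, "truth.tsv"))
signature <- read_results_table("results/signature.tsv")

ces <- run_cessation(expr, meta, signature)
write_results_table(ces, "results/cessation.tsv")
tp <- truth$mirna_id[truth$persistence == "persistent"]
cat(sprintf("persistent: %d of %d signature miRNAs (%.0f%%); %.0f%% of planted persistents recovered\n",
            sum(ces$persistent), nrow(ces),
            100 * sum(ces$persistent) / nrow(ces),
            100 * mean(tp %in% ces$mirna_id[ces$persistent])))

curve <- reversal_fraction_curve(ces$percent_change, c(25, 50))
write_results_table(curve, "results/reversal_curve.tsv")
cat(sprintf("reversal: %.0f%% of miRNAs reversed <25%%, %.0f%% reversed <50%%\n",
            curve$fraction_below[1], curve$fraction_below[2]))

idx <- compute_index(expr, meta, signature)
write_results_table(idx, "results/mirna_index.tsv")
gm <- tapply(idx$index, idx$group, mean)
cmp <- index_group_comparison(idx)
cat(sprintf("index means: nonsmoker %.1f, smoker %.1f (%.1f-fold), quitter %.1f (%.1f-fold vs nonsmoker)\n",
            gm[["nonsmoker"]], gm[["smoker_baseline"]],
            gm[["smoker_baseline"]] / gm[["nonsmoker"]],
            gm[["quitter"]], gm[["quitter"]] / gm[["nonsmoker"]]))
cat(sprintf("Kruskal-Wallis H = %.2f, p = %.2g\n", cmp$H, cmp$p))
write_results_table(cmp$pairs, "results/index_dunn_pairs.tsv")
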