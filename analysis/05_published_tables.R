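#!/usr/bin/env Rscript
# Re-run the selection and persistence gates over the transcribed study
# tables: the 34-miRNA smoking signature and the 12 cessation-persistent
# miRNAs, gated at the precision the tables were printed with.

library(saemir)

cfg <- threshold_config()
t2 <- load_fixture_table("table2")
sel <- select_smoking_dependent(t2, cfg, printed_decimals = 1)
cat(sprintf("signature table: %d of %d miRNAs pass p<%.2g & |FC|>%.1f (%d up / %d down)\n",
            nrow(sel), nrow(t2), cfg$de_p, cfg$de_fc,
            sum(sel$direction == "up"), sum(sel$direction == "down")))
cat(sprintf("extremes: %s %+0.1f-fold, %s %+0.1f-fold\n",
            t2$probeset_id[which.max(t2$fold_change)], max(t2$fold_change),
            t2$probeset_id[which.min(t2$fold_change)], min(t2$fold_change)))

t4 <- load_fixture_table("table4")
per <- classify_persistence(
  data.frame(mirna_id = t4$probeset_id, direction = t4$direction),
  data.frame(mirna_id = t4$probeset_id, fold_change = t4$fold_change,
             p_value = t4$p_value),
  cfg, printed_decimals = 1)
cat(sprintf("persistence table: %d of %d pass p<%.2g & |FC|>%.1f — %d%% of the signature\n",
            sum(per$persistent), nrow(t4), cfg$persist_p, cfg$persist_fc,
            round(100 * sum(per$persistent) / nrow(sel))))
write_results_table(sel, "results/table2_regated.tsv")
write_results_table(per, "results/table4_regated.tsv")
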