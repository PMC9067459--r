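#!/usr/bin/env Rscript
# Spike-in-normalized ddCt quantification across polysome fraction pools.
#
# Emulates the fraction-pool qPCR: a pro-growth transcript whose
# dense-polysome abundance halves after 15 min of starvation (partial, not
# complete, runoff), a very long transcript that stays in heavy fractions,
# and a stress-induced transcript that rises in the total pool. Ct tables
# are generated with 0.2-cycle noise and 3 replicates, then folded back
# through the spike-normalized ddCt quantifier.

library(riboshift)

dir.create("results", showWarnings = FALSE)

truth <- rbind(
  data.frame(gene_id = "growth_gene", pool = "dense_poly",
             condition = c("log", "starved"), abundance = c(10, 5)),
  data.frame(gene_id = "long_gene", pool = "dense_poly",
             condition = c("log", "starved"), abundance = c(4, 3)),
  data.frame(gene_id = "stress_gene", pool = "total",
             condition = c("log", "starved"), abundance = c(1, 12)))

tab <- generate_ct_table(truth, spike_amount = 2, ct_noise_sd = 0.2,
                         n_replicates = 3, seed = 1)
write.table(format(tab, digits = 4), "results/ct_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

quant <- do.call(rbind, lapply(unique(truth$gene_id), function(g) {
  pool <- truth$pool[truth$gene_id == g][1]
  q <- delta_delta_ct(tab, g, pool, "starved", "log")
  tr <- truth$abundance[truth$gene_id == g]
  data.frame(gene_id = g, pool = pool, fold = q$fold, sem = q$sem,
             true_fold = tr[2] / tr[1])
}))
write.table(format(quant, digits = 3), "results/ddct_folds.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("ddCt fold changes (starved / log), spike-normalized:\n")
print(quant, digits = 3)
cat("\nThe growth gene drops ~twofold out of dense polysomes while the\n")
cat("long gene leaves only modestly and the stress gene is induced.\n")
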