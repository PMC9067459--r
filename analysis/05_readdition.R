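#!/usr/bin/env Rscript
# Glucose readdition: the wave of new initiations and resumed elongation.
#
# After 30 min of simulated starvation glucose returns: initiation is
# restored and elongation restarts at the calibrated post-restart rate.
# Measured here: (1) the extent of the wave of newly initiated ribosomes at
# 5 min (95th-percentile footprint position on genes > 3,000 nt, ~2,200 nt);
# (2) bimodal footprint distributions on very long genes (new 5' wave plus
# the 3' population that built up during starvation); (3) the reporter-level
# LTM/CHX treatment differences showing that early post-readdition protein
# output comes from ribosomes loaded before readdition.

library(riboshift)

dir.create("results", showWarnings = FALSE)

waves <- sapply(1:10, function(s) readdition_wave_extent(seed = s)$wave_nt)
cat(sprintf("Readdition wave extent at 5 min: %.0f nt (SEM %.0f, 10 seeds)\n",
            mean(waves), sd(waves) / sqrt(length(waves))))

flags <- sapply(1:10, function(s) {
  sc <- build_scenario("readdition", list(snapshot_times_s = 2100,
                                          duration_s = 2100))
  sim <- simulate_scenario(sc, seed = s)
  i <- which(sc$genes$gene_id == "g6000")
  pos_nt <- 3 * (sim$per_gene[[i]][[1]]$positions - 1) + 1
  is_bimodal(pos_nt, sc$genes$cds_length_nt[i])
})
cat(sprintf("Bimodal 6,000-nt gene profiles at 5 min readdition: %d/10 seeds\n",
            sum(flags)))

# reporter assay: LTM (initiation block) vs CHX (elongation block)
pre <- seq(1400, 2050, by = 50)
un <- lapply(1:6, function(r)
  generate_readdition_curves(pre, treatment = "none", noise_cv = 0.05,
                             seed = r))
ltm <- lapply(1:6, function(r)
  generate_readdition_curves(pre, treatment = "ltm", noise_cv = 0.05,
                             seed = 100 + r))
chx <- lapply(1:6, function(r)
  generate_readdition_curves(pre, treatment = "chx", noise_cv = 0.05,
                             seed = 200 + r))

res <- rbind(
  data.frame(inhibitor = "ltm", at_min = 5,
             as.data.frame(treatment_difference(un, ltm, 300)[c("mean_difference", "sem", "p_value")])),
  data.frame(inhibitor = "ltm", at_min = 15,
             as.data.frame(treatment_difference(un, ltm, 900)[c("mean_difference", "sem", "p_value")])),
  data.frame(inhibitor = "chx", at_min = 5,
             as.data.frame(treatment_difference(un, chx, 300)[c("mean_difference", "sem", "p_value")])),
  data.frame(inhibitor = "chx", at_min = 15,
             as.data.frame(treatment_difference(un, chx, 900)[c("mean_difference", "sem", "p_value")])))
write.table(format(res, digits = 3), "results/readdition_treatment_diff.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nTreatment differences (untreated minus treated signal accrual):\n")
print(res, digits = 3)
cat("\nLTM leaves 5-min output untouched (pre-loaded ribosomes finish),\n")
cat("but reduces 15-min output (new initiations start contributing);\n")
cat("CHX suppresses output at both times.\n")
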