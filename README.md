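# riboshift

Translation elongation analysis for acute glucose starvation in budding
yeast — with a built-in generative model so every statistic is testable
against known truth.

## The problem

When exponentially growing yeast abruptly loses glucose, translation
initiation shuts down within seconds, yet ribosomes do not simply run off
their mRNAs: elongation itself slows progressively, so ribosomes build up on
the downstream (3') halves of transcripts, short genes empty out while long
genes stay occupied, and the stalled ribosomes can resume and finish their
proteins when glucose returns. riboshift packages the statistics used to
establish this picture, for people analyzing ribosome profiling and
reporter-kinetics data under nutrient stress:

* **Polarity score** per gene: with footprint densities
  $d_i = c_i/\sum c$ and weights $w_i = \frac{2i-(L+1)}{L-1}$ over CDS
  positions $i = 1..L$, the score $\sum_i d_i w_i \in [-1, 1]$ is negative
  for 5'-skewed and positive for 3'-skewed ribosome distributions.
  Distributions are compared across conditions over genes with >25 reads.
* **Metagene density**: start-codon-aligned, depth-normalized aggregate
  footprint density over genes >1,000 nt with >25 reads, plus a
  start-codon density-drop statistic and a centroid-displacement transit
  proxy for time courses.
* **Ribosome occupancy (RO)**: $\log_2(\mathrm{RPF}/\mathrm{mRNA})$ per
  gene with TPM normalization, and the printed classification rules
  (mRNA log2 FC > 2.5 and RO log2 FC > 0.09 → upregulated; >4-fold mRNA
  increase; top-150 mean TPM), read-category budgets, and RO-change versus
  gene length.
* **Schleif-plot elongation rates**: paired inducible Nluc / LacZ-Nluc
  luciferase curves linearized as $\sqrt{S}$ vs $t$; onset times
  subtracted, corrected for transcription (2,000 nt/min through the
  3,072-nt LacZ ORF), giving
  $k = \frac{L_{aa}}{\Delta T - t_{txn}}$ in aa/s; plus the LTM/CHX
  treatment-difference analysis of post-readdition protein output.
* **Spike-in-normalized ΔΔCt** across polysome fraction pools
  (total / free / monosome / di-tri / dense).

All of it runs without any external download: a TASEP (totally asymmetric
simple exclusion process) ribosome-traffic simulator with time-dependent
initiation/elongation schedules, an mRNA induction model and multinomial
sequencing sampling generates footprint libraries for log phase, acute
starvation, heat shock, initiation-only stresses, postdiauxic shift,
stationary phase and glucose readdition; a reporter-curve generator does the
same for the luciferase assays. Real data enters through plain GFF3 /
bedGraph / TSV readers.

## Worked example

Fifteen simulated minutes of acute starvation, compared with log phase:

```r
library(riboshift)

sc  <- build_scenario("starvation", list(snapshot_times_s = 900, duration_s = 900))
sim <- simulate_scenario(sc, seed = 1)
reads <- sample_sequencing(snapshots_to_profiles(sim, 900),
                           sc$sequencing_depth, seed = 1)
stv <- polarity_distribution(reads, min_reads = 25)

base <- simulate_scenario(build_scenario("log_phase",
          list(snapshot_times_s = 0, duration_s = 1)), seed = 1)
lp <- polarity_distribution(sample_sequencing(snapshots_to_profiles(base, 0),
                                              1e6, seed = 1), min_reads = 25)
polarity_shift(lp, stv)

measure_elongation_rate(k_aa_per_s = 5, noise_cv = 0.1, n_replicates = 4, seed = 1)
```

prints

```
<polarity_dist> 17 genes (> 25 reads), mean 0.082, median 0.082   # starved
<polarity_dist> 18 genes (> 25 reads), mean -0.049, median -0.045 # log phase
polarity shift (starved - log): +0.131 mean, +0.127 median
<elongation_estimate> 4.53 aa/s (SEM 0.25, n=4)
```

The positive shift is the 3' build-up of slowed ribosomes (one gene also
dropped below the read filter — a short gene running off); the
reporter-assay estimate recovers the generative 5 aa/s elongation rate to
within its replicate error, inside the 3-10 aa/s basal range for growing
yeast.

The `analysis/` directory holds the full narrative as numbered drivers —
`01_stress_panel.R` (stress-specific polarity signs), `02_starvation_timecourse.R`
(saturating polarity/transit dynamics), `03_occupancy_classes.R`
(classification and read budgets), `04_elongation_rates.R` (rate recovery),
`05_readdition.R` (initiation wave, bimodal long genes, LTM/CHX timing),
`06_polysome_ddct.R` (fraction-pool quantification) — each writing its
tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the median
elongation rate recovered by the Schleif estimator from synthetic 5 aa/s
log-phase curves (50 seeds, 10% noise, 4 replicates); the time at which the
starvation-preset polarity first exceeds the matched log-phase baseline
(15-s snapshots, genes >1,000 nt with >25 reads); and the extent of the
post-readdition initiation wave at 5 min (95th-percentile footprint
position of newly initiated ribosomes on genes >3,000 nt), writing one JSON
number per target.
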