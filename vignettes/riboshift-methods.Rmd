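---
title: "Models and methods behind riboshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riboshift studies how translation elongation is regulated when exponentially
growing yeast abruptly loses glucose. The package implements the analysis
statistics (polarity scores, metagene densities, occupancy classification,
Schleif-plot elongation rates, spike-normalized ddCt) together with the
generative models that make every statistic testable against known truth.
This vignette records the models, their assumptions, and the numerical and
design choices a maintainer would want to know about.

## The ribosome traffic model

The synthetic footprint data comes from a totally asymmetric simple
exclusion process (TASEP) with extended particles. Each mRNA copy is a
lattice of `L` codons; a ribosome occupies `ell = 10` codons (~30 nt, the
footprint size). Initiation places a ribosome at codon 1 at rate
`alpha(t)` if the first `ell` codons are free; a ribosome at codon `j` hops
to `j + 1` at rate `k(t, j)` if the ribosome ahead is more than `ell` codons
away; the ribosome at the last codon terminates at rate `beta = 10`/s
(deliberately non-limiting). The simulation is an exact event-driven kinetic
Monte Carlo; time-dependent rates are handled by Poisson thinning against
piecewise-constant upper bounds, refreshed on short windows within which all
schedules are non-increasing. Nothing is tau-leaped; exactness is cheap at
desk scale.

The source papers describe the stress response verbally (ribosomes "slow
down and build up"); they propose no equations, so the generative model is
this package's own construction and all quantitative claims about it are
claims about this stated world, not about the original measurements.

Baseline (log-phase) kinetics: initiation `alpha0 = 0.1`/s per mRNA and
elongation `k0 = 5` codons/s, the middle of the 3-10 aa/s basal range
reported for growing yeast. At these rates a gene carries about
`alpha0 * L / k0` ribosomes, e.g. ~8 on a PGK1-length CDS, and per-gene
polarity fluctuates around zero.

### Stress schedules

* **Acute glucose starvation.** Initiation collapses exponentially with
  `tau = 5` s to a 2% residual floor (the shutdown is reported to act within
  seconds; the floor keeps short genes sparsely occupied rather than empty —
  "more devoid", not devoid). Elongation decays hyperbolically,
  `k(t) = k0 / (1 + t/tau_k)` with `tau_k = 20` s. The hyperbolic form (over
  an exponential) makes the polarity shift fast at first and then saturating,
  matching the observation that neither the polarity change nor the
  start-codon density drop is proportional to elapsed time. `tau_k = 20` s
  was chosen so the mean ribosome displacement is ~380 codons by 15 min and
  ~450 by 30 min: a 1,251-nt (417-codon) PGK1-like CDS then still carries
  pre-stress ribosomes at 15 min, runoff is complete on short genes and
  incomplete on long ones, and the 3' population needed for the readdition
  bimodality survives 30 min of starvation. A slower decay (e.g. tau_k on
  the order of 2 min) sweeps every gene clean and contradicts those anchor
  observations.
* **Heat shock.** Elongation is cut 10-fold over the first 33 codons
  (~60-100 nt downstream of the start codon), unchanged elsewhere: ribosomes
  jam early in the CDS and polarity shifts negative.
* **Initiation-only stress** (oxidative / amino-acid starvation style).
  Initiation is cut to 20%, elongation untouched: the steady state re-forms
  at lower loading with an unchanged density profile, so polarity is
  unchanged — these stresses are the negative controls.
* **Postdiauxic shift.** Gradual glucose exhaustion: initiation decays with
  `tau = 120` s to a 5% floor and elongation decays with `tau_k = 120` s.
  Slower than acute starvation, same direction: polarity shifts positive.
* **Stationary phase.** Initiation and elongation both scaled to 10%.
  Scaling both rates together leaves the steady-state density profile (and
  hence polarity) unchanged — the model's explanation for polarity returning
  to center after 5 days.
* **Glucose readdition.** Starvation kinetics for 30 min, then initiation
  restored to `alpha0` and elongation restarted at a constant
  `k_post = 2.7` codons/s. `k_post` is a calibrated parameter: it is fixed
  so that the 95th-percentile footprint position of post-readdition
  initiations on genes > 3,000 nt lands near the printed ~2,200 nt at 5 min.
  The naive inversion 2,200 nt / (300 s x 3 nt/codon) = 2.4 codons/s ignores
  steric exclusion: at restored initiation pressure the bulk wave moves
  ~8-10% slower than the bare hop rate, so the calibrated value is higher.
  The calibration was performed once against the generative model and
  frozen.

Stress-induced genes (the `hs*` panel entries) run log-phase kinetics inside
every stress scenario — they escape the initiation shutdown — and their mRNA
copy number approaches an 8-fold target exponentially (`tau = 300` s), so at
15 min they sit ~7.7-fold induced, above the 4-fold classification rule.
Their growing copy number is applied as a deterministic weight on the
per-copy steady profile rather than spawning new lattice copies mid-run; the
approximation overstates ribosome load on the very newest transcripts but is
invisible at the depths sampled.

### The simulated gene panel

18 CDSs from 300 to 7,002 nt, including a 1,251-nt glycolytic
("PGK1-like") gene, with copy numbers falling off with length (3-60) the
way abundant transcripts do, plus four short stress-induced genes starting
at 2 copies. Sequencing is modeled as a single multinomial draw of 1e6
reads over all (gene, position) cells proportional to copy-weighted
occupancy; mRNA-seq counts are drawn with weights copy_number x length.
Three stochastic copies are simulated per gene (`copies_sim`) and rescaled
to the nominal copy numbers — this trades per-gene granularity for speed
and is the main source of per-gene polarity noise at fixed depth, which is
why distribution-level checks average over seeds.

What the generator does **not** emulate: UTR and non-CDS reads, footprint
size heterogeneity and P-site offset uncertainty (counts land exactly on the
P-site first nucleotide; an offset is only a config concern for real data),
codon-specific dwell times, disomes, library-preparation biases, and
harvesting artifacts (the CHX-pretreatment effects discussed in the source
literature). A green test therefore establishes that the statistics behave
correctly on clean traffic dynamics, not that they are robust to every
artifact of real libraries.

## Analysis statistics

**Polarity.** With per-nucleotide densities `d_i = c_i / sum(c)` and linear
weights `w_i = (2i - (L+1)) / (L-1)`, the score `sum(d_i * w_i)` lies in
[-1, 1]. The cited methodology does not print the formula; this linear-weight
form is fixed as this package's contract. Scores are computed at nucleotide
resolution (the traces are per-nt). Genes with zero reads are excluded, not
imputed; the distribution filter is the printed strict ">25 reads".
Distribution smoothing (Gaussian kernel, Silverman bandwidth) is for
plotting only — no statistic depends on it.

**Metagene density.** Genes passing the strict ">1,000 nt, >25 reads"
filters are aligned at the start codon, summed per offset, and scaled per
million mapped reads. The start-codon drop statistic normalizes each
metagene to its own 151-1,000-nt mean before differencing, making it robust
to depth and gene-set composition; a value of -1 means the near-start window
emptied completely relative to the gene body.

**Transit proxy.** The supplementary material gives no formula for transit
rates; the package's proxy is the read-weighted centroid displacement per
minute. It is a population statistic: it can legitimately go negative late
in starvation when 3'-most ribosomes terminate while residual initiation
refills the 5' end. The same caveat applies to the polarity-versus-length
summary; both are declared proxies, part of this package's contract.

**Occupancy and classification.** RO is `log2(RPF/mRNA)`, computed on TPM
by default (the sources do not say; length bias cancels in fold changes
either way, and the choice is config-exposed). Fold changes receive a +0.5
pseudocount on zero counts only (occupancy definedness is untouched). The
printed thresholds are applied verbatim and strictly: mRNA log2 FC > 2.5
with RO log2 FC > 0.09 (the odd 0.09 is unexplained at source and adopted
as-is), 4-fold induction, top-150 mean TPM with deterministic
gene-id tie-breaking. The printed "149 genes" depends on the original
deposited data and is recovered only as rule-recovery on simulated truth.

**Reporter kinetics and the Schleif estimator.** Induction curves follow
`S(t) = r/lambda^2 (lambda*tau - 1 + exp(-lambda*tau))`, `tau = t - T`, the
closed form of a linear synthesis ramp with first-order (PEST, 5-min
half-life) decay; `lambda -> 0` recovers the pure quadratic `r tau^2/2`.
The onset is `T = T_base + orf_nt/txn_speed + (orf_nt/3)/k` with
`T_base = 300` s shared between reporters (induction, reporter synthesis
and maturation), which cancels in the subtraction — the same assumption the
assay itself makes. Noise is multiplicative log-normal per 30-s sample.

The Schleif fit linearizes the rise as sqrt(signal) vs time and reports the
x-intercept. Two numerical choices matter and deviate deliberately from the
obvious ones:

1. *Window on the sqrt scale.* A window set as 10-60% of the raw signal
   maximum drifts deep into the decay-bent region for PEST reporters, and
   does so asymmetrically between the short control and the long fusion —
   at 1 aa/s that alone pushes the recovered rate past 15% error. The
   default window is instead 10-60% of max(sqrt(signal)), which brackets the
   near-linear regime on the fitted scale. Both bounds are exposed.
2. *Inverse-variance weighting.* Under multiplicative noise
   sd(sqrt(S)) grows with S, so the line is fitted by WLS with weights
   1/S. With OLS the k = 8-10 grid points showed 15-17% median error;
   with WLS every point in the k = 1-10 grid recovers with <= 11% median
   error (50 seeds, 10% noise, 4 replicates).

The baseline is the median of the first five samples (reads taken before
induction takes hold). The elongation rate inverts the closed form:
`rate = (orf_nt/3) / (dT - orf_nt/txn_speed)` with the printed constants
(3,072 nt LacZ, 2,000 nt/min transcription). Pairs with `dT` at or below
the transcription time are flagged "faster than resolvable" rather than
errored. The residual ~8% underestimate of the noiseless estimator is the
cost of fitting a decaying reporter with a straight line; it is documented
rather than corrected because the assay's published form does not correct
it either.

**Readdition reporters.** Pre-loaded ribosomes at codon `p` complete after
`(L - p)/k_post` s and contribute one unit convolved with PEST decay; new
initiations contribute a ramp delayed by one full transit `L/k_post`. LTM
removes only the new-initiation term; CHX removes all completions. With a
2,100-codon reporter and `k_post = 2.4` aa/s, new initiations complete at
~875 s: LTM therefore cannot change the 5-min signal (the pre-loaded
population is LTM-blind) but reduces the 15-min signal — the package's
operational restatement of the drug experiment.

**ddCt.** Classic Livak ordering: per-replicate delta-Ct against the
spike-in, condition means differenced, exponentiated with efficiency 2.0
(configurable; no standard-curve correction is described at source).
Per-replicate folds are retained for SEM. The generator writes
`Ct = c0 - log2(abundance) + N(0, sd)` with one spike row per
(pool, condition, replicate) group.

**Bimodality.** Hartigan's dip test is the natural tool but is not
available in the pinned environment, so the readdition two-population check
is a descriptive valley criterion: the kernel density (Silverman bandwidth
halved — the reference rule assumes unimodality and oversmooths separated
modes) is split at its deepest interior minimum; both sides must carry a
mode of at least 25% of the global peak, separated by at least 20% of the
CDS, with the valley below 60% of the smaller mode. On the stated world it
flags 10/10 readdition long-gene profiles and ~1/10 log-phase ones.

## Degenerate inputs and tie-breaking

Zero-read genes yield NA polarity and are excluded from distributions;
empty coverage files yield all-zero profiles; reads outside the CDS are
dropped with a warning (UTRs are out of scope); negative counts are errors.
TPM requires at least one nonzero count. The top-N abundance class breaks
ties by gene id so classification is deterministic. Every stochastic
routine takes an explicit seed, and multi-seed checks use 3 x SEM bands or
majority votes rather than single draws.

## Known limitations

* The traffic model is sequence-agnostic; it cannot reproduce codon-level
  pause sites or gene-specific elongation programs.
* The mRNA pool is deterministic (no transcription/decay noise), so
  mRNA-side dispersion is purely multinomial.
* The elongation-rate estimator inherits the Schleif method's assumptions
  (shared maturation constant, quadratic early rise); conditions that break
  the ramp assumption (substrate depletion, strong decay during the rise)
  bias it.
* The postdiauxic and stationary presets compress days-long physiology into
  a single kinetic schedule; they reproduce the direction and rough size of
  the polarity effects, nothing more.
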