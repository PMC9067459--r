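#' Polarity shift panel across stress presets
#'
#' Simulates each requested preset alongside a matched log-phase library and
#' reports the shift in mean/median polarity (stress minus log phase) over
#' genes passing the read filter — the stress-specificity comparison:
#' glucose withdrawal (and the postdiauxic shift) move polarity positive,
#' heat shock moves it negative, initiation-only stresses and stationary
#' phase leave it near zero.
#'
#' @param presets preset names to run (default: all stress presets).
#' @param seeds integer vector; results are averaged over seeds.
#' @param snapshot_s snapshot time (s past stress onset).
#' @param min_reads polarity read filter (strict >).
#' @param overrides scenario overrides applied to every preset.
#' @return data.frame: preset, delta_mean, delta_median, n_genes (mean over
#'   seeds).
#' @export
run_stress_panel <- function(presets = c("starvation", "heat_shock",
                                         "initiation_only", "postdiauxic",
                                         "stationary"),
                             seeds = 1:3, snapshot_s = 900, min_reads = 25,
                             overrides = list()) {
  rows <- lapply(presets, function(pr) {
    per_seed <- vapply(seeds, function(sd) {
      ov <- overrides
      ov$snapshot_times_s <- snapshot_s
      ov$duration_s <- snapshot_s
      base_sc <- build_scenario("log_phase", ov)
      stress_sc <- build_scenario(pr, ov)
      base <- .preset_polarity(base_sc, sd, snapshot_s, min_reads)
      stress <- .preset_polarity(stress_sc, sd, snapshot_s, min_reads)
      sh <- polarity_shift(base, stress)
      c(sh$delta_mean, sh$delta_median, nrow(stress$scores))
    }, numeric(3))
    data.frame(preset = pr,
               delta_mean = mean(per_seed[1, ]),
               delta_median = mean(per_seed[2, ]),
               n_genes = mean(per_seed[3, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.preset_polarity <- function(scenario, seed, snapshot_s, min_reads) {
  sim <- simulate_scenario(scenario, seed = seed)
  prof <- snapshots_to_profiles(sim, snapshot_s)
  reads <- sample_sequencing(prof, scenario$sequencing_depth, seed = seed)
  polarity_distribution(reads, min_reads = min_reads)
}

#' Starvation time-course analysis
#'
#' Simulates the starvation preset with snapshots at the profiled timepoints
#' and computes, per timepoint: the mean polarity over filtered genes, the
#' start-codon density-drop magnitude versus the previous timepoint, and the
#' mean transit-rate proxy on long genes between consecutive snapshots. Also
#' evaluates the saturation property — the polarity shift per elapsed minute
#' decreases as starvation progresses.
#'
#' @param times_min snapshot times in minutes.
#' @param seed RNG seed.
#' @param min_len_nt,min_reads metagene/polarity filters.
#' @param long_gene_nt length threshold for the transit proxy.
#' @param overrides scenario overrides.
#' @return list: `polarity` (time, mean/median polarity), `start_drop`,
#'   `transit`, `saturating` (logical).
#' @export
run_timecourse <- function(times_min = c(1, 5, 10, 15, 20, 30), seed = 1,
                           min_len_nt = 1000, min_reads = 25,
                           long_gene_nt = 3000, overrides = list()) {
  if (length(times_min) == 0) stop("empty snapshot list")
  times_s <- times_min * 60
  ov <- overrides
  ov$snapshot_times_s <- times_s
  ov$duration_s <- max(times_s)
  sc <- build_scenario("starvation", ov)
  sim <- simulate_scenario(sc, seed = seed)
  genes <- sc$genes

  prof_t <- lapply(seq_along(times_s), function(i) {
    p <- snapshots_to_profiles(sim, times_s[i])
    sample_sequencing(p, sc$sequencing_depth, seed = seed + i)
  })

  pol <- do.call(rbind, lapply(seq_along(times_s), function(i) {
    d <- polarity_distribution(prof_t[[i]], min_reads = min_reads)
    keep <- genes$cds_length_nt[match(d$scores$gene_id, genes$gene_id)] > min_len_nt
    data.frame(time_min = times_min[i],
               mean_polarity = mean(d$scores$polarity[keep]),
               median_polarity = median(d$scores$polarity[keep]),
               n_genes = sum(keep))
  }))

  metas <- lapply(prof_t, function(p)
    metagene_density(p, genes, min_len_nt = min_len_nt, min_reads = min_reads,
                     total_mapped_reads = sc$sequencing_depth))
  drops <- if (length(times_s) > 1)
    data.frame(
      from_min = times_min[-length(times_min)], to_min = times_min[-1],
      drop = vapply(seq_len(length(metas) - 1), function(i)
        start_drop_magnitude(metas[[i]], metas[[i + 1]]), numeric(1)))
  else NULL

  long <- genes$gene_id[genes$cds_length_nt > long_gene_nt & !genes$induced]
  transit <- if (length(times_s) > 1)
    data.frame(
      from_min = times_min[-length(times_min)], to_min = times_min[-1],
      nt_per_min = vapply(seq_len(length(prof_t) - 1), function(i) {
        v <- vapply(long, function(g) {
          transit_rate_proxy(prof_t[[i]][[g]], prof_t[[i + 1]][[g]],
                             times_min[i + 1] - times_min[i])
        }, numeric(1))
        mean(v, na.rm = TRUE)
      }, numeric(1)))
  else NULL

  saturating <- if (nrow(pol) > 1) {
    per_min <- diff(c(0, pol$mean_polarity)) / diff(c(0, pol$time_min))
    per_min[1] > per_min[length(per_min)]
  } else NA

  list(polarity = pol, start_drop = drops, transit = transit,
       saturating = saturating, seed = seed)
}

#' Time for starvation polarity to exceed the log-phase baseline
#'
#' Runs matched log-phase and starvation simulations with fine-grained
#' snapshots and returns the first snapshot time at which mean polarity over
#' filtered long genes exceeds the log-phase baseline mean.
#'
#' @param seed RNG seed.
#' @param snapshot_every_s snapshot spacing (s).
#' @param horizon_s last snapshot (s).
#' @param min_len_nt,min_reads gene filters (strict >).
#' @return list: `crossing_min` (NA if never crossed), `baseline_mean`,
#'   `trace` data.frame.
#' @export
polarity_onset_time <- function(seed = 1, snapshot_every_s = 15,
                                horizon_s = 120, min_len_nt = 1000,
                                min_reads = 25) {
  times_s <- seq(snapshot_every_s, horizon_s, by = snapshot_every_s)
  ov <- list(snapshot_times_s = times_s, duration_s = horizon_s)
  stv <- simulate_scenario(build_scenario("starvation", ov), seed = seed)
  base_sc <- build_scenario("log_phase",
                            list(snapshot_times_s = 0, duration_s = 1))
  base_sim <- simulate_scenario(base_sc, seed = seed)
  sc <- stv$scenario
  genes <- sc$genes

  mean_pol <- function(sim, t, s_off) {
    prof <- snapshots_to_profiles(sim, t)
    reads <- sample_sequencing(prof, sc$sequencing_depth, seed = seed + s_off)
    d <- polarity_distribution(reads, min_reads = min_reads)
    keep <- genes$cds_length_nt[match(d$scores$gene_id, genes$gene_id)] > min_len_nt
    mean(d$scores$polarity[keep])
  }
  baseline <- mean_pol(base_sim, 0, 0)
  trace <- vapply(seq_along(times_s), function(i)
    mean_pol(stv, times_s[i], i), numeric(1))
  crossed <- which(trace > baseline)
  list(crossing_min = if (length(crossed)) times_s[crossed[1]] / 60 else NA_real_,
       baseline_mean = baseline,
       trace = data.frame(time_min = times_s / 60, mean_polarity = trace))
}

#' Extent of the newly-initiated ribosome wave after glucose readdition
#'
#' Runs the readdition preset, tags ribosomes initiated after glucose
#' returns, and measures the 95th-percentile footprint position (nt) of the
#' tagged population on long genes at the requested time after readdition —
#' the extent of the wave of new initiations.
#'
#' @param seed RNG seed.
#' @param at_min minutes after readdition.
#' @param min_len_nt only genes with CDS longer than this contribute.
#' @param prob quantile reported.
#' @param overrides extra scenario overrides (e.g. `k_readd`).
#' @return list: `wave_nt`, `n_tagged`, `positions_nt` (tagged, pooled).
#' @export
readdition_wave_extent <- function(seed = 1, at_min = 5, min_len_nt = 3000,
                                   prob = 0.95, overrides = list()) {
  t_re <- 1800
  snap <- t_re + at_min * 60
  ov <- overrides
  ov$snapshot_times_s <- snap
  ov$duration_s <- snap
  sc <- build_scenario("readdition", ov)
  sim <- simulate_scenario(sc, seed = seed)
  g <- sc$genes
  keep <- which(g$cds_length_nt > min_len_nt & !g$induced)
  pos_nt <- unlist(lapply(keep, function(i) {
    snap_dat <- sim$per_gene[[i]][[1]]
    tagged <- snap_dat$init_times > t_re
    3 * (snap_dat$positions[tagged] - 1) + 1
  }))
  list(wave_nt = if (length(pos_nt)) quantile(pos_nt, prob, names = FALSE)
       else NA_real_,
       n_tagged = length(pos_nt), positions_nt = pos_nt)
}

#' Two-population (bimodality) check for a footprint profile
#'
#' Detects the readdition signature — a 5' wave of newly initiated ribosomes
#' coexisting with the 3' population that built up during starvation — as
#' two well-separated kernel-density modes with a deep valley between them.
#' This is a descriptive valley-depth criterion (no installed package
#' provides Hartigan's dip test): the kernel density is split at its deepest
#' interior minimum; the profile is called bimodal when each side carries a
#' substantial mode (at least `side_frac` of the global peak), the two side
#' modes are separated by at least `min_separation` of the CDS, and the
#' valley lies below `valley_frac` of the smaller side mode.
#'
#' @param positions_nt footprint positions (nt) along one CDS.
#' @param cds_length_nt CDS length.
#' @param valley_frac valley depth criterion.
#' @param min_separation minimum mode separation as a fraction of the CDS.
#' @param side_frac minimum height of each side mode relative to the global
#'   density peak.
#' @param adjust bandwidth factor on the Silverman reference rule; the
#'   default halves it, since the reference rule assumes unimodality and
#'   oversmooths well-separated modes.
#' @return logical.
#' @export
is_bimodal <- function(positions_nt, cds_length_nt, valley_frac = 0.6,
                       min_separation = 0.2, side_frac = 0.25,
                       adjust = 0.5) {
  if (length(positions_nt) < 20) return(FALSE)
  d <- density(positions_nt, from = 1, to = cds_length_nt, n = 512,
               adjust = adjust)
  y <- d$y
  interior <- which(d$x > 0.1 * cds_length_nt & d$x < 0.9 * cds_length_nt)
  iv <- interior[which.min(y[interior])]
  left <- y[seq_len(iv - 1)]
  right <- y[seq(iv + 1, length(y))]
  if (!length(left) || !length(right)) return(FALSE)
  lmax <- max(left); rmax <- max(right)
  if (min(lmax, rmax) < side_frac * max(y)) return(FALSE)
  sep <- d$x[iv + which.max(right)] - d$x[which.max(left)]
  if (sep / cds_length_nt < min_separation) return(FALSE)
  y[iv] < valley_frac * min(lmax, rmax)
}
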