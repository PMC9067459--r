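#' Default simulated gene panel
#'
#' A fixed panel of CDSs spanning 300-7,002 nt, including a 1,251-nt
#' glycolytic ("PGK1-like") gene, with baseline mRNA copy numbers falling off
#' with length the way abundant yeast transcripts do, plus four short
#' stress-induced genes held at low copy number pre-stress.
#'
#' @return gene model data.frame with `codons` and `induced` columns added.
#' @export
sim_gene_panel <- function() {
  g <- gene_models(
    gene_id = c("g0300", "g0600", "g0900", "gPGK1", "g1500", "g1800",
                "g2400", "g3000", "g3600", "g4200", "g5100", "g6000",
                "g6600", "g7002",
                "hs0600", "hs0900", "hs1200", "hs1500"),
    cds_length_nt = c(300, 600, 900, 1251, 1500, 1800, 2400, 3000, 3600,
                      4200, 5100, 6000, 6600, 7002,
                      600, 900, 1200, 1500),
    tags = c("ribi", "ribi", "ribi", "glycolytic", "", "", "", "", "", "",
             "", "", "", "",
             rep("stress_induced", 4)),
    copies = c(12, 20, 25, 60, 30, 25, 18, 14, 10, 8, 6, 5, 4, 3,
               2, 2, 2, 2)
  )
  g$codons <- g$cds_length_nt %/% 3L
  g$induced <- g$tags == "stress_induced"
  g
}

.presets <- c("log_phase", "starvation", "heat_shock", "initiation_only",
              "postdiauxic", "stationary", "readdition")

.default_schedule <- function() {
  list(t_stress = 0, t_readd = Inf,
       alpha0 = 0.1, alpha_mode = 0L, alpha_tau = 5, alpha_floor = 0.02,
       alpha_factor = 1, alpha_readd = 0.1,
       k0 = 5, k_mode = 0L, k_tau = 120, k_factor = 1, k_readd = 2.7,
       k_slow_codon_max = 0L, k_slow_factor = 1)
}

#' Build a simulation scenario from a preset
#'
#' Presets encode the kinetic regimes of the conditions studied:
#'
#' * `log_phase`: constant initiation (0.1/s per mRNA) and elongation
#'   (5 codons/s, the middle of the 3-10 aa/s basal range).
#' * `starvation`: initiation collapses within seconds (exponential decay,
#'   tau 5 s, 2 percent residual floor) while elongation slows
#'   hyperbolically, k(t) = k0/(1 + t/tau) with tau = 20 s, chosen so the
#'   mean ribosome displacement by 15 min (~380 codons) leaves a PGK1-length
#'   CDS still occupied by pre-stress ribosomes (incomplete runoff).
#' * `heat_shock`: elongation reduced 10-fold over the first 33 codons
#'   (~60-100 nt downstream of the start), unchanged elsewhere.
#' * `initiation_only`: initiation cut to 20 percent, elongation untouched
#'   (oxidative / amino-acid starvation style).
#' * `postdiauxic`: gradual glucose exhaustion; initiation decays with tau
#'   120 s to a 5 percent floor, elongation slows as in starvation.
#' * `stationary`: initiation and elongation both scaled to 10 percent,
#'   leaving the steady-state density profile unchanged.
#' * `readdition`: starvation for 30 min, then initiation restored to 0.1/s
#'   and elongation restarted at a constant post-restart rate
#'   (2.7 codons/s, calibrated so the 5-min wave of new initiations spans
#'   ~2,200 nt; see the methods vignette).
#'
#' Stress-induced panel genes always run log-phase kinetics (they escape the
#' initiation shutdown) and their mRNA copy number grows per
#' [simulate_mrna_pool()].
#'
#' @param preset one of the names above.
#' @param overrides named list overriding scenario fields (e.g. `k0`,
#'   `alpha0`, `snapshot_times_s`, `genes`, `copies_sim`,
#'   `sequencing_depth`, any schedule field).
#' @return object of class `sim_scenario`.
#' @export
build_scenario <- function(preset, overrides = list()) {
  if (!preset %in% .presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(.presets, collapse = ", "))
  sched <- .default_schedule()
  snap <- 900
  t_end <- 900
  if (preset == "starvation") {
    sched$alpha_mode <- 1L
    sched$k_mode <- 1L
    sched$k_tau <- 20
  } else if (preset == "heat_shock") {
    sched$k_slow_codon_max <- 33L
    sched$k_slow_factor <- 0.1
  } else if (preset == "initiation_only") {
    sched$alpha_mode <- 2L
    sched$alpha_factor <- 0.2
  } else if (preset == "postdiauxic") {
    sched$alpha_mode <- 1L
    sched$alpha_tau <- 120
    sched$alpha_floor <- 0.05
    sched$k_mode <- 1L
  } else if (preset == "stationary") {
    sched$alpha_mode <- 2L
    sched$alpha_factor <- 0.1
    sched$k_mode <- 2L
    sched$k_factor <- 0.1
  } else if (preset == "readdition") {
    sched$alpha_mode <- 1L
    sched$k_mode <- 1L
    sched$k_tau <- 20
    sched$t_readd <- 1800
    snap <- 2100
    t_end <- 2100
  }
  sc <- list(
    preset = preset,
    genes = sim_gene_panel(),
    schedule = sched,
    ell = 10L,                 # footprint, codons (~30 nt)
    beta = 10,                 # termination rate, /s (non-limiting)
    burn_in_s = 600,           # pre-stress equilibration
    duration_s = t_end,
    snapshot_times_s = snap,
    copies_sim = 3L,           # stochastic copies simulated per gene
    sequencing_depth = 1e6,
    mrna_depth = 1e6,
    induction_fold = 8,        # stress-induced mRNA copy target
    induction_tau_s = 300
  )
  for (nm in names(overrides)) {
    if (nm %in% names(sc$schedule)) sc$schedule[[nm]] <- overrides[[nm]]
    else sc[[nm]] <- overrides[[nm]]
  }
  # keep schedule shorthand overrides ('k0', 'alpha0') consistent
  structure(sc, class = "sim_scenario")
}

#' Run the exclusion-process traffic simulation for a scenario
#'
#' Each (gene, simulated copy) is an independent one-lane TASEP with extended
#' particles (footprint `ell` codons), simulated exactly by event-driven
#' kinetic Monte Carlo with Poisson thinning for the time-dependent rates.
#' Stress-induced genes use a constant log-phase schedule. The simulation
#' starts empty at `-burn_in_s` (log-phase kinetics) so the state at t = 0 is
#' a steady-state draw.
#'
#' @param scenario a [build_scenario()] object.
#' @param seed integer RNG seed (reproducible).
#' @return object of class `sim_result`: per snapshot time, a list per gene
#'   with pooled P-site codon `positions` and matching `init_times` across
#'   simulated copies; plus per-gene `n_init`/`n_term` bookkeeping.
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  set.seed(seed)
  g <- scenario$genes
  snap <- scenario$snapshot_times_s
  log_sched <- .default_schedule()
  log_sched$k0 <- scenario$schedule$k0
  log_sched$alpha0 <- scenario$schedule$alpha0
  per_gene <- vector("list", nrow(g))
  names(per_gene) <- g$gene_id
  n_init <- n_term <- setNames(numeric(nrow(g)), g$gene_id)
  for (i in seq_len(nrow(g))) {
    sched <- if (g$induced[i]) log_sched else scenario$schedule
    snaps <- replicate(scenario$copies_sim, simplify = FALSE,
      sim_tasep_cpp(L = g$codons[i], ell = scenario$ell,
                    beta = scenario$beta, schedule = sched,
                    t_start = -scenario$burn_in_s,
                    t_end = scenario$duration_s,
                    snapshot_times = as.numeric(snap),
                    init_positions = integer(0)))
    n_init[i] <- sum(vapply(snaps, `[[`, numeric(1), "n_init"))
    n_term[i] <- sum(vapply(snaps, `[[`, numeric(1), "n_term"))
    per_gene[[i]] <- lapply(seq_along(snap), function(s) {
      list(positions = unlist(lapply(snaps, function(x) x$positions[[s]])),
           init_times = unlist(lapply(snaps, function(x) x$init_times[[s]])))
    })
  }
  structure(list(scenario = scenario, snapshot_times_s = snap,
                 per_gene = per_gene, n_init = n_init, n_term = n_term,
                 seed = seed),
            class = "sim_result")
}

#' Convert a simulation snapshot to footprint profiles
#'
#' Each bound ribosome with P-site codon p contributes one count at CDS
#' nucleotide position 3(p-1)+1. Counts are averaged over the simulated
#' copies and scaled by the gene's mRNA copy number at the snapshot time
#' (growing for induced genes), giving expected footprint abundances.
#'
#' @param sim a [simulate_scenario()] result.
#' @param snapshot_time one of the scenario's snapshot times (s).
#' @param library_id attached to the returned profiles.
#' @param weight_copies logical; apply mRNA copy-number weights (default) or
#'   return raw pooled simulated counts.
#' @return named list of [gene_profile()] objects.
#' @export
snapshots_to_profiles <- function(sim, snapshot_time, library_id = NULL,
                                  weight_copies = TRUE) {
  s <- match(snapshot_time, sim$snapshot_times_s)
  if (is.na(s)) stop("snapshot time ", snapshot_time, " was not simulated")
  sc <- sim$scenario
  g <- sc$genes
  if (is.null(library_id))
    library_id <- paste0(sc$preset, "_t", snapshot_time)
  copies_now <- mrna_copies_at(sc, snapshot_time)
  out <- lapply(seq_len(nrow(g)), function(i) {
    pos <- sim$per_gene[[i]][[s]]$positions
    counts <- numeric(g$cds_length_nt[i])
    if (length(pos)) {
      nt <- 3L * (pos - 1L) + 1L
      tb <- tabulate(nt, nbins = g$cds_length_nt[i])
      counts <- as.numeric(tb)
    }
    w <- if (weight_copies) copies_now[i] / sc$copies_sim else 1
    gene_profile(g$gene_id[i], counts * w, library_id)
  })
  names(out) <- g$gene_id
  out
}

# mRNA copy number per gene at time t (s past stress onset): constitutive
# genes constant; induced genes approach fold*copies exponentially.
mrna_copies_at <- function(scenario, t) {
  g <- scenario$genes
  n <- g$copies
  if (t > 0 && any(g$induced)) {
    target <- g$copies * scenario$induction_fold
    frac <- 1 - exp(-t / scenario$induction_tau_s)
    n[g$induced] <- g$copies[g$induced] +
      (target[g$induced] - g$copies[g$induced]) * frac
  }
  n
}

#' Simulate finite sequencing depth
#'
#' Resamples all (gene, position) cells multinomially with probabilities
#' proportional to the true footprint abundances; the total equals `depth`
#' exactly.
#'
#' @param profiles list of [gene_profile()] objects (true abundances).
#' @param depth total reads to draw.
#' @param seed RNG seed.
#' @return list of profiles with integer sampled counts.
#' @export
sample_sequencing <- function(profiles, depth, seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  sizes <- vapply(profiles, function(p) length(p$counts), integer(1))
  w <- unlist(lapply(profiles, `[[`, "counts"), use.names = FALSE)
  if (sum(w) == 0) stop("no true counts to sample from")
  draw <- as.numeric(rmultinom(1, size = depth, prob = w))
  idx <- rep(seq_along(profiles), sizes)
  out <- lapply(seq_along(profiles), function(i) {
    gene_profile(profiles[[i]]$gene_id, draw[idx == i],
                 profiles[[i]]$library_id)
  })
  names(out) <- names(profiles)
  out
}

#' Simulated mRNA pool and RPF/mRNA expression tables
#'
#' mRNA-seq counts are drawn multinomially with weights copy_number x length
#' (fragment-proportional sampling); RPF counts are the sampled footprint
#' totals per gene. Returns one [expression_table()] per requested time.
#'
#' @param sim a [simulate_scenario()] result.
#' @param times snapshot times (s) to tabulate; default all simulated.
#' @param seed RNG seed for the sequencing draws.
#' @return named list of expression tables (names = times).
#' @export
simulate_mrna_pool <- function(sim, times = NULL, seed = 1) {
  sc <- sim$scenario
  if (is.null(times)) times <- sim$snapshot_times_s
  g <- sc$genes
  out <- lapply(seq_along(times), function(ti) {
    t <- times[ti]
    prof <- snapshots_to_profiles(sim, t)
    rpf <- sample_sequencing(prof, sc$sequencing_depth, seed = seed + ti)
    rpf_counts <- vapply(rpf, function(p) sum(p$counts), numeric(1))
    set.seed(seed + 1000 + ti)
    w <- mrna_copies_at(sc, t) * g$cds_length_nt
    mrna_counts <- as.numeric(rmultinom(1, size = sc$mrna_depth, prob = w))
    expression_table(g$gene_id, rpf_counts, mrna_counts, g$cds_length_nt)
  })
  names(out) <- as.character(times)
  out
}

#' Single-ribosome clearance times (runoff bound)
#'
#' Places one ribosome at codon 1 with initiation off and measures the time
#' to terminate past codon L at constant elongation rate k (termination at
#' the same rate), i.e. a sum of L exponential steps with Erlang mean L/k.
#' Used to verify the runoff bound for a PGK1-length CDS: 417 codons at the
#' slowest basal rate (3 aa/s) clear in ~139 s, well under 3 minutes.
#'
#' @param L_codons CDS length in codons.
#' @param k elongation rate, codons/s.
#' @param n_rep replicates.
#' @param seed RNG seed.
#' @return numeric vector of clearance times (s).
#' @export
clearance_times <- function(L_codons, k, n_rep = 200, seed = 1) {
  set.seed(seed)
  sched <- .default_schedule()
  sched$alpha0 <- 0
  sched$alpha_readd <- 0
  sched$k0 <- k
  vapply(seq_len(n_rep), function(r) {
    res <- sim_tasep_cpp(L = L_codons, ell = 10L, beta = k, schedule = sched,
                         t_start = 0, t_end = 20 * L_codons / k,
                         snapshot_times = numeric(0),
                         init_positions = 1L)
    if (length(res$term_times) == 0) stop("ribosome failed to clear")
    res$term_times[1]
  }, numeric(1))
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> preset=%s genes=%d snapshots=%s\n",
              x$preset, nrow(x$genes),
              paste(x$snapshot_times_s, collapse = ",")))
  invisible(x)
}
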