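#' Generate inducible luciferase reporter time courses
#'
#' Models the induction assay used to measure elongation rates in vivo. A
#' shared constant `t_base_s` (induction + reporter synthesis + maturation,
#' identical across reporters so it cancels in subtraction) is followed, for
#' a fusion reporter carrying `orf_extra_nt` of extra upstream ORF, by the
#' transcription delay `orf_extra_nt / txn_speed` and the elongation delay
#' `(orf_extra_nt/3) / k_aa_per_s`. After the onset T, synthesis ramps
#' linearly (each successive mRNA/ribosome adds output), so accumulated
#' signal grows quadratically — the regime the Schleif linearization assumes.
#' PEST-tagged constructs decay with `lambda = ln 2 / half-life`:
#' \deqn{S(t) = r/\lambda^2 (\lambda\tau - 1 + e^{-\lambda\tau}),\ \tau = t - T}
#' (the closed-form solution of dS/dt = r tau - lambda S), reducing to
#' \eqn{r\tau^2/2} as lambda -> 0. Multiplicative log-normal noise with the
#' given CV is applied per 30-s sample.
#'
#' @param k_aa_per_s true elongation rate through the extra ORF (aa/s).
#' @param orf_extra_nt extra ORF length; 3,072 nt for the LacZ fusion, 0 for
#'   the control reporter.
#' @param txn_speed_nt_per_min RNA polymerase speed used for the
#'   transcription delay (2,000 nt/min).
#' @param decay_half_life_min PEST reporter half-life (5 min); 0 disables
#'   decay.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_replicates number of replicate wells.
#' @param seed RNG seed.
#' @param t_base_s shared onset constant (s).
#' @param rate_au synthesis ramp slope r (a.u./s^2).
#' @param duration_s measurement span; samples every `dt_s` seconds.
#' @param dt_s sampling interval (plate reader reads every 30 s).
#' @param reporter label stored on the series.
#' @param condition,treatment,treatment_time_s metadata labels.
#' @return list of `luminescence_series` objects (times_s, signal, onset
#'   truth in `attr(, "true_onset_s")`).
#' @export
generate_curves <- function(k_aa_per_s, orf_extra_nt = 3072,
                            txn_speed_nt_per_min = 2000,
                            decay_half_life_min = 5, noise_cv = 0.1,
                            n_replicates = 4, seed = 1, t_base_s = 300,
                            rate_au = 1, duration_s = 3000, dt_s = 30,
                            reporter = if (orf_extra_nt > 0) "lacz_nluc" else "nluc",
                            condition = "log_phase", treatment = "none",
                            treatment_time_s = NA_real_) {
  if (k_aa_per_s <= 0) stop("k_aa_per_s must be > 0")
  set.seed(seed)
  T_on <- t_base_s + orf_extra_nt / (txn_speed_nt_per_min / 60) +
    (orf_extra_nt / 3) / k_aa_per_s
  lambda <- if (decay_half_life_min > 0) log(2) / (decay_half_life_min * 60) else 0
  times <- seq(0, duration_s, by = dt_s)
  clean <- .signal_closed_form(times, T_on, rate_au, lambda)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_cv > 0)
      exp(rnorm(length(times), -sdlog^2 / 2, sdlog)) else 1
    structure(
      list(times_s = times, signal = clean * noise, reporter = reporter,
           condition = condition, treatment = treatment,
           treatment_time_s = treatment_time_s, replicate_id = r),
      class = "luminescence_series", true_onset_s = T_on)
  })
}

# accumulated signal under a linear synthesis ramp starting at T with
# first-order decay lambda
.signal_closed_form <- function(times, T_on, rate_au, lambda) {
  tau <- pmax(0, times - T_on)
  if (lambda > 0) rate_au / lambda^2 * (lambda * tau - 1 + exp(-lambda * tau))
  else rate_au * tau^2 / 2
}

#' Schleif-plot fit of an induction curve
#'
#' Linearizes the early quadratic rise by fitting a straight line to
#' sqrt(signal) against time; the x-intercept estimates the onset time (the
#' minimum reaction time for the first complete protein). The baseline
#' (median of the first `n_baseline` samples, read before induction takes
#' hold) is subtracted first. The fit window is taken where sqrt(signal)
#' lies between
#' `window[1]` and `window[2]` of its maximum: on the linearized scale this
#' brackets the early-quadratic regime even for decaying PEST reporters
#' (see the methods vignette for why the window is set on the sqrt scale).
#' Under multiplicative measurement noise the standard deviation of
#' sqrt(signal) grows with the signal, so the line is fitted by weighted
#' least squares with inverse-variance weights (1/signal), which also keeps
#' the early, least-curved part of the rise in charge of the intercept.
#'
#' @param series a `luminescence_series`.
#' @param window lower/upper bounds of the fit window as fractions of
#'   max(sqrt(signal)).
#' @param n_baseline number of leading samples (pre-induction reads) whose
#'   median is subtracted as background.
#' @param min_points minimum points required in the fit window.
#' @param weighted logical; inverse-variance weights (default) or ordinary
#'   least squares.
#' @return object of class `schleif_fit`: `onset_time_s`, `slope`,
#'   `fit_window` (index range), `r_squared`, `low_r2` warning flag.
#' @export
schleif_fit <- function(series, window = c(0.1, 0.6), n_baseline = 5,
                        min_points = 6, weighted = TRUE) {
  s <- series$signal
  t <- series$times_s
  if (all(s <= 0) || max(s) == min(s))
    stop("degenerate signal: nothing to fit")
  base <- median(s[seq_len(min(n_baseline, length(s)))])
  y <- sqrt(pmax(0, s - base))
  ymax <- max(y)
  idx <- which(y >= window[1] * ymax & y <= window[2] * ymax & t > 0)
  idx <- idx[idx > which.max(y > 0)[1] - 1]  # rising limb only
  if (length(idx) < min_points)
    stop("fewer than ", min_points, " points above the noise floor in the fit window")
  wts <- if (weighted) 1 / pmax(y[idx], 1e-8)^2 else NULL
  fit <- lm(y[idx] ~ t[idx], weights = wts)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0) stop("non-rising signal in fit window")
  onset <- -coef(fit)[[1]] / slope
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(onset_time_s = onset, slope = slope,
         fit_window = range(idx), r_squared = r2, low_r2 = r2 < 0.9),
    class = "schleif_fit")
}

#' Elongation rate from paired Schleif fits
#'
#' The control (Nluc) onset is subtracted from the fusion (LacZ-Nluc) onset;
#' the transcription time `orf_extra_nt / txn_speed` is removed; the
#' remaining time is the elongation time through the extra ORF:
#' \deqn{rate = (orf\_extra\_nt/3) / (\Delta T - t_{txn})\ \ \mathrm{aa/s}.}
#' With replicate pairs, per-pair rates are aggregated as mean +/- SEM.
#'
#' @param fit_fusion,fit_control single [schleif_fit()]s or lists of them
#'   (paired by position).
#' @param orf_extra_nt extra ORF length (3,072 nt for LacZ).
#' @param txn_speed_nt_per_min transcription speed (2,000 nt/min).
#' @return object of class `elongation_estimate`: `rate_aa_per_s` (mean),
#'   `sem`, `per_replicate`, and the constants used. Pairs whose
#'   \eqn{\Delta T \le t_{txn}} are flagged undefined
#'   ("elongation faster than resolvable") and dropped from the mean;
#'   negative \eqn{\Delta T} is an error.
#' @export
elongation_rate <- function(fit_fusion, fit_control, orf_extra_nt = 3072,
                            txn_speed_nt_per_min = 2000) {
  if (inherits(fit_fusion, "schleif_fit")) fit_fusion <- list(fit_fusion)
  if (inherits(fit_control, "schleif_fit")) fit_control <- list(fit_control)
  if (length(fit_fusion) != length(fit_control))
    stop("fusion and control fits must pair up")
  t_txn <- orf_extra_nt / (txn_speed_nt_per_min / 60)
  per <- vapply(seq_along(fit_fusion), function(i) {
    dT <- fit_fusion[[i]]$onset_time_s - fit_control[[i]]$onset_time_s
    if (dT < 0) stop("fusion onset precedes control onset")
    if (dT <= t_txn) return(NA_real_)  # faster than resolvable
    (orf_extra_nt / 3) / (dT - t_txn)
  }, numeric(1))
  ok <- per[!is.na(per)]
  structure(
    list(rate_aa_per_s = if (length(ok)) mean(ok) else NA_real_,
         sem = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else NA_real_,
         per_replicate = per,
         n_undefined = sum(is.na(per)),
         orf_length_nt = orf_extra_nt,
         txn_speed_nt_per_min = txn_speed_nt_per_min),
    class = "elongation_estimate")
}

#' @export
print.elongation_estimate <- function(x, ...) {
  cat(sprintf("<elongation_estimate> %.2f aa/s (SEM %.2f, n=%d)\n",
              x$rate_aa_per_s, x$sem, sum(!is.na(x$per_replicate))))
  invisible(x)
}

#' Full simulated elongation-rate measurement
#'
#' Generates paired control and fusion reporter curves at a known elongation
#' rate, Schleif-fits each replicate, and recovers the rate — the complete
#' in-silico version of the reporter assay.
#'
#' @param k_aa_per_s true elongation rate.
#' @param noise_cv,n_replicates,seed passed to [generate_curves()].
#' @param ... further arguments to [generate_curves()].
#' @return an [elongation_rate()] estimate with the generative truth in
#'   `attr(, "true_rate")`.
#' @export
measure_elongation_rate <- function(k_aa_per_s = 5, noise_cv = 0.1,
                                    n_replicates = 4, seed = 1, ...) {
  ctrl <- generate_curves(k_aa_per_s, orf_extra_nt = 0, noise_cv = noise_cv,
                          n_replicates = n_replicates, seed = seed, ...)
  fus <- generate_curves(k_aa_per_s, orf_extra_nt = 3072, noise_cv = noise_cv,
                         n_replicates = n_replicates, seed = seed + 5e5, ...)
  est <- elongation_rate(lapply(fus, schleif_fit), lapply(ctrl, schleif_fit))
  attr(est, "true_rate") <- k_aa_per_s
  est
}

#' Reporter curves after glucose readdition
#'
#' Models the readdition assay on a long endogenous gene tagged with a
#' short-lived (PEST) luciferase. Ribosomes loaded on the ORF before
#' readdition (positions in codons) resume elongation at `k_post` and each
#' contributes one luciferase unit on completion, decaying with the PEST
#' rate; new initiations (rate `alpha_new`) complete after the full ORF
#' transit `L_codons / k_post`. Treatments branch the model: `ltm` blocks
#' only the new-initiation term (preferential initiation inhibitor); `chx`
#' blocks all completions (elongation inhibitor), leaving only decay of the
#' pre-existing signal `s0`.
#'
#' @param loaded_positions codon positions of pre-loaded ribosomes (pooled
#'   over mRNA copies).
#' @param k_post post-readdition elongation rate, codons/s (aa/s).
#' @param treatment `"none"`, `"ltm"`, or `"chx"` applied at t = 0.
#' @param L_codons reporter ORF length in codons (default 2100, the scale of
#'   the long tagged genes used in the readdition assay).
#' @param alpha_new new-initiation rate after readdition (completions ramp
#'   in only after one full transit).
#' @param decay_half_life_min PEST half-life.
#' @param s0 pre-existing luciferase signal at readdition.
#' @param noise_cv,seed noise model as in [generate_curves()].
#' @param duration_s,dt_s sampling grid.
#' @return a `luminescence_series`.
#' @export
generate_readdition_curves <- function(loaded_positions, k_post = 2.4,
                                       treatment = c("none", "ltm", "chx"),
                                       L_codons = 2100, alpha_new = 0.05,
                                       decay_half_life_min = 5, s0 = 0,
                                       noise_cv = 0, seed = 1,
                                       duration_s = 1200, dt_s = 30) {
  treatment <- match.arg(treatment)
  if (any(loaded_positions < 1 | loaded_positions > L_codons))
    stop("loaded positions outside the reporter ORF")
  set.seed(seed)
  lambda <- log(2) / (decay_half_life_min * 60)
  times <- seq(0, duration_s, by = dt_s)
  sig <- s0 * exp(-lambda * times)
  if (treatment != "chx") {
    compl <- (L_codons - loaded_positions) / k_post
    for (tc in compl)
      sig <- sig + ifelse(times >= tc, exp(-lambda * (times - tc)), 0)
    if (treatment == "none") {
      # new initiations: completions ramp at rate alpha_new after one transit
      t0 <- L_codons / k_post
      tau <- pmax(0, times - t0)
      sig <- sig + alpha_new / lambda * (1 - exp(-lambda * tau)) *
        ifelse(tau > 0, 1, 0)
    }
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    sig <- sig * exp(rnorm(length(times), -sdlog^2 / 2, sdlog))
  }
  structure(
    list(times_s = times, signal = sig, reporter = "gene_e2a_nluc",
         condition = "readdition", treatment = treatment,
         treatment_time_s = 0, replicate_id = 1),
    class = "luminescence_series")
}

#' Treatment-difference analysis of paired reporter series
#'
#' For each (untreated, treated) pair sharing a time grid, computes the
#' signal accrued from treatment start to `at_time_s` in each and takes the
#' difference (untreated minus treated) — the luciferase production that the
#' inhibitor prevented. Returns mean, SEM and a two-sided paired t-test.
#'
#' @param untreated,treated lists of `luminescence_series`, paired by
#'   position.
#' @param at_time_s end of the accrual window (s after treatment).
#' @return list: `differences`, `mean_difference`, `sem`, `p_value`.
#' @export
treatment_difference <- function(untreated, treated, at_time_s) {
  if (inherits(untreated, "luminescence_series")) untreated <- list(untreated)
  if (inherits(treated, "luminescence_series")) treated <- list(treated)
  if (length(untreated) != length(treated))
    stop("unpaired inputs: lengths differ")
  accrued <- function(s, from, to) {
    if (!isTRUE(all.equal(s$times_s, treated[[1]]$times_s)) &&
        length(s$times_s) != length(treated[[1]]$times_s))
      stop("paired series must share time grids")
    i0 <- which.min(abs(s$times_s - from))
    i1 <- which.min(abs(s$times_s - to))
    s$signal[i1] - s$signal[i0]
  }
  d <- vapply(seq_along(untreated), function(i) {
    from <- untreated[[i]]$treatment_time_s
    if (is.na(from)) from <- 0
    accrued(untreated[[i]], from, at_time_s) -
      accrued(treated[[i]], from, at_time_s)
  }, numeric(1))
  p <- if (length(d) > 1 && sd(d) > 0) t.test(d)$p.value else NA_real_
  list(differences = d, mean_difference = mean(d),
       sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
       p_value = p)
}
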