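test_that("noiseless reporter curves rise exactly at the modeled onset", {
  ctrl <- generate_curves(5, orf_extra_nt = 0, noise_cv = 0,
                          n_replicates = 1)[[1]]
  expect_equal(attr(ctrl, "true_onset_s"), 300)          # t_base only
  expect_true(all(ctrl$signal[ctrl$times_s <= 300] == 0))
  expect_gt(ctrl$signal[ctrl$times_s == 330], 0)
  # fusion onset adds transcription (3072/2000 min) and elongation delays
  fus <- generate_curves(5, orf_extra_nt = 3072, noise_cv = 0,
                         n_replicates = 1)[[1]]
  expect_equal(attr(fus, "true_onset_s"), 300 + 92.16 + 1024 / 5)
  # same seed -> identical replicates
  a <- generate_curves(5, noise_cv = 0.2, n_replicates = 3, seed = 9)
  b <- generate_curves(5, noise_cv = 0.2, n_replicates = 3, seed = 9)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
})

test_that("PEST decay halves the signal every five minutes once synthesis stops", {
  # CHX branch: no completions, pre-existing signal only decays
  s <- generate_readdition_curves(loaded_positions = c(500, 900),
                                  treatment = "chx", s0 = 64,
                                  duration_s = 900)
  expect_equal(s$signal[s$times_s == 300], 32)
  expect_equal(s$signal[s$times_s == 600], 16)
})

test_that("Schleif fit recovers exact quadratics and rejects degenerate input", {
  t <- seq(0, 3000, 30)
  for (Tq in c(150, 444, 900)) for (cq in c(0.1, 3)) {
    s <- structure(list(times_s = t, signal = cq * pmax(0, t - Tq)^2),
                   class = "luminescence_series")
    expect_equal(schleif_fit(s)$onset_time_s, Tq, tolerance = 1e-6)
  }
  flat <- structure(list(times_s = t, signal = numeric(length(t))),
                    class = "luminescence_series")
  expect_error(schleif_fit(flat), "degenerate")
})

test_that("Schleif onset estimate converges to the truth as noise shrinks", {
  errs <- vapply(c(0.2, 0.05, 0), function(cv) {
    est <- vapply(1:30, function(s) {
      cur <- generate_curves(5, orf_extra_nt = 3072, noise_cv = cv,
                             n_replicates = 1, seed = s)[[1]]
      schleif_fit(cur)$onset_time_s - attr(cur, "true_onset_s")
    }, numeric(1))
    mean(abs(est))
  }, numeric(1))
  expect_true(errs[2] < errs[1] + 5)
  expect_true(errs[3] <= errs[2])
  # absolute recovery at the documented noise level
  expect_lt(errs[2], 120)
})

test_that("elongation rate inverts the closed form and flags degeneracies", {
  fit <- function(T) structure(list(onset_time_s = T), class = "schleif_fit")
  # dT = t_txn + 1024/5 = 92.16 + 204.8 -> 5.0 aa/s exactly
  est <- elongation_rate(fit(300 + 296.96), fit(300))
  expect_equal(est$rate_aa_per_s, 5.0, tolerance = 1e-10)
  # dT equal to the transcription time: unresolvable, flagged not errored
  und <- elongation_rate(fit(300 + 92.16), fit(300))
  expect_true(is.na(und$rate_aa_per_s))
  expect_equal(und$n_undefined, 1L)
  expect_error(elongation_rate(fit(100), fit(300)), "precedes")
  # shared constant delays cancel in the subtraction
  est2 <- elongation_rate(fit(1000 + 296.96), fit(1000))
  expect_equal(est2$rate_aa_per_s, est$rate_aa_per_s)
})

test_that("noiseless onset separation shrinks strictly with faster elongation", {
  dT <- vapply(c(1, 2, 3, 5, 8, 10), function(k) {
    ctrl <- generate_curves(k, orf_extra_nt = 0, noise_cv = 0,
                            n_replicates = 1)[[1]]
    fus <- generate_curves(k, orf_extra_nt = 3072, noise_cv = 0,
                           n_replicates = 1)[[1]]
    schleif_fit(fus)$onset_time_s - schleif_fit(ctrl)$onset_time_s
  }, numeric(1))
  expect_true(all(diff(dT) < 0))
})

test_that("rate recovery across the basal range stays within 15% median error", {
  for (k in c(1, 2, 3, 5, 8, 10)) {
    est <- vapply(1:50, function(s)
      measure_elongation_rate(k, noise_cv = 0.1, n_replicates = 4,
                              seed = s)$rate_aa_per_s, numeric(1))
    expect_lt(median(abs(est - k) / k), 0.15)
  }
})

test_that("treatment differences: identity, CHX positivity, LTM timing", {
  pre <- seq(1400, 2050, by = 50)  # ribosomes loaded well into the ORF
  un <- generate_readdition_curves(pre, treatment = "none", s0 = 10)
  tr_same <- treatment_difference(un, un, at_time_s = 600)
  expect_equal(tr_same$mean_difference, 0)

  chx <- generate_readdition_curves(pre, treatment = "chx", s0 = 10)
  expect_gt(treatment_difference(un, chx, at_time_s = 600)$mean_difference, 0)

  # LTM (initiation-only block): no effect at 5 min, clear effect at 15 min
  ltm <- generate_readdition_curves(pre, treatment = "ltm", s0 = 10)
  d5 <- treatment_difference(un, ltm, at_time_s = 300)$mean_difference
  d15 <- treatment_difference(un, ltm, at_time_s = 900)$mean_difference
  expect_equal(d5, 0, tolerance = 1e-9)
  expect_gt(d15, 0)

  expect_error(treatment_difference(list(un, un), list(ltm), 300), "unpaired")
})

test_that("pre-loaded ribosomes near the stop produce immediate signal", {
  s <- generate_readdition_curves(loaded_positions = 2100, L_codons = 2100,
                                  treatment = "ltm")
  expect_gt(s$signal[1], 0.99)  # completion at t ~ 0 regardless of LTM
  # all ribosomes < 1000 codons from the stop finish within ~416 s at 2.4 aa/s
  s2 <- generate_readdition_curves(loaded_positions = seq(1101, 2091, 90),
                                   treatment = "ltm")
  t_done <- (2100 - 1101) / 2.4
  expect_lt(t_done, 420)
  sig <- s2$signal
  # after t_done the only change is decay: signal never increases
  late <- sig[s2$times_s >= 450]
  expect_true(all(diff(late) <= 0))
})
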