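test_that("TPM: hand case, equal-share case, normalization, invariance", {
  expect_equal(tpm(c(10, 10), c(1000, 2000)),
               c(666666.67, 333333.33), tolerance = 1e-8)
  for (n in c(2, 7, 150))
    expect_equal(tpm(rep(5, n), rep(1200, n)), rep(1e6 / n, n))
  set.seed(1)
  counts <- rpois(40, 50); lengths <- sample(300:6000, 40)
  expect_equal(sum(tpm(counts, lengths)), 1e6)
  expect_equal(tpm(counts * 17, lengths), tpm(counts, lengths))
  expect_error(tpm(c(0, 0), c(10, 10)), "zero")
  expect_error(tpm(c(1, 1), c(10, 0)), "positive")
})

test_that("log2 occupancy: hand cases, undefined at zero, antisymmetry", {
  expect_equal(log2_ro(100, 100), 0)
  expect_equal(log2_ro(200, 50), 2)
  expect_true(is.na(log2_ro(10, 0)))
  expect_true(is.na(log2_ro(0, 10)))
  set.seed(2)
  a <- runif(20, 1, 100); b <- runif(20, 1, 100)
  expect_equal(log2_ro(a, b), -log2_ro(b, a))
})

test_that("threshold layer is strict at the 2.5 / 0.09 boundaries", {
  fc <- data.frame(
    gene_id = c("above", "ro_at", "mrna_at", "below", "induced_only"),
    log2_mrna_fc = c(3.0, 3.0, 2.5, 1.0, 2.0001),
    log2_ro_fc = c(0.10, 0.09, 0.10, 0.0, -1),
    mean_ref_tpm = c(5, 4, 3, 2, 1))
  cl <- classify_from_fc(fc, top_n = 2)
  expect_equal(cl$gene_id[cl$upregulated], "above")
  expect_false(cl$upregulated[cl$gene_id == "ro_at"])     # 0.09 exactly: out
  expect_false(cl$upregulated[cl$gene_id == "mrna_at"])   # 2.5 exactly: out
  expect_setequal(cl$gene_id[cl$induced_4fold], c("above", "ro_at", "mrna_at",
                                                  "induced_only"))
  expect_setequal(cl$gene_id[cl$abundant_log_top150], c("above", "ro_at"))
})

test_that("top-N abundance ties break deterministically by gene_id", {
  fc <- data.frame(gene_id = c("zz", "aa", "mm"),
                   log2_mrna_fc = 0, log2_ro_fc = 0,
                   mean_ref_tpm = c(10, 10, 10))
  cl <- classify_from_fc(fc, top_n = 2)
  expect_setequal(cl$gene_id[cl$abundant_log_top150], c("aa", "mm"))
  # determinism: repeated runs identical
  expect_identical(cl, classify_from_fc(fc, top_n = 2))
})

test_that("simulated induction is recovered by the 4-fold rule", {
  sc <- build_scenario("starvation", small_overrides(snapshot_times_s = 900,
                                                     duration_s = 900))
  sim <- simulate_scenario(sc, seed = 5)
  base_sc <- build_scenario("log_phase", small_overrides(snapshot_times_s = 0,
                                                         duration_s = 1))
  base_sim <- simulate_scenario(base_sc, seed = 5)
  tab_log <- simulate_mrna_pool(base_sim, 0, seed = 5)[[1]]
  tab_str <- simulate_mrna_pool(sim, 900, seed = 6)[[1]]
  expect_warning(cl <- classify_genes(tab_log, tab_str, top_n = 2),
                 "single reference")
  induced_truth <- sc$genes$gene_id[sc$genes$induced]
  # 8-fold induction target, tau 300 s: ~7.7-fold at 15 min, above the 4x rule
  expect_setequal(cl$gene_id[cl$induced_4fold], induced_truth)
})

test_that("read-category fractions partition all reads (induced wins overlap)", {
  tab <- expression_table(c("i1", "a1", "o1", "o2"),
                          rpf_count = c(10, 70, 15, 5),
                          mrna_count = c(20, 40, 30, 10),
                          lengths = rep(1000, 4))
  cl <- data.frame(gene_id = c("i1", "a1", "o1", "o2"),
                   induced_4fold = c(TRUE, FALSE, FALSE, FALSE),
                   abundant_log_top150 = c(TRUE, TRUE, FALSE, FALSE))
  pr <- read_category_proportions(tab, cl)
  expect_equal(sum(pr$rpf_fraction), 1)
  expect_equal(sum(pr$mrna_fraction), 1)
  expect_equal(pr$rpf_fraction[pr$category == "induced"], 0.1)
  expect_equal(pr$mrna_fraction[pr$category == "abundant"], 0.4)
  # single-bucket universe
  one <- read_category_proportions(tab[2, ], cl)
  expect_equal(one$rpf_fraction[one$category == "abundant"], 1)
  expect_error(read_category_proportions(tab[0, ], cl), "empty")
})

test_that("induced mRNA mass fraction matches the generative truth", {
  sc <- build_scenario("starvation", list(snapshot_times_s = 900,
                                          duration_s = 900))
  sim <- simulate_scenario(sc, seed = 8)
  tab <- simulate_mrna_pool(sim, 900, seed = 8)[[1]]
  g <- sc$genes
  copies <- riboshift:::mrna_copies_at(sc, 900)
  truth <- sum((copies * g$cds_length_nt)[g$induced]) /
    sum(copies * g$cds_length_nt)
  obs <- sum(tab$mrna_count[g$induced]) / sum(tab$mrna_count)
  expect_equal(obs, truth, tolerance = 0.05)
})

test_that("occupancy-change ratios: identity, omission, length ordering", {
  tab <- expression_table(paste0("g", 1:4), c(10, 20, 30, 40),
                          c(10, 10, 10, 10), c(501, 1500, 3000, 5001))
  genes <- gene_models(paste0("g", 1:4), c(501, 1500, 3000, 5001))
  rc <- ro_change_vs_length(tab, tab, genes, bins = c(0, 1000, 4000, Inf))
  expect_true(all(rc$per_gene$ro_ratio == 1))
  # gene missing from the stress table is omitted
  expect_message(rc2 <- ro_change_vs_length(tab, tab[-2, ], genes),
                 "omitted")
  expect_false("g2" %in% rc2$per_gene$gene_id)

  # starvation simulation: long bulk genes keep occupancy better than short
  # ones (stress-induced genes escape the shutdown and are set aside)
  per <- do.call(rbind, lapply(1:3, function(s) {
    sim <- simulate_scenario(build_scenario("starvation",
      list(snapshot_times_s = 900, duration_s = 900)), seed = s)
    base <- simulate_scenario(build_scenario("log_phase",
      list(snapshot_times_s = 0, duration_s = 1)), seed = s)
    tab_log <- simulate_mrna_pool(base, 0, seed = s)[[1]]
    tab_str <- simulate_mrna_pool(sim, 900, seed = s + 100)[[1]]
    g <- sim$scenario$genes
    bulk <- g$gene_id[!g$induced]
    rr <- ro_change_vs_length(tab_log[tab_log$gene_id %in% bulk, ],
                              tab_str[tab_str$gene_id %in% bulk, ], g,
                              bins = c(0, 1000, 4000, Inf))
    rr$per_gene
  }))
  long <- per$ro_ratio[per$length_nt > 4000]
  short <- per$ro_ratio[per$length_nt < 1000]
  expect_gt(median(long), median(short))
  # the paper-scale pattern: long-gene occupancy ratios sit above 1
  expect_gt(median(long), 1)
})
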