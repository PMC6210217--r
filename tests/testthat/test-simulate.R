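test_that("ground truth census follows the configuration", {
  cfg <- sim_config(n_proteins = 100, peptides_per_protein = c(3, 3),
                    n_populations = 1, replicates = 1, batches = 1,
                    frac_differential = 0, seed = 2)
  gt <- generate_ground_truth(cfg)
  tgt <- gt$library[gt$library$ProteinId != "IRT_STANDARD", , drop = FALSE]
  cz <- census(assay_library(as.data.frame(tgt), check_mz = FALSE))
  expect_equal(cz$n_proteins, 100)
  expect_equal(cz$n_peptides, 300)
  expect_equal(cz$n_precursors, 300)
  expect_equal(cz$n_transitions, 1500)
  # 16 standards appended
  expect_equal(sum(gt$truth$peptides$protein == "IRT_STANDARD"), 16)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_proteins = 20, n_populations = 2, replicates = 2,
                    batches = 2, frac_signal_free = 0.1,
                    interference_rate = 0.1, seed = 5)
  g1 <- generate_ground_truth(cfg)
  g2 <- generate_ground_truth(cfg)
  expect_identical(g1, g2)
  r1 <- simulate_dia_experiment(g1$library, g1$truth, g1$annot, cfg)
  r2 <- simulate_dia_experiment(g2$library, g2$truth, g2$annot, cfg)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$interferences, r2$interferences)
})

test_that("differential bookkeeping is exact", {
  cfg <- sim_config(n_proteins = 50, frac_differential = 0.1, log2fc = 1,
                    n_populations = 4, replicates = 2, batches = 1,
                    seed = 6)
  gt <- generate_ground_truth(cfg)
  d <- gt$truth$differential
  expect_equal(nrow(d), 4 * floor(0.1 * 50))
  expect_equal(unname(table(d$population)), rep(5L, 4), ignore_attr = TRUE)
  expect_true(all(abs(d$log2fc) == 1))
  expect_equal(anyDuplicated(d$protein), 0)  # disjoint sets
  # planted effects are present in the abundance matrix
  for (i in seq_len(nrow(d))) {
    pop_cols <- gt$annot$sample_id[gt$annot$population == d$population[i]]
    rest <- setdiff(gt$annot$sample_id, pop_cols)
    gap <- mean(gt$truth$abundance[d$protein[i], pop_cols]) -
      mean(gt$truth$abundance[d$protein[i], rest])
    expect_equal(gap, d$log2fc[i], tolerance = 0.8)
  }
})

test_that("noise-free simulation is linear in protein abundance", {
  cfg <- sim_config(n_proteins = 5, peptides_per_protein = c(2, 2),
                    n_populations = 1, replicates = 1, batches = 1,
                    frac_differential = 0, rep_sigma = 0,
                    noise_sigma = 0, baseline_level = 0,
                    interference_rate = 0, rt_jitter_sd = 0, seed = 7)
  gt <- generate_ground_truth(cfg)
  run1 <- simulate_dia_experiment(gt$library, gt$truth, gt$annot, cfg)
  gt2 <- gt
  gt2$truth$abundance <- gt$truth$abundance + 1   # double every protein
  run2 <- simulate_dia_experiment(gt$library, gt2$truth, gt$annot, cfg)
  s <- gt$annot$sample_id[1]
  keys <- setdiff(names(run1$traces[[s]]), run1$standard_keys)
  for (k in keys[1:5]) {
    expect_equal(run2$traces[[s]][[k]]$intens,
                 2 * run1$traces[[s]][[k]]$intens, tolerance = 1e-9)
  }
})

test_that("signal-free targets carry baseline only", {
  cfg <- sim_config(n_proteins = 20, peptides_per_protein = c(2, 2),
                    n_populations = 1, replicates = 1, batches = 1,
                    frac_differential = 0, frac_signal_free = 0.5,
                    interference_rate = 0, seed = 8)
  gt <- generate_ground_truth(cfg)
  run <- simulate_dia_experiment(gt$library, gt$truth, gt$annot, cfg)
  s <- gt$annot$sample_id[1]
  sf_keys <- run$precursors$key[run$precursors$signal_free]
  expect_gt(length(sf_keys), 0)
  for (k in sf_keys) {
    tr <- run$traces[[s]][[k]]
    pg <- detect_peak_groups(tr$times, tr$intens, tr$pred_rt, min_sn = 0)
    if (nrow(pg$candidates) > 0)
      expect_lt(pg$candidates$sn[1], 1.5)
  }
})

test_that("interference registry matches what was injected", {
  cfg <- sim_config(n_proteins = 20, peptides_per_protein = c(2, 2),
                    n_populations = 1, replicates = 2, batches = 1,
                    frac_differential = 0, interference_rate = 0.3,
                    seed = 9)
  gt <- generate_ground_truth(cfg)
  run <- simulate_dia_experiment(gt$library, gt$truth, gt$annot, cfg)
  reg <- run$interferences
  expect_gt(nrow(reg), 0)
  expect_true(all(reg$sample_id %in% gt$annot$sample_id))
  expect_true(all(reg$key %in% run$precursors$key))
  # per-sample counts are Binomial(n_transitions, rate): all within 5 sd
  n_tr <- sum(vapply(run$library_rows, length, 0L))
  expected <- n_tr * 0.3
  counts <- table(factor(reg$sample_id, levels = gt$annot$sample_id))
  expect_true(all(abs(counts - expected) <
                    5 * sqrt(n_tr * 0.3 * 0.7)))
})

test_that("abundance dispersion matches the configured sigma", {
  cfg <- sim_config(n_proteins = 1000, peptides_per_protein = c(2, 2),
                    n_populations = 1, replicates = 1, batches = 1,
                    frac_differential = 0, abundance_sigma = 1.5,
                    seed = 10)
  gt <- generate_ground_truth(cfg)
  expect_lt(abs(sd(gt$truth$base) - 1.5) / 1.5, 0.1)
})
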