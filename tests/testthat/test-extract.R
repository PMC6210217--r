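test_that("isolation scheme reproduces the published window count", {
  sch <- build_isolation_scheme(390, 1065, 10, 0.5)
  expect_equal(nrow(sch$windows), 75)
  expect_equal(sch$windows$high - sch$windows$low, rep(10, 75))
  # consecutive windows share 1 Th (0.5 per edge)
  expect_equal(sch$windows$high[-75] - sch$windows$low[-1], rep(1, 74))
  # tiling covers the range with no gaps
  expect_lte(sch$windows$low[1], 390)
  expect_gte(sch$windows$high[75], 1065)
})

test_that("disjoint scheme arithmetic and parameter validation", {
  sch <- build_isolation_scheme(400, 500, 10, 0)
  expect_equal(nrow(sch$windows), 10)
  expect_equal(sch$windows$low, seq(400, 490, 10))
  expect_equal(sch$windows$high, seq(410, 500, 10))
  expect_error(build_isolation_scheme(500, 400, 10, 0.5), "exceed")
  expect_error(build_isolation_scheme(400, 500, 1, 0.5), "overlap")
})

test_that("window assignment is nearest-centre with lower-index ties", {
  sch <- build_isolation_scheme(390, 1065, 10, 0.5)
  expect_equal(assign_window(sch, 395), 1)
  # every in-range precursor assigns to exactly one window
  for (mz in seq(391, 1064, length.out = 25)) {
    w <- assign_window(sch, mz)
    expect_true(sch$windows$low[w] <= mz && mz <= sch$windows$high[w])
  }
  # equidistant from two centres -> lower index
  mid <- mean(c(mean(unlist(sch$windows[1, ])),
                mean(unlist(sch$windows[2, ]))))
  expect_equal(assign_window(sch, mid), 1)
  expect_error(assign_window(sch, 2000), "outside")
})

test_that("XIC extraction honours the m/z tolerance and sums matches", {
  tab <- data.frame(rt = c(1, 1, 2, 2, 3),
                    mz = c(500.02, 500.03, 500.05, 499.99, 500.2),
                    intensity = c(10, 20, 5, 7, 100))
  x <- extract_xic(tab, 500.00, tol = 0.035)
  expect_equal(x$times, c(1, 2, 3))
  expect_equal(x$intensities, c(30, 7, 0))  # 0.05 out, 0.2 out; 1 min sums
  expect_error(extract_xic(tab[0, ], 500), "empty")
  # linearity: extraction of concatenated tables equals the sum
  tab2 <- tab; tab2$intensity <- tab2$intensity * 3
  x2 <- extract_xic(rbind(tab, tab2), 500.00)
  expect_equal(x2$intensities, x$intensities * 4)
})

test_that("iRT calibration recovers exact lines and rejects outliers", {
  irt <- seq(0, 100, length.out = 16)
  m <- fit_irt(irt, 0.8 * irt + 10)
  expect_equal(m$slope, 0.8, tolerance = 1e-10)
  expect_equal(m$intercept, 10, tolerance = 1e-9)
  expect_equal(m$residual_sd, 0, tolerance = 1e-9)
  rt <- 0.8 * irt + 10; rt[5] <- rt[5] + 30
  m2 <- fit_irt(irt, rt)
  expect_equal(m2$outliers_removed, 1)
  expect_equal(m2$slope, 0.8, tolerance = 0.01)
  expect_error(fit_irt(c(0, 50), c(10, 50)), "at least")
  # prediction is affine
  expect_equal(predict_rt(m, 100), 90, tolerance = 1e-9)
  expect_equal(predict_rt(m, 3) + predict_rt(m, 4) - predict_rt(m, 0),
               predict_rt(m, 7), tolerance = 1e-9)
})

test_that("noisy iRT fits recover the line within standard errors", {
  irt <- seq(0, 100, length.out = 16)
  truth <- c(slope = 0.8, intercept = 10)
  se_slope <- 0.1 / sqrt(sum((irt - mean(irt))^2))
  se_int <- 0.1 * sqrt(1 / 16 + mean(irt)^2 / sum((irt - mean(irt))^2))
  set.seed(123)
  ok_slope <- ok_int <- 0
  for (i in 1:100) {
    m <- fit_irt(irt, 0.8 * irt + 10 + rnorm(16, 0, 0.1))
    ok_slope <- ok_slope + (abs(m$slope - 0.8) <= 3 * se_slope)
    ok_int <- ok_int + (abs(m$intercept - 10) <= 3 * se_int)
  }
  expect_gte(ok_slope, 97)
  expect_gte(ok_int, 97)
})

test_that("peak-group detection finds planted Gaussians", {
  times <- seq(10, 20, by = 0.05)
  # one clean Gaussian at the predicted RT
  tr <- gauss_traces(times, 15, areas = c(100, 60, 40))
  pg <- detect_peak_groups(times, tr, predicted_rt = 15)
  expect_equal(nrow(pg$candidates), 1)
  expect_lt(abs(pg$candidates$rt_apex[1] - 15), 0.051)
  expect_equal(pg$areas[1, ] / sum(pg$areas[1, ]), c(100, 60, 40) / 200,
               tolerance = 0.02)
  # two equal Gaussians 2 min apart
  tr2 <- gauss_traces(times, 14, c(100)) + gauss_traces(times, 16, c(100))
  pg2 <- detect_peak_groups(times, tr2, predicted_rt = 15)
  expect_equal(nrow(pg2$candidates), 2)
  # flat baseline: no candidate above S/N 1
  flat <- matrix(5, length(times), 2)
  pg3 <- detect_peak_groups(times, flat, predicted_rt = 15, min_sn = 1.01)
  expect_equal(nrow(pg3$candidates), 0)
  expect_error(detect_peak_groups(times[1:3], tr[1:3, ], 15), "5 points")
})

test_that("peak areas are invariant to a uniform time shift", {
  times <- seq(10, 20, by = 0.05)
  tr <- gauss_traces(times, 15, areas = c(100, 60))
  a <- detect_peak_groups(times, tr, 15)$areas
  b <- detect_peak_groups(times + 7, tr, 22)$areas
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("QC report computes ppm errors and iRT deviations", {
  cfg <- sim_config(n_proteins = 10, peptides_per_protein = c(2, 2),
                    n_populations = 1, replicates = 2, batches = 1,
                    frac_differential = 0, interference_rate = 0,
                    seed = 21)
  gt <- generate_ground_truth(cfg)
  run <- simulate_dia_experiment(gt$library, gt$truth, gt$annot, cfg)
  models <- calibrate_rt(run)
  qc <- qc_report(run, models, attr(models, "standard_rt"))
  # jitter is drawn uniformly within +/-5 ppm
  expect_true(all(qc$mass_error$max_abs_ppm <= 20))
  expect_true(all(abs(qc$irt_deviation$deviation) <= 1, na.rm = TRUE))
  # exact m/z values give zero ppm error
  run0 <- run
  run0$mz_observed$observed_mz <- run0$mz_observed$theoretical_mz
  qc0 <- qc_report(run0, models, attr(models, "standard_rt"))
  expect_equal(max(abs(qc0$mass_error$max_abs_ppm)), 0)
})
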