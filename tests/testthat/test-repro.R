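mk_cs <- function(df) comparison_set(df)

base_cs <- function() {
  # 3 proteins x 1 population x 4 batches
  mk_cs(data.frame(
    protein = rep(c("A", "B", "C"), each = 4),
    population = "pop1",
    batch = rep(paste0("PS", 1:4), 3),
    log2fc = c(1.1, -1.2, 1.05, 1.0,      # A: sign flip in PS2
               1.2, 1.1, 1.15, 1.0,       # B: consistent, PS4 misses p
               0.5, 0.6, 0.4, 0.5),       # C: below threshold
    adj_p = c(0.01, 0.01, 0.01, 0.01,
              0.01, 0.01, 0.01, 0.2,
              0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE))
}

test_that("false positives are opposite-direction threshold crossings", {
  cs <- base_cs()
  # A is significant in PS1 with FC 2^1.1 and FC 2^-1.2 in PS2
  expect_equal(count_false_positives(cs, "pop1", "PS1"), 1)
  # in PS3 A is significant and PS2 is still opposite
  expect_equal(count_false_positives(cs, "pop1", "PS3"), 1)
  # B never flips direction
  cs_b <- mk_cs(cs[cs$protein == "B", ])
  expect_equal(count_false_positives(cs_b, "pop1", "PS1"), 0)
  expect_error(count_false_positives(mk_cs(cs[cs$batch == "PS1", ]),
                                     "pop1", "PS1"), "2 sampling batches")
  expect_error(count_false_positives(cs, "popX", "PS1"), "unknown")
})

test_that("false negatives reach the FC threshold but miss significance", {
  cs <- base_cs()
  # B in PS4: FC 2.0 in consensus direction, adj_p 0.2
  expect_equal(count_false_negatives(cs, "pop1", "PS4"), 1)
  expect_equal(count_false_negatives(cs, "pop1", "PS1"), 0)
  # C never reaches the threshold
  cs_c <- mk_cs(cs[cs$protein == "C", ])
  expect_equal(count_false_negatives(cs_c, "pop1", "PS2"), 0)
})

test_that("relaxing alpha never increases the false-negative count", {
  set.seed(55)
  cs <- mk_cs(data.frame(
    protein = rep(sprintf("P%02d", 1:30), each = 4),
    population = "pop1", batch = rep(paste0("PS", 1:4), 30),
    log2fc = rnorm(120, 0, 1.2), adj_p = runif(120, 0, 0.2),
    stringsAsFactors = FALSE))
  for (b in paste0("PS", 1:4)) {
    expect_lte(count_false_negatives(cs, "pop1", b, alpha = 0.05),
               count_false_negatives(cs, "pop1", b, alpha = 0.01))
  }
})

test_that("signatures require consistency in every batch", {
  cs <- base_cs()
  sig <- extract_signature(cs, "pop1")
  expect_equal(sig$up, character(0))   # A flips, B misses p in PS4
  expect_equal(sig$down, character(0))
  # planted always-elevated proteins are recovered exactly
  planted <- sprintf("UP%02d", 1:12)
  df <- expand.grid(protein = c(planted, "N1", "N2"),
                    batch = paste0("PS", 1:4), stringsAsFactors = FALSE)
  df$population <- "pop1"
  df$log2fc <- ifelse(df$protein %in% planted, 1.5, 0.1)
  df$adj_p <- ifelse(df$protein %in% planted, 0.001, 0.5)
  sig2 <- extract_signature(mk_cs(df), "pop1")
  expect_setequal(sig2$up, planted)
  expect_equal(sig2$down, character(0))
  # one protein missing one batch -> error
  drop_one <- !(df$protein == "UP01" & df$batch == "PS4")
  expect_error(extract_signature(mk_cs(df[drop_one, ]), "pop1"),
               "missing batch")
})

test_that("FP/FN/signature counts equal a brute-force re-scan", {
  set.seed(66)
  prots <- sprintf("P%02d", 1:50)
  df <- expand.grid(protein = prots, population = c("pop1", "pop2"),
                    batch = paste0("PS", 1:4), stringsAsFactors = FALSE)
  df$log2fc <- rnorm(nrow(df), 0, 1.3)
  df$adj_p <- runif(nrow(df))^2
  cs <- mk_cs(df)
  alpha <- 0.05; thr <- 2; l <- log2(thr)
  for (pop in c("pop1", "pop2")) {
    sub <- cs[cs$population == pop, ]
    cons <- tapply(sub$log2fc, sub$protein, mean)
    for (b in paste0("PS", 1:4)) {
      f <- sub[sub$batch == b, ]
      o <- sub[sub$batch != b, ]
      fp <- 0L; fn <- 0L
      for (i in seq_len(nrow(f))) {
        oo <- o[o$protein == f$protein[i], ]
        sig_i <- f$adj_p[i] < alpha && abs(f$log2fc[i]) >= l
        if (sig_i && ((f$log2fc[i] > 0 && any(oo$log2fc <= -l)) ||
                      (f$log2fc[i] < 0 && any(oo$log2fc >= l))))
          fp <- fp + 1L
        dir_i <- sign(cons[f$protein[i]])
        if (f$adj_p[i] >= alpha && sign(f$log2fc[i]) == dir_i &&
            abs(f$log2fc[i]) >= l)
          fn <- fn + 1L
      }
      expect_equal(count_false_positives(cs, pop, b, alpha, thr), fp)
      expect_equal(count_false_negatives(cs, pop, b, alpha, thr), fn)
    }
    up <- prots[vapply(prots, function(p) {
      d <- sub[sub$protein == p, ]
      all(d$adj_p < alpha & d$log2fc >= l)
    }, logical(1))]
    expect_setequal(extract_signature(cs, pop, alpha, thr)$up, up)
  }
})

test_that("volcano tables classify and clip like the figure legend", {
  cs <- mk_cs(data.frame(
    protein = c("A", "B", "C", "D"), population = "pop1", batch = "PS1",
    log2fc = c(log2(2.5), log2(2.5), 3, 0.2),
    adj_p = c(0.005, 0.03, 0.001, 0.001), stringsAsFactors = FALSE))
  v <- volcano_table(cs, "pop1", "PS1")
  expect_equal(v$significance, c("p<0.01", "p<0.05", "p<0.01", "ns"))
  expect_equal(v$direction, c("elevated", "elevated", "elevated", "none"))
  expect_equal(v$log2fc_plot[3], 2)       # clipped at FC 4
  expect_true(v$clipped[3])
  expect_false(any(v$clipped[-3]))
})

test_that("a protein is FP-, FN- or signature-counted at most once", {
  set.seed(44)
  cs <- mk_cs(data.frame(
    protein = rep(sprintf("Q%02d", 1:20), each = 4),
    population = "pop1", batch = rep(paste0("PS", 1:4), 20),
    log2fc = rnorm(80, 0.5, 1), adj_p = runif(80, 0, 0.1),
    stringsAsFactors = FALSE))
  alpha <- 0.05; thr <- 2; l <- log2(thr)
  sig <- extract_signature(cs, "pop1", alpha, thr)
  for (b in paste0("PS", 1:4)) {
    f <- cs[cs$batch == b, ]
    cons <- tapply(cs$log2fc, cs$protein, mean)
    for (p in unique(cs$protein)) {
      r <- f[f$protein == p, ]
      is_fp_cand <- r$adj_p < alpha && abs(r$log2fc) >= l
      is_fn <- r$adj_p >= alpha && abs(r$log2fc) >= l &&
        sign(r$log2fc) == sign(cons[p])
      in_sig <- p %in% c(sig$up, sig$down)
      # signature membership requires per-batch significance, which
      # excludes the FN condition; FP requires an opposite batch, which
      # excludes signature membership
      expect_false(is_fn && in_sig)
    }
  }
})
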