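# Run-level orchestration: per-sample iRT calibration from standard
# peptides, peak-group detection and scoring across a run, and protein
# quantitation of accepted peak groups.

#' Calibrate per-sample iRT models from standard peptides
#'
#' Detects the strongest peak group for each iRT standard in each sample
#' (searching the full simulated trace) and fits a linear iRT-to-RT model
#' per sample.
#'
#' @param run A `dia_run`.
#' @return Named list of `irt_model` objects, one per sample, with an
#'   attribute `standard_rt` (data.frame `sample_id`, `irt`, `observed_rt`).
#' @export
calibrate_rt <- function(run) {
  std <- run$precursors[run$precursors$standard, , drop = FALSE]
  if (nrow(std) < 3) stop("run contains fewer than 3 iRT standards")
  models <- list()
  obs_all <- list()
  for (s in run$annot$sample_id) {
    rt_obs <- rep(NA_real_, nrow(std))
    for (i in seq_len(nrow(std))) {
      tr <- run$traces[[s]][[std$key[i]]]
      pg <- detect_peak_groups(tr$times, tr$intens,
                               predicted_rt = mean(tr$times),
                               rt_window = diff(range(tr$times)))
      if (nrow(pg$candidates) > 0) rt_obs[i] <- pg$candidates$rt_apex[1]
    }
    models[[s]] <- fit_irt(std$irt, rt_obs)
    obs_all[[s]] <- data.frame(sample_id = s, irt = std$irt,
                               observed_rt = rt_obs,
                               stringsAsFactors = FALSE)
  }
  attr(models, "standard_rt") <- do.call(rbind, obs_all)
  models
}

# Candidate matrix with subscores for one (precursor, sample): numeric
# matrix with columns rt_apex, start, end, fwhm, sn, dotp, coelution,
# rt_dev, log_area, cand_id; plus the per-candidate area matrix.
candidate_subscores <- function(tr, pred_rt, lib_int, rt_window) {
  pg <- pg_detect(tr$times, tr$intens, pred_rt, rt_window)
  n <- pg$n
  if (n == 0L) return(NULL)
  dotp <- numeric(n); coel <- numeric(n)
  for (i in seq_len(n)) {
    dotp[i] <- dotp_fast(lib_int, pg$areas[i, ])
    coel[i] <- coelution_fast(
      tr$intens[pg$start_idx[i]:pg$end_idx[i], , drop = FALSE])
  }
  m <- cbind(rt_apex = pg$rt_apex, start = pg$start, end = pg$end,
             fwhm = pg$fwhm, sn = pg$sn, dotp = dotp, coelution = coel,
             rt_dev = abs(pg$rt_apex - pred_rt),
             log_area = log10(1 + rowSums(pg$areas)),
             cand_id = seq_len(n))
  list(candidates = m, areas = pg$areas)
}

#' Detect and score peak groups across a DIA run
#'
#' For every non-standard precursor and sample, candidate peak groups are
#' detected around the predicted RT (from per-sample iRT calibration) and
#' subscored; a semi-supervised linear discriminant is trained on the best
#' target candidates against decoy candidates, all candidates are rescored,
#' and q-values are estimated for the best target peak group per
#' (precursor, sample) against the corresponding decoy scores.
#'
#' @param lib The `assay_library` the run was acquired against (targets and
#'   decoys).
#' @param run A `dia_run`.
#' @param rt_window RT search half-window, minutes (default 3).
#' @param iterations Discriminant refinement iterations (default 3).
#' @param seed Seed recorded in the discriminant model (default 1).
#' @return List of class `scored_run`: `peak_groups` (best candidate per
#'   precursor and sample with subscores, discriminant `score` and
#'   `qvalue` for targets), `areas` (long per-transition areas of best
#'   target candidates), `model`, `irt_models`, `qc`.
#' @export
score_dia_run <- function(lib, run, rt_window = 3, iterations = 3L,
                          seed = 1L) {
  irt_models <- calibrate_rt(run)
  df <- as.data.frame(lib)
  keyvec <- precursor_key(lib)
  prec <- run$precursors[!run$precursors$standard, , drop = FALSE]
  samples <- run$annot$sample_id

  all_cand <- vector("list", nrow(prec) * length(samples))
  all_areas <- vector("list", length(all_cand))
  slot_si <- integer(length(all_cand))
  slot_pi <- integer(length(all_cand))
  slot <- 0L
  for (si in seq_along(samples)) {
    s <- samples[si]
    model_s <- irt_models[[s]]
    traces_s <- run$traces[[s]]
    for (pi in seq_len(nrow(prec))) {
      key <- prec$key[pi]
      tr <- traces_s[[key]]
      if (is.null(tr)) next
      pred <- predict_rt(model_s, prec$irt[pi])
      rows <- run$library_rows[[key]]
      cs <- candidate_subscores(tr, pred, df$LibraryIntensity[rows],
                                rt_window)
      if (is.null(cs)) next
      slot <- slot + 1L
      all_cand[[slot]] <- cs$candidates
      all_areas[[slot]] <- cs$areas
      slot_si[slot] <- si
      slot_pi[slot] <- pi
    }
  }
  if (slot == 0L) stop("no candidate peak groups detected in the run")
  cm <- do.call(rbind, all_cand[seq_len(slot)])
  n_per_slot <- vapply(all_cand[seq_len(slot)], nrow, 0L)
  cand <- as.data.frame(cm)
  cand$row_id <- seq_len(nrow(cand))
  cand$sample_id <- samples[rep(slot_si[seq_len(slot)], n_per_slot)]
  pidx <- rep(slot_pi[seq_len(slot)], n_per_slot)
  cand$key <- prec$key[pidx]
  cand$decoy <- prec$decoy[pidx]
  cand$protein <- prec$protein[pidx]
  cand$signal_free <- prec$signal_free[pidx]

  sub_mat <- cm[, SUBSCORE_NAMES, drop = FALSE]
  pair <- paste(cand$sample_id, cand$key)
  # training set: best candidate per (precursor, sample) by dotp
  best_by_dotp <- tapply(cand$row_id, pair, function(r)
    r[which.max(cand$dotp[r])])
  best0 <- unlist(best_by_dotp, use.names = FALSE)
  tgt <- best0[!cand$decoy[best0]]
  dec <- best0[cand$decoy[best0]]
  if (length(dec) == 0)
    stop("scoring requires decoy precursors in the library")
  model <- train_discriminant(sub_mat[tgt, , drop = FALSE],
                              sub_mat[dec, , drop = FALSE],
                              seed = seed, iterations = iterations)
  cand$score <- score_subscores(model, sub_mat)
  best <- tapply(cand$row_id, pair, function(r)
    r[which.max(cand$score[r])])
  best <- unlist(best, use.names = FALSE)
  bg <- cand[cand$row_id %in% best, , drop = FALSE]
  bg$qvalue <- NA_real_
  is_t <- !bg$decoy
  bg$qvalue[is_t] <- estimate_qvalues(bg$score[is_t], bg$score[!is_t])

  # long per-transition areas for best target candidates
  area_rows <- list()
  # map row_id back to its (slot, cand_id) to index the areas matrices
  slot_of <- rep(seq_len(slot), n_per_slot)
  for (r in which(is_t)) {
    row_id <- bg$row_id[r]
    sl <- slot_of[row_id]
    a <- all_areas[[sl]][bg$cand_id[r], ]
    rows <- run$library_rows[[bg$key[r]]]
    area_rows[[length(area_rows) + 1]] <- data.frame(
      sample_id = bg$sample_id[r], key = bg$key[r],
      feature = paste0(bg$key[r], "_", df$FragmentType[rows],
                       df$FragmentSeriesNumber[rows], "_",
                       df$FragmentCharge[rows]),
      protein = bg$protein[r], area = as.numeric(a),
      qvalue = bg$qvalue[r], stringsAsFactors = FALSE)
  }
  areas <- do.call(rbind, area_rows)
  qc <- qc_report(run, irt_models, attr(irt_models, "standard_rt"))
  structure(list(peak_groups = bg, areas = areas, model = model,
                 irt_models = irt_models, qc = qc),
            class = "scored_run")
}

#' Protein quantitation of a scored run
#'
#' Accepts target peak groups at the q-value threshold, assembles the
#' transition-level log2 matrix (absent peaks missing), equalizes sample
#' medians, and summarizes each protein by median polish.
#'
#' @param scored A `scored_run`.
#' @param annot Sample annotation (fixes the sample column order).
#' @param q_threshold Peak-group acceptance threshold (default 0.005).
#' @return List with `protein_abundance` (matrix, proteins x samples) and
#'   `quant` (the normalized transition-level `quant_matrix`).
#' @export
quantify_run <- function(scored, annot, q_threshold = 0.005) {
  acc <- scored$areas[scored$areas$qvalue <= q_threshold, , drop = FALSE]
  if (nrow(acc) == 0) stop("no peak groups accepted at q <= ", q_threshold)
  qm <- quant_matrix(acc, samples = annot$sample_id)
  qm <- normalize_medians(qm)
  list(protein_abundance = summarize_proteins(qm), quant = qm)
}

#' One-vs-rest differential testing for every population
#'
#' @param protein_abund Protein abundance matrix (proteins x samples).
#' @param annot Sample annotation.
#' @param combined Include the sampling-batch term (default TRUE).
#' @return Named list of `diff_result` data.frames, one per population.
#' @export
compare_populations <- function(protein_abund, annot, combined = TRUE) {
  pops <- sort(unique(annot$population))
  out <- lapply(pops, function(p)
    differential_test(protein_abund, annot, p, combined = combined))
  names(out) <- pops
  out
}
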