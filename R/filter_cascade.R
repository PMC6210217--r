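# Seven-step reduction of an initial target list to a final assay library.
#
# Steps 1-4 are static sequence/library rules; step 5 (dotp) and step 7
# (codified peak curation) need a scored training run; step 6 is the
# two-peptides-per-protein rule. A per-step census report tracks shrinkage.

#' Curation settings for the codified peak-quality rules
#'
#' @param rt_window Half-width of the retention-time search window around
#'   the predicted RT, minutes (default 3).
#' @param detect_min_sn Minimum apex signal-to-noise for a precursor to
#'   count as detected (default 3).
#' @param width_ratio_max Maximum tolerated ratio between the median FWHM of
#'   the wider and narrower halves of a population's samples (default 2).
#' @param max_interfered_transitions Maximum number of interference-flagged
#'   transitions tolerated per precursor (default 1).
#' @param population_fraction Fraction of one population's samples in which
#'   a defect must occur to trigger removal (default 0.5).
#' @return A list of class `curation_settings`.
#' @export
curation_settings <- function(rt_window = 3, detect_min_sn = 3,
                              width_ratio_max = 2,
                              max_interfered_transitions = 1L,
                              population_fraction = 0.5) {
  stopifnot(rt_window > 0, detect_min_sn > 0, width_ratio_max > 0,
            max_interfered_transitions >= 0, population_fraction > 0)
  structure(list(rt_window = rt_window, detect_min_sn = detect_min_sn,
                 width_ratio_max = width_ratio_max,
                 max_interfered_transitions =
                   as.integer(max_interfered_transitions),
                 population_fraction = population_fraction),
            class = "curation_settings")
}

# prune precursors/peptides whose parents vanished; no-op for flat table
drop_rows <- function(lib, keep, step_id) {
  out <- as.data.frame(lib)[keep, , drop = FALSE]
  rownames(out) <- NULL
  assay_library(out, provenance = c(attr(lib, "provenance"), step_id),
                check_mz = FALSE)
}

#' Apply one of the four static library filters
#'
#' Step 1 removes peptides carrying any modification other than
#' Met-oxidation or Cys-carbamidomethylation. Step 2 removes repeated
#' peptide entries and peptides shared between proteins (peptide uniqueness
#' by proteins). Step 3 removes precursors with fewer than four transitions.
#' Step 4 removes peptides with any missed cleavage.
#'
#' @param lib An `assay_library`.
#' @param step Integer 1-4.
#' @param min_transitions Minimum transitions per precursor for step 3
#'   (default 4).
#' @return Filtered `assay_library`.
#' @export
apply_static_filter <- function(lib, step, min_transitions = 4L) {
  if (!(step %in% 1:4)) stop("invalid static filter step: ", step)
  if (nrow(lib) == 0) return(lib)
  if (step == 1) {
    ok_pep <- vapply(unique(lib$ModifiedPeptideSequence), function(s) {
      mods <- parse_modified_sequence(s)$modifications
      all(mods$kind %in% c("Met-oxidation", "Cys-carbamidomethyl"))
    }, logical(1))
    keep <- lib$ModifiedPeptideSequence %in%
      names(ok_pep)[ok_pep]
    return(drop_rows(lib, keep, "step1_ptm"))
  }
  if (step == 2) {
    # duplicate transition rows collapse to one; peptides mapping to more
    # than one protein are removed entirely
    dup <- duplicated(paste(lib$ModifiedPeptideSequence, lib$PrecursorCharge,
                            lib$ProductMz, lib$FragmentCharge,
                            lib$ProteinId))
    prot_per_pep <- tapply(lib$ProteinId, lib$PeptideSequence,
                           function(x) length(unique(x)))
    shared <- names(prot_per_pep)[prot_per_pep > 1]
    keep <- !dup & !(lib$PeptideSequence %in% shared)
    return(drop_rows(lib, keep, "step2_unique"))
  }
  if (step == 3) {
    key <- paste0(precursor_key(lib), "|", lib$Decoy)
    n_tr <- table(key)
    keep <- key %in% names(n_tr)[n_tr >= min_transitions]
    return(drop_rows(lib, keep, "step3_min_transitions"))
  }
  # step 4
  mc <- vapply(lib$PeptideSequence, missed_cleavages, 0L)
  drop_rows(lib, mc == 0L, "step4_missed_cleavage")
}

#' Dot-product filter (step 5)
#'
#' Removes a peptide when its precursor's dotp is below `threshold` in
#' every training sample; one passing sample suffices to keep it
#' (strict `<` at the boundary).
#'
#' @param lib An `assay_library`.
#' @param dotp_table data.frame with columns `key` (precursor key,
#'   `"<modseq>/<charge>"`), `sample_id`, `dotp`.
#' @param threshold dotp threshold (default 0.8).
#' @return Filtered `assay_library`.
#' @export
dotp_filter <- function(lib, dotp_table, threshold = 0.8) {
  if (nrow(lib) == 0) return(lib)
  keys <- unique(precursor_key(lib)[lib$Decoy == 0L])
  missing_keys <- setdiff(keys, dotp_table$key)
  if (length(missing_keys) > 0)
    stop("dotp table lacks coverage for precursor(s): ",
         paste(utils::head(missing_keys, 5), collapse = ", "))
  max_dotp <- tapply(dotp_table$dotp, dotp_table$key, max)
  fails <- names(max_dotp)[max_dotp < threshold]
  fail_pep <- sub("/[0-9]+$", "", fails)
  keep <- !(lib$ModifiedPeptideSequence %in% fail_pep) | lib$Decoy == 1L
  drop_rows(lib, keep, "step5_dotp")
}

#' Minimum-peptides-per-protein filter (step 6)
#'
#' @param lib An `assay_library`.
#' @param min_peptides Minimum remaining peptides per protein (default 2).
#' @return Filtered `assay_library`.
#' @export
protein_min_peptides <- function(lib, min_peptides = 2L) {
  if (nrow(lib) == 0) return(lib)
  tgt <- lib$Decoy == 0L
  n_pep <- tapply(lib$ModifiedPeptideSequence[tgt], lib$ProteinId[tgt],
                  function(x) length(unique(x)))
  good <- names(n_pep)[n_pep >= min_peptides]
  keep <- (lib$ProteinId %in% good & tgt) | !tgt
  drop_rows(lib, keep, "step6_min_peptides")
}

# Measurements used by the curation rules for one (precursor, sample):
# on-target apex, S/N, FWHM, and the per-transition interference flag
# (an off-target local maximum within the RT window exceeding the on-target
# apex of that transition).
curation_measure <- function(times, intens, pred_rt, settings) {
  win <- abs(times - pred_rt) <= settings$rt_window
  k <- ncol(intens)
  if (!any(win))
    return(list(detected = FALSE, fwhm = NA_real_, interfered = rep(FALSE, k)))
  total <- rowSums(intens)
  sm <- sg_smooth(total)
  baseline <- stats::median(abs(sm))
  apex_idx <- which(win)[which.max(sm[win])]
  apex <- sm[apex_idx]
  sn <- apex / max(baseline, 1e-9)
  detected <- sn >= settings$detect_min_sn
  fwhm <- trace_fwhm(times, sm, apex_idx)
  # per-transition interference: the on-target peak is the local maximum
  # nearest the predicted RT; an off-target maximum separated by more than
  # one nominal peak width that exceeds it flags the transition
  interfered <- vapply(seq_len(k), function(j) {
    s <- sg_smooth(intens[, j])
    loc <- local_maxima(s)
    loc <- loc[abs(times[loc] - pred_rt) <= settings$rt_window]
    if (length(loc) == 0) return(FALSE)
    on_idx <- loc[which.min(abs(times[loc] - pred_rt))]
    on_apex <- s[on_idx]
    off <- loc[abs(times[loc] - times[on_idx]) > 0.5]
    length(off) > 0 && max(s[off]) > on_apex
  }, logical(1))
  list(detected = detected, fwhm = fwhm, interfered = interfered, sn = sn)
}

#' Codified peak-shape curation (step 7)
#'
#' Applies, in order, the four peak-quality rules: (1) a transition is
#' removed when an interference exceeds its on-target peak in at least
#' `population_fraction` of the samples of any one population; (2) a
#' precursor is removed when it is not detected (apex S/N below
#' `detect_min_sn` within `rt_window` minutes of the predicted RT) in at
#' least half the samples of any one population; (3) a precursor is removed
#' when, within any population, the median FWHM of the wider half of samples
#' exceeds `width_ratio_max` times the median FWHM of the narrower half;
#' (4) a precursor is removed when more than `max_interfered_transitions` of
#' its transitions are interference-flagged in the same sample, in at least
#' `population_fraction` of any population's samples. The minimum-transition
#' and minimum-peptide constraints are re-applied afterwards.
#'
#' @param lib An `assay_library` (targets; decoy rows pass through).
#' @param run A `dia_run` (see [simulate_dia_experiment()]) covering every
#'   target precursor in every sample.
#' @param annot Sample annotation data.frame.
#' @param settings A [curation_settings()].
#' @return Filtered `assay_library`.
#' @export
automated_curation <- function(lib, run, annot,
                               settings = curation_settings()) {
  if (nrow(lib) == 0) return(lib)
  tgt_rows <- lib$Decoy == 0L
  keys <- unique(precursor_key(lib)[tgt_rows])
  samples <- annot$sample_id
  pops <- split(annot$sample_id, annot$population)

  drop_precursor <- character(0)
  drop_transition <- list()  # key -> integer vector of transition indices

  for (key in keys) {
    meas <- vector("list", length(samples))
    names(meas) <- samples
    for (s in samples) {
      tr <- run$traces[[s]][[key]]
      if (is.null(tr))
        stop("missing peak data for precursor ", key, " in sample ", s)
      meas[[s]] <- curation_measure(tr$times, tr$intens, tr$pred_rt, settings)
    }
    k <- ncol(run$traces[[samples[1]]][[key]]$intens)
    removed_tr <- integer(0)
    for (pop in names(pops)) {
      ps <- pops[[pop]]
      frac_needed <- settings$population_fraction
      # rule 1: per-transition interference fraction
      for (j in seq_len(k)) {
        bad <- mean(vapply(ps, function(s) meas[[s]]$interfered[j],
                           logical(1)))
        if (bad >= frac_needed) removed_tr <- union(removed_tr, j)
      }
      # rule 2: undetected in >= half the population
      undet <- mean(vapply(ps, function(s) !meas[[s]]$detected, logical(1)))
      if (undet >= 0.5) drop_precursor <- union(drop_precursor, key)
      # rule 3: peak-width split ratio
      fw <- vapply(ps, function(s) meas[[s]]$fwhm, 0)
      fw <- fw[is.finite(fw)]
      if (length(fw) >= 4) {
        fw <- sort(fw)
        half <- floor(length(fw) / 2)
        lo <- stats::median(fw[seq_len(half)])
        hi <- stats::median(fw[(length(fw) - half + 1):length(fw)])
        if (hi > settings$width_ratio_max * lo)
          drop_precursor <- union(drop_precursor, key)
      }
      # rule 4: multiple interfered transitions in the same sample
      multi <- mean(vapply(ps, function(s)
        sum(meas[[s]]$interfered) > settings$max_interfered_transitions,
        logical(1)))
      if (multi >= frac_needed) drop_precursor <- union(drop_precursor, key)
    }
    if (length(removed_tr) > 0) drop_transition[[key]] <- removed_tr
  }

  keep <- rep(TRUE, nrow(lib))
  keyvec <- precursor_key(lib)
  keep[tgt_rows & keyvec %in% drop_precursor] <- FALSE
  for (key in names(drop_transition)) {
    rows <- which(tgt_rows & keyvec == key)
    # transition order in traces follows the library row order within key
    keep[rows[drop_transition[[key]]]] <- FALSE
  }
  out <- drop_rows(lib, keep, "step7_curation")
  out <- apply_static_filter(out, 3)
  protein_min_peptides(out)
}

#' Run the seven-step filter cascade
#'
#' @param initial The initial `assay_library`.
#' @param training List with components `dotp` (data.frame `key`,
#'   `sample_id`, `dotp` for step 5) and `run` (a `dia_run` for step 7);
#'   either may be `NULL` to skip the corresponding data-driven step.
#' @param annot Sample annotation for the training samples.
#' @param settings A [curation_settings()].
#' @param dotp_threshold dotp threshold for step 5 (default 0.8).
#' @return List with `library` (final `assay_library`) and `report`
#'   (data.frame of class `filter_report`: per-step censuses and removals).
#' @export
run_cascade <- function(initial, training = NULL, annot = NULL,
                        settings = curation_settings(),
                        dotp_threshold = 0.8) {
  lib <- initial
  report <- cbind(data.frame(step_id = 0L, step = "initial"),
                  as.data.frame(census(lib)))
  record <- function(step_id, step, lib) {
    prev <- report[nrow(report), ]
    row <- cbind(data.frame(step_id = step_id, step = step),
                 as.data.frame(census(lib)))
    row$removed_proteins <- prev$n_proteins - row$n_proteins
    row$removed_peptides <- prev$n_peptides - row$n_peptides
    row$removed_precursors <- prev$n_precursors - row$n_precursors
    row$removed_transitions <- prev$n_transitions - row$n_transitions
    if (is.null(report$removed_proteins))
      report[c("removed_proteins", "removed_peptides", "removed_precursors",
               "removed_transitions")] <<- 0L
    report <<- rbind(report, row)
  }
  lib <- apply_static_filter(lib, 1); record(1L, "ptm", lib)
  lib <- apply_static_filter(lib, 2); record(2L, "uniqueness", lib)
  lib <- apply_static_filter(lib, 3); record(3L, "min_transitions", lib)
  lib <- apply_static_filter(lib, 4); record(4L, "missed_cleavage", lib)
  if (!is.null(training$dotp)) {
    lib <- dotp_filter(lib, training$dotp, dotp_threshold)
  }
  record(5L, "dotp", lib)
  lib <- protein_min_peptides(lib); record(6L, "min_peptides", lib)
  if (!is.null(training$run)) {
    lib <- automated_curation(lib, training$run, annot, settings)
  }
  record(7L, "curation", lib)
  class(report) <- c("filter_report", "data.frame")
  list(library = lib, report = report)
}
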