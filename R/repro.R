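# Cross-sampling reproducibility statistics and population proteome
# signatures.

#' Assemble a comparison set from per-batch differential results
#'
#' @param results Named list (by sampling batch) of lists (by population) of
#'   `diff_result` data.frames, or a single long data.frame with columns
#'   `protein`, `population`, `batch`, `log2fc`, `adj_p`.
#' @return data.frame of class `comparison_set` with one row per (protein,
#'   population, batch).
#' @export
comparison_set <- function(results) {
  if (is.data.frame(results)) {
    cs <- results
  } else {
    rows <- list()
    for (batch in names(results)) {
      for (pop in names(results[[batch]])) {
        d <- results[[batch]][[pop]]
        rows[[length(rows) + 1]] <- data.frame(
          protein = d$protein, population = pop, batch = batch,
          log2fc = d$log2fc, adj_p = d$adj_p, stringsAsFactors = FALSE)
      }
    }
    cs <- do.call(rbind, rows)
  }
  need <- c("protein", "population", "batch", "log2fc", "adj_p")
  stopifnot(all(need %in% names(cs)))
  key <- paste(cs$protein, cs$population, cs$batch)
  if (anyDuplicated(key))
    stop("duplicate (protein, population, batch) record in comparison set")
  class(cs) <- c("comparison_set", "data.frame")
  cs
}

significant_in <- function(cs, alpha, fc_threshold) {
  cs$adj_p < alpha & abs(cs$log2fc) >= log2(fc_threshold)
}

check_pop_batch <- function(cs, population, batch = NULL) {
  if (!(population %in% cs$population))
    stop("unknown population: ", population)
  if (!is.null(batch) && !(batch %in% cs$batch))
    stop("unknown sampling batch: ", batch)
}

#' Count cross-batch false positives for one population and batch
#'
#' Counts proteins significant in the focal batch (adjusted p below `alpha`
#' and absolute fold change at or above `fc_threshold`) whose fold change in
#' any other batch lies beyond the reciprocal threshold in the opposite
#' direction (e.g. fold change 2 in the focal batch but 0.5 elsewhere).
#'
#' @param cs A `comparison_set`.
#' @param population,batch Focal population and sampling batch.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param fc_threshold Fold-change threshold (default 2).
#' @return Integer count.
#' @export
count_false_positives <- function(cs, population, batch, alpha = 0.05,
                                  fc_threshold = 2) {
  check_pop_batch(cs, population, batch)
  sub <- cs[cs$population == population, , drop = FALSE]
  if (length(unique(sub$batch)) < 2)
    stop("false-positive counting needs at least 2 sampling batches")
  focal <- sub[sub$batch == batch, , drop = FALSE]
  focal <- focal[significant_in(focal, alpha, fc_threshold), , drop = FALSE]
  other <- sub[sub$batch != batch, , drop = FALSE]
  lfc_thr <- log2(fc_threshold)
  n <- 0L
  for (i in seq_len(nrow(focal))) {
    o <- other[other$protein == focal$protein[i], , drop = FALSE]
    opposite <- if (focal$log2fc[i] > 0) any(o$log2fc <= -lfc_thr)
                else any(o$log2fc >= lfc_thr)
    if (isTRUE(opposite)) n <- n + 1L
  }
  n
}

#' Count false negatives for one population and batch
#'
#' Counts proteins whose fold change in the focal batch reaches
#' `fc_threshold` in the consensus direction (the sign of the mean log2
#' fold change across batches) but whose adjusted p-value misses `alpha`.
#'
#' @inheritParams count_false_positives
#' @return Integer count.
#' @export
count_false_negatives <- function(cs, population, batch, alpha = 0.05,
                                  fc_threshold = 2) {
  check_pop_batch(cs, population, batch)
  sub <- cs[cs$population == population, , drop = FALSE]
  if (length(unique(sub$batch)) < 2)
    stop("false-negative counting needs at least 2 sampling batches")
  consensus <- tapply(sub$log2fc, sub$protein, mean)
  focal <- sub[sub$batch == batch, , drop = FALSE]
  dir <- sign(consensus[focal$protein])
  lfc_thr <- log2(fc_threshold)
  hits <- focal$log2fc * dir >= lfc_thr & sign(focal$log2fc) == dir &
    focal$adj_p >= alpha
  sum(hits, na.rm = TRUE)
}

#' Extract a population proteome signature
#'
#' A protein enters the elevated (reduced) signature when it is significant
#' with fold change at or above `fc_threshold` (at or below its reciprocal)
#' in every sampling batch.
#'
#' @param cs A `comparison_set`.
#' @param population Focal population.
#' @param alpha Significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2).
#' @return List with `up` and `down` protein character vectors.
#' @export
extract_signature <- function(cs, population, alpha = 0.05,
                              fc_threshold = 2) {
  check_pop_batch(cs, population)
  sub <- cs[cs$population == population, , drop = FALSE]
  batches <- unique(cs$batch)
  per_prot <- split(sub, sub$protein)
  lfc_thr <- log2(fc_threshold)
  up <- character(0); down <- character(0)
  for (p in names(per_prot)) {
    d <- per_prot[[p]]
    if (!setequal(d$batch, batches))
      stop("protein ", p, " is missing batch(es) for population ",
           population)
    if (all(d$adj_p < alpha & d$log2fc >= lfc_thr)) up <- c(up, p)
    if (all(d$adj_p < alpha & d$log2fc <= -lfc_thr)) down <- c(down, p)
  }
  list(up = sort(up), down = sort(down))
}

#' Volcano-plot table for one population and batch
#'
#' Classifies each protein by significance tier and direction, and clips
#' plotting coordinates to the fold-change range `[1/max_fc, max_fc]`.
#'
#' @param cs A `comparison_set`.
#' @param population,batch Focal population and sampling batch.
#' @param fc_threshold Fold-change component of the significance call
#'   (default 2).
#' @param max_fc Fold-change clipping bound (default 4).
#' @return data.frame with `protein`, `log2fc`, `neg_log10_adj_p`,
#'   `significance` (`"p<0.01"`, `"p<0.05"`, `"ns"`), `direction`
#'   (`"elevated"`, `"reduced"`, `"none"`), `log2fc_plot`, `clipped`.
#' @export
volcano_table <- function(cs, population, batch, fc_threshold = 2,
                          max_fc = 4) {
  check_pop_batch(cs, population, batch)
  d <- cs[cs$population == population & cs$batch == batch, , drop = FALSE]
  lfc_thr <- log2(fc_threshold)
  passes_fc <- abs(d$log2fc) >= lfc_thr
  sig <- ifelse(d$adj_p < 0.01 & passes_fc, "p<0.01",
                ifelse(d$adj_p < 0.05 & passes_fc, "p<0.05", "ns"))
  direction <- ifelse(sig == "ns", "none",
                      ifelse(d$log2fc > 0, "elevated", "reduced"))
  lim <- log2(max_fc)
  clipped <- abs(d$log2fc) > lim
  data.frame(protein = d$protein, log2fc = d$log2fc,
             neg_log10_adj_p = -log10(d$adj_p), significance = sig,
             direction = direction,
             log2fc_plot = pmin(pmax(d$log2fc, -lim), lim),
             clipped = clipped, stringsAsFactors = FALSE)
}
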