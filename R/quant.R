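# Quantitation and inference: median normalization, median-polish protein
# summarization, one-vs-rest differential testing, BH correction, and the
# minimum-detectable-fold-change power calculation.

#' Build a transition-level quantitation matrix from scored peak groups
#'
#' @param areas Long data.frame with columns `sample_id`, `feature`
#'   (transition identifier), `protein`, `area`; absent (feature, sample)
#'   combinations are treated as missing peaks.
#' @param samples Character vector fixing the column order.
#' @return List of class `quant_matrix`: `values` (log2(area + 1), `NA`
#'   where missing), `protein` (per row), `samples`.
#' @export
quant_matrix <- function(areas, samples = sort(unique(areas$sample_id))) {
  feats <- unique(areas[c("feature", "protein")])
  m <- matrix(NA_real_, nrow(feats), length(samples),
              dimnames = list(feats$feature, samples))
  idx <- cbind(match(areas$feature, feats$feature),
               match(areas$sample_id, samples))
  ok <- !is.na(idx[, 2])
  m[idx[ok, , drop = FALSE]] <- log2(areas$area[ok] + 1)
  structure(list(values = m, protein = feats$protein, samples = samples),
            class = "quant_matrix")
}

#' Equalize sample medians
#'
#' Each sample column is shifted so that all column medians (over
#' non-missing values) equal the median of the original column medians;
#' within-sample differences are unchanged.
#'
#' @param qm A `quant_matrix` (or bare matrix of log2 intensities).
#' @return Same type as the input, normalized.
#' @export
normalize_medians <- function(qm) {
  m <- if (inherits(qm, "quant_matrix")) qm$values else qm
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) {
    bad <- colnames(m)[!is.finite(med)]
    stop("sample(s) with no non-missing values: ",
         paste(bad, collapse = ", "))
  }
  target <- stats::median(med)
  m <- sweep(m, 2, med - target)
  if (inherits(qm, "quant_matrix")) {
    qm$values <- m
    qm
  } else m
}

#' Tukey median polish
#'
#' Additive decomposition `overall + row + column` by alternating median
#' sweeps, row sweep first, iterated until the largest change is below
#' `tol` or `max_iter` sweeps.
#'
#' @param m Numeric matrix (no missing values).
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Maximum sweep pairs (default 10).
#' @return List with `overall`, `row`, `col`, `residuals`.
#' @export
median_polish <- function(m, tol = 1e-6, max_iter = 10L) {
  m <- as.matrix(m)
  overall <- 0
  row_eff <- rep(0, nrow(m))
  col_eff <- rep(0, ncol(m))
  r <- m
  for (it in seq_len(max_iter)) {
    rmed <- apply(r, 1, stats::median)
    r <- sweep(r, 1, rmed)
    row_eff <- row_eff + rmed
    d <- stats::median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    cmed <- apply(r, 2, stats::median)
    r <- sweep(r, 2, cmed)
    col_eff <- col_eff + cmed
    d <- stats::median(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    if (max(abs(rmed), abs(cmed)) < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

#' Summarize one protein's transitions to per-sample abundances
#'
#' Missing peaks are imputed as zero intensity (log2(0 + 1) = 0) and the
#' transition-by-sample block is decomposed by Tukey median polish; the
#' protein abundance in each sample is the overall effect plus the column
#' effect.
#'
#' @param block Matrix of log2 intensities (transitions x samples), `NA`
#'   for missing peaks.
#' @return Named numeric vector of per-sample protein abundances.
#' @export
summarize_protein <- function(block) {
  block <- as.matrix(block)
  stopifnot(nrow(block) >= 1)
  block[is.na(block)] <- 0
  if (nrow(block) == 1) return(stats::setNames(block[1, ], colnames(block)))
  mp <- median_polish(block)
  stats::setNames(mp$overall + mp$col, colnames(block))
}

#' Summarize a quantitation matrix to protein level
#'
#' @param qm A `quant_matrix`.
#' @return Matrix of protein abundances (proteins x samples).
#' @export
summarize_proteins <- function(qm) {
  prots <- unique(qm$protein)
  out <- matrix(NA_real_, length(prots), length(qm$samples),
                dimnames = list(prots, qm$samples))
  for (p in prots) {
    out[p, ] <- summarize_protein(
      qm$values[qm$protein == p, , drop = FALSE])
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Step-up BH adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' One-vs-rest differential abundance test
#'
#' Fits, per protein, a fixed-effects linear model of log2 abundance on a
#' group indicator (focal population vs all others), with an additive
#' sampling-batch term when `combined = TRUE`. The log2 fold change is the
#' group coefficient (positive = elevated in the focal population), tested
#' two-sided against the t distribution of the residual degrees of freedom.
#'
#' @param protein_abund Matrix, proteins x samples (log2 scale).
#' @param annot Sample annotation with `sample_id`, `population`,
#'   `sampling_batch` matching the matrix columns.
#' @param population Focal population label.
#' @param combined Include a sampling-batch term (use when samples span
#'   several batches).
#' @return data.frame of class `diff_result`: `protein`, `comparison`,
#'   `log2fc`, `se`, `p`, `adj_p`, `n_group`, `n_rest`.
#' @export
differential_test <- function(protein_abund, annot, population,
                              combined = FALSE) {
  samples <- colnames(protein_abund)
  ai <- annot[match(samples, annot$sample_id), ]
  if (any(is.na(ai$sample_id)))
    stop("annotation missing for sample(s): ",
         paste(samples[is.na(ai$sample_id)], collapse = ", "))
  grp <- as.numeric(ai$population == population)
  if (sum(grp) < 2 || sum(1 - grp) < 2)
    stop("need at least 2 samples on each side of the contrast")
  X <- cbind(intercept = 1, group = grp)
  if (combined && length(unique(ai$sampling_batch)) > 1) {
    b <- stats::model.matrix(~ factor(ai$sampling_batch))[, -1, drop = FALSE]
    colnames(b) <- paste0("batch", seq_len(ncol(b)))
    X <- cbind(X, b)
  }
  df_resid <- length(samples) - ncol(X)
  if (df_resid <= 0) stop("zero residual degrees of freedom")
  qr_x <- qr(X)
  xtx_inv_gg <- chol2inv(qr.R(qr_x))[2, 2]
  Y <- t(protein_abund)                    # samples x proteins
  coefs <- qr.coef(qr_x, Y)
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / df_resid
  beta <- coefs["group", ]
  se <- sqrt(sigma2 * xtx_inv_gg)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  out <- data.frame(protein = rownames(protein_abund),
                    comparison = paste0(population, "_vs_rest"),
                    log2fc = unname(beta), se = unname(se), p = unname(p),
                    adj_p = bh_adjust(unname(p)),
                    n_group = sum(grp), n_rest = sum(1 - grp),
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Power settings for the minimum-detectable-fold-change calculation
#'
#' @param power Target statistical power (default 0.8).
#' @param fdr Significance level used in the normal approximation
#'   (default 0.01).
#' @param cv Anticipated coefficient of variation of protein intensity on
#'   the natural scale.
#' @param m_tests Number of proteins tested (informational).
#' @return List of class `power_settings`.
#' @export
power_settings <- function(power = 0.8, fdr = 0.01, cv = 0.3,
                           m_tests = NULL) {
  stopifnot(power > 0, power < 1, fdr > 0, fdr < 1, cv > 0)
  structure(list(power = power, fdr = fdr, cv = cv, m_tests = m_tests),
            class = "power_settings")
}

cv_to_sigma_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)
sigma_log2_to_cv <- function(sigma) sqrt(exp((sigma * log(2))^2) - 1)

#' Minimum detectable fold change for a two-group comparison
#'
#' Classical two-sample normal approximation on the log2 scale:
#' `delta = (z[1 - fdr/2] + z[power]) * sqrt(2 * sigma^2 / n)` with
#' `sigma = sqrt(log(1 + cv^2)) / log(2)`; the returned fold change is
#' `2^delta`. Quadrupling `n` halves `delta`.
#'
#' @param n_per_group Biological replicates per group (>= 2).
#' @param settings A [power_settings()].
#' @return Minimum detectable fold change (> 1).
#' @export
min_detectable_fc <- function(n_per_group, settings = power_settings()) {
  stopifnot(n_per_group >= 2)
  sigma <- cv_to_sigma_log2(settings$cv)
  z <- stats::qnorm(1 - settings$fdr / 2) + stats::qnorm(settings$power)
  2^(z * sqrt(2 * sigma^2 / n_per_group))
}

#' Coefficient of variation implied by a target minimum detectable fold
#' change
#'
#' Inverts [min_detectable_fc()]: returns the CV at which the minimum
#' detectable fold change at `n_per_group` equals `fc`.
#'
#' @param fc Target fold change (> 1).
#' @param n_per_group Replicates per group.
#' @param settings A [power_settings()] (its `cv` is ignored).
#' @return Coefficient of variation on the natural scale.
#' @export
cv_for_min_fc <- function(fc, n_per_group, settings = power_settings()) {
  stopifnot(fc > 1)
  z <- stats::qnorm(1 - settings$fdr / 2) + stats::qnorm(settings$power)
  sigma <- log2(fc) / (z * sqrt(2 / n_per_group))
  sigma_log2_to_cv(sigma)
}
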