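# Semi-supervised target-decoy discrimination of peak groups and q-value
# estimation.

SUBSCORE_NAMES <- c("dotp", "coelution", "rt_dev", "log_area", "sn")

#' Normalized spectral contrast (dotp) between library and observed
#' intensities
#'
#' Cosine similarity of the square-root-transformed vectors:
#' `sum(sqrt(l * o)) / (sqrt(sum(l)) * sqrt(sum(o)))`.
#'
#' @param library_intensities Non-negative library intensity vector.
#' @param observed_areas Non-negative observed area vector (same length).
#' @return dotp in `[0, 1]`; 0 when the observed vector is all zero.
#' @export
compute_dotp <- function(library_intensities, observed_areas) {
  l <- library_intensities; o <- observed_areas
  stopifnot(length(l) == length(o), length(l) >= 2, all(l >= 0),
            all(o >= 0))
  if (all(l == 0)) stop("library intensity vector is all zero")
  if (all(o == 0)) return(0)
  min(1, sum(sqrt(l * o)) / (sqrt(sum(l)) * sqrt(sum(o))))
}

#' Subscores for one candidate peak group
#'
#' @param areas Per-transition areas within the candidate boundaries.
#' @param library_intensities Matching library intensities.
#' @param traces Matrix of raw transition traces restricted to the candidate
#'   boundaries (columns = transitions), used for the coelution score (mean
#'   pairwise Pearson correlation; constant traces contribute 0, a single
#'   transition scores 1).
#' @param rt_apex,predicted_rt Apex and predicted RT, minutes.
#' @param sn Apex signal-to-noise of the summed trace.
#' @return Named numeric vector with elements `dotp`, `coelution`,
#'   `rt_dev`, `log_area`, `sn`.
#' @export
compute_subscores <- function(areas, library_intensities, traces, rt_apex,
                              predicted_rt, sn) {
  k <- length(areas)
  coel <- 1
  if (k >= 2 && !is.null(traces) && nrow(traces) >= 3) {
    cors <- c()
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (stats::sd(traces[, i]) == 0 || stats::sd(traces[, j]) == 0) {
        cors <- c(cors, 0)
      } else {
        cors <- c(cors, stats::cor(traces[, i], traces[, j]))
      }
    }
    coel <- mean(cors)
  }
  c(dotp = compute_dotp(library_intensities, areas),
    coelution = coel,
    rt_dev = abs(rt_apex - predicted_rt),
    log_area = log10(1 + sum(areas)),
    sn = sn)
}

# unchecked fast paths used by the run-level scorer
dotp_fast <- function(l, o) {
  so <- sum(o)
  if (so <= 0) return(0)
  min(1, sum(sqrt(l * o)) / sqrt(sum(l) * so))
}

coelution_fast <- function(m) {
  k <- ncol(m); n <- nrow(m)
  if (k < 2 || n < 3) return(1)
  mc <- m - rep(colMeans(m), each = n)
  ss <- sqrt(colSums(mc^2))
  ok <- ss > 0
  tot <- 0
  if (sum(ok) >= 2) {
    r <- crossprod(mc[, ok, drop = FALSE]) / outer(ss[ok], ss[ok])
    tot <- (sum(r) - sum(ok)) / 2    # sum of upper triangle
  }
  tot / (k * (k - 1) / 2)            # zero-variance pairs contribute 0
}

#' Estimate q-values from target and decoy discriminant scores
#'
#' For each target score `s` the raw FDR is
#' `(1 + #decoys >= s) / max(1, #targets >= s) * (n_targets / n_decoys)`;
#' the q-value is the minimum raw FDR over all thresholds at or below `s`,
#' clipped to `[0, 1]` (monotone non-increasing in the score).
#'
#' @param target_scores,decoy_scores Numeric score vectors.
#' @return q-value per target, in input order.
#' @export
estimate_qvalues <- function(target_scores, decoy_scores) {
  stopifnot(length(target_scores) > 0, length(decoy_scores) > 0)
  nt <- length(target_scores); nd <- length(decoy_scores)
  ord <- order(target_scores, decreasing = TRUE)
  s <- target_scores[ord]
  # counts of scores >= s via sorted search; tied targets share one count
  n_dec_ge <- nd - findInterval(s - 1e-12, sort(decoy_scores))
  n_tgt_ge <- nt - findInterval(s - 1e-12, sort(target_scores))
  raw <- (1 + n_dec_ge) / pmax(1, n_tgt_ge) * (nt / nd)
  q_sorted <- rev(cummin(rev(raw)))
  q_sorted <- pmin(pmax(q_sorted, 0), 1)
  q <- numeric(nt)
  q[ord] <- q_sorted
  q
}

#' Train the semi-supervised linear discriminant
#'
#' Iteration 0 scores by dotp alone; each subsequent iteration labels
#' targets with current q-value below `q_learn` as positives, all decoys as
#' negatives, fits a linear discriminant (pooled covariance with a small
#' ridge), and rescores. If no target reaches `q_learn` at iteration 0 the
#' model falls back to dotp-only scoring with a warning.
#'
#' @param targets Matrix of target subscores (columns named as in
#'   `compute_subscores`), best candidate per (precursor, sample).
#' @param decoys Matrix of decoy subscores.
#' @param seed Integer seed (stored; the procedure is deterministic).
#' @param iterations Number of refinement iterations (default 3).
#' @param q_learn q-value threshold for positive labelling (default 0.15).
#' @return List of class `discriminant_model` with `weights` (named vector,
#'   includes the orientation), `iterations`, `seed`.
#' @export
train_discriminant <- function(targets, decoys, seed = 1L, iterations = 3L,
                               q_learn = 0.15) {
  targets <- as.matrix(targets); decoys <- as.matrix(decoys)
  stopifnot(nrow(targets) >= 20, nrow(decoys) >= 20,
            identical(colnames(targets), colnames(decoys)))
  dotp_w <- numeric(ncol(targets))
  names(dotp_w) <- colnames(targets)
  dotp_w["dotp"] <- 1
  w <- dotp_w
  ts <- drop(targets %*% w); ds <- drop(decoys %*% w)
  q <- estimate_qvalues(ts, ds)
  if (!any(q < q_learn)) {
    warning("no target reaches q < ", q_learn,
            " at iteration 0; falling back to dotp-only scoring")
    return(structure(list(weights = dotp_w, iterations = 0L,
                          seed = as.integer(seed)),
                     class = "discriminant_model"))
  }
  for (it in seq_len(iterations)) {
    pos <- targets[q < q_learn, , drop = FALSE]
    if (nrow(pos) < 2) break
    neg <- decoys
    mu1 <- colMeans(pos); mu0 <- colMeans(neg)
    s1 <- stats::cov(pos); s0 <- stats::cov(neg)
    sp <- ((nrow(pos) - 1) * s1 + (nrow(neg) - 1) * s0) /
      (nrow(pos) + nrow(neg) - 2)
    sp <- sp + diag(1e-6, ncol(sp))
    w <- drop(solve(sp, mu1 - mu0))
    names(w) <- colnames(targets)
    ts <- drop(targets %*% w); ds <- drop(decoys %*% w)
    q <- estimate_qvalues(ts, ds)
  }
  structure(list(weights = w, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "discriminant_model")
}

#' Score a peak group subscore matrix with a trained discriminant
#'
#' @param model A `discriminant_model`.
#' @param subscores Matrix with the model's subscore columns.
#' @return Numeric discriminant scores.
#' @export
score_subscores <- function(model, subscores) {
  drop(as.matrix(subscores)[, names(model$weights), drop = FALSE] %*%
         model$weights)
}
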