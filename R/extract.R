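# Isolation-window schemes, targeted chromatogram extraction, iRT
# calibration, and peak-group detection.

#' Build an overlapping isolation-window scheme
#'
#' Windows of fixed `width` are stepped by `width - 2 * edge_overlap` so
#' that consecutive windows share `2 * edge_overlap` Th (0.5 Th per edge
#' with the default overlap), covering `[range_low, range_high]`. The
#' default parameters (390-1065 Th, width 10, overlap 0.5) produce 75
#' windows.
#'
#' @param range_low,range_high Covered precursor m/z range, Th.
#' @param width Window width, Th.
#' @param edge_overlap Overlap per window edge, Th.
#' @return List of class `isolation_scheme` with a `windows` data.frame
#'   (`low`, `high`).
#' @export
build_isolation_scheme <- function(range_low = 390, range_high = 1065,
                                   width = 10, edge_overlap = 0.5) {
  if (range_high <= range_low)
    stop("range_high must exceed range_low")
  if (width <= 2 * edge_overlap)
    stop("width must exceed twice the edge overlap")
  step <- width - 2 * edge_overlap
  n <- ceiling((range_high - range_low) / step)
  low <- range_low - edge_overlap + (seq_len(n) - 1) * step
  structure(list(windows = data.frame(low = low, high = low + width),
                 width = width, edge_overlap = edge_overlap),
            class = "isolation_scheme")
}

#' @export
print.isolation_scheme <- function(x, ...) {
  n <- nrow(x$windows)
  cat(sprintf("Isolation scheme: %d windows of %.1f Th (%.2f Th edge overlap), %.1f-%.1f Th\n",
              n, x$width, x$edge_overlap, x$windows$low[1],
              x$windows$high[n]))
  invisible(x)
}

#' Assign a precursor m/z to its isolation window
#'
#' Returns the index of the window whose centre is nearest the precursor
#' m/z; ties (shared window boundaries) resolve to the lower index.
#'
#' @param scheme An `isolation_scheme`.
#' @param precursor_mz Precursor m/z, Th.
#' @return 1-based window index.
#' @export
assign_window <- function(scheme, precursor_mz) {
  w <- scheme$windows
  inside <- precursor_mz >= w$low & precursor_mz <= w$high
  if (!any(inside))
    stop("precursor m/z ", precursor_mz, " outside the covered range")
  centers <- (w$low + w$high) / 2
  d <- abs(centers - precursor_mz)
  which.min(d)  # which.min takes the first (lower index) on ties
}

#' Extract an ion chromatogram from per-window spectra records
#'
#' @param spectra_table data.frame with columns `rt` (minutes), `mz` (Th),
#'   `intensity` for one isolation window.
#' @param product_mz Transition product m/z, Th.
#' @param tol Extraction tolerance, Th (default 0.035).
#' @return List of class `chromatogram` with `times` and `intensities`
#'   (summed intensity of all peaks within `tol` at each time point, zero
#'   where none match).
#' @export
extract_xic <- function(spectra_table, product_mz, tol = 0.035) {
  if (nrow(spectra_table) == 0) stop("empty window data")
  times <- sort(unique(spectra_table$rt))
  hit <- abs(spectra_table$mz - product_mz) <= tol
  intensities <- numeric(length(times))
  if (any(hit)) {
    agg <- tapply(spectra_table$intensity[hit], spectra_table$rt[hit], sum)
    intensities[match(as.numeric(names(agg)), times)] <- as.numeric(agg)
  }
  structure(list(times = times, intensities = intensities),
            class = "chromatogram")
}

#' Fit a linear iRT-to-RT calibration model
#'
#' Ordinary least squares with up to two rounds of outlier rejection
#' (points with absolute residual above three residual standard deviations
#' are dropped and the line refitted).
#'
#' @param irt iRT coordinates of the standards.
#' @param rt Observed retention times, minutes.
#' @param min_standards Minimum surviving points (default 3).
#' @return List of class `irt_model` with `slope` (min per iRT unit),
#'   `intercept` (min), `n_standards`, `residual_sd`, `outliers_removed`.
#' @export
fit_irt <- function(irt, rt, min_standards = 3L) {
  stopifnot(length(irt) == length(rt))
  ok <- is.finite(irt) & is.finite(rt)
  irt <- irt[ok]; rt <- rt[ok]
  n0 <- length(irt)
  if (n0 < min_standards)
    stop("iRT calibration requires at least ", min_standards,
         " standards; got ", n0)
  keep <- rep(TRUE, n0)
  for (round in 0:2) {
    fit <- stats::lm.fit(cbind(1, irt[keep]), rt[keep])
    resid <- fit$residuals
    rsd <- sqrt(sum(resid^2) / max(1, length(resid) - 2))
    if (round == 2 || rsd == 0) break
    out <- abs(resid) > 3 * rsd
    if (!any(out)) break
    idx <- which(keep)[out]
    if (sum(keep) - length(idx) < min_standards) break
    keep[idx] <- FALSE
  }
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_standards = n0,
                 residual_sd = rsd,
                 outliers_removed = n0 - sum(keep)),
            class = "irt_model")
}

#' Predict retention time from an iRT model
#'
#' @param model An `irt_model`.
#' @param irt iRT coordinate(s).
#' @return Predicted RT, minutes.
#' @export
predict_rt <- function(model, irt) {
  model$slope * irt + model$intercept
}

#' @export
print.irt_model <- function(x, ...) {
  cat(sprintf("iRT model: RT = %.4f x iRT + %.4f min (n = %d, %d outlier(s) removed, residual SD %.4f min)\n",
              x$slope, x$intercept, x$n_standards, x$outliers_removed,
              x$residual_sd))
  invisible(x)
}

# Savitzky-Golay smoothing, quadratic, 7-point window; short traces pass
# through. The kernel is computed once per session from signal::sgolay.
sg_kernel_env <- new.env(parent = emptyenv())
sg_smooth <- function(x) {
  n <- length(x)
  if (n < 7) return(x)
  if (is.null(sg_kernel_env$k))
    sg_kernel_env$k <- signal::sgolay(p = 2, n = 7)[4, ]
  k <- sg_kernel_env$k
  out <- stats::filter(x, rev(k), sides = 2)
  out <- as.numeric(out)
  out[1:3] <- x[1:3]
  out[(n - 2):n] <- x[(n - 2):n]
  out
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# FWHM by linear interpolation at half the apex height
trace_fwhm <- function(times, s, apex_idx) {
  half <- s[apex_idx] / 2
  n <- length(s)
  left <- apex_idx
  while (left > 1 && s[left] > half) left <- left - 1L
  right <- apex_idx
  while (right < n && s[right] > half) right <- right + 1L
  if (s[left] > half || s[right] > half) return(NA_real_)
  tl <- if (left == apex_idx) times[left] else
    times[left] + (times[left + 1] - times[left]) *
      (half - s[left]) / (s[left + 1] - s[left])
  tr <- if (right == apex_idx) times[right] else
    times[right - 1] + (times[right] - times[right - 1]) *
      (s[right - 1] - half) / (s[right - 1] - s[right])
  tr - tl
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[2:n] - x[1:(n - 1)]) * (y[2:n] + y[1:(n - 1)])) / 2
}

#' Detect candidate peak groups in a set of transition chromatograms
#'
#' The summed trace is Savitzky-Golay smoothed (window 7, order 2); local
#' maxima within `rt_window` minutes of the predicted RT become candidates.
#' Boundaries are set at the flanking local minima or where the trace falls
#' to 1 percent of the apex, whichever is nearer; per-transition areas are
#' trapezoidal integrals within the boundaries.
#'
#' @param times Time grid, minutes (strictly increasing, >= 5 points).
#' @param intens Matrix of intensities, one column per transition.
#' @param predicted_rt Predicted RT, minutes.
#' @param rt_window Search half-window, minutes (default 3).
#' @param min_sn Minimum apex signal-to-noise for a candidate (default 1).
#' @param max_candidates Keep at most this many candidates, by descending
#'   apex intensity (default 10).
#' @return List with `candidates` (data.frame: `rt_apex`, `start`, `end`,
#'   `apex_intensity`, `fwhm`, `sn`) and `areas` (matrix, candidates x
#'   transitions).
#' @export
detect_peak_groups <- function(times, intens, predicted_rt, rt_window = 3,
                               min_sn = 1, max_candidates = 10L) {
  pg <- pg_detect(times, intens, predicted_rt, rt_window, min_sn,
                  max_candidates)
  list(candidates = data.frame(rt_apex = pg$rt_apex, start = pg$start,
                               end = pg$end,
                               apex_intensity = pg$apex_intensity,
                               fwhm = pg$fwhm, sn = pg$sn),
       areas = pg$areas)
}

# matrix/vector core of detect_peak_groups; start_idx/end_idx index `times`
pg_detect <- function(times, intens, predicted_rt, rt_window = 3,
                      min_sn = 1, max_candidates = 10L) {
  if (is.vector(intens)) intens <- matrix(intens, ncol = 1)
  if (length(times) < 5) stop("traces need at least 5 points")
  total <- rowSums(intens)
  s <- sg_smooth(total)
  baseline <- max(stats::median(abs(s)), 1e-9)
  apexes <- local_maxima(s)
  apexes <- apexes[abs(times[apexes] - predicted_rt) <= rt_window]
  apexes <- apexes[s[apexes] / baseline >= min_sn & s[apexes] > 0]
  k <- ncol(intens)
  if (length(apexes) == 0)
    return(list(n = 0L, rt_apex = numeric(0), start = numeric(0),
                end = numeric(0), apex_intensity = numeric(0),
                fwhm = numeric(0), sn = numeric(0),
                start_idx = integer(0), end_idx = integer(0),
                areas = matrix(0, 0, k)))
  apexes <- apexes[order(-s[apexes])]
  apexes <- apexes[seq_len(min(length(apexes), max_candidates))]
  minima <- local_maxima(-s)
  n <- length(s)
  nc <- length(apexes)
  areas <- matrix(0, nc, k)
  start_idx <- integer(nc); end_idx <- integer(nc)
  fwhm <- numeric(nc)
  dtimes <- diff(times)
  for (i in seq_len(nc)) {
    a <- apexes[i]
    thr <- 0.01 * s[a]
    left_min <- max(c(1L, minima[minima < a]))
    below <- which(s[1:a] <= thr)
    left <- max(left_min, if (length(below) > 0) max(below) else 1L)
    right_min <- min(c(n, minima[minima > a]))
    below <- which(s[a:n] <= thr)
    right <- min(right_min,
                 if (length(below) > 0) a + min(below) - 1L else n)
    idx <- left:right
    # trapezoidal integration of every transition at once
    w <- dtimes[left:(right - 1L)]
    block <- intens[idx, , drop = FALSE]
    m <- nrow(block)
    areas[i, ] <- colSums((block[-1L, , drop = FALSE] +
                             block[-m, , drop = FALSE]) * w) / 2
    start_idx[i] <- left; end_idx[i] <- right
    fwhm[i] <- trace_fwhm(times, s, a)
  }
  list(n = nc, rt_apex = times[apexes], start = times[start_idx],
       end = times[end_idx], apex_intensity = s[apexes], fwhm = fwhm,
       sn = s[apexes] / baseline, start_idx = start_idx,
       end_idx = end_idx, areas = areas)
}

#' Mass-accuracy and retention-time QC report
#'
#' @param run A `dia_run` with an `mz_observed` table (columns `sample_id`,
#'   `key`, `theoretical_mz`, `observed_mz`).
#' @param irt_models Named list of per-sample `irt_model` objects.
#' @param standard_rt data.frame with columns `sample_id`, `irt`,
#'   `observed_rt` for the iRT standards.
#' @return List of class `qc_report` with `mass_error` (per-sample ppm
#'   summary: mean, sd, max absolute) and `irt_deviation` (per standard and
#'   sample: observed minus fitted RT).
#' @export
qc_report <- function(run, irt_models, standard_rt) {
  mz <- run$mz_observed
  mz$ppm <- 1e6 * (mz$observed_mz - mz$theoretical_mz) / mz$theoretical_mz
  summ <- do.call(rbind, lapply(split(mz, mz$sample_id), function(d)
    data.frame(sample_id = d$sample_id[1], mean_ppm = mean(d$ppm),
               sd_ppm = stats::sd(d$ppm), max_abs_ppm = max(abs(d$ppm)))))
  rownames(summ) <- NULL
  dev <- standard_rt
  dev$fitted_rt <- NA_real_
  for (s in unique(dev$sample_id)) {
    m <- irt_models[[s]]
    rows <- dev$sample_id == s
    dev$fitted_rt[rows] <- predict_rt(m, dev$irt[rows])
  }
  dev$deviation <- dev$observed_rt - dev$fitted_rt
  structure(list(mass_error = summ, irt_deviation = dev),
            class = "qc_report")
}
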