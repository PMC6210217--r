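# Seeded synthetic DIA experiment generator with full ground truth.
#
# The defaults emulate the study design the package targets: four
# populations, six biological replicates, four sampling batches, log-normal
# protein abundance with designated population-specific fold changes,
# per-peptide fragment intensity profiles, per-sample linear iRT-to-RT maps
# with jitter, Gaussian chromatographic peaks, baseline noise, and injected
# interference peaks. Sixteen iRT standard peptides are appended to every
# sample.

#' Simulation configuration
#'
#' @param n_proteins Number of target proteins (default 200).
#' @param peptides_per_protein Range (length-2) of peptides per protein
#'   (default `c(2, 3)`).
#' @param n_populations,replicates,batches Study design (defaults 4, 6, 4).
#' @param frac_differential Fraction of proteins given a population-specific
#'   effect, per population (default 0.1; populations get disjoint sets).
#' @param log2fc Absolute log2 fold change of differential proteins
#'   (default 1.5; sign alternates between elevated and reduced).
#' @param abundance_mu,abundance_sigma Log2 mean and SD of the protein
#'   base abundance, in total ion counts (defaults 17, 1.5).
#' @param rep_sigma Within-population biological SD, log2 (default 0.25).
#' @param peptide_response_sigma SD of the fixed per-peptide log2 response
#'   factor (default 0.5).
#' @param fragment_dirichlet Dirichlet concentration of fragment intensity
#'   profiles (default 2).
#' @param n_transitions Transitions per precursor (default 5).
#' @param rt_slope_range,rt_intercept_range Per-sample linear iRT-to-RT map
#'   parameter ranges (defaults 0.7-1.3 min/iRT unit and 0-20 min).
#' @param rt_jitter_sd Per-peak RT jitter SD, minutes (default 0.1).
#' @param fwhm_mean,fwhm_sdlog Log-normal chromatographic peak FWHM,
#'   minutes (defaults 0.3, 0.15).
#' @param baseline_level Baseline intensity, counts (constant half plus
#'   Poisson half; default 50).
#' @param noise_sigma SD (natural log) of multiplicative intensity noise
#'   (default 0.1).
#' @param interference_rate Per-transition-per-sample probability of an
#'   injected interference peak (default 0.05).
#' @param interference_amp Interference amplitude as a multiple of the
#'   on-target apex (default 1.5).
#' @param frac_signal_free Fraction of target peptides emitted without any
#'   planted peak (default 0).
#' @param mz_jitter_ppm Half-width of the uniform observed-m/z jitter, ppm
#'   (default 5).
#' @param n_irt_standards Number of iRT standard peptides (default 16).
#' @param dt Chromatogram sampling interval, minutes (default 0.05).
#' @param trace_halfwidth Half-width of the simulated trace around the
#'   mapped RT, minutes (default 3.2).
#' @param seed Integer seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200L, peptides_per_protein = c(2L, 3L),
                       n_populations = 4L, replicates = 6L, batches = 4L,
                       frac_differential = 0.1, log2fc = 1.5,
                       abundance_mu = 17, abundance_sigma = 1.5,
                       rep_sigma = 0.25, peptide_response_sigma = 0.5,
                       fragment_dirichlet = 2, n_transitions = 5L,
                       rt_slope_range = c(0.7, 1.3),
                       rt_intercept_range = c(0, 20), rt_jitter_sd = 0.1,
                       fwhm_mean = 0.3, fwhm_sdlog = 0.15,
                       baseline_level = 50, noise_sigma = 0.1,
                       interference_rate = 0.05, interference_amp = 1.5,
                       frac_signal_free = 0, mz_jitter_ppm = 5,
                       n_irt_standards = 16L, dt = 0.05,
                       trace_halfwidth = 3.2, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_proteins >= 1, frac_differential >= 0, frac_differential <= 1,
            frac_signal_free >= 0, frac_signal_free <= 1,
            abundance_sigma >= 0, rep_sigma >= 0, noise_sigma >= 0,
            interference_rate >= 0, interference_rate <= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Random tryptic peptide: interior residues exclude K/R (and P at the
# position following the previous cleavage site), terminal residue K or R.
random_peptide <- function(len) {
  interior <- setdiff(names(AA_MONO), c("K", "R"))
  first <- setdiff(interior, "P")
  paste0(paste(c(sample(first, 1),
                 sample(interior, len - 2L, replace = TRUE)), collapse = ""),
         sample(c("K", "R"), 1))
}

#' Generate ground truth for a synthetic DIA experiment
#'
#' Builds random tryptic proteins, an assay library (one charge-2 precursor
#' per peptide with Dirichlet fragment profiles over y/b ions), iRT
#' standards, a sample annotation spanning populations x replicates x
#' batches, per-sample linear RT maps, log-normal protein abundances with
#' the configured population effects, and the signal-free target list.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `library` (an `assay_library` including decoy-free
#'   targets and iRT standards), `truth` (class `ground_truth`) and `annot`.
#' @export
generate_ground_truth <- function(cfg) {
  set.seed(cfg$seed)
  pp <- cfg$peptides_per_protein
  n_pep_per <- if (pp[1] == pp[2]) rep(pp[1], cfg$n_proteins) else
    sample(pp[1]:pp[2], cfg$n_proteins, replace = TRUE)
  all_peps <- character(0)
  prot_pep <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    peps <- character(n_pep_per[i])
    for (j in seq_len(n_pep_per[i])) {
      repeat {
        p <- random_peptide(sample(8:14, 1))
        if (!(p %in% all_peps)) break
      }
      all_peps <- c(all_peps, p)
      peps[j] <- p
    }
    prot_pep[[i]] <- peps
  }
  proteins <- sprintf("PROT%04d", seq_len(cfg$n_proteins))

  # iRT standards
  std_peps <- character(cfg$n_irt_standards)
  for (j in seq_len(cfg$n_irt_standards)) {
    repeat {
      p <- random_peptide(sample(8:14, 1))
      if (!(p %in% c(all_peps, std_peps))) break
    }
    std_peps[j] <- p
  }
  std_irt <- seq(0, 100, length.out = cfg$n_irt_standards)

  build_entries <- function(modseq, protein, irt) {
    z <- 2L
    prec_mz <- peptide_mz(modseq, z)
    n <- nchar(modseq)
    frag <- rbind(
      data.frame(type = "y", ordinal = 3:(n - 1)),
      data.frame(type = "b", ordinal = 3:(n - 1)))
    frag$mz <- mapply(function(ty, o) fragment_mz(modseq, ty, o, 1L),
                      frag$type, frag$ordinal)
    frag <- frag[abs(frag$mz - prec_mz) > 5, , drop = FALSE]
    k <- min(cfg$n_transitions, nrow(frag))
    if (k < 3) return(NULL)
    pick <- frag[sample(nrow(frag), k), , drop = FALSE]
    w <- stats::rgamma(k, shape = cfg$fragment_dirichlet)
    w <- w / sum(w)
    data.frame(ProteinId = protein, PeptideSequence = modseq,
               ModifiedPeptideSequence = modseq, PrecursorMz = prec_mz,
               PrecursorCharge = z, ProductMz = pick$mz,
               FragmentType = pick$type, FragmentSeriesNumber = pick$ordinal,
               FragmentCharge = 1L, LibraryIntensity = 1000 * w,
               NormalizedRetentionTime = irt, Decoy = 0L,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  pep_tab <- list()
  for (i in seq_len(cfg$n_proteins)) {
    for (p in prot_pep[[i]]) {
      irt <- stats::runif(1, 0, 100)
      e <- build_entries(p, proteins[i], irt)
      if (is.null(e)) next
      rows[[length(rows) + 1]] <- e
      pep_tab[[length(pep_tab) + 1]] <-
        data.frame(peptide = p, protein = proteins[i], irt = irt,
                   stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(cfg$n_irt_standards)) {
    e <- build_entries(std_peps[j], "IRT_STANDARD", std_irt[j])
    if (is.null(e)) next
    rows[[length(rows) + 1]] <- e
    pep_tab[[length(pep_tab) + 1]] <-
      data.frame(peptide = std_peps[j], protein = "IRT_STANDARD",
                 irt = std_irt[j], stringsAsFactors = FALSE)
  }
  lib <- assay_library(do.call(rbind, rows), provenance = "simulated")
  pep_tab <- do.call(rbind, pep_tab)
  if (sum(pep_tab$protein != "IRT_STANDARD") == 0)
    stop("infeasible configuration: no usable peptides generated")

  # annotation
  pops <- sprintf("pop%d", seq_len(cfg$n_populations))
  annot <- expand.grid(replicate = seq_len(cfg$replicates),
                       population = pops,
                       sampling_batch = sprintf("PS%d",
                                                seq_len(cfg$batches)),
                       stringsAsFactors = FALSE)
  annot$sample_id <- sprintf("%s_%s_r%d", annot$population,
                             annot$sampling_batch, annot$replicate)
  annot <- annot[c("sample_id", "population", "sampling_batch", "replicate")]

  # differential proteins: disjoint sets per population, alternating sign
  n_diff <- floor(cfg$frac_differential * cfg$n_proteins)
  shuffled <- sample(proteins)
  differential <- NULL
  if (n_diff > 0) {
    sets <- lapply(seq_len(cfg$n_populations), function(k)
      shuffled[((k - 1) * n_diff + 1):(k * n_diff)])
    differential <- do.call(rbind, lapply(seq_len(cfg$n_populations),
      function(k) data.frame(
        protein = sets[[k]], population = pops[k],
        log2fc = cfg$log2fc * rep_len(c(1, -1), n_diff),
        stringsAsFactors = FALSE)))
  }

  # abundances: base + population effect + biological replicate noise
  base <- stats::rnorm(cfg$n_proteins, cfg$abundance_mu, cfg$abundance_sigma)
  names(base) <- proteins
  abundance <- matrix(stats::rnorm(cfg$n_proteins * nrow(annot), 0,
                                   cfg$rep_sigma),
                      cfg$n_proteins, nrow(annot),
                      dimnames = list(proteins, annot$sample_id))
  abundance <- abundance + base
  if (!is.null(differential)) {
    for (r in seq_len(nrow(differential))) {
      cols <- annot$sample_id[annot$population == differential$population[r]]
      abundance[differential$protein[r], cols] <-
        abundance[differential$protein[r], cols] + differential$log2fc[r]
    }
  }

  # per-sample RT maps
  rt_maps <- data.frame(
    sample_id = annot$sample_id,
    slope = stats::runif(nrow(annot), cfg$rt_slope_range[1],
                         cfg$rt_slope_range[2]),
    intercept = stats::runif(nrow(annot), cfg$rt_intercept_range[1],
                             cfg$rt_intercept_range[2]),
    stringsAsFactors = FALSE)

  # fixed per-peptide response factors; signal-free targets
  tgt_peps <- pep_tab$peptide[pep_tab$protein != "IRT_STANDARD"]
  response <- stats::rnorm(nrow(pep_tab), 0, cfg$peptide_response_sigma)
  names(response) <- pep_tab$peptide
  n_sf <- floor(cfg$frac_signal_free * length(tgt_peps))
  signal_free <- if (n_sf > 0) sample(tgt_peps, n_sf) else character(0)

  truth <- structure(list(
    abundance = abundance, base = base, differential = differential,
    peptides = pep_tab, response = response, signal_free = signal_free,
    rt_maps = rt_maps, standard_peptides = std_peps, standard_irt = std_irt,
    config = cfg), class = "ground_truth")
  list(library = lib, truth = truth, annot = annot)
}

#' Simulate DIA chromatograms for an assay library
#'
#' Emits, per precursor and sample, transition traces on a time grid
#' centred at the sample's mapped RT: a Gaussian peak at the jittered apex
#' with area `abundance x peptide response x fragment fraction`, log-normal
#' multiplicative noise, a constant-plus-Poisson baseline, and injected
#' interference peaks (registered in the output). Signal-free targets and
#' decoys receive baseline only; iRT standards are always emitted at high
#' intensity.
#'
#' @param lib An `assay_library` (targets, optionally decoys and
#'   `IRT_STANDARD` entries).
#' @param truth A `ground_truth` from [generate_ground_truth()].
#' @param annot Sample annotation (subset of the truth's samples).
#' @param cfg The [sim_config()] used for the ground truth.
#' @return List of class `dia_run`: `annot`, `precursors` (index
#'   data.frame), `traces` (per sample, per precursor key: `times`,
#'   `intens`, `pred_rt`), `mz_observed`, `interferences`,
#'   `standard_keys`.
#' @export
simulate_dia_experiment <- function(lib, truth, annot, cfg) {
  set.seed(cfg$seed + 1L)
  df <- as.data.frame(lib)
  df$key <- precursor_key(lib)
  key_order <- unique(df$key)
  grp <- split(seq_len(nrow(df)), df$key)[key_order]
  prec <- data.frame(
    key = key_order,
    protein = df$ProteinId[vapply(grp, `[`, 1L, 1L)],
    peptide = df$ModifiedPeptideSequence[vapply(grp, `[`, 1L, 1L)],
    irt = df$NormalizedRetentionTime[vapply(grp, `[`, 1L, 1L)],
    decoy = df$Decoy[vapply(grp, `[`, 1L, 1L)] == 1L,
    stringsAsFactors = FALSE)
  prec$standard <- prec$protein == "IRT_STANDARD"
  prec$signal_free <- (prec$peptide %in% truth$signal_free) & !prec$standard
  half_grid <- seq(-cfg$trace_halfwidth, cfg$trace_halfwidth, by = cfg$dt)
  nt <- length(half_grid)
  sd_from_fwhm <- 1 / (2 * sqrt(2 * log(2)))

  traces <- vector("list", nrow(annot))
  names(traces) <- annot$sample_id
  interf <- list()
  mzobs <- list()
  for (si in seq_len(nrow(annot))) {
    s <- annot$sample_id[si]
    map <- truth$rt_maps[truth$rt_maps$sample_id == s, ]
    if (nrow(map) == 0) stop("no RT map for sample ", s)
    smpl <- vector("list", nrow(prec))
    names(smpl) <- prec$key
    for (pi in seq_len(nrow(prec))) {
      rows <- grp[[pi]]
      k <- length(rows)
      center <- map$slope * prec$irt[pi] + map$intercept
      times <- center + half_grid
      base_lvl <- cfg$baseline_level
      intens <- matrix(base_lvl / 2 + stats::rpois(nt * k, base_lvl / 2),
                       nt, k)
      has_signal <- !prec$decoy[pi] && !prec$signal_free[pi]
      apex_sn <- rep(0, k)
      if (has_signal) {
        apex <- center + stats::rnorm(1, 0, cfg$rt_jitter_sd)
        log2_ab <- if (prec$standard[pi]) cfg$abundance_mu + 2 else
          truth$abundance[prec$protein[pi], s] + truth$response[prec$peptide[pi]]
        total_area <- 2^log2_ab
        frac <- df$LibraryIntensity[rows] / sum(df$LibraryIntensity[rows])
        fwhm <- stats::rlnorm(1, log(cfg$fwhm_mean), cfg$fwhm_sdlog)
        shape <- stats::dnorm(times, apex, fwhm * sd_from_fwhm)
        peak <- outer(shape, total_area * frac)
        if (cfg$noise_sigma > 0)
          peak <- peak * exp(matrix(stats::rnorm(nt * k, 0,
                                                 cfg$noise_sigma), nt, k))
        intens <- intens + peak
        apex_sn <- total_area * frac * stats::dnorm(0, 0, fwhm * sd_from_fwhm)
      }
      if (cfg$interference_rate > 0) {
        hit <- which(stats::runif(k) < cfg$interference_rate)
        for (j in hit) {
          offset <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 2.5)
          amp <- cfg$interference_amp *
            max(apex_sn[j], 5 * base_lvl) *
            stats::rlnorm(1, 0, 0.2)
          fw_i <- stats::rlnorm(1, log(cfg$fwhm_mean), cfg$fwhm_sdlog)
          sd_i <- fw_i * sd_from_fwhm
          intens[, j] <- intens[, j] +
            amp * sd_i * sqrt(2 * pi) * stats::dnorm(times, center + offset,
                                                     sd_i)
          interf[[length(interf) + 1]] <- data.frame(
            sample_id = s, key = prec$key[pi], transition = j,
            rt = center + offset, amplitude = amp,
            stringsAsFactors = FALSE)
        }
      }
      smpl[[pi]] <- list(times = times, intens = intens, pred_rt = center)
    }
    traces[[si]] <- smpl
    mzobs[[si]] <- data.frame(
      sample_id = s, key = df$key,
      theoretical_mz = df$ProductMz,
      observed_mz = df$ProductMz *
        (1 + stats::runif(nrow(df), -cfg$mz_jitter_ppm,
                          cfg$mz_jitter_ppm) * 1e-6),
      stringsAsFactors = FALSE)
  }
  structure(list(
    annot = annot, precursors = prec, traces = traces,
    mz_observed = do.call(rbind, mzobs),
    interferences = if (length(interf)) do.call(rbind, interf) else NULL,
    standard_keys = prec$key[prec$standard],
    library_rows = grp, config = cfg), class = "dia_run")
}
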