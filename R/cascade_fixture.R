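# A small planted-violation fixture for the filter cascade, with an
# independent exhaustive oracle that predicts the post-cascade census from
# the planted bookkeeping rather than from the cascade implementation.

fixture_peptide_rows <- function(protein, modseq, irt, n_transitions = 5L) {
  plain <- parse_modified_sequence(modseq)$sequence
  z <- 2L
  prec_mz <- peptide_mz(modseq, z)
  n <- nchar(plain)
  frag <- rbind(data.frame(type = "y", ordinal = 3:(n - 1)),
                data.frame(type = "b", ordinal = 3:(n - 1)))
  frag$mz <- mapply(function(ty, o) fragment_mz(modseq, ty, o, 1L),
                    frag$type, frag$ordinal)
  frag <- frag[abs(frag$mz - prec_mz) > 5, , drop = FALSE]
  frag <- frag[seq_len(min(n_transitions, nrow(frag))), , drop = FALSE]
  w <- stats::rgamma(nrow(frag), 2) + 0.5   # floor keeps every transition visible
  data.frame(ProteinId = protein, PeptideSequence = plain,
             ModifiedPeptideSequence = modseq, PrecursorMz = prec_mz,
             PrecursorCharge = z, ProductMz = frag$mz,
             FragmentType = frag$type, FragmentSeriesNumber = frag$ordinal,
             FragmentCharge = 1L, LibraryIntensity = 1000 * w / sum(w),
             NormalizedRetentionTime = irt, Decoy = 0L,
             stringsAsFactors = FALSE)
}

#' Planted-violation fixture for the filter cascade
#'
#' Emits a small assay library (about 30 proteins) containing clean entries
#' plus one planted violation of each filter rule: a disallowed PTM, a
#' duplicated transition block, a protein-shared peptide, a
#' three-transition precursor, a missed-cleavage peptide, a uniformly
#' low-dotp peptide, a one-peptide protein, and one violation of each of
#' the four codified curation rules (dominant interference on one
#' transition; undetectable precursor in half of one population; two-fold
#' peak-width split within a population; two interfered transitions).
#' Synthetic training chromatograms, a dotp table, a 24-sample annotation
#' and the expected post-cascade census (computed by an independent
#' exhaustive re-scan of the planted flags) are returned alongside.
#'
#' @param seed Integer seed.
#' @param violations Emit the planted violations (default TRUE); with
#'   FALSE only clean entries are produced and the cascade should remove
#'   nothing.
#' @return List with `library`, `training` (list `dotp`, `run`), `annot`
#'   and `expected_census`.
#' @export
make_cascade_fixture <- function(seed = 1L, violations = TRUE) {
  set.seed(as.integer(seed))
  pops <- c("popA", "popB", "popC", "popD")
  annot <- expand.grid(replicate = 1:6, population = pops,
                       stringsAsFactors = FALSE)
  annot$sampling_batch <- "PS1"
  annot$sample_id <- sprintf("%s_r%d", annot$population, annot$replicate)
  annot <- annot[c("sample_id", "population", "sampling_batch", "replicate")]

  used <- character(0)
  new_pep <- function(len = 10L) {
    repeat {
      p <- random_peptide(len)
      if (!(p %in% used)) break
    }
    used <<- c(used, p)
    p
  }
  rows <- list()
  flags <- list()
  add <- function(protein, modseq, irt, n_tr = 5L, mod_other = FALSE,
                  shared = FALSE, dup_block = FALSE, low_dotp = FALSE,
                  rule1_tr = integer(0), rule2 = FALSE, rule3 = FALSE,
                  rule4_tr = integer(0), no_trace = FALSE) {
    r <- fixture_peptide_rows(protein, modseq, irt, n_tr)
    rows[[length(rows) + 1]] <<- r
    flags[[length(flags) + 1]] <<- data.frame(
      key = paste0(modseq, "/2"), protein = protein,
      n_rows = nrow(r), mod_other = mod_other, shared = shared,
      dup_block = dup_block, low_dotp = low_dotp,
      rule1 = paste(rule1_tr, collapse = ","), rule2 = rule2, rule3 = rule3,
      rule4 = paste(rule4_tr, collapse = ","), no_trace = no_trace,
      irt = irt, stringsAsFactors = FALSE)
    if (dup_block) rows[[length(rows) + 1]] <<- r
  }

  irt_pool <- seq(10, 90, length.out = 40)
  irt_i <- 0L
  next_irt <- function() {
    irt_i <<- irt_i + 1L
    irt_pool[irt_i]
  }

  for (i in 1:20) {
    prot <- sprintf("CLN%02d", i)
    add(prot, new_pep(), next_irt())
    add(prot, new_pep(11L), 5 + (i %% 20) * 4.7)
  }
  if (violations) {
    # step 1: disallowed PTM on the second peptide
    add("VPTM", new_pep(), next_irt())
    add("VPTM", new_pep(11L), 22.3)
    p <- new_pep(10L)
    modp <- paste0(substr(p, 1, 4), "S[+79.96633]",
                   substr(p, 5, nchar(p)))
    rows[[length(rows) + 1]] <- fixture_peptide_rows("VPTM", modp, 33.1)
    flags[[length(flags) + 1]] <- data.frame(
      key = paste0(modp, "/2"), protein = "VPTM", n_rows = 5L,
      mod_other = TRUE, shared = FALSE, dup_block = FALSE,
      low_dotp = FALSE, rule1 = "", rule2 = FALSE, rule3 = FALSE,
      rule4 = "", no_trace = TRUE, irt = 33.1, stringsAsFactors = FALSE)
    # step 2: duplicated block on a clean protein, and a shared peptide
    add("VDUP", new_pep(), next_irt())
    add("VDUP", new_pep(12L), 47.9, dup_block = TRUE)
    shared_pep <- new_pep(11L)
    for (prot in c("VSHA", "VSHB")) {
      add(prot, new_pep(), next_irt())
      add(prot, new_pep(12L), next_irt())
    }
    srows <- fixture_peptide_rows("VSHA", shared_pep, 51.2)
    rows[[length(rows) + 1]] <- srows
    srows$ProteinId <- "VSHB"
    rows[[length(rows) + 1]] <- srows
    flags[[length(flags) + 1]] <- data.frame(
      key = paste0(shared_pep, "/2"), protein = "VSHA", n_rows = 10L,
      mod_other = FALSE, shared = TRUE, dup_block = FALSE,
      low_dotp = FALSE, rule1 = "", rule2 = FALSE, rule3 = FALSE,
      rule4 = "", no_trace = TRUE, irt = 51.2, stringsAsFactors = FALSE)
    # step 3: three-transition precursor
    add("VTR3", new_pep(), next_irt())
    add("VTR3", new_pep(11L), next_irt())
    add("VTR3", new_pep(12L), 63.7, n_tr = 3L, no_trace = TRUE)
    # step 4: missed cleavage
    add("VMC", new_pep(), next_irt())
    add("VMC", new_pep(11L), next_irt())
    mcp <- new_pep(12L)
    mcp <- paste0(substr(mcp, 1, 5), "K",
                  substr(mcp, 7, nchar(mcp)))  # internal K, next not P
    if (substr(mcp, 7, 7) == "P")
      substr(mcp, 7, 7) <- "A"
    used <- c(used, mcp)
    rows[[length(rows) + 1]] <- fixture_peptide_rows("VMC", mcp, 71.8)
    flags[[length(flags) + 1]] <- data.frame(
      key = paste0(mcp, "/2"), protein = "VMC", n_rows = 5L,
      mod_other = FALSE, shared = FALSE, dup_block = FALSE,
      low_dotp = FALSE, rule1 = "", rule2 = FALSE, rule3 = FALSE,
      rule4 = "", no_trace = TRUE, irt = 71.8, stringsAsFactors = FALSE)
    # step 5: low dotp everywhere
    add("VDOTP", new_pep(), next_irt())
    add("VDOTP", new_pep(11L), next_irt())
    add("VDOTP", new_pep(12L), 82.4, low_dotp = TRUE, no_trace = TRUE)
    # step 6: one-peptide protein
    add("V1PEP", new_pep(), next_irt(), no_trace = TRUE)
    # step 7 rule 1: dominant interference on one transition
    add("VR1", new_pep(), next_irt())
    add("VR1", new_pep(11L), 15.6, rule1_tr = 1L)
    # rule 2: undetected in half of popA
    add("VR2", new_pep(), next_irt())
    add("VR2", new_pep(11L), next_irt())
    add("VR2", new_pep(12L), 37.2, rule2 = TRUE)
    # rule 3: two-fold width split within popA
    add("VR3", new_pep(), next_irt())
    add("VR3", new_pep(11L), next_irt())
    add("VR3", new_pep(12L), 58.9, rule3 = TRUE)
    # rule 4: two interfered transitions
    add("VR4", new_pep(), next_irt())
    add("VR4", new_pep(11L), next_irt())
    add("VR4", new_pep(12L), 77.5, rule4_tr = c(1L, 2L))
  }
  lib <- assay_library(do.call(rbind, rows), provenance = "fixture")
  flags <- do.call(rbind, flags)

  # training chromatograms for precursors that reach step 7
  grid <- seq(-3.2, 3.2, by = 0.05)
  nt <- length(grid)
  mk_trace <- function(irt, frac, fwhm = 0.3, detected = TRUE,
                       interfere = integer(0)) {
    times <- irt + grid
    k <- length(frac)
    intens <- matrix(5 + abs(stats::rnorm(nt * k, 0, 0.5)), nt, k)
    if (detected) {
      shape <- stats::dnorm(times, irt, fwhm / 2.3548)
      intens <- intens + outer(shape / max(shape), 1000 * frac)
    }
    for (j in interfere) {
      shape <- stats::dnorm(times, irt + 1.5, 0.3 / 2.3548)
      intens[, j] <- intens[, j] + 3000 * frac[j] * shape / max(shape)
    }
    list(times = times, intens = intens, pred_rt = irt)
  }
  traces <- vector("list", nrow(annot))
  names(traces) <- annot$sample_id
  for (si in seq_len(nrow(annot))) {
    s <- annot$sample_id[si]
    pop <- annot$population[si]
    rep_i <- annot$replicate[si]
    smpl <- list()
    for (fi in seq_len(nrow(flags))) {
      f <- flags[fi, ]
      if (f$no_trace) next
      key_rows <- which(precursor_key(lib) == f$key)
      if (f$dup_block) key_rows <- key_rows[1:(length(key_rows) / 2)]
      frac <- lib$LibraryIntensity[key_rows]
      frac <- frac / sum(frac)
      interfere <- integer(0)
      detected <- TRUE
      fwhm <- 0.3
      if (nzchar(f$rule1)) interfere <-
          as.integer(strsplit(f$rule1, ",")[[1]])
      if (nzchar(f$rule4)) interfere <-
          as.integer(strsplit(f$rule4, ",")[[1]])
      if (f$rule2 && pop == "popA" && rep_i <= 3) detected <- FALSE
      if (f$rule3 && pop == "popA" && rep_i <= 3) fwhm <- 0.9
      smpl[[f$key]] <- mk_trace(f$irt, frac, fwhm, detected, interfere)
    }
    traces[[si]] <- smpl
  }
  run <- structure(list(annot = annot, traces = traces), class = "dia_run")

  # dotp table covering all target precursors
  dotp <- expand.grid(key = flags$key, sample_id = annot$sample_id,
                      stringsAsFactors = FALSE)
  dotp$dotp <- ifelse(flags$low_dotp[match(dotp$key, flags$key)], 0.5, 0.95)

  expected_census <- cascade_oracle(lib, flags)
  list(library = lib, training = list(dotp = dotp, run = run),
       annot = annot, expected_census = expected_census, flags = flags)
}

# Exhaustive re-scan of the planted flags: applies every filter rule to the
# flat transition table by direct counting, independent of the cascade
# implementation.
cascade_oracle <- function(lib, flags) {
  df <- as.data.frame(lib)
  df$key <- paste0(df$ModifiedPeptideSequence, "/", df$PrecursorCharge)
  df$tr_index <- stats::ave(rep(1, nrow(df)), df$key, df$ProteinId,
                            FUN = seq_along)
  # step 1: peptides with a bracket delta other than Met-ox/Cys-CAM
  allowed <- function(ms) {
    deltas <- regmatches(ms, gregexpr("\\[[^]]*\\]", ms))[[1]]
    if (length(deltas) == 0) return(TRUE)
    d <- as.numeric(gsub("[][+]", "", deltas))
    all(abs(d - 15.99491) < 5e-3 | abs(d - 57.02146) < 5e-3)
  }
  keep_pep <- vapply(unique(df$ModifiedPeptideSequence), allowed, logical(1))
  df <- df[keep_pep[df$ModifiedPeptideSequence], , drop = FALSE]
  # step 2: exact duplicate rows out; peptides under >1 protein out
  df <- df[!duplicated(df[c("ModifiedPeptideSequence", "PrecursorCharge",
                            "ProductMz", "FragmentCharge", "ProteinId")]), ,
           drop = FALSE]
  shared <- tapply(df$ProteinId, df$PeptideSequence,
                   function(x) length(unique(x)))
  df <- df[!(df$PeptideSequence %in% names(shared)[shared > 1]), ,
           drop = FALSE]
  # step 3
  ntr <- table(df$key)
  df <- df[df$key %in% names(ntr)[ntr >= 4], , drop = FALSE]
  # step 4: internal K/R not followed by P
  has_mc <- vapply(df$PeptideSequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    any(ch[-n] %in% c("K", "R") & ch[-1] != "P")
  }, logical(1))
  df <- df[!has_mc, , drop = FALSE]
  # step 5
  low <- flags$key[flags$low_dotp]
  df <- df[!(df$key %in% low), , drop = FALSE]
  # step 6
  npep <- tapply(df$ModifiedPeptideSequence, df$ProteinId,
                 function(x) length(unique(x)))
  df <- df[df$ProteinId %in% names(npep)[npep >= 2], , drop = FALSE]
  # step 7: planted curation flags
  r1 <- flags[nzchar(flags$rule1), ]
  for (i in seq_len(nrow(r1))) {
    bad <- as.integer(strsplit(r1$rule1[i], ",")[[1]])
    df <- df[!(df$key == r1$key[i] & df$tr_index %in% bad), , drop = FALSE]
  }
  drop_prec <- flags$key[flags$rule2 | flags$rule3 | nzchar(flags$rule4)]
  df <- df[!(df$key %in% drop_prec), , drop = FALSE]
  # re-apply steps 3 and 6
  ntr <- table(df$key)
  df <- df[df$key %in% names(ntr)[ntr >= 4], , drop = FALSE]
  npep <- tapply(df$ModifiedPeptideSequence, df$ProteinId,
                 function(x) length(unique(x)))
  df <- df[df$ProteinId %in% names(npep)[npep >= 2], , drop = FALSE]
  structure(list(
    n_proteins = length(unique(df$ProteinId)),
    n_peptides = length(unique(df$ModifiedPeptideSequence)),
    n_precursors = length(unique(df$key)),
    n_transitions = nrow(df)), class = "census")
}
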