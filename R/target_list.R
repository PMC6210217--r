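# Initial target-list construction from library spectra, and scrambled-decoy
# generation.

#' Transition-selection settings
#'
#' Defaults mirror common DIA assay-library practice: y/b fragments from ion
#' 3 to the last ion minus one, fragment charges 1-2, precursor charges 1-4,
#' the five most intense qualifying fragments per precursor, peak-to-theory
#' matching within +/-0.035 Th, and exclusion of fragments inside the 10-Th
#' precursor isolation window.
#'
#' @param min_ordinal Minimum fragment series number (default 3).
#' @param max_ordinal_offset Fragments up to `length - max_ordinal_offset`
#'   (default 1, i.e. last ion minus one).
#' @param fragment_charges Allowed fragment charges (default 1:2).
#' @param precursor_charges Allowed precursor charges (default 1:4).
#' @param top_n Number of transitions to keep per precursor (default 5).
#' @param mz_match_tol Peak-to-theoretical matching tolerance in Th
#'   (default 0.035).
#' @param precursor_exclusion_width Width of the excluded window centred on
#'   the precursor m/z, in Th (default 10; i.e. +/-5 Th).
#' @return A list of class `transition_settings`.
#' @export
transition_settings <- function(min_ordinal = 3L, max_ordinal_offset = 1L,
                                fragment_charges = 1:2,
                                precursor_charges = 1:4, top_n = 5L,
                                mz_match_tol = 0.035,
                                precursor_exclusion_width = 10) {
  stopifnot(top_n >= 1, mz_match_tol > 0, precursor_exclusion_width > 0)
  structure(list(min_ordinal = as.integer(min_ordinal),
                 max_ordinal_offset = as.integer(max_ordinal_offset),
                 fragment_charges = as.integer(fragment_charges),
                 precursor_charges = as.integer(precursor_charges),
                 top_n = as.integer(top_n),
                 mz_match_tol = mz_match_tol,
                 precursor_exclusion_width = precursor_exclusion_width),
            class = "transition_settings")
}

# All theoretical y/b fragments of a peptide satisfying the ordinal and
# charge bounds of `settings`.
theoretical_fragments <- function(modseq, settings = transition_settings()) {
  plain <- parse_modified_sequence(modseq)$sequence
  n <- nchar(plain)
  max_ord <- n - settings$max_ordinal_offset
  if (max_ord < settings$min_ordinal)
    return(data.frame(type = character(0), ordinal = integer(0),
                      charge = integer(0), mz = numeric(0)))
  grid <- expand.grid(type = c("y", "b"),
                      ordinal = settings$min_ordinal:max_ord,
                      charge = settings$fragment_charges,
                      stringsAsFactors = FALSE)
  grid$mz <- mapply(function(ty, o, z) fragment_mz(modseq, ty, o, z),
                    grid$type, grid$ordinal, grid$charge)
  grid
}

#' Build an initial target list from library spectra
#'
#' For each (peptide, charge) spectrum, candidate peaks are matched to
#' theoretical y/b fragment m/z values within `settings$mz_match_tol`
#' (greedily by smallest absolute m/z difference, each peak used at most
#' once), filtered to the ordinal window `[min_ordinal, n - 1]`, fragment
#' charge 1-2, and to fragments outside the precursor isolation window
#' (+/- half of `precursor_exclusion_width` around the precursor m/z); the
#' `top_n` most intense qualifying fragments are retained. Intensity ties
#' break by lower fragment m/z, then y before b.
#'
#' @param spectra A `spectral_library` data.frame
#'   (see [read_spectral_library()]); a `protein` column may map peptides to
#'   accessions, otherwise proteins are labelled by peptide sequence.
#' @param settings A [transition_settings()].
#' @return An `assay_library` with provenance `"initial"`.
#' @export
build_initial_target_list <- function(spectra,
                                      settings = transition_settings()) {
  stopifnot(is.data.frame(spectra))
  if (is.null(spectra$protein))
    spectra$protein <- parse_plain(spectra$peptide)
  groups <- split(spectra,
                  paste(spectra$peptide, spectra$charge, sep = "\r"))
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    sp <- groups[[g]]
    modseq <- sp$peptide[1]
    z <- sp$charge[1]
    if (!(z %in% settings$precursor_charges)) next
    if (nrow(sp) == 0 || all(sp$intensity == 0)) {
      warning("empty spectrum for ", modseq, "/", z, "; skipped")
      next
    }
    prec_mz <- peptide_mz(modseq, z)
    frags <- theoretical_fragments(modseq, settings)
    half <- settings$precursor_exclusion_width / 2
    frags <- frags[abs(frags$mz - prec_mz) > half, , drop = FALSE]
    if (nrow(frags) == 0) next
    # greedy peak-fragment matching by smallest |delta mz|
    cand <- expand.grid(peak = seq_len(nrow(sp)), frag = seq_len(nrow(frags)))
    cand$d <- abs(sp$mz[cand$peak] - frags$mz[cand$frag])
    cand <- cand[cand$d <= settings$mz_match_tol, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_peak <- logical(nrow(sp))
    used_frag <- logical(nrow(frags))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_peak[cand$peak[i]] && !used_frag[cand$frag[i]]) {
        keep[i] <- TRUE
        used_peak[cand$peak[i]] <- TRUE
        used_frag[cand$frag[i]] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    tab <- data.frame(
      ProteinId = sp$protein[1],
      PeptideSequence = parse_plain(modseq),
      ModifiedPeptideSequence = modseq,
      PrecursorMz = prec_mz,
      PrecursorCharge = z,
      ProductMz = frags$mz[cand$frag],
      FragmentType = frags$type[cand$frag],
      FragmentSeriesNumber = frags$ordinal[cand$frag],
      FragmentCharge = frags$charge[cand$frag],
      LibraryIntensity = sp$intensity[cand$peak],
      NormalizedRetentionTime = sp$irt[1],
      Decoy = 0L,
      stringsAsFactors = FALSE)
    # top_n by intensity; ties by lower m/z, then y before b
    ord <- order(-tab$LibraryIntensity, tab$ProductMz,
                 match(tab$FragmentType, c("y", "b")))
    tab <- tab[ord, , drop = FALSE]
    rows[[g]] <- tab[seq_len(min(settings$top_n, nrow(tab))), , drop = FALSE]
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(empty_library("initial"))
  assay_library(do.call(rbind, rows), provenance = "initial")
}

parse_plain <- function(modseq) {
  vapply(modseq, function(s) parse_modified_sequence(s)$sequence, "",
         USE.NAMES = FALSE)
}

empty_library <- function(provenance = character(0)) {
  df <- data.frame(ProteinId = character(0), PeptideSequence = character(0),
                   ModifiedPeptideSequence = character(0),
                   PrecursorMz = numeric(0), PrecursorCharge = integer(0),
                   ProductMz = numeric(0), FragmentType = character(0),
                   FragmentSeriesNumber = integer(0),
                   FragmentCharge = integer(0), LibraryIntensity = numeric(0),
                   NormalizedRetentionTime = numeric(0), Decoy = integer(0),
                   stringsAsFactors = FALSE)
  assay_library(df, provenance = provenance)
}

# Shuffle the non-C-terminal residues of a plain sequence, keeping bracket
# modifications attached to their residues.
shuffle_sequence <- function(modseq) {
  p <- parse_modified_sequence(modseq)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  perm <- c(sample(n - 1L), n)
  rebuild_modseq(res[perm], p$modifications, perm)
}

rebuild_modseq <- function(res, mods, perm) {
  tags <- rep("", length(res))
  if (nrow(mods) > 0) {
    newpos <- match(mods$position, perm)
    tags[newpos] <- sprintf("[%+.5f]", mods$delta)
  }
  paste0(res, tags, collapse = "")
}

#' Generate scrambled decoy entries for an assay library
#'
#' One decoy peptide is generated per target peptide by a seeded shuffle of
#' the non-C-terminal residues (the C-terminal residue is fixed, preserving
#' tryptic character and the precursor mass distribution). Fragment m/z
#' values are recomputed from the decoy sequence for the same fragment type,
#' ordinal and charge; library intensities are copied from the target.
#' Decoys colliding with any target sequence are reshuffled (up to 20
#' retries), then fall back to a deterministic positional residue swap.
#'
#' @param lib An `assay_library` of target entries.
#' @param seed Integer seed; same seed, same decoys.
#' @return An `assay_library` of decoy entries (`Decoy == 1`), peptide-level
#'   census equal to the target library's.
#' @export
generate_decoys <- function(lib, seed) {
  stopifnot(nrow(lib) > 0)
  targets <- as.data.frame(lib[lib$Decoy == 0L, , drop = FALSE])
  target_seqs <- unique(targets$PeptideSequence)
  set.seed(as.integer(seed))
  peps <- unique(targets$ModifiedPeptideSequence)
  out <- vector("list", length(peps))
  for (i in seq_along(peps)) {
    modseq <- peps[i]
    plain <- parse_plain(modseq)
    n <- nchar(plain)
    if (n <= 2L) {
      warning("peptide ", plain, " too short to scramble; decoy skipped")
      next
    }
    dec <- NULL
    for (try in 1:20) {
      cand <- shuffle_sequence(modseq)
      if (!(parse_plain(cand) %in% target_seqs) && cand != modseq) {
        dec <- cand
        break
      }
    }
    if (is.null(dec)) {
      # positional swap fallback: rotate non-terminal residues by 8 (mod n-1)
      p <- parse_modified_sequence(modseq)
      res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
      k <- n - 1L
      perm <- c(((seq_len(k) - 1L + 8L) %% k) + 1L, n)
      dec <- rebuild_modseq(res[perm], p$modifications, perm)
    }
    rows <- targets[targets$ModifiedPeptideSequence == modseq, , drop = FALSE]
    rows$ModifiedPeptideSequence <- dec
    rows$PeptideSequence <- parse_plain(dec)
    rows$ProteinId <- paste0("DECOY_", rows$ProteinId)
    rows$PrecursorMz <- vapply(rows$PrecursorCharge,
                               function(z) peptide_mz(dec, z), 0)
    rows$ProductMz <- mapply(function(ty, o, z) fragment_mz(dec, ty, o, z),
                             rows$FragmentType, rows$FragmentSeriesNumber,
                             rows$FragmentCharge)
    rows$Decoy <- 1L
    out[[i]] <- rows
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_library("decoys"))
  assay_library(do.call(rbind, out), provenance = "decoys")
}
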