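# The assay library container: a long-format transition table (one row per
# transition) carrying the protein -> peptide -> precursor -> transition
# hierarchy implicitly, in the OpenSWATH-style column dialect.

LIBRARY_COLUMNS <- c(
  "ProteinId", "PeptideSequence", "ModifiedPeptideSequence", "PrecursorMz",
  "PrecursorCharge", "ProductMz", "FragmentType", "FragmentSeriesNumber",
  "FragmentCharge", "LibraryIntensity", "NormalizedRetentionTime", "Decoy"
)

#' Construct and validate an assay library
#'
#' An assay library is a data.frame with one row per transition and the
#' OpenSWATH-style columns `ProteinId`, `PeptideSequence`,
#' `ModifiedPeptideSequence`, `PrecursorMz`, `PrecursorCharge`, `ProductMz`,
#' `FragmentType`, `FragmentSeriesNumber`, `FragmentCharge`,
#' `LibraryIntensity`, `NormalizedRetentionTime` and `Decoy` (0/1).
#' The constructor validates hierarchy invariants: precursor charge 1-4,
#' fragment charge 1-2, positive m/z values, non-negative library
#' intensities, modification syntax, and precursor m/z consistency with the
#' peptide mass.
#'
#' @param df data.frame with the columns above.
#' @param provenance Character vector of filter-step identifiers already
#'   applied to this library.
#' @param check_mz Validate `PrecursorMz` against the sequence-derived value
#'   (tolerance 1e-4 Th). Disable for libraries whose precursor m/z comes
#'   from an external tool with different mass constants.
#' @return An object of class `assay_library` (a data.frame).
#' @export
assay_library <- function(df, provenance = character(0), check_mz = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("transition table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[LIBRARY_COLUMNS]
  df$PrecursorCharge <- as.integer(df$PrecursorCharge)
  df$FragmentCharge <- as.integer(df$FragmentCharge)
  df$FragmentSeriesNumber <- as.integer(df$FragmentSeriesNumber)
  df$Decoy <- as.integer(df$Decoy)
  if (nrow(df) > 0) {
    bad <- which(!(df$PrecursorCharge %in% 1:4))
    if (length(bad) > 0)
      stop("row ", bad[1], ": precursor charge ", df$PrecursorCharge[bad[1]],
           " violates the precursor charge 1-4 rule")
    bad <- which(!(df$FragmentCharge %in% 1:2))
    if (length(bad) > 0)
      stop("row ", bad[1], ": fragment charge ", df$FragmentCharge[bad[1]],
           " violates the fragment charge 1-2 rule")
    bad <- which(!(df$FragmentType %in% c("y", "b")))
    if (length(bad) > 0)
      stop("row ", bad[1], ": fragment type must be 'y' or 'b'")
    bad <- which(df$ProductMz <= 0 | df$PrecursorMz <= 0)
    if (length(bad) > 0)
      stop("row ", bad[1], ": m/z values must be positive")
    bad <- which(df$LibraryIntensity < 0)
    if (length(bad) > 0)
      stop("row ", bad[1], ": library intensity must be non-negative")
    if (check_mz) {
      prec <- !duplicated(paste(df$ModifiedPeptideSequence, df$PrecursorCharge))
      for (i in which(prec)) {
        expect <- peptide_mz(df$ModifiedPeptideSequence[i],
                             df$PrecursorCharge[i])
        if (abs(expect - df$PrecursorMz[i]) > 1e-4)
          stop("row ", i, ": precursor m/z ", format(df$PrecursorMz[i]),
               " inconsistent with sequence mass (expected ",
               format(round(expect, 5)), ")")
      }
    }
  }
  structure(df, provenance = provenance,
            class = c("assay_library", "data.frame"))
}

#' @export
print.assay_library <- function(x, ...) {
  cz <- census(x)
  cat("Assay library:", cz$n_proteins, "proteins,", cz$n_peptides,
      "peptides,", cz$n_precursors, "precursors,", cz$n_transitions,
      "transitions\n")
  prov <- attr(x, "provenance")
  if (length(prov) > 0)
    cat("Applied filters:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

#' Precursor key strings for an assay library
#'
#' Identifies a precursor by modified sequence and charge, e.g.
#' `"PEPTIDEK/2"`.
#'
#' @param lib An `assay_library`.
#' @return Character vector, one element per transition row.
#' @export
precursor_key <- function(lib) {
  if (nrow(lib) == 0) return(character(0))
  paste0(lib$ModifiedPeptideSequence, "/", lib$PrecursorCharge)
}

#' Library census
#'
#' Counts distinct proteins, peptides (by modified sequence), precursors
#' (modified sequence x charge) and transitions.
#'
#' @param lib An `assay_library`.
#' @return A list of class `census` with fields `n_proteins`, `n_peptides`,
#'   `n_precursors`, `n_transitions`.
#' @export
census <- function(lib) {
  structure(list(
    n_proteins = length(unique(lib$ProteinId)),
    n_peptides = length(unique(lib$ModifiedPeptideSequence)),
    n_precursors = length(unique(precursor_key(lib))),
    n_transitions = nrow(lib)
  ), class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("proteins %d | peptides %d | precursors %d | transitions %d\n",
              x$n_proteins, x$n_peptides, x$n_precursors, x$n_transitions))
  invisible(x)
}

#' @export
as.data.frame.census <- function(x, ...) {
  data.frame(n_proteins = x$n_proteins, n_peptides = x$n_peptides,
             n_precursors = x$n_precursors, n_transitions = x$n_transitions)
}

#' Read a transition list from a tab-separated file
#'
#' @param path Path to a TSV transition list with the OpenSWATH-style header
#'   (see [assay_library()]).
#' @param check_mz Passed to [assay_library()].
#' @return An `assay_library`.
#' @export
read_transition_list <- function(path, check_mz = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  assay_library(df, check_mz = check_mz)
}

#' Write a transition list to a tab-separated file
#'
#' Rows are written in a deterministic order (protein id, peptide sequence,
#' precursor m/z, product m/z ascending); m/z values are serialized at five
#' decimals so that a read/write round trip is byte-identical.
#'
#' @param lib An `assay_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(lib, path) {
  df <- as.data.frame(lib)
  ord <- order(df$ProteinId, df$PeptideSequence, df$PrecursorMz, df$ProductMz)
  df <- df[ord, , drop = FALSE]
  df$PrecursorMz <- sprintf("%.5f", df$PrecursorMz)
  df$ProductMz <- sprintf("%.5f", df$ProductMz)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectral library in long peak-per-row format
#'
#' Expected tab-separated columns: `peptide` (modified sequence), `charge`,
#' `mz`, `intensity`, `annotation` (may be empty), `source_rt` (minutes),
#' and `irt` (library iRT coordinate). One row per spectrum peak.
#'
#' @param path Path to the TSV file.
#' @return data.frame of class `spectral_library`, peaks sorted by peptide,
#'   charge, and m/z.
#' @export
read_spectral_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("peptide", "charge", "mz", "intensity", "source_rt", "irt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("spectral library is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$annotation)) df$annotation <- ""
  if (any(df$intensity < 0)) stop("spectrum peak intensities must be >= 0")
  df <- df[order(df$peptide, df$charge, df$mz), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spectral_library", "data.frame")
  df
}

#' Read a sample annotation table
#'
#' Tab-separated columns `sample_id`, `population`, `sampling_batch`,
#' `replicate`. The (population, sampling_batch, replicate) triple must be
#' unique.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the four columns.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "sampling_batch", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("sample annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(df$population, df$sampling_batch, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (population, sampling_batch, replicate) triple in ",
         "sample annotation")
  df
}
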