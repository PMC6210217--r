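# Monoisotopic mass arithmetic for peptides and y/b fragment ions.
# Residue masses are IUPAC monoisotopic values; proton and water constants
# follow standard proteomics practice.

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

#' @noRd
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# UniMod deltas for the two allowed modifications
MOD_MET_OX <- 15.99491
MOD_CYS_CAM <- 57.02146

#' Parse a modified peptide sequence in bracket notation
#'
#' Modified sequences use UniMod-style bracket notation with an explicit
#' signed mass delta after the modified residue, e.g. `"PEPC[+57.02146]IDEK"`.
#'
#' @param modseq Modified sequence string.
#' @return A list with `sequence` (plain uppercase sequence), and
#'   `modifications`, a data.frame with columns `position` (1-based residue
#'   index), `delta` (mass shift in Da) and `kind` (`"Met-oxidation"`,
#'   `"Cys-carbamidomethyl"` or `"other"`).
#' @export
parse_modified_sequence <- function(modseq) {
  stopifnot(is.character(modseq), length(modseq) == 1L, nzchar(modseq))
  chars <- strsplit(modseq, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  pos <- integer(0)
  delta <- numeric(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unbalanced '[' in modified sequence: ", modseq)
      if (length(seq_chars) == 0L)
        stop("modification before first residue in: ", modseq)
      d <- suppressWarnings(as.numeric(paste(chars[(i + 1L):(close - 1L)],
                                             collapse = "")))
      if (is.na(d)) stop("unparseable modification delta in: ", modseq)
      pos <- c(pos, length(seq_chars))
      delta <- c(delta, d)
      i <- close + 1L
    } else {
      if (!ch %in% names(AA_MONO))
        stop("non-standard residue '", ch, "' in sequence: ", modseq)
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  sequence <- paste(seq_chars, collapse = "")
  kind <- rep("other", length(pos))
  on_res <- seq_chars[pos]
  kind[abs(delta - MOD_MET_OX) < 5e-3 & on_res == "M"] <- "Met-oxidation"
  kind[abs(delta - MOD_CYS_CAM) < 5e-3 & on_res == "C"] <- "Cys-carbamidomethyl"
  list(sequence = sequence,
       modifications = data.frame(position = pos, delta = delta, kind = kind,
                                  stringsAsFactors = FALSE))
}

#' Neutral monoisotopic mass of a (possibly modified) peptide
#'
#' @param modseq Modified sequence in bracket notation (plain sequences are
#'   accepted and treated as unmodified).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(modseq) {
  p <- parse_modified_sequence(modseq)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sum(AA_MONO[res]) + sum(p$modifications$delta) + WATER_MASS
}

#' Precursor m/z of a peptide at a given charge
#'
#' @param modseq Modified sequence in bracket notation.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(modseq, charge) {
  stopifnot(is.numeric(charge), length(charge) == 1L, charge >= 1)
  (peptide_neutral_mass(modseq) + charge * PROTON_MASS) / charge
}

#' Fragment ion m/z for y and b series
#'
#' y ions carry the C-terminal `ordinal` residues plus water; b ions carry the
#' N-terminal `ordinal` residues. Modification deltas are applied to the
#' residues covered by the fragment.
#'
#' @param modseq Modified peptide sequence in bracket notation.
#' @param type `"y"` or `"b"`.
#' @param ordinal Fragment series number, `1 <= ordinal <= length - 1`.
#' @param charge Fragment charge (positive integer).
#' @return m/z in Thomson.
#' @export
fragment_mz <- function(modseq, type, ordinal, charge = 1L) {
  type <- match.arg(type, c("y", "b"))
  p <- parse_modified_sequence(modseq)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (ordinal < 1 || ordinal > n - 1)
    stop("fragment ordinal ", ordinal, " out of range for length-", n,
         " peptide")
  idx <- if (type == "y") (n - ordinal + 1L):n else 1L:ordinal
  m <- sum(AA_MONO[res[idx]]) +
    sum(p$modifications$delta[p$modifications$position %in% idx])
  if (type == "y") m <- m + WATER_MASS
  (m + charge * PROTON_MASS) / charge
}

#' Count missed tryptic cleavage sites in a peptide
#'
#' A missed cleavage is an internal K or R not followed by P.
#'
#' @param sequence Plain peptide sequence.
#' @return Non-negative integer count.
#' @export
missed_cleavages <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(0L)
  sum(res[1:(n - 1L)] %in% c("K", "R") & res[2:n] != "P")
}
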