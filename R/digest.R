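# In-silico tryptic digestion.

#' Digestion rule
#'
#' Trypsin-style cleavage C-terminal of the residues in `cleave_after`,
#' suppressed when the following residue is in `suppress_before`.
#'
#' @param cleave_after Residues after which to cleave (default K, R).
#' @param suppress_before Residues that suppress cleavage when they follow
#'   the site (default P).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return A list of class `digest_rule`.
#' @export
digest_rule <- function(cleave_after = c("K", "R"), suppress_before = "P",
                        max_missed = 2L) {
  stopifnot(max_missed >= 0)
  structure(list(cleave_after = cleave_after,
                 suppress_before = suppress_before,
                 max_missed = as.integer(max_missed)),
            class = "digest_rule")
}

#' Digest a protein sequence
#'
#' Returns every peptide with 0 to `rule$max_missed` missed cleavages.
#'
#' @param sequence Protein sequence (uppercase standard residues).
#' @param rule A [digest_rule()].
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, ordered by start position then missed-cleavage
#'   count.
#' @export
digest_protein <- function(sequence, rule = digest_rule()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad) > 0)
    stop("non-standard residue(s) in protein sequence: ",
         paste(unique(bad), collapse = ", "))
  n <- length(res)
  # cleavage site after position i
  sites <- which(res %in% rule$cleave_after)
  sites <- sites[sites < n & !(res[pmin(sites + 1L, n)] %in%
                                 rule$suppress_before)]
  bounds <- c(0L, sites, n)   # peptide i spans (bounds[i]+1) .. bounds[i+1]
  k <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(k)) {
    for (mc in 0:rule$max_missed) {
      j <- i + mc
      if (j > k) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(res[start:end], collapse = ""),
        start = start, end = end, missed_cleavages = mc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
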