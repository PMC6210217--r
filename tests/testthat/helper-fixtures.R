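# Shared builders for small in-code fixtures.

# A tiny valid library: n_prot proteins x n_pep peptides x 1 charge-2
# precursor x n_tr transitions, built from deterministic sequences.
tiny_library <- function(n_prot = 3, n_pep = 2, n_tr = 5, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_prot)) {
    for (j in seq_len(n_pep)) {
      repeat {
        pep <- diaforge:::random_peptide(9 + ((i + j) %% 4))
        if (!pep %in% vapply(rows, function(r) r$PeptideSequence[1], ""))
          break
      }
      prec_mz <- peptide_mz(pep, 2)
      n <- nchar(pep)
      ords <- 3:(n - 1)
      mzs <- vapply(ords, function(o) fragment_mz(pep, "y", o, 1), 0)
      ok <- which(abs(mzs - prec_mz) > 5)[seq_len(n_tr)]
      rows[[length(rows) + 1]] <- data.frame(
        ProteinId = sprintf("P%02d", i), PeptideSequence = pep,
        ModifiedPeptideSequence = pep, PrecursorMz = prec_mz,
        PrecursorCharge = 2L, ProductMz = mzs[ok], FragmentType = "y",
        FragmentSeriesNumber = ords[ok], FragmentCharge = 1L,
        LibraryIntensity = seq(100, 10, length.out = n_tr),
        NormalizedRetentionTime = 10 * (i + j), Decoy = 0L,
        stringsAsFactors = FALSE)
    }
  }
  assay_library(do.call(rbind, rows))
}

# Gaussian transition trace matrix on a grid
gauss_traces <- function(times, apex_rt, areas, fwhm = 0.3, baseline = 0) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  shape <- dnorm(times, apex_rt, sd)
  outer(shape, areas) + baseline
}

# small one-batch annotation
tiny_annot <- function(n_pop = 2, n_rep = 3, batch = "PS1") {
  a <- expand.grid(replicate = seq_len(n_rep),
                   population = sprintf("pop%d", seq_len(n_pop)),
                   stringsAsFactors = FALSE)
  a$sampling_batch <- batch
  a$sample_id <- sprintf("%s_%s_r%d", a$population, batch, a$replicate)
  a[c("sample_id", "population", "sampling_batch", "replicate")]
}
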