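# Brute-force oracle for transition selection: enumerate all theoretical
# y/b fragments, match peaks exhaustively, filter, sort, take 5.
selection_oracle <- function(modseq, charge, peaks, top_n = 5,
                             tol = 0.035) {
  plain <- parse_modified_sequence(modseq)$sequence
  n <- nchar(plain)
  prec <- peptide_mz(modseq, charge)
  frags <- expand.grid(type = c("y", "b"), ordinal = 3:(n - 1),
                       charge = 1:2, stringsAsFactors = FALSE)
  frags$mz <- mapply(function(ty, o, z) fragment_mz(modseq, ty, o, z),
                     frags$type, frags$ordinal, frags$charge)
  frags <- frags[abs(frags$mz - prec) > 5, ]
  hits <- list()
  for (p in seq_len(nrow(peaks))) {
    d <- abs(frags$mz - peaks$mz[p])
    if (min(d) <= tol) {
      f <- which.min(d)
      hits[[length(hits) + 1]] <- cbind(frags[f, ],
                                        intensity = peaks$intensity[p])
    }
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$intensity, hits$mz,
                     match(hits$type, c("y", "b"))), ]
  head(hits, top_n)
}

spectrum_for <- function(modseq, charge, frag_spec, irt = 50) {
  # frag_spec: data.frame(type, ordinal, intensity); peaks at exact mz
  mz <- mapply(function(ty, o) fragment_mz(modseq, ty, o, 1),
               frag_spec$type, frag_spec$ordinal)
  data.frame(peptide = modseq, charge = charge, mz = mz,
             intensity = frag_spec$intensity, annotation = "",
             source_rt = 30, irt = irt, protein = "P1",
             stringsAsFactors = FALSE)
}

test_that("top-5 selection equals the exhaustive oracle", {
  modseq <- "GASPMNDLER"   # length 10: y/b ordinals 3..9
  fs <- data.frame(type = rep("y", 7), ordinal = 3:9,
                   intensity = c(50, 200, 120, 400, 80, 300, 10))
  fs <- rbind(fs, data.frame(type = "b", ordinal = 4, intensity = 250))
  sp <- spectrum_for(modseq, 2, fs)
  lib <- build_initial_target_list(sp)
  expect_equal(nrow(lib), 5)
  oracle <- selection_oracle(modseq, 2, sp)
  got <- lib[order(-lib$LibraryIntensity), ]
  expect_equal(got$LibraryIntensity, oracle$intensity)
  expect_equal(got$FragmentSeriesNumber, oracle$ordinal)
  expect_equal(got$FragmentType, oracle$type)
  # order of input peaks must not matter
  sp2 <- sp[sample(nrow(sp)), ]
  lib2 <- build_initial_target_list(sp2)
  expect_equal(sort(lib2$ProductMz), sort(lib$ProductMz))
})

test_that("fragments inside the precursor isolation window are excluded", {
  modseq <- "GASPMNDLER"
  prec <- peptide_mz(modseq, 2)
  frags <- expand.grid(type = c("y", "b"), ordinal = 3:9,
                       stringsAsFactors = FALSE)
  frags$mz <- mapply(function(ty, o) fragment_mz(modseq, ty, o, 1),
                     frags$type, frags$ordinal)
  eligible <- frags[abs(frags$mz - prec) > 5, ]
  # a spurious peak right at the precursor m/z is the most intense
  sp <- data.frame(peptide = modseq, charge = 2,
                   mz = c(prec + 2, eligible$mz[1:4]),
                   intensity = c(9999, 100, 90, 80, 70), annotation = "",
                   source_rt = 30, irt = 50, protein = "P1",
                   stringsAsFactors = FALSE)
  lib <- build_initial_target_list(sp)
  expect_false(any(abs(lib$ProductMz - prec) <= 5))
  expect_equal(nrow(lib), 4)   # only 4 eligible peaks -> 4 transitions kept
})

test_that("decoy generation preserves structure and differs from targets", {
  lib <- tiny_library(n_prot = 4, n_pep = 2)
  dec <- generate_decoys(lib, seed = 9)
  # one decoy per target peptide, same peptide-level census
  expect_equal(census(dec)$n_peptides, census(lib)$n_peptides)
  expect_equal(census(dec)$n_transitions, census(lib)$n_transitions)
  expect_true(all(dec$Decoy == 1L))
  # determinism
  dec2 <- generate_decoys(lib, seed = 9)
  expect_identical(as.data.frame(dec), as.data.frame(dec2))
  dec3 <- generate_decoys(lib, seed = 10)
  expect_false(identical(dec$PeptideSequence, dec3$PeptideSequence))
  # length and C-terminal residue preserved; sequence not among targets
  tseq <- unique(lib$PeptideSequence); dseq <- unique(dec$PeptideSequence)
  expect_equal(nchar(dseq), nchar(tseq))
  expect_equal(substr(dseq, nchar(dseq), nchar(dseq)),
               substr(tseq, nchar(tseq), nchar(tseq)))
  expect_length(intersect(dseq, tseq), 0)
  # fragment m/z recomputed from the decoy sequence
  for (i in sample(nrow(dec), 10)) {
    expect_equal(dec$ProductMz[i],
                 fragment_mz(dec$ModifiedPeptideSequence[i],
                             dec$FragmentType[i],
                             dec$FragmentSeriesNumber[i],
                             dec$FragmentCharge[i]),
                 tolerance = 1e-9)
  }
  # intensities copied from the target
  expect_equal(sort(dec$LibraryIntensity), sort(lib$LibraryIntensity))
})
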