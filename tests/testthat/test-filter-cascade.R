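make_lib <- function(rows) assay_library(do.call(rbind, rows))

pep_rows <- function(protein, modseq, n_tr = 5, irt = 30) {
  diaforge:::fixture_peptide_rows(protein, modseq, irt, n_tr)
}

test_that("step 1 keeps only Met-ox / Cys-CAM modifications", {
  lib <- make_lib(list(
    pep_rows("P1", "GASPMNDLER"),
    pep_rows("P1", "GASPM[+15.99491]NDLEK"),
    pep_rows("P1", "GAC[+57.02146]PMNDLER"),
    pep_rows("P1", "GAS[+79.96633]PMNDLEK")))
  out <- apply_static_filter(lib, 1)
  expect_setequal(unique(out$ModifiedPeptideSequence),
                  c("GASPMNDLER", "GASPM[+15.99491]NDLEK",
                    "GAC[+57.02146]PMNDLER"))
})

test_that("step 2 removes shared peptides and duplicate rows", {
  shared <- pep_rows("P2", "WNDAETGLLER")
  shared2 <- shared; shared2$ProteinId <- "P3"
  lib <- make_lib(list(pep_rows("P2", "GASPMNDLER"),
                       pep_rows("P3", "MNWEDATLLK"),
                       shared, shared2,
                       pep_rows("P2", "HHWEDATLLK"),
                       pep_rows("P2", "HHWEDATLLK")))  # duplicated block
  out <- apply_static_filter(lib, 2)
  expect_false("WNDAETGLLER" %in% out$PeptideSequence)
  expect_equal(sum(out$PeptideSequence == "HHWEDATLLK"), 5)
})

test_that("step 3 boundary: 4 transitions kept, 3 removed", {
  lib <- make_lib(list(pep_rows("P1", "GASPMNDLER", n_tr = 4),
                       pep_rows("P1", "MNWEDATLLK", n_tr = 3)))
  out <- apply_static_filter(lib, 3)
  expect_setequal(unique(out$PeptideSequence), "GASPMNDLER")
})

test_that("step 4 removes missed-cleavage peptides", {
  lib <- make_lib(list(pep_rows("P1", "GASPMNDLER"),
                       pep_rows("P1", "GAKSPMNDLER")))
  out <- apply_static_filter(lib, 4)
  expect_setequal(unique(out$PeptideSequence), "GASPMNDLER")
  expect_error(apply_static_filter(lib, 9), "invalid")
})

test_that("dotp filter removes only all-sample failures, strict at 0.8", {
  lib <- make_lib(list(pep_rows("P1", "GASPMNDLER"),
                       pep_rows("P1", "MNWEDATLLK"),
                       pep_rows("P1", "HHWEDATLLK"),
                       pep_rows("P1", "WNDAETGLLER")))
  keys <- unique(precursor_key(lib))
  samples <- sprintf("s%d", 1:24)
  tab <- expand.grid(key = keys, sample_id = samples,
                     stringsAsFactors = FALSE)
  tab$dotp <- 0.95
  tab$dotp[tab$key == keys[1]] <- 0.79                  # fails everywhere
  tab$dotp[tab$key == keys[2]] <- 0.5                   # fails except once
  tab$dotp[tab$key == keys[2] & tab$sample_id == "s7"] <- 0.85
  tab$dotp[tab$key == keys[3]] <- 0.80                  # exactly at cutoff
  out <- dotp_filter(lib, tab, threshold = 0.8)
  kept <- unique(precursor_key(out))
  expect_false(keys[1] %in% kept)
  expect_true(all(keys[2:4] %in% kept))
  expect_error(dotp_filter(lib, tab[tab$key != keys[4], ]), "coverage")
})

test_that("protein minimum-peptide filter boundary", {
  lib <- make_lib(list(pep_rows("P1", "GASPMNDLER"),
                       pep_rows("P1", "MNWEDATLLK"),
                       pep_rows("P2", "HHWEDATLLK")))
  out <- protein_min_peptides(lib)
  expect_setequal(unique(out$ProteinId), "P1")
  empty <- diaforge:::empty_library()
  expect_equal(nrow(protein_min_peptides(empty)), 0)
})

test_that("static filter steps are idempotent", {
  fx <- make_cascade_fixture(seed = 3)
  lib <- fx$library
  for (step in 1:4) {
    once <- apply_static_filter(lib, step)
    twice <- apply_static_filter(once, step)
    expect_equal(unclass(census(twice)), unclass(census(once)),
                 label = paste("step", step))
  }
  pm <- protein_min_peptides(lib)
  expect_equal(unclass(census(protein_min_peptides(pm))),
               unclass(census(pm)))
})

test_that("cascade on the planted fixture equals the exhaustive oracle", {
  fx <- make_cascade_fixture(seed = 1)
  res <- run_cascade(fx$library, fx$training, fx$annot)
  expect_equal(unclass(census(res$library)),
               unclass(fx$expected_census))
  # all post-conditions hold globally
  lib <- res$library
  mods <- lapply(unique(lib$ModifiedPeptideSequence),
                 function(s) parse_modified_sequence(s)$modifications$kind)
  expect_true(all(unlist(mods) %in% c("Met-oxidation",
                                      "Cys-carbamidomethyl")))
  expect_true(all(tapply(lib$ProteinId, lib$PeptideSequence,
                         function(x) length(unique(x))) == 1))
  expect_true(all(table(precursor_key(lib)) >= 4))
  expect_true(all(vapply(lib$PeptideSequence, missed_cleavages, 0L) == 0))
  expect_true(all(tapply(lib$ModifiedPeptideSequence, lib$ProteinId,
                         function(x) length(unique(x))) >= 2))
  # provenance lists every applied step
  expect_true(all(c("step1_ptm", "step2_unique", "step4_missed_cleavage",
                    "step5_dotp", "step7_curation") %in%
                    attr(lib, "provenance")))
})

test_that("cascade censuses shrink monotonically at every level", {
  fx <- make_cascade_fixture(seed = 2)
  rep <- run_cascade(fx$library, fx$training, fx$annot)$report
  for (col in c("n_proteins", "n_peptides", "n_precursors",
                "n_transitions")) {
    expect_true(all(diff(rep[[col]]) <= 0), label = col)
  }
})

test_that("violation-free fixture passes the cascade untouched", {
  fx <- make_cascade_fixture(seed = 4, violations = FALSE)
  res <- run_cascade(fx$library, fx$training, fx$annot)
  expect_equal(unclass(census(res$library)),
               unclass(census(fx$library)))
})

test_that("codified curation implements each rule", {
  fx <- make_cascade_fixture(seed = 5)
  # reduce to the precursors that reach step 7, then curate
  lib <- fx$library
  for (s in 1:4) lib <- apply_static_filter(lib, s)
  lib <- dotp_filter(lib, fx$training$dotp)
  lib <- protein_min_peptides(lib)
  out <- automated_curation(lib, fx$training$run, fx$annot)
  fl <- fx$flags
  kept <- unique(precursor_key(out))
  # rule 1: flagged transition dropped, precursor retained with 4
  r1key <- fl$key[nzchar(fl$rule1)]
  expect_true(r1key %in% kept)
  expect_equal(sum(precursor_key(out) == r1key), 4)
  # rules 2-4: flagged precursors dropped
  expect_false(any(fl$key[fl$rule2 | fl$rule3 | nzchar(fl$rule4)] %in%
                     kept))
})
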