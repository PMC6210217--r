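---
title: "Methods: assay-library construction and quantitation for DIA proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assay-library construction and quantitation for DIA proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaforge)
```

# Overview

`diaforge` implements an end-to-end workflow for label-free quantitative
proteomics by data-independent acquisition (DIA): building a curated assay
library from a spectral library, extracting and scoring targeted
chromatograms against it, summarizing transitions to protein abundances,
testing one population against the rest, and quantifying how reproducible
the resulting proteome signatures are across repeated population samplings.
Every stage can be exercised on a bundled synthetic DIA simulator with full
ground truth, so all statistical claims made by the test suite are computed,
not asserted.

This vignette documents the models and procedures, the tunable parameters
and their defaults, the numerical choices, and the known limitations.

# Library construction

## Digestion and mass arithmetic

In-silico digestion is tryptic: cleavage C-terminal of Lys or Arg, suppressed
before Pro, with up to two missed cleavages
(`digest_rule()`). Peptide and fragment masses use IUPAC monoisotopic residue
masses with proton 1.007276 Da and water 18.010565 Da; only y and b ions at
fragment charge 1-2 are modelled. Modified sequences use bracket notation
with explicit deltas (e.g. `C[+57.02146]`), which round-trips through the
tab-separated transition-list format without ambiguity. Only Met oxidation
(+15.99491) and Cys carbamidomethylation (+57.02146) are recognized as named
modifications; anything else is carried as `other` and removed by the first
library filter.

## Transition selection

`build_initial_target_list()` picks, per (peptide, charge) spectrum, the five
most intense fragment peaks that (i) match a theoretical y/b m/z within
±0.035 Th, (ii) have ordinal between 3 and peptide length − 1, (iii) have
fragment charge 1-2, and (iv) lie outside the 10-Th isolation window centred
on the precursor (interpreted as ±5 Th; the window width is stated, the
interpretation as a symmetric half-width is ours). Intensity ties break by
lower fragment m/z, then y before b — an arbitrary but deterministic rule.
Un-annotated peaks are matched to theoretical fragments greedily by smallest
absolute m/z difference, each peak used at most once.

## Decoys

`generate_decoys()` emits one decoy peptide per target peptide by a seeded
shuffle of the non-C-terminal residues. Fixing the terminal residue preserves
tryptic character and the precursor-mass distribution; fragment m/z values
are recomputed from the shuffled sequence while library intensities are
copied from the target, so decoys are indistinguishable from targets in every
summary statistic except the actual signal under their transitions.
Collisions with target sequences are reshuffled (20 retries) before a
deterministic positional rotation is used as a last resort; peptides of
length ≤ 2 cannot be scrambled and are skipped with a warning.

# The seven-step filter cascade

`run_cascade()` reduces an initial target list in a fixed order:

1. remove peptides with modifications other than Met oxidation /
   Cys carbamidomethylation;
2. remove repeated peptide entries and peptides shared between proteins;
3. remove precursors with fewer than four transitions;
4. remove peptides with missed cleavages;
5. remove peptides whose dotp is below 0.8 in **every** training sample
   (one passing sample suffices; the inequality is strict);
6. remove proteins with fewer than two remaining peptides;
7. codified peak-shape curation (below), after which the step-3 and step-6
   constraints are re-applied, since removing transitions or precursors can
   re-create violations.

Step 7 replaces a manual two-investigator review with four codified rules
evaluated on training chromatograms (`curation_settings()`):

* **Rule 1** (interference, per transition): an off-target local maximum
  within ±3 min of the predicted RT, separated from the on-target apex by
  more than 0.5 min (about two nominal peak widths), exceeding the on-target
  apex. The transition is dropped when this occurs in at least half the
  samples of any one population.
* **Rule 2** (detectability): apex signal-to-noise below 3 within the RT
  window, in at least half of one population's samples, drops the precursor.
  "Clearly discernable" has no published numeric criterion; S/N ≥ 3 against
  the median absolute level of the summed smoothed trace is our
  operationalization.
* **Rule 3** (peak-width consistency): within any population, if the median
  FWHM of the wider half of samples exceeds twice the median FWHM of the
  narrower half, the precursor is dropped. FWHM is measured on the smoothed
  summed-transition trace by linear interpolation at half the apex.
* **Rule 4** (multiple interferences): more than one rule-1-flagged
  transition in the same sample, in at least half of one population's
  samples, drops the whole precursor.

The per-population aggregation threshold (half the samples) is stated for
rule 2 only; we apply the same aggregation to rules 1 and 4 for consistency.
`make_cascade_fixture()` builds a ~30-protein library with one planted
violation per rule and predicts the final census by an independent
exhaustive re-scan of the planted flags; the test suite requires exact
agreement.

# Extraction and calibration

`build_isolation_scheme()` steps windows of fixed width by
`width − 2 × edge_overlap`; with the acquisition defaults (390-1065 Th,
width 10, overlap 0.5 per edge) this yields exactly 75 windows, which is
what pins down the "0.5 overlap means 0.5 Th per shared edge"
interpretation (the alternative reading gives 71). Chromatogram extraction
sums all peaks within ±0.035 Th — the same tolerance used for library
matching, as no separate extraction tolerance is published.

iRT calibration (`fit_irt()`) is ordinary least squares of observed RT on
library iRT over 16 standard peptides, with up to two rounds of rejection of
points whose residual exceeds three residual SDs. Peak-group detection
(`detect_peak_groups()`) smooths the summed trace with a Savitzky-Golay
filter (window 7, order 2 — a conventional choice; the reference
implementation in commercial software is unpublished), takes local maxima
within ±3 min of the predicted RT, and sets boundaries at the flanking
minima or the 1%-of-apex crossing, whichever is nearer. Per-transition areas
are trapezoidal integrals within the boundaries. At most 10 candidates per
(precursor, sample) are kept, bounding the scoring cost.

# Peak scoring and q-values

Each candidate peak group is described by five subscores: dotp (cosine
similarity of square-root-transformed library intensities and observed
areas), coelution (mean pairwise Pearson correlation of the transition
traces within the boundaries; constant traces contribute 0, a single
transition scores 1), absolute RT deviation from prediction, log10 total
area, and apex signal-to-noise. The subscore set is fixed here; commercial
mProphet implementations use their own unpublished feature sets, and
equivalence with their scores is not claimed.

`train_discriminant()` is semi-supervised: iteration 0 ranks by dotp alone;
each of three iterations labels targets at q < 0.15 as positives and all
decoys as negatives, fits a linear discriminant with pooled covariance and a
1e-6 ridge, and rescores. The procedure is deterministic; the seed is
recorded for provenance. q-values use target-decoy counting with a +1
pseudo-count,

\[ \widehat{FDR}(s) = \frac{1 + \#\{d \ge s\}}{\max(1, \#\{t \ge s\})}
   \cdot \frac{N_t}{N_d}, \qquad q(s) = \min_{s' \le s} \widehat{FDR}(s'), \]

which is simpler and more conservative than a parametric null; at small
target counts the pseudo-count floors the attainable q at roughly
\(1/N_t\), which is intentional. Acceptance for quantitation uses
q ≤ 0.005 (FDR < 0.5%), the operating point this workflow standardizes on.

# Quantitation and inference

Transition areas of accepted peak groups form a log2(area + 1) matrix.
Sample medians are equalized exactly (each column is shifted to the median
of the column medians). Each protein's transition-by-sample block is
decomposed by Tukey median polish (row sweep first, converged when the
largest sweep change falls below 1e-6 or after 10 sweep pairs); the protein
abundance per sample is the overall plus the column effect. Missing peaks
are imputed as zero intensity *before* the log transform — the
conventional "zero for missing peaks" setting — which biases low-abundance proteins downward when acceptance is
sporadic; censored-value modelling is deliberately out of scope and this is
the main known limitation of the quantitation module.

Differential abundance is a fixed-effects linear model per protein of log2
abundance on a focal-population indicator, with an additive sampling-batch
term for combined analyses; after summarization there is one measurement per
biological replicate, so the fixed-effects model coincides with the
mixed-model formulation used by MSstats for this design. The log2 fold
change is the group coefficient (positive = elevated in the focal
population), tested two-sided against the t distribution, and adjusted by
Benjamini-Hochberg (via `stats::p.adjust`). The significance call used
downstream is adj. p < 0.05 **and** fold change ≥ 2.0 for single-batch
(n = 6) comparisons or ≥ 1.45 for combined (n = 24) comparisons.

The minimum detectable fold change uses the classical two-sample normal
approximation \( \Delta_{\log_2} = (z_{1-\alpha/2} + z_{power})
\sqrt{2\sigma^2/n} \) with \(\sigma = \sqrt{\ln(1 + CV^2)}/\ln 2\) and
\(\alpha\) at the FDR level. Calibrating the CV so that the threshold at
n = 6 equals 2.0 gives 1.414 at n = 24; MSstats' FDR-anticipating power
formula gives 1.45 for the same design, and we treat agreement within 3%
as the consistency check rather than expecting equality of two different
power formulas.

# Reproducibility statistics

`comparison_set()` collects per-(protein, population, batch) fold changes
and adjusted p-values. A **false positive** for a focal batch is a protein
significant there whose fold change in any other batch crosses the
reciprocal threshold in the opposite direction (FC ≥ 2 here, ≤ 0.5 there).
A **false negative** reaches the fold-change threshold in the consensus
direction (the sign of the mean log2 FC across batches; the consensus rule had to
be fixed somewhere, and the mean is the least surprising choice)
but misses significance. A protein enters a population's proteome
**signature** only when significant in the required direction in every
batch. Volcano tables classify proteins into the p < 0.01 / p < 0.05 / not
significant tiers (requiring the fold-change threshold for either tier) and
clip plotting coordinates at fold change 4.

# The synthetic simulator

`sim_config()` defaults encode the emulated study design: 4 populations ×
6 replicates × 4 sampling batches (96 samples), 200 proteins with 2-3
tryptic peptides each, 10% of proteins given a population-specific effect of
|log2 FC| = 1.5 with alternating sign (disjoint protein sets per population,
keeping one-vs-rest contrasts clean), and 16 iRT standards per sample.
Remaining defaults are values a practitioner would call realistic for a
label-free gradient: log2 protein abundance N(17, 1.5) in total ion counts,
within-population biological SD 0.25 log2 units (~19% CV), fixed per-peptide
response factors with SD 0.5, Dirichlet(2) fragment profiles, per-sample RT
maps with slope 0.7-1.3 and intercept 0-20 min, RT jitter SD 0.1 min,
log-normal FWHM around 0.3 min, baseline 50 counts (constant plus Poisson),
10% multiplicative intensity noise, 5% per-transition interference rate at
1.5× the on-target apex, and uniform ±5 ppm m/z jitter. Chromatograms are
sampled at 0.05 min over ±3.2 min around the mapped RT — enough to contain
the ±3 min search window.

Peaks are pure Gaussians: no tailing, no isotope structure, no profile-mode
m/z dimension, and interferences are single offset Gaussians rather than
structured co-eluting peptides. Consequently, passing tests demonstrate the
correctness and calibration of the algorithms under the stated generative
model, not performance on real chromatography; in particular the scoring
problem here is easier than on real data, where peak shapes and
interferences are worse behaved.

Problem sizes used by the test suite were chosen to exercise the full
design while keeping the suite fast to iterate: the FDR-calibration check
uses 1000 target peptides (200 signal-free) plus 1000 decoys in a single
sample across ten seeds; the end-to-end study uses the full default design
(96 samples, ~1000 precursors including decoys). Both finish in a few
minutes on one core.

# Degenerate inputs and tie-breaks

* All-zero observed areas give dotp 0; an all-zero library vector is an
  error.
* Constant traces contribute correlation 0 to coelution.
* Window-assignment ties on shared boundaries go to the lower window index.
* Duplicate transition rows collapse to one at filter step 2.
* Empty libraries pass through every filter unchanged with census
  (0, 0, 0, 0).
* `estimate_qvalues()` handles tied scores by assigning the full tied count
  to every member of the tie.

# Design choices that were genuinely open

* **Global vs per-sample scoring model**: one discriminant pooled across all
  samples of a run set, chosen for stability at 24 training samples.
* **Best-candidate selection**: the training set uses the best candidate per
  (precursor, sample) by dotp; after training, the best by discriminant
  score enters q-value estimation and quantitation.
* **Step-5 dotp source**: the best-scoring peak group per sample supplies
  the dotp, rather than a q-value-passing one.
* **Decoy strategy**: sequence shuffle with fixed C-terminus rather than
  reversal; reversal of tryptic peptides produces near-palindromic fragment
  ladders that overlap targets too much at these peptide lengths.
* **Missing data**: zero imputation (published setting) rather than
  censored-likelihood modelling.
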