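---
title: "Methods: urinary peptidome ageing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary peptidome ageing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptiage)
```

## The measurement and the data model

Capillary electrophoresis coupled to mass spectrometry (CE-MS) profiles the
urinary peptidome — the naturally occurring peptides below about 20 kDa —
without enzymatic digestion.  After charge-state deconvolution (outside the
scope of this package), one sample is a *peak list*: a set of
(molecular mass [Da], CE migration time [min], signal intensity) triples,
held here as a `peak_table`.  A study is a collection of peak lists plus
sample metadata (species, age, genotype), and after cross-sample clustering
becomes a `cohort_matrix`: one row per peptide feature, one column per
sample.

Two conventions run through the package:

* **Zeros, not NAs.**  A feature undetected in a sample is stored as
  intensity 0.  The screening stage deliberately applies no detection
  frequency threshold — every feature is correlated with age across *all*
  samples — and that requires a defined value for non-detections.  Zeros
  enter the rank correlation as mid-ranked ties at the bottom.
* **Lowercase modified residues.**  Sequences use the reporting convention
  `p` = hydroxyproline, `m` = oxidised methionine, `k` = hydroxylysine;
  all other residues are uppercase.  `normalize_sequence()` folds the
  modified letters onto their parent residue for comparisons and records
  their positions.

## Preprocessing

**Axis calibration** (`fit_calibration()`): mass and migration-time axes are
calibrated against reference control points by one-pass tricube-weighted
local linear regression (span 0.3 by default).  The fitted curve is applied
by linear interpolation between control points and extended linearly from
the boundary segments outside the control range.  Calibration curves in this
setting are near-linear, so a moderate span with no robustness iterations
recovers them well; the fitted values are forced monotone (by a running
maximum) because the physical axis mapping cannot fold back on itself.

**Internal-standard normalisation** (`normalize_sample()`): analytical and
urine-dilution variance is removed by rescaling each sample so that a set of
age-stable internal-standard peptides (29 by default) return to their
reference amplitudes.  Each standard is located in the peak list through the
clustering tolerance windows; the scale factor is the **median** of
reference/observed intensity ratios.  The median was chosen over the mean or
a regression because it is robust to a mismatched or saturated standard,
idempotent (normalising twice is a no-op), and exactly scale-equivariant.
Standards observed at zero intensity are excluded from the median; a sample
matching no standard raises an error rather than passing through
unnormalised.

## Cross-sample clustering

Signals from different samples are the same peptide when their masses agree
within 50 ppm (below 4,000 Da) or 75 ppm (at or above), and their migration
times agree within a half-window of ±1 min at 19 min widening to ±2.5 min at
50 min.  Three numerical decisions close gaps the window prose leaves open:

* the widening is **linear** between the two anchor points and clamped
  outside — the simplest curve through both printed anchors;
* tolerances are applied **inclusively** (≤) even though the prose says
  "<"; the boundary has measure zero and inclusivity simplifies testing;
* clustering is **greedy agglomeration after a canonical sort** of all
  pooled peaks by (mass, time, intensity, sample id).  A peak joins the
  existing feature whose running intensity-weighted consensus lies within
  both windows and which holds no peak from the same sample yet; ties go to
  the smallest mass distance, then time distance, then earliest feature.
  Graph-based clique finding would be quadratic and no better on
  well-separated data; on such data the greedy result provably equals the
  connected-component optimum, which the test suite checks against an
  exhaustive oracle on instances of up to 30 peaks.  The canonical sort
  makes the output invariant to the order in which samples are supplied.

## Sequence-assignment validation

Candidate sequence identifications are screened by two orthogonal physics
checks (`validate_identification()`): the observed mass must match the
theoretical monoisotopic mass within ±80 ppm, and the observed migration
time must match the time predicted from the candidate's charge within
±2 min.  Charge at pH 2 is `1 + #K + #R + #H` (N-terminal amine plus the
residues basic at pH 2, modified residues counting as their parents), and
the predictor is a least-squares fit `time ~ a + b·charge + c·ln(mass)` on
user-supplied training identifications — charge and size are the two
variables that drive electrophoretic mobility.  Both the charge convention
(His counted as basic) and the functional form are configuration points, so
an alternative mobility model can be swapped in.  The acceptance region is a
closed rectangle; a 1e-9 relative guard keeps the boundary inclusive under
floating point.  Note the validation tolerance (±80 ppm) is intentionally
independent of the clustering tolerance (50/75 ppm): they belong to
different stages and are not reconciled.

## Age-correlation screening

Each feature's intensity profile is tested against age as a continuous
variable with Spearman's rank coefficient on mid-ranks, p-values from the
large-sample t approximation (cohorts of 60–1200 samples make exact
permutation both infeasible and unnecessary), and Benjamini-Hochberg
step-up adjustment across all tested features.  Significance is called at
adjusted p ≤ 0.05, inclusive.  Constant profiles (for example all-zero
features) have no defined correlation and are reported as skipped with a
reason.  A `detected_only` flag restricts each test to samples where the
feature was seen, since it is not knowable whether the original analysis
included zeros; zeros-included is the default because it uses the full
cohort for every feature.

## Cross-species orthology

Age-correlated mouse and human peptides are paired by three sequence rules
plus a direction filter (`is_ortholog()`):

1. **identical** folded sequences;
2. **region_overlap** — an ungapped overlap of ≥ 6 residues with no
   mismatch (and, when both records carry gene symbols, symbols in the same
   gene family, e.g. any two collagen chains);
3. **one_mismatch** — an overlap of ≥ 6 residues containing exactly one
   internal substitution.

In every case the two peptides must correlate with age in the same
direction.  The "one amino acid gap" of rule 3 is read as a substitution in
an ungapped alignment, not an indel: in the published ortholog table every
non-matching internal letter (T/S, T/A, L/V, …) aligns without shifting the
frame, and the matched regions are length-preserving.  Mismatches at window
edges are trimmed rather than counted, again following how the published
table marks its matched regions, and hydroxylation/oxidation differences
never count as mismatches.  `best_ungapped_overlap()` scans all relative
offsets and maximises window length subject to the mismatch budget, with
ties broken by fewer mismatches then smaller offset; the test suite checks
it against exhaustive enumeration on short sequences.  Whether rule 3 also
requires the 6-residue minimum is not specified anywhere; this
implementation requires it (the threshold is a parameter).

`map_orthologs()` evaluates all cross-species pairs and keeps the
many-to-many structure — one mouse peptide may match several human peptides
and vice versa — and its summary counts distinct sequences per species and
per gene.  On the packaged ortholog table (55 printed pairs) the matcher
accepts every printed pair and reproduces the published panel sizes: 49
distinct mouse sequences orthologous to 42 distinct human sequences, 44
from collagen genes and 5 from uromodulin.

## The SVM ageing score

`train_ageing_classifier()` fits a radial-basis-kernel support vector
machine (via e1071/libsvm) on binary young/old training labels over the
`ln(intensity + 1)` coordinates of a fixed peptide panel; the ageing score
of any sample is its signed decision-function value — its distance to the
maximal-margin hyperplane — oriented so the training "old" class averages
positive.  `ln(x + 1)` is used so a non-detection maps to coordinate 0.  No
per-feature scaling is applied before the kernel; whether the original
software normalised feature vectors is unknown, and this is flagged as a
deviation of unknown direction.  The cost C and kernel width gamma are not
published either, so they are chosen by 5-fold cross-validated accuracy on
the training set only, over the grid {0.1, 1, 10, 100} × {1/(d·Var),
0.01, 0.1, 1}, with deterministic stratified folds derived from a seed and
ties resolved to the smallest C, then gamma.  Group contrasts of scores use
the two-sided Mann-Whitney test, exact when the smaller group has ≤ 8
observations and no ties, normal approximation with tie correction
otherwise.

Training mirrors the published design: the classifier is fitted on binary
young/old labels only, then scores *all* samples continuously — mature
groups and accelerated-ageing genotypes are never trained on.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with known ground truth so every stage
is testable without raw instrument data.  Defaults describe a mouse-like
study: six age groups at 4, 12, 48, 61, 84 and 96 weeks with 10 samples
each (60 samples); 2,000 peptide features with true masses in
[800, 20000] Da (kept ≥ 4 Da apart so tolerance windows cannot merge
neighbours) and migration times in [19, 50] min; 50 negative (collagen-like)
and 20 positive (uromodulin-like) markers with per-week log-intensity slopes
drawn from ±[0.01, 0.03] — moving a marker by roughly 1–3 natural-log units
across the age range; 29 zero-slope internal standards; log-scale noise
SD 0.3; 10% dropout (never applied to standards); and per-sample dilution
factors uniform in [0.5, 2].  Intensities are generated on the natural-log
scale and exponentiated, matching the classifier's log transform and giving
realistically skewed amplitudes; dropout is applied after dilution.
Observed coordinates are the true values plus uniform perturbations capped
at half the clustering window, so replicates of a feature always fall within
one window of each other (`truth_mass_within_tolerance_report()` verifies
this).  Everything is deterministic given the seed, and the caller's RNG
state is restored.

An optional accelerated-ageing group models a premature-ageing genotype by
multiplying every marker slope, i.e. an effective age of
`multiplier × chronological age`.  The default multiplier is 2.0: the study
design this emulates has 61-week knockouts scoring above 96-week wild-types,
which requires an effective-age ratio above 96/61 ≈ 1.6; a multiplier of
1.5 would place the knockouts at an effective 91.5 weeks, *below* the oldest
wild-type group, and make the qualitative contrast unattainable by
construction.

What the generator does **not** emulate: isotope envelopes, charge states
and deconvolution artefacts; migration-time drift beyond a global
calibration; correlated peptide families (fragments of one protein rising
and falling together); age-dependent detectability; non-linear trajectories.
Passing the recovery tests therefore shows the pipeline is correct under
its stated model — log-linear trends, independent noise, multiplicative
dilution — not that it is robust to every artefact of real CE-MS data.

## Problem sizes and empirical behaviour

The test suite exercises the full pipeline at the default cohort size
(60 samples × 2,000 features, one fixed seed), where it verifies ≥ 90%
marker recovery with correct direction at adjusted p ≤ 0.05 and an
empirical FDR on null features ≤ 0.07; in the runs performed here recovery
was complete and the FDR stayed near the nominal 5%.  The classifier checks
use the same design plus a 5-sample accelerated group: an SVM trained on
half the wild-type cohort reaches ≥ 0.9 held-out young/old accuracy, median
scores increase strictly across young/mature/old validation groups, and the
accelerated group at 61 weeks scores above the 96-week wild-types.  Unit
tests run the same properties at smaller sizes (≈ 80–200 features) for
speed.

## Known limitations

* The greedy clustering is order-canonical but not globally optimal on
  *dense* data where windows overlap chains of peaks; only the
  well-separated regime carries an optimality guarantee.
* The migration-time predictor is a two-variable linear surrogate; real
  electrophoretic mobility has sequence effects it cannot capture.
* The internal-standard normalisation assumes the standards are present
  and quantified in essentially every sample; it corrects a single
  multiplicative dilution factor, not intensity-dependent effects.
* Published cohort-level statistics that depend on the deposited raw data
  (significant-peptide counts per species, per-peptide rho values, cohort
  p-values) are out of reach by design; the package reproduces the
  published worked example (the ortholog table) and validates everything
  else against synthetic ground truth and independent oracles.
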