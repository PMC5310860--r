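# peptiage

Age-correlation analysis of the urinary peptidome measured by CE-MS
(capillary electrophoresis coupled to mass spectrometry), for researchers
evaluating mouse models of ageing against human cohorts.  Urine carries
thousands of naturally occurring peptides; with age, fibrillar collagen
fragments (COL1A1, COL1A2, COL3A1) decline and uromodulin (UMOD) fragments
rise in both species, and a fixed panel of cross-species *ortholog*
peptides supports an SVM "ageing score" that tracks molecular age — and
flags premature-ageing genotypes scoring older than their chronological
age.

The package implements the full desk-scale workflow:

* **I/O** — TSV peak lists (mass [Da], migration time [min], intensity),
  cohort matrices, annotation tables, and the packaged table of published
  mouse–human ortholog peptides.
* **Preprocessing** — axis calibration by locally weighted regression;
  per-sample intensity normalisation to 29 internal-standard peptides
  (scale factor = median of reference/observed ratios).
* **Clustering** — cross-sample matching of signals into peptide features
  under mass tolerance (50 ppm < 4,000 Da, else 75 ppm) and a migration
  half-window widening linearly from ±1 min at 19 min to ±2.5 min at
  50 min.
* **Screening** — Spearman rank correlation of every feature with age as a
  continuous variable (ρ), Benjamini–Hochberg adjustment, significance at
  adjusted p ≤ 0.05.
* **Sequence validation** — candidate identifications accepted iff
  |Δmass| ≤ 80 ppm and |Δtime| ≤ 2 min against a migration-time model
  `t = a + b·z + c·ln(m)`, with charge `z = 1 + #K + #R + #H` at pH 2.
* **Orthology** — mouse–human peptide pairing by identity, same-region
  ungapped overlap ≥ 6 residues, or one internal substitution, requiring
  concordant age-correlation direction.
* **Ageing score** — RBF-kernel SVM over `ln(intensity + 1)` of a fixed
  peptide panel; the score is the signed distance to the maximal-margin
  hyperplane; group contrasts by Mann–Whitney.
* **Synthetic cohorts** — a generator with programmed marker trends,
  internal standards, dilution, noise and dropout, so the whole pipeline is
  testable with known ground truth.

See the methods vignette (`vignettes/urinary-peptidome-ageing.Rmd`) for the
models, defaults and design decisions.

## Worked example

Reconstructing the published mouse–human ortholog panel from the packaged
sequence table:

```r
library(peptiage)

tab2 <- load_table2_orthologs()   # 55 printed pairs; collagens -1, UMOD +1
mouse <- unique(data.frame(peptide_id = tab2$mouse_id,
                           sequence = tab2$mouse_sequence,
                           gene_symbol = tab2$gene_symbol,
                           direction = tab2$direction))
human <- unique(data.frame(peptide_id = tab2$human_id,
                           sequence = tab2$human_sequence,
                           gene_symbol = tab2$gene_symbol,
                           direction = tab2$direction))
res <- map_orthologs(mouse, human)
res$summary[c("n_mouse", "n_human")]
#> $n_mouse
#> [1] 49
#>
#> $n_human
#> [1] 42
```

49 distinct mouse sequences are orthologous to 42 distinct human sequences
(the map is many-to-many).  An individual uromodulin pair shows the
one-substitution rule at work — an 8-residue window `IDQ[T/S]RVLN`:

```r
res$pairs[res$pairs$mouse_id == 6864 & res$pairs$human_id == 43605,
          c("mouse_sequence", "human_sequence", "rule",
            "overlap_length", "mismatches")]
#>     mouse_sequence human_sequence         rule overlap_length mismatches
#> 908      FIDQTRVLN SVIDQSRVLNLGPI one_mismatch              8          1
```

Screening a synthetic cohort (30 samples, 300 features, 18 programmed
markers) recovers the programmed trends:

```r
cfg <- simulation_config(n_samples_per_age_group = 5, n_features = 300,
                         n_negative_markers = 12, n_positive_markers = 6,
                         seed = 42)
coh <- generate_cohort(cfg)
scr <- run_age_screen(coh$tables, coh$samples, coh$standards)
head(scr$screen$significant[, c("feature_id", "rho", "p_adjusted",
                                "direction")], 4)
#>     feature_id        rho   p_adjusted direction
#> 207     F00207 -0.9504816 2.889670e-13        -1
#> 240     F00240 -0.9369516 3.908108e-12        -1
#> 274     F00274 -0.9144016 1.635057e-10        -1
#> 148     F00148 -0.8130171 2.393622e-06        -1
```

The most significant features are collagen-like markers with strongly
negative ρ; `match_features_to_truth()` links them back to the generator's
ground truth.  From there, `train_ageing_classifier()` /
`score_samples()` / `evaluate_age_groups()` build and assess the SVM
ageing score (see the vignette).

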