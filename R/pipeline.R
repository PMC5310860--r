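#' Run the preprocessing, clustering and age-screening pipeline
#'
#' Convenience wrapper tying the stages together for a set of per-sample
#' peak tables: normalise every sample against the internal-standard
#' definitions, cluster the normalised signals into cross-sample peptide
#' features, and screen every feature for Spearman correlation with age
#' (Benjamini-Hochberg adjusted).
#'
#' @param tables named list of [peak_table()]s (names are sample ids).
#' @param samples sample metadata ([sample_meta()]) aligned with `tables`.
#' @param standards internal-standard definitions (see
#'   [normalize_sample()]); `NULL` skips normalisation.
#' @param model a [tolerance_model()].
#' @param alpha significance threshold on the adjusted p-value.
#' @return list with `matrix` (the clustered [cohort_matrix()]),
#'   `normalization` (per-sample scale factors, or `NULL`), `screen`
#'   (the [correlate_with_age()] result).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(
#'   n_samples_per_age_group = 3, n_features = 60,
#'   n_negative_markers = 5, n_positive_markers = 3, seed = 7))
#' res <- run_age_screen(cohort$tables, cohort$samples, cohort$standards)
#' head(res$screen$significant)
run_age_screen <- function(tables, samples, standards = NULL,
                           model = tolerance_model(), alpha = 0.05) {
  normalization <- NULL
  if (!is.null(standards)) {
    norm <- normalize_cohort(tables, standards, model)
    tables <- norm$tables
    normalization <- norm$results
  }
  matrix <- cluster_samples(tables, model, samples = samples)
  screen <- correlate_with_age(matrix, alpha = alpha)
  list(matrix = matrix, normalization = normalization, screen = screen)
}
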