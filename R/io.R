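#' Construct a peak table
#'
#' A peak table holds one sample's deconvoluted CE-MS signals: molecular mass
#' in Daltons, (normalised) CE migration time in minutes and (normalised)
#' signal intensity.  Intensities of zero are legitimate and mean "not
#' detected"; masses and migration times must be strictly positive.
#'
#' @param mass_da numeric vector of molecular masses (Da), all > 0.
#' @param migration_min numeric vector of CE migration times (min), all > 0.
#' @param intensity numeric vector of signal intensities, all >= 0.
#' @return a `peak_table`, a data frame with columns `mass_da`,
#'   `migration_min`, `intensity`.
#' @export
#' @examples
#' peak_table(c(1000, 2000), c(20, 30), c(5, 0))
peak_table <- function(mass_da = numeric(), migration_min = numeric(),
                       intensity = numeric()) {
  x <- data.frame(mass_da = as.numeric(mass_da),
                  migration_min = as.numeric(migration_min),
                  intensity = as.numeric(intensity))
  validate_peak_table(x)
  class(x) <- c("peak_table", "data.frame")
  x
}

validate_peak_table <- function(x, where = "peak table") {
  bad <- which(!is.finite(x$mass_da) | x$mass_da <= 0)
  if (length(bad) > 0)
    pa_stop(sprintf("%s: non-positive or non-finite mass_da at row(s) %s",
                    where, paste(bad, collapse = ", ")),
            "peptiage_validation_error")
  bad <- which(!is.finite(x$migration_min) | x$migration_min <= 0)
  if (length(bad) > 0)
    pa_stop(sprintf("%s: non-positive or non-finite migration_min at row(s) %s",
                    where, paste(bad, collapse = ", ")),
            "peptiage_validation_error")
  bad <- which(!is.finite(x$intensity) | x$intensity < 0)
  if (length(bad) > 0)
    pa_stop(sprintf("%s: negative or non-finite intensity at row(s) %s",
                    where, paste(bad, collapse = ", ")),
            "peptiage_validation_error")
  invisible(x)
}

#' Read a peak table from a delimited text file
#'
#' The expected dialect is tab-separated UTF-8 with one header line.  Column
#' names are configurable through `columns` so externally produced peak lists
#' with different headers can be ingested without rewriting the file.
#'
#' @param path path to the file.
#' @param columns named character vector mapping the canonical roles
#'   `mass`, `time`, `intensity` to the column names present in the file.
#' @param sep field separator, tab by default.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path,
                            columns = c(mass = "mass_da",
                                        time = "migration_min",
                                        intensity = "intensity"),
                            sep = "\t") {
  pa_assert(file.exists(path), sprintf("file not found: %s", path),
            "peptiage_io_error")
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (role in c("mass", "time", "intensity")) {
    if (!columns[[role]] %in% names(raw))
      pa_stop(sprintf("missing column '%s' (role: %s) in %s",
                      columns[[role]], role, path),
              "peptiage_format_error")
  }
  x <- data.frame(mass_da = as.numeric(raw[[columns[["mass"]]]]),
                  migration_min = as.numeric(raw[[columns[["time"]]]]),
                  intensity = as.numeric(raw[[columns[["intensity"]]]]))
  validate_peak_table(x, where = path)
  class(x) <- c("peak_table", "data.frame")
  x
}

#' Write a peak table
#'
#' @param x a [peak_table()].
#' @param path output path (TSV).
#' @export
write_peak_table <- function(x, path) {
  validate_peak_table(x)
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param species `"mouse"` or `"human"`.
#' @param age positive numeric ages; the unit must be consistent within a
#'   cohort (weeks for mouse, years for human).
#' @param age_unit `"weeks"` or `"years"`.
#' @param genotype one of `"wild_type"`, `"terc_ko"`, `"healthy_human"`.
#' @return a data frame with one row per sample.
#' @export
sample_meta <- function(sample_id, species, age, age_unit,
                        genotype = "wild_type") {
  species <- match.arg(species, c("mouse", "human"))
  age_unit <- match.arg(age_unit, c("weeks", "years"))
  pa_assert(all(is.finite(age) & age > 0), "ages must be positive",
            "peptiage_validation_error")
  pa_assert(!anyDuplicated(sample_id), "duplicate sample_id",
            "peptiage_validation_error")
  genotype <- rep_len(genotype, length(sample_id))
  pa_assert(all(genotype %in% c("wild_type", "terc_ko", "healthy_human")),
            "unknown genotype", "peptiage_validation_error")
  data.frame(sample_id = as.character(sample_id), species = species,
             age = as.numeric(age), age_unit = age_unit, genotype = genotype,
             stringsAsFactors = FALSE)
}

#' Construct a cohort matrix
#'
#' A cohort matrix is the clustered, cross-sample view of a study: one row
#' per peptide feature, one column per sample.  A value of 0 means the
#' feature was not detected in that sample (never `NA`): the screening stage
#' correlates every feature across *all* samples without a detection
#' frequency threshold, which requires a defined value for non-detections.
#'
#' @param intensities numeric matrix, features x samples, non-negative.
#' @param features data frame with at least a `feature_id` column (typically
#'   also `consensus_mass`, `consensus_time`).
#' @param samples data frame of sample metadata (see [sample_meta()]).
#' @return an object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  pa_assert(is.data.frame(features) && "feature_id" %in% names(features),
            "features must be a data frame with a feature_id column",
            "peptiage_validation_error")
  pa_assert(nrow(intensities) == nrow(features),
            "row count of intensities must match features",
            "peptiage_validation_error")
  pa_assert(ncol(intensities) == nrow(samples),
            "column count of intensities must match samples",
            "peptiage_validation_error")
  pa_assert(all(is.finite(intensities)) && all(intensities >= 0),
            "intensities must be finite and non-negative",
            "peptiage_validation_error")
  pa_assert(!anyDuplicated(features$feature_id), "duplicate feature_id",
            "peptiage_validation_error")
  dimnames(intensities) <- list(features$feature_id, samples$sample_id)
  structure(list(intensities = intensities,
                 features = as.data.frame(features),
                 samples = as.data.frame(samples)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("cohort_matrix: %d features x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  if ("annotated" %in% names(x$features))
    cat(sprintf("  annotated features: %d\n", sum(x$features$annotated)))
  if (nrow(x$samples) > 0)
    cat(sprintf("  species: %s; age range: %g-%g %s\n",
                paste(unique(x$samples$species), collapse = ","),
                min(x$samples$age), max(x$samples$age),
                paste(unique(x$samples$age_unit), collapse = ",")))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$intensities)

#' Subset a cohort matrix
#'
#' @param x a [cohort_matrix()].
#' @param features logical/integer/character index into features.
#' @param samples logical/integer/character index into samples.
#' @return the subsetted `cohort_matrix`.
#' @export
subset_cohort <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$intensities)) else features
  if (is.character(fi)) fi <- match(fi, x$features$feature_id)
  si <- if (is.null(samples)) seq_len(ncol(x$intensities)) else samples
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  pa_assert(!anyNA(fi) && !anyNA(si), "unknown feature or sample id",
            "peptiage_validation_error")
  cohort_matrix(x$intensities[fi, si, drop = FALSE],
                x$features[fi, , drop = FALSE],
                x$samples[si, , drop = FALSE])
}

#' Write / read a cohort matrix
#'
#' The on-disk form is a TSV whose first column is the feature id and whose
#' remaining columns are sample ids, plus a companion metadata TSV
#' (`sample_id`, `species`, `age`, `age_unit`, `genotype`).  Zeros are
#' written as `0`, never as blanks, so non-detections survive a round trip.
#'
#' @param x a [cohort_matrix()].
#' @param path path for the intensity matrix TSV.
#' @param meta_path path for the sample metadata TSV; defaults to
#'   `<path>.meta.tsv`.
#' @return `write_cohort_matrix` returns `path` invisibly;
#'   `read_cohort_matrix` returns a `cohort_matrix`.
#' @export
write_cohort_matrix <- function(x, path, meta_path = paste0(path, ".meta.tsv")) {
  df <- data.frame(feature_id = x$features$feature_id,
                   x$intensities, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_matrix
#' @export
read_cohort_matrix <- function(path, meta_path = paste0(path, ".meta.tsv")) {
  pa_assert(file.exists(path), sprintf("file not found: %s", path),
            "peptiage_io_error")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  body <- readLines(path)[-1]
  if (length(body) > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header)))
      pa_stop(sprintf("%s: row(s) %s have %s fields, header has %d",
                      path,
                      paste(which(nf != length(header)), collapse = ", "),
                      paste(unique(nf[nf != length(header)]), collapse = "/"),
                      length(header)),
              "peptiage_format_error")
  }
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  pa_assert(file.exists(meta_path),
            sprintf("metadata file not found: %s", meta_path),
            "peptiage_io_error")
  meta <- read.delim(meta_path, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
  intens <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(intens) <- "double"
  cohort_matrix(intens,
                data.frame(feature_id = as.character(raw[[1]]),
                           stringsAsFactors = FALSE),
                meta)
}

#' Read a peptide annotation table
#'
#' Annotation tables carry sequenced peptides: the amino-acid sequence (with
#' the lowercase convention `p` = hydroxyproline, `m` = oxidised methionine,
#' `k` = hydroxylysine), protein name, gene symbol and start/stop residue
#' coordinates, and optionally the CE-MS coordinates (`mass_da`,
#' `migration_min`) used to attach annotations to clustered features.
#'
#' @param path TSV with columns `peptide_id`, `sequence`, `protein_name`,
#'   `gene_symbol`, `start_aa`, `stop_aa` (extra columns are kept).
#' @return a data frame.
#' @export
read_annotation_table <- function(path) {
  pa_assert(file.exists(path), sprintf("file not found: %s", path),
            "peptiage_io_error")
  x <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    pa_stop(sprintf("missing column(s) %s in %s",
                    paste(miss, collapse = ", "), path),
            "peptiage_format_error")
  invisible(lapply(x$sequence, normalize_sequence))  # alphabet check
  if (all(c("start_aa", "stop_aa") %in% names(x))) {
    bad <- which(!is.na(x$start_aa) & !is.na(x$stop_aa) &
                   x$stop_aa < x$start_aa)
    if (length(bad) > 0)
      pa_stop(sprintf("stop_aa < start_aa at row(s) %s",
                      paste(bad, collapse = ", ")),
              "peptiage_validation_error")
  }
  x
}

# checksum of the packaged ortholog fixture: sum of UTF-8 code points over
# the sequence columns, frozen at packaging time to catch silent corruption
TABLE2_CHECKSUM <- NULL  # computed lazily below

fixture_checksum <- function(x) {
  sum(vapply(c(x$mouse_sequence, x$human_sequence),
             function(s) sum(utf8ToInt(s)), numeric(1)))
}

#' Load the packaged mouse-human ortholog peptide fixture
#'
#' Returns the published table of ortholog urinary peptides identified in
#' mice and humans: one row per printed mouse-human pair, with the peptide
#' ids, the sequences exactly as printed (lowercase `p` = hydroxyproline;
#' lowercase `m`/`k` denote other modified residues) and the shared gene
#' symbol.  Collagen-gene peptides decrease with age in both species and
#' uromodulin (UMOD) peptides increase, so `direction` is filled in as -1
#' for collagen genes and +1 for UMOD.
#'
#' @return a data frame with columns `pair_id`, `mouse_id`,
#'   `mouse_sequence`, `human_id`, `human_sequence`, `gene_symbol`,
#'   `direction`.
#' @export
#' @examples
#' tab2 <- load_table2_orthologs()
#' length(unique(tab2$mouse_sequence))
load_table2_orthologs <- function() {
  path <- system.file("extdata", "table2_orthologs.tsv", package = "peptiage")
  pa_assert(nzchar(path), "packaged fixture table2_orthologs.tsv not found",
            "peptiage_packaging_error")
  x <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pa_assert(identical(names(x), c("pair_id", "mouse_id", "mouse_sequence",
                                  "human_id", "human_sequence",
                                  "gene_symbol")),
            "ortholog fixture has unexpected columns",
            "peptiage_packaging_error")
  if (fixture_checksum(x) != 187892)
    pa_stop("ortholog fixture checksum mismatch: packaged file corrupted",
            "peptiage_packaging_error")
  x$direction <- ifelse(x$gene_symbol == "UMOD", 1L, -1L)
  x
}

#' Load the packaged table of top age-correlated mouse peptides
#'
#' The published list of the twenty most strongly age-correlated urinary
#' peptides in wild-type mice: Spearman rho, Benjamini-Hochberg adjusted
#' p-value, sequence and protein annotation.  Negative-rho rows are fibrillar
#' collagen fragments; positive rows are dominated by kidney
#' androgen-regulated protein fragments.  Start/stop coordinates are stored
#' verbatim as printed (a few rows are internally inconsistent with the
#' sequence length; they are not reconciled here).
#'
#' @return a data frame with columns `rho`, `adjusted_p`, `sequence`,
#'   `protein_name`, `start_aa`, `stop_aa`.
#' @export
load_table1_markers <- function() {
  path <- system.file("extdata", "table1_top_age_correlated.tsv",
                      package = "peptiage")
  pa_assert(nzchar(path), "packaged fixture table1_top_age_correlated.tsv not found",
            "peptiage_packaging_error")
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
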