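test_that("peak tables round-trip through TSV, including zeros and empties", {
  tb <- peak_table(c(1000.5, 2500.25, 19999.9), c(19.5, 35.0, 49.9),
                   c(120.5, 0, 3.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(tb, path)
  back <- read_peak_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tb))
  expect_identical(back$intensity[2], 0)

  writeLines("mass_da\tmigration_min\tintensity", path)
  empty <- read_peak_table(path)
  expect_s3_class(empty, "peak_table")
  expect_identical(nrow(empty), 0L)

  for (seed in 1:5) {
    tb <- random_peak_table(25, seed)
    write_peak_table(tb, path)
    expect_equal(as.data.frame(read_peak_table(path)), as.data.frame(tb),
                 tolerance = 1e-12)
  }
})

test_that("malformed peak tables are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mass_da\tmigration_min\tintensity",
               "1000\t20\t5", "-5\t21\t3"), path)
  expect_error(read_peak_table(path), "row\\(s\\) 2",
               class = "peptiage_validation_error")

  writeLines(c("mass\tmigration_min\tintensity", "1000\t20\t5"), path)
  expect_error(read_peak_table(path), "mass_da",
               class = "peptiage_format_error")

  expect_error(peak_table(1000, 20, -1), class = "peptiage_validation_error")
  expect_error(peak_table(1000, -20, 1), class = "peptiage_validation_error")
})

test_that("cohort matrices round-trip with zeros preserved", {
  meta <- sample_meta(c("A", "B"), "mouse", c(4, 96), "weeks")
  m <- cohort_matrix(matrix(c(1.5, 0, 2.25, 3), 2, 2),
                     data.frame(feature_id = c("F1", "F2")), meta)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_matrix(m, path)
  back <- read_cohort_matrix(path)
  expect_equal(back$intensities, m$intensities)
  expect_identical(unname(back$intensities[2, 1]), 0)
  expect_equal(back$samples$age, c(4, 96))
  expect_identical(back$features$feature_id, c("F1", "F2"))
})

test_that("a ragged cohort matrix file is a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tA\tB", "F1\t1\t2", "F2\t1"), path)
  meta_path <- paste0(path, ".meta.tsv")
  writeLines(c("sample_id\tage", "A\t4", "B\t96"), meta_path)
  expect_error(read_cohort_matrix(path), class = "peptiage_format_error")
})

test_that("cohort matrix construction enforces shape and sign invariants", {
  meta <- sample_meta(c("A", "B"), "mouse", c(4, 96), "weeks")
  expect_error(cohort_matrix(matrix(1, 2, 2),
                             data.frame(feature_id = "F1"), meta),
               class = "peptiage_validation_error")
  expect_error(cohort_matrix(matrix(-1, 1, 2),
                             data.frame(feature_id = "F1"), meta),
               class = "peptiage_validation_error")
})

test_that("the ortholog fixture matches the published table", {
  tab2 <- load_table2_orthologs()
  expect_identical(nrow(tab2), 55L)

  r6864 <- tab2[tab2$mouse_id == 6864, ]
  expect_identical(r6864$mouse_sequence, "FIDQTRVLN")
  expect_identical(r6864$gene_symbol, "UMOD")

  r7545 <- tab2[tab2$mouse_id == 7545, ]
  expect_identical(unique(r7545$mouse_sequence), "AGPpGPTGPTGPp")
  expect_identical(unique(r7545$gene_symbol), "COL1A1")

  expect_setequal(unique(tab2$gene_symbol),
                  c("COL1A1", "COL3A1", "COL1A2", "COL5A2", "UMOD"))

  # unique sequence counts per species as reported for the ortholog panel
  expect_identical(length(unique(tab2$mouse_sequence)), 49L)
  expect_identical(length(unique(tab2$human_sequence)), 42L)
  # ids and printed sequences are in bijection
  expect_identical(length(unique(tab2$mouse_id)), 49L)
  expect_identical(length(unique(tab2$human_id)), 42L)

  # directions: collagens fall with age, uromodulin rises
  expect_true(all(tab2$direction[tab2$gene_symbol == "UMOD"] == 1L))
  expect_true(all(tab2$direction[tab2$gene_symbol != "UMOD"] == -1L))
})

test_that("the top-marker fixture carries the published extremes", {
  tab1 <- load_table1_markers()
  expect_identical(nrow(tab1), 20L)
  expect_equal(min(tab1$rho), -0.787)
  expect_equal(max(tab1$rho), 0.717)
  expect_identical(tab1$sequence[which.min(tab1$rho)],
                   "GSPGAKGEVGpAGSPGSNGSPGQRGEpGpQ")
  expect_identical(tab1$protein_name[which.max(tab1$rho)],
                   "E3 ubiquitin-protein ligase HERC2")
  # every printed sequence parses under the modified-residue alphabet
  expect_silent(lapply(tab1$sequence, normalize_sequence))
})

test_that("annotation tables validate coordinates and alphabet", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tsequence\tstart_aa\tstop_aa",
               "1\tGRpGER\t10\t5"), path)
  expect_error(read_annotation_table(path),
               class = "peptiage_validation_error")
  writeLines(c("peptide_id\tsequence", "1\tGR3GER"), path)
  expect_error(read_annotation_table(path), class = "peptiage_alphabet_error")
  writeLines(c("peptide_id\tsequence", "1\tGRpGER"), path)
  expect_identical(read_annotation_table(path)$sequence, "GRpGER")
})
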