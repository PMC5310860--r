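test_that("sequence normalisation folds modified residues and records positions", {
  ns <- normalize_sequence("GRpGERGPpGP")
  expect_identical(ns$canonical, "GRPGERGPPGP")
  expect_identical(ns$modification_positions, c(3L, 9L))
  expect_identical(normalize_sequence("AAAA")$modification_positions,
                   integer(0))
  expect_identical(normalize_sequence("GPPGkNGDDGEAGKPG")$canonical,
                   "GPPGKNGDDGEAGKPG")
  err <- tryCatch(normalize_sequence("GRxGER"), error = identity)
  expect_s3_class(err, "peptiage_alphabet_error")
  expect_match(conditionMessage(err), "position 3")
})

test_that("best_ungapped_overlap reproduces the published worked alignments", {
  # uromodulin pair: IDQ[T/S]RVLN, one internal substitution
  r <- best_ungapped_overlap("FIDQTRVLN", "SVIDQSRVLNLGPI")
  expect_identical(r$overlap_length, 8L)
  expect_identical(r$mismatches, 1L)

  # collagen pair: AGPpGPTGP[T/A]GPp across the full 13-mer
  r2 <- best_ungapped_overlap("AGPpGPTGPTGPp",
                              "ARGNDGATGAAGPpGPTGPAGppGFpGAVGAKGEAGPQGPRG")
  expect_identical(r2$overlap_length, 13L)
  expect_identical(r2$mismatches, 1L)

  # identical strings: full-length exact overlap at offset 0
  r3 <- best_ungapped_overlap("GRPGERGPPGP", "GRpGERGPpGP")
  expect_identical(r3$overlap_length, 11L)
  expect_identical(r3$mismatches, 0L)
  expect_identical(r3$offset, 0L)

  # mismatches at window edges are trimmed, not counted
  r4 <- best_ungapped_overlap("WAAAAAA", "YAAAAAA")
  expect_identical(r4$overlap_length, 6L)
  expect_identical(r4$mismatches, 0L)

  # with zero allowed mismatches the window stops at the substitution
  r5 <- best_ungapped_overlap("FIDQTRVLN", "SVIDQSRVLNLGPI",
                              max_mismatches = 0)
  expect_identical(r5$overlap_length, 4L)  # RVLN
  expect_identical(r5$mismatches, 0L)
})

test_that("best_ungapped_overlap equals exhaustive enumeration on short pairs", {
  set.seed(71)
  alpha <- c("G", "P", "A", "K", "E", "R")
  for (i in 1:60) {
    a <- paste(sample(alpha, sample(3:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(3:12, 1), replace = TRUE), collapse = "")
    for (k in 0:1) {
      got <- best_ungapped_overlap(a, b, max_mismatches = k)
      want <- overlap_oracle(a, b, k = k)
      expect_identical(got$overlap_length, want$overlap_length,
                       info = sprintf("a=%s b=%s k=%d", a, b, k))
      expect_identical(got$mismatches, want$mismatches,
                       info = sprintf("a=%s b=%s k=%d", a, b, k))
    }
  }
})

test_that("is_ortholog applies the three sequence rules plus direction agreement", {
  # rule i: identical up to modification state
  v <- is_ortholog("GRpGERGPpGP", "GRPGERGPPGP", -1, -1)
  expect_true(v$ortholog)
  expect_identical(v$pair$rule, "identical")

  # rule ii: same-region exact overlap of >= 6
  v2 <- is_ortholog("GRpGERGPpGP", "KNGDDGEAGKpGRpGERGPPGpQ", -1, -1,
                    mouse_gene = "COL1A1", human_gene = "COL1A1")
  expect_true(v2$ortholog)
  expect_identical(v2$pair$rule, "region_overlap")
  expect_identical(v2$pair$overlap_length, 11L)

  # rule iii: one internal substitution
  v3 <- is_ortholog("FIDQTRVLN", "SVIDQSRVLNLGPI", 1, 1)
  expect_true(v3$ortholog)
  expect_identical(v3$pair$rule, "one_mismatch")

  # opposite correlation directions veto everything, even identity
  expect_false(is_ortholog("AAAAAA", "AAAAAA", 1, -1)$ortholog)

  # unrelated sequences
  expect_false(is_ortholog("AAAAAA", "CCCCCC", 1, 1)$ortholog)

  # overlap below the 6-residue minimum
  expect_false(is_ortholog("GPGPA", "KKGPGPAKK", -1, -1)$ortholog)

  # gene-family disagreement blocks the same-region rule
  v4 <- is_ortholog("GRpGERGPpGP", "KNGDDGEAGKpGRpGERGPPGpQ", -1, -1,
                    mouse_gene = "COL1A1", human_gene = "UMOD")
  expect_false(v4$ortholog)
  # ... but collagen family members agree across chain symbols
  v5 <- is_ortholog("GRpGERGPpGP", "KNGDDGEAGKpGRpGERGPPGpQ", -1, -1,
                    mouse_gene = "COL1A1", human_gene = "COL1A2")
  expect_true(v5$ortholog)
})

test_that("is_ortholog is symmetric in its two peptides", {
  set.seed(72)
  alpha <- c("G", "P", "A", "K", "E", "R", "S", "T")
  for (i in 1:40) {
    a <- paste(sample(alpha, sample(4:14, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(4:14, 1), replace = TRUE), collapse = "")
    d <- sample(c(-1, 1), 2, replace = TRUE)
    ab <- is_ortholog(a, b, d[1], d[2])
    ba <- is_ortholog(b, a, d[2], d[1])
    expect_identical(ab$ortholog, ba$ortholog)
    if (ab$ortholog) {
      expect_identical(ab$pair$rule, ba$pair$rule)
      expect_identical(ab$pair$overlap_length, ba$pair$overlap_length)
    }
  }
})

test_that("identical sequences of length >= 6 also satisfy the overlap criterion", {
  set.seed(73)
  for (i in 1:20) {
    s <- paste(sample(c("G", "P", "A", "K"), sample(6:15, 1), replace = TRUE),
               collapse = "")
    r <- best_ungapped_overlap(s, s, max_mismatches = 0)
    expect_gte(r$overlap_length, 6L)
    expect_identical(r$mismatches, 0L)
  }
})

test_that("the published ortholog table is fully reproduced", {
  tab2 <- load_table2_orthologs()
  mouse <- unique(data.frame(peptide_id = tab2$mouse_id,
                             sequence = tab2$mouse_sequence,
                             gene_symbol = tab2$gene_symbol,
                             direction = tab2$direction,
                             stringsAsFactors = FALSE))
  human <- unique(data.frame(peptide_id = tab2$human_id,
                             sequence = tab2$human_sequence,
                             gene_symbol = tab2$gene_symbol,
                             direction = tab2$direction,
                             stringsAsFactors = FALSE))
  res <- map_orthologs(mouse, human)

  # every printed pair is individually accepted
  accepted <- paste(res$pairs$mouse_id, res$pairs$human_id)
  printed <- paste(tab2$mouse_id, tab2$human_id)
  expect_true(all(printed %in% accepted))

  # published panel sizes: 49 mouse orthologs map to 42 human orthologs
  expect_identical(res$summary$n_mouse, 49L)
  expect_identical(res$summary$n_human, 42L)

  # 44 collagen-gene and 5 uromodulin mouse ortholog peptides
  pg <- res$summary$per_gene_mouse
  expect_identical(unname(pg["UMOD"]), 5L)
  expect_identical(sum(pg[grepl("^COL", names(pg))]), 44L)
})

test_that("map_orthologs handles empty inputs", {
  mouse <- data.frame(sequence = "GPGPAG", direction = -1)
  human <- data.frame(sequence = character(0), direction = numeric(0))
  res <- map_orthologs(mouse, human)
  expect_identical(res$summary$n_pairs, 0L)
  expect_identical(res$summary$n_mouse, 0L)
  expect_identical(nrow(res$pairs), 0L)
})
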