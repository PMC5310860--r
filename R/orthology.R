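# sequence alphabet: 20 amino acids, uppercase; lowercase p (hydroxyproline),
# m (oxidised methionine) and k (hydroxylysine) mark modified residues
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
MOD_LOWER <- c("p", "m", "k")

#' Normalise a peptide sequence for cross-species comparison
#'
#' Folds the lowercase modified-residue convention (`p` = hydroxyproline,
#' `m` = oxidised methionine, `k` = hydroxylysine) onto the parent residue:
#' hydroxylation and oxidation states never count as sequence differences
#' when comparing peptides between species.
#'
#' @param seq a peptide string over the 20 amino acids, with `p`/`m`/`k`
#'   admitted in lowercase.
#' @return a list of class `normalized_sequence` with elements `canonical`
#'   (all-uppercase string), `original`, and `modification_positions`
#'   (1-based indices of folded residues).
#' @export
#' @examples
#' normalize_sequence("GRpGERGPpGP")$canonical
normalize_sequence <- function(seq) {
  pa_assert(is.character(seq) && length(seq) == 1 && nzchar(seq),
            "sequence must be a single non-empty string",
            "peptiage_validation_error")
  chars <- strsplit(seq, "")[[1]]
  ok <- chars %in% AA20 | chars %in% MOD_LOWER
  if (!all(ok))
    pa_stop(sprintf("invalid character '%s' at position %d in sequence '%s'",
                    chars[which(!ok)[1]], which(!ok)[1], seq),
            "peptiage_alphabet_error")
  structure(list(canonical = toupper(seq),
                 original = seq,
                 modification_positions = which(chars %in% MOD_LOWER)),
            class = "normalized_sequence")
}

as_canonical <- function(x) {
  if (inherits(x, "normalized_sequence")) x$canonical
  else normalize_sequence(x)$canonical
}

#' Best ungapped overlap between two peptide sequences
#'
#' Scans all ungapped relative offsets of `a` against `b` and returns the
#' longest contiguous aligned window containing at most `max_mismatches`
#' substitutions, where every mismatch must be internal: a window either
#' consists purely of matches, or starts and ends with a match and contains
#' isolated single-position mismatches each flanked by matches.  Mismatches
#' at window edges are trimmed away rather than counted.  Ties are broken by
#' fewer mismatches, then by smaller absolute offset.
#'
#' Modified residues are folded to their parent amino acid before comparison
#' (see [normalize_sequence()]), so a hydroxyproline aligned with a proline
#' is a match.
#'
#' @param a,b peptide strings or [normalize_sequence()] results.
#' @param max_mismatches maximum number of internal substitutions allowed in
#'   the window (default 1).
#' @return list with `overlap_length` (window length, mismatch positions
#'   included), `mismatches`, and `offset` (start of `a` minus start of `b`
#'   in the alignment; 0 when the sequences start together).
#' @export
#' @examples
#' best_ungapped_overlap("FIDQTRVLN", "SVIDQSRVLNLGPI")  # length 8, 1 mismatch
best_ungapped_overlap <- function(a, b, max_mismatches = 1) {
  ca <- strsplit(as_canonical(a), "")[[1]]
  cb <- strsplit(as_canonical(b), "")[[1]]
  prof <- overlap_profile(ca, cb, max_mismatches)
  if (max_mismatches == 0) prof$best0 else prof$bestk
}

# single scan over all ungapped offsets, tracking both the best pure-match
# window (best0) and the best window with at most kmax internal single
# mismatches (bestk); ties: longer, then fewer mismatches, then |offset|
overlap_profile <- function(ca, cb, kmax) {
  na <- length(ca); nb <- length(cb)
  best0 <- list(overlap_length = 0L, mismatches = 0L, offset = 0L)
  bestk <- list(overlap_length = 0L, mismatches = 0L, offset = 0L)
  better <- function(len, mm, off, cur) {
    len > cur$overlap_length ||
      (len == cur$overlap_length && len > 0 &&
         (mm < cur$mismatches ||
            (mm == cur$mismatches && abs(off) < abs(cur$offset))))
  }
  for (off in seq(-(nb - 1L), na - 1L)) {
    # a[i] aligns with b[i - off]
    i1 <- max(1L, off + 1L); i2 <- min(na, nb + off)
    if (i2 < i1) next
    m <- ca[i1:i2] == cb[(i1:i2) - off]
    cand <- best_window(m, kmax)
    if (better(cand$len0, 0L, off, best0))
      best0 <- list(overlap_length = cand$len0, mismatches = 0L, offset = off)
    if (better(cand$len, cand$mm, off, bestk))
      bestk <- list(overlap_length = cand$len, mismatches = cand$mm,
                    offset = off)
  }
  list(best0 = best0, bestk = bestk)
}

# longest window in a logical match vector made of match-runs joined by
# isolated single mismatches, using at most k mismatches; also reports the
# longest pure match run (len0)
best_window <- function(m, k) {
  r <- rle(m)
  lens <- r$lengths; vals <- r$values
  ti <- which(vals)            # indices of match runs
  if (length(ti) == 0) return(list(len = 0L, mm = 0L, len0 = 0L))
  len0 <- max(lens[ti])
  best_len <- len0; best_mm <- 0L
  if (k > 0) {
    for (s in seq_along(ti)) {
      len <- lens[ti[s]]; mm <- 0L
      e <- s
      while (e < length(ti) && mm < k &&
             ti[e + 1L] == ti[e] + 2L && lens[ti[e] + 1L] == 1L) {
        # next match run is separated by exactly one mismatch position
        e <- e + 1L
        mm <- mm + 1L
        len <- len + 1L + lens[ti[e]]
        if (len > best_len || (len == best_len && mm < best_mm)) {
          best_len <- len; best_mm <- mm
        }
      }
    }
  }
  list(len = best_len, mm = best_mm, len0 = len0)
}

gene_family <- function(symbol) {
  # "COL1A1", "COL3A1" etc. collapse to the family stem "COL"; "UMOD" stays
  sub("[0-9].*$", "", toupper(symbol))
}

#' Decide orthology between a mouse and a human peptide
#'
#' Two age-correlated peptides from different species are orthologs when
#' (i) their folded sequences are identical, (ii) they derive from the same
#' protein region with an ungapped overlap of at least `min_overlap` amino
#' acids, or (iii) they overlap by at least `min_overlap` amino acids with a
#' single internal amino-acid substitution -- and, in every case, the two
#' peptides correlate with age in the same direction.  When both records
#' carry gene symbols, the same-region rule additionally requires the
#' symbols to map to the same gene family.
#'
#' @param mouse_seq,human_seq peptide strings (lowercase modified-residue
#'   convention admitted).
#' @param direction_mouse,direction_human age-correlation direction signs
#'   (+1 or -1) of the two peptides.
#' @param mouse_gene,human_gene optional gene symbols.
#' @param min_overlap minimum overlap length in amino acids (inclusive;
#'   default 6).
#' @param max_mismatch maximum internal substitutions for rule (iii);
#'   default 1.
#' @return list with `ortholog` (logical) and, when `TRUE`, `pair`: a list
#'   holding `rule` (`"identical"`, `"region_overlap"` or `"one_mismatch"`),
#'   `overlap_length`, `mismatches` and `direction`.
#' @export
is_ortholog <- function(mouse_seq, human_seq,
                        direction_mouse, direction_human,
                        mouse_gene = NULL, human_gene = NULL,
                        min_overlap = 6, max_mismatch = 1) {
  no <- list(ortholog = FALSE, pair = NULL)
  if (is.na(direction_mouse) || is.na(direction_human) ||
      direction_mouse == 0 || direction_human == 0 ||
      sign(direction_mouse) != sign(direction_human))
    return(no)
  ms <- normalize_sequence(if (inherits(mouse_seq, "normalized_sequence"))
    mouse_seq$original else mouse_seq)
  hs <- normalize_sequence(if (inherits(human_seq, "normalized_sequence"))
    human_seq$original else human_seq)
  direction <- sign(direction_mouse)
  if (ms$canonical == hs$canonical) {
    return(list(ortholog = TRUE,
                pair = list(rule = "identical",
                            overlap_length = nchar(ms$canonical),
                            mismatches = 0L, direction = direction)))
  }
  genes_known <- !is.null(mouse_gene) && !is.null(human_gene) &&
    !is.na(mouse_gene) && !is.na(human_gene)
  prof <- overlap_profile(strsplit(ms$canonical, "")[[1]],
                          strsplit(hs$canonical, "")[[1]],
                          max_mismatch)
  exact <- prof$best0
  if (exact$overlap_length >= min_overlap &&
      (!genes_known || gene_family(mouse_gene) == gene_family(human_gene))) {
    return(list(ortholog = TRUE,
                pair = list(rule = "region_overlap",
                            overlap_length = exact$overlap_length,
                            mismatches = 0L, direction = direction)))
  }
  if (max_mismatch >= 1) {
    sub1 <- prof$bestk
    if (sub1$overlap_length >= min_overlap && sub1$mismatches >= 1) {
      return(list(ortholog = TRUE,
                  pair = list(rule = "one_mismatch",
                              overlap_length = sub1$overlap_length,
                              mismatches = sub1$mismatches,
                              direction = direction)))
    }
  }
  no
}

#' Map orthologs between mouse and human peptide lists
#'
#' Evaluates [is_ortholog()] on every cross-species pair and tabulates the
#' many-to-many ortholog map: one mouse peptide may have several human
#' orthologs and vice versa, so no uniqueness constraint is applied.  The
#' summary counts distinct sequences participating in at least one accepted
#' pair, per species and per gene symbol.
#'
#' @param mouse,human data frames with columns `sequence` and `direction`,
#'   and optionally `peptide_id` and `gene_symbol`.
#' @param min_overlap,max_mismatch see [is_ortholog()].
#' @return list with `pairs` (data frame: ids, sequences, genes, rule,
#'   overlap statistics, direction) and `summary` (list: `n_pairs`,
#'   `n_mouse`, `n_human`, `per_gene_mouse`, `per_gene_human`).
#' @export
#' @examples
#' tab2 <- load_table2_orthologs()
#' mouse <- unique(data.frame(peptide_id = tab2$mouse_id,
#'                            sequence = tab2$mouse_sequence,
#'                            gene_symbol = tab2$gene_symbol,
#'                            direction = tab2$direction))
#' human <- unique(data.frame(peptide_id = tab2$human_id,
#'                            sequence = tab2$human_sequence,
#'                            gene_symbol = tab2$gene_symbol,
#'                            direction = tab2$direction))
#' res <- map_orthologs(mouse, human)
#' res$summary$n_mouse  # 49
map_orthologs <- function(mouse, human, min_overlap = 6, max_mismatch = 1) {
  for (nm in c("sequence", "direction")) {
    pa_assert(nm %in% names(mouse) && nm %in% names(human),
              sprintf("mouse and human tables need a '%s' column", nm),
              "peptiage_format_error")
  }
  mg <- if ("gene_symbol" %in% names(mouse)) mouse$gene_symbol else
    rep(NA_character_, nrow(mouse))
  hg <- if ("gene_symbol" %in% names(human)) human$gene_symbol else
    rep(NA_character_, nrow(human))
  mid <- if ("peptide_id" %in% names(mouse)) mouse$peptide_id else
    seq_len(nrow(mouse))
  hid <- if ("peptide_id" %in% names(human)) human$peptide_id else
    seq_len(nrow(human))

  rows <- vector("list", 0L)
  for (i in seq_len(nrow(mouse))) {
    for (j in seq_len(nrow(human))) {
      v <- is_ortholog(mouse$sequence[i], human$sequence[j],
                       mouse$direction[i], human$direction[j],
                       mouse_gene = mg[i], human_gene = hg[j],
                       min_overlap = min_overlap,
                       max_mismatch = max_mismatch)
      if (v$ortholog) {
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = mid[i], mouse_sequence = mouse$sequence[i],
          mouse_gene = mg[i],
          human_id = hid[j], human_sequence = human$sequence[j],
          human_gene = hg[j],
          rule = v$pair$rule,
          overlap_length = v$pair$overlap_length,
          mismatches = v$pair$mismatches,
          direction = v$pair$direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mouse_id = character(0), mouse_sequence = character(0),
               mouse_gene = character(0), human_id = character(0),
               human_sequence = character(0), human_gene = character(0),
               rule = character(0), overlap_length = integer(0),
               mismatches = integer(0), direction = integer(0))
  per_gene <- function(seqs, genes) {
    if (length(seqs) == 0) return(integer(0))
    tab <- tapply(seqs, genes, function(s) length(unique(s)))
    setNames(as.integer(tab), names(tab))
  }
  list(pairs = pairs,
       summary = list(
         n_pairs = nrow(pairs),
         n_mouse = length(unique(pairs$mouse_sequence)),
         n_human = length(unique(pairs$human_sequence)),
         per_gene_mouse = per_gene(pairs$mouse_sequence, pairs$mouse_gene),
         per_gene_human = per_gene(pairs$human_sequence, pairs$human_gene)))
}
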