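#' Tolerance model for cross-sample peptide matching
#'
#' Two signals in different samples are considered the same peptide when
#' their masses agree within a ppm tolerance (50 ppm below the small-peptide
#' threshold of 4,000 Da, 75 ppm at or above it) and their CE migration
#' times agree within a half-window that widens linearly from +/- 1 min at
#' 19 min to +/- 2.5 min at 50 min (clamped outside that range).  The linear
#' form between the two anchors is the simplest curve through both printed
#' points; tolerances are applied inclusively (<=).
#'
#' @param ppm_small ppm tolerance for peptides below `mass_threshold`.
#' @param ppm_large ppm tolerance for peptides at/above `mass_threshold`.
#' @param mass_threshold mass (Da) at which the ppm tolerance switches; the
#'   small-peptide tolerance applies strictly below this value.
#' @param time_anchors data frame with columns `time` (min) and
#'   `half_window` (min), strictly increasing in `time`, non-decreasing in
#'   `half_window`.
#' @return an object of class `tolerance_model`.
#' @export
#' @examples
#' tm <- tolerance_model()
#' mass_tolerance_da(c(1000, 3999, 4000), tm)
#' time_half_window(c(19, 34.5, 50), tm)
tolerance_model <- function(ppm_small = 50, ppm_large = 75,
                            mass_threshold = 4000,
                            time_anchors = data.frame(
                              time = c(19, 50),
                              half_window = c(1.0, 2.5))) {
  pa_assert(ppm_small > 0 && ppm_large > 0 && mass_threshold > 0,
            "tolerances must be positive", "peptiage_config_error")
  pa_assert(nrow(time_anchors) >= 2 &&
              all(diff(time_anchors$time) > 0) &&
              all(diff(time_anchors$half_window) >= 0) &&
              all(time_anchors$half_window > 0),
            "time anchors must be strictly increasing with positive, non-decreasing half-windows",
            "peptiage_config_error")
  structure(list(ppm_small = ppm_small, ppm_large = ppm_large,
                 mass_threshold = mass_threshold,
                 time_anchors = time_anchors),
            class = "tolerance_model")
}

#' Mass tolerance in Daltons at a given mass
#'
#' @param mass numeric vector of masses (Da), > 0.
#' @param model a [tolerance_model()].
#' @return numeric vector: `mass * ppm / 1e6`, with the small-peptide ppm
#'   for masses strictly below the threshold.
#' @export
mass_tolerance_da <- function(mass, model = tolerance_model()) {
  pa_assert(all(mass > 0), "mass must be positive", "peptiage_validation_error")
  ppm <- ifelse(mass < model$mass_threshold, model$ppm_small, model$ppm_large)
  mass * ppm * 1e-6
}

#' Migration-time half-window at a given time
#'
#' Piecewise-linear interpolation between the model's anchors, clamped to
#' the boundary half-windows outside the anchored range.
#'
#' @param time numeric vector of migration times (min), > 0.
#' @param model a [tolerance_model()].
#' @return numeric vector of half-window widths (min).
#' @export
time_half_window <- function(time, model = tolerance_model()) {
  pa_assert(all(time > 0), "time must be positive", "peptiage_validation_error")
  a <- model$time_anchors
  approx(a$time, a$half_window, xout = time, rule = 2)$y
}

#' Cluster peak tables across samples into peptide features
#'
#' Greedy agglomeration with a canonical sort: all peaks are pooled, sorted
#' by (mass, time, intensity, sample), and each peak joins the existing
#' feature whose running consensus lies within the mass and time windows --
#' provided the feature has no member from the same sample yet.  Ties are
#' broken by smallest mass distance, then smallest time distance, then
#' earliest-created feature.  The consensus (mass, time) is the
#' intensity-weighted running mean of member coordinates.  Because of the
#' canonical sort, the result does not depend on the order in which samples
#' are supplied.
#'
#' @param tables named list of [peak_table()] objects; names are sample ids.
#' @param model a [tolerance_model()].
#' @param samples optional sample metadata data frame ([sample_meta()]);
#'   defaults to a minimal frame with unknown ages.
#' @return a [cohort_matrix()] with one row per feature; undetected
#'   feature/sample combinations are 0.  The feature table carries
#'   `consensus_mass`, `consensus_time` and `n_members`.
#' @export
cluster_samples <- function(tables, model = tolerance_model(),
                            samples = NULL) {
  pa_assert(length(tables) > 0, "no peak tables supplied",
            "peptiage_validation_error")
  ids <- names(tables)
  pa_assert(!is.null(ids) && all(nzchar(ids)),
            "tables must be a named list (names are sample ids)",
            "peptiage_validation_error")
  if (anyDuplicated(ids))
    pa_stop("duplicate sample_id across peak tables", "peptiage_validation_error")
  for (tb in tables) validate_peak_table(tb)

  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    if (nrow(tb) == 0) return(NULL)
    data.frame(sample = i, mass = tb$mass_da, time = tb$migration_min,
               intensity = tb$intensity)
  }))

  n_samp <- length(tables)
  if (is.null(pooled) || nrow(pooled) == 0) {
    feats <- data.frame(feature_id = character(0),
                        consensus_mass = numeric(0),
                        consensus_time = numeric(0),
                        n_members = integer(0))
    meta <- samples %||% data.frame(sample_id = ids,
                                    stringsAsFactors = FALSE)
    return(cohort_matrix(matrix(0, 0, n_samp), feats, meta))
  }

  ord <- order(pooled$mass, pooled$time, pooled$intensity, ids[pooled$sample])
  pooled <- pooled[ord, ]

  # blocks of peaks that cannot possibly share a feature: consecutive sorted
  # masses further apart than the (larger) local tolerance can never fall in
  # the same window, so each block is clustered independently
  n <- nrow(pooled)
  gap_tol <- mass_tolerance_da(pooled$mass[-1], model)
  block <- cumsum(c(TRUE, diff(pooled$mass) > gap_tol))

  cons_mass <- numeric(0); cons_time <- numeric(0)
  cons_wt <- numeric(0); cons_n <- integer(0)
  members <- list()   # per feature: integer sample indices
  intens <- list()    # per feature: member intensities (aligned with members)

  for (b in split(seq_len(n), block)) {
    first_feat <- length(cons_mass) + 1L
    for (i in b) {
      m <- pooled$mass[i]; t <- pooled$time[i]; w <- pooled$intensity[i]
      s <- pooled$sample[i]
      cand <- seq.int(first_feat, length.out = length(cons_mass) - first_feat + 1L)
      assigned <- 0L
      if (length(cand) > 0) {
        dm <- abs(m - cons_mass[cand])
        dt <- abs(t - cons_time[cand])
        ok <- dm <= mass_tolerance_da(cons_mass[cand], model) &
          dt <= time_half_window(cons_time[cand], model)
        if (any(ok)) {
          # exclude features already holding a peak from this sample
          ok[ok] <- vapply(cand[ok], function(f) !(s %in% members[[f]]),
                           logical(1))
        }
        if (any(ok)) {
          sel <- cand[ok]
          o <- order(dm[ok], dt[ok], sel)
          assigned <- sel[o[1]]
        }
      }
      if (assigned == 0L) {
        cons_mass <- c(cons_mass, m); cons_time <- c(cons_time, t)
        cons_wt <- c(cons_wt, w); cons_n <- c(cons_n, 1L)
        members[[length(cons_mass)]] <- s
        intens[[length(cons_mass)]] <- w
      } else {
        f <- assigned
        tot <- cons_wt[f] + w
        if (tot > 0) {
          cons_mass[f] <- (cons_mass[f] * cons_wt[f] + m * w) / tot
          cons_time[f] <- (cons_time[f] * cons_wt[f] + t * w) / tot
        } else {
          # all member intensities zero: fall back to unweighted mean
          cons_mass[f] <- (cons_mass[f] * cons_n[f] + m) / (cons_n[f] + 1L)
          cons_time[f] <- (cons_time[f] * cons_n[f] + t) / (cons_n[f] + 1L)
        }
        cons_wt[f] <- tot
        cons_n[f] <- cons_n[f] + 1L
        members[[f]] <- c(members[[f]], s)
        intens[[f]] <- c(intens[[f]], w)
      }
    }
  }

  nf <- length(cons_mass)
  # canonical feature order and ids: by consensus coordinates, so the output
  # is invariant to input sample order up to nothing at all
  ford <- order(cons_mass, cons_time)
  X <- matrix(0, nrow = nf, ncol = n_samp)
  for (k in seq_len(nf)) {
    f <- ford[k]
    X[k, members[[f]]] <- intens[[f]]
  }
  feats <- data.frame(
    feature_id = sprintf("F%05d", seq_len(nf)),
    consensus_mass = cons_mass[ford],
    consensus_time = cons_time[ford],
    n_members = cons_n[ford],
    stringsAsFactors = FALSE)
  meta <- samples %||% data.frame(sample_id = ids, stringsAsFactors = FALSE)
  pa_assert(identical(as.character(meta$sample_id), as.character(ids)),
            "sample metadata must match peak-table names (same ids, same order)",
            "peptiage_validation_error")
  cohort_matrix(X, feats, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach sequence annotations to clustered features
#'
#' Each annotation carrying CE-MS coordinates (`mass_da`, `migration_min`)
#' is attached to the clustered feature within the tolerance windows of its
#' coordinates; when several features fall inside the window an ambiguity
#' warning is raised and the nearest-mass feature wins.  Features without an
#' annotation are retained but flagged, so the `sequenced_only` view can
#' drop them (only sequenced peptides enter downstream biological
#' interpretation).
#'
#' @param matrix a [cohort_matrix()].
#' @param annotations data frame with columns `peptide_id`, `sequence`,
#'   `mass_da`, `migration_min` and optionally `protein_name`,
#'   `gene_symbol`, `start_aa`, `stop_aa`.
#' @param model a [tolerance_model()].
#' @return the `cohort_matrix` with annotation columns (`sequence`,
#'   `protein_name`, `gene_symbol`, `start_aa`, `stop_aa`, `annotated`)
#'   added to its feature table.
#' @export
annotate_features <- function(matrix, annotations, model = tolerance_model()) {
  pa_assert(all(c("sequence", "mass_da", "migration_min") %in%
                  names(annotations)),
            "annotations need sequence, mass_da, migration_min columns",
            "peptiage_format_error")
  ft <- matrix$features
  ft$sequence <- NA_character_
  ft$protein_name <- NA_character_
  ft$gene_symbol <- NA_character_
  ft$start_aa <- NA_integer_
  ft$stop_aa <- NA_integer_
  for (j in seq_len(nrow(annotations))) {
    am <- annotations$mass_da[j]; at <- annotations$migration_min[j]
    dm <- abs(ft$consensus_mass - am)
    dt <- abs(ft$consensus_time - at)
    ok <- dm <= mass_tolerance_da(ft$consensus_mass, model) &
      dt <= time_half_window(ft$consensus_time, model)
    if (!any(ok)) next
    if (sum(ok) > 1)
      warning(sprintf(
        "annotation '%s' matches %d features; assigning nearest mass",
        annotations$sequence[j], sum(ok)))
    sel <- which(ok)[which.min(dm[ok])]
    ft$sequence[sel] <- annotations$sequence[j]
    if ("protein_name" %in% names(annotations))
      ft$protein_name[sel] <- annotations$protein_name[j]
    if ("gene_symbol" %in% names(annotations))
      ft$gene_symbol[sel] <- annotations$gene_symbol[j]
    if ("start_aa" %in% names(annotations))
      ft$start_aa[sel] <- annotations$start_aa[j]
    if ("stop_aa" %in% names(annotations))
      ft$stop_aa[sel] <- annotations$stop_aa[j]
  }
  ft$annotated <- !is.na(ft$sequence)
  matrix$features <- ft
  matrix
}

#' @rdname annotate_features
#' @export
sequenced_only <- function(matrix) {
  pa_assert("annotated" %in% names(matrix$features),
            "run annotate_features() first", "peptiage_validation_error")
  subset_cohort(matrix, features = which(matrix$features$annotated))
}
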