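#' Build the log-intensity feature matrix for a peptide panel
#'
#' The ageing score operates in an x-dimensional space whose coordinates are
#' the log-transformed intensities of a fixed panel of x peptides.  The
#' transform is `ln(intensity + 1)` so that a non-detection (intensity 0)
#' maps to coordinate 0.
#'
#' @param matrix a [cohort_matrix()].
#' @param panel character vector of feature ids, in panel order.
#' @return numeric matrix, samples x panel features.
#' @export
classifier_design <- function(matrix, panel) {
  pa_assert(length(panel) > 0 && !anyDuplicated(panel),
            "panel must be non-empty without duplicates",
            "peptiage_config_error")
  idx <- match(panel, matrix$features$feature_id)
  if (anyNA(idx))
    pa_stop(sprintf("panel feature(s) missing from matrix: %s",
                    paste(panel[is.na(idx)], collapse = ", ")),
            "peptiage_config_error")
  t(log1p(matrix$intensities[idx, , drop = FALSE]))
}

#' @rdname classifier_design
#' @param sample a single sample id (or column index).
#' @return `feature_vector` returns the numeric vector for one sample.
#' @export
feature_vector <- function(matrix, panel, sample) {
  X <- classifier_design(matrix, panel)
  if (is.character(sample)) sample <- match(sample, rownames(X))
  pa_assert(!is.na(sample) && sample >= 1 && sample <= nrow(X),
            "unknown sample", "peptiage_validation_error")
  X[sample, ]
}

#' Train an SVM ageing classifier on a peptide panel
#'
#' Fits a support vector machine with a radial-basis (Gaussian) kernel on
#' binary young/old training labels; the decision-function value -- the
#' signed distance of a sample's log-intensity vector to the maximal-margin
#' hyperplane -- is the ageing score.  The cost parameter C and the kernel
#' width gamma are selected by k-fold cross-validated accuracy on the
#' training set only, over a small grid, with deterministic fold assignment
#' from `seed`; ties resolve to the smallest C, then the smallest gamma.
#' Feature vectors are used as-is (no unit-length or z-score scaling).
#'
#' @param x numeric matrix, samples x features (see [classifier_design()]),
#'   or a [cohort_matrix()] together with `panel`.
#' @param labels factor or character with exactly the levels `young` and
#'   `old` (any two labels work; the second level is the "old" pole).
#' @param panel peptide panel, required when `x` is a `cohort_matrix`.
#' @param cost_grid candidate C values.
#' @param gamma_grid candidate gamma values; defaults to
#'   `1 / (ncol(x) * var(x))` (the scale heuristic) plus 0.01, 0.1, 1.
#' @param folds cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @return an object of class `ageing_classifier` carrying the fitted SVM,
#'   the panel, the selected `(C, gamma)`, the CV accuracy and the score
#'   orientation.
#' @export
train_ageing_classifier <- function(x, labels, panel = NULL,
                                    cost_grid = c(0.1, 1, 10, 100),
                                    gamma_grid = NULL,
                                    folds = 5, seed = 1L) {
  if (inherits(x, "cohort_matrix")) {
    pa_assert(!is.null(panel), "panel is required with a cohort_matrix",
              "peptiage_config_error")
    x <- classifier_design(x, panel)
  } else {
    x <- as.matrix(x)
    if (is.null(panel)) panel <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  }
  labels <- factor(labels)
  pa_assert(nlevels(labels) == 2,
            "training labels must have exactly two classes",
            "peptiage_single_class_error")
  pa_assert(all(table(labels) >= 2), "need at least 2 samples per class",
            "peptiage_validation_error")
  old_level <- if ("old" %in% levels(labels)) "old" else levels(labels)[2]

  if (is.null(gamma_grid)) {
    v <- var(as.vector(x))
    scale_gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 0.1
    gamma_grid <- unique(c(scale_gamma, 0.01, 0.1, 1))
  }

  n <- nrow(x)
  fold_id <- with_preserved_seed(seed, {
    # stratified folds: deterministic given seed
    id <- integer(n)
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })

  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (length(unique(labels[tr])) < 2 || sum(!tr) == 0) next
      fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / n
  }, numeric(1))
  best <- which(acc == max(acc))[1]  # grid sorted: smallest C then gamma wins

  fit <- e1071::svm(x, labels, kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  # orient scores so the "old" training class has positive mean score
  orientation <- if (mean(dv[labels == old_level]) >=
                       mean(dv[labels != old_level])) 1 else -1
  structure(list(model = fit, panel = panel,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best], orientation = orientation,
                 levels = levels(labels), old_level = old_level),
            class = "ageing_classifier")
}

#' @export
print.ageing_classifier <- function(x, ...) {
  cat(sprintf(
    "ageing_classifier: RBF SVM on %d peptides; C = %g, gamma = %g, CV accuracy %.2f\n",
    length(x$panel), x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Score samples with a trained ageing classifier
#'
#' The score is the signed decision-function value of the RBF SVM, oriented
#' so that the training "old" class averages positive: higher score = older
#' molecular profile.
#'
#' @param classifier a trained [train_ageing_classifier()].
#' @param x a [cohort_matrix()] (scored over the classifier's panel) or a
#'   samples x features numeric matrix in panel order.
#' @return data frame with `sample_id` and `score`.
#' @export
score_samples <- function(classifier, x) {
  if (inherits(x, "cohort_matrix")) x <- classifier_design(x, classifier$panel)
  x <- as.matrix(x)
  pa_assert(ncol(x) == length(classifier$panel),
            "feature dimension does not match the classifier panel",
            "peptiage_validation_error")
  dv <- attr(predict(classifier$model, x, decision.values = TRUE),
             "decision.values")[, 1]
  data.frame(sample_id = rownames(x) %||% sprintf("S%03d", seq_len(nrow(x))),
             score = classifier$orientation * unname(dv),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two score groups
#'
#' Two-sided test of a location difference between two groups of ageing
#' scores.  The p-value is exact when the smaller group has at most 8
#' observations and there are no ties, and uses the normal approximation
#' with tie correction otherwise.
#'
#' @param a,b numeric vectors of scores (each non-empty).
#' @return list with `u_statistic` (the Mann-Whitney U of `a`),
#'   `p_two_sided` and `medians`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
mann_whitney <- function(a, b) {
  pa_assert(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty",
            "peptiage_validation_error")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                     correct = !use_exact))
  list(u_statistic = unname(wt$statistic),
       p_two_sided = wt$p.value,
       medians = c(a = median(a), b = median(b)))
}

#' Pairwise group comparisons of ageing scores
#'
#' Runs [mann_whitney()] on every pair of groups (for example young /
#' mature / old age groups, or a genotype contrast such as telomerase
#' knock-out versus the oldest wild-type group) and reports per-group
#' medians.  Empty groups are skipped with a warning.
#'
#' @param scores data frame from [score_samples()].
#' @param groups factor (or character) of group membership, aligned with
#'   `scores`.
#' @return data frame with one row per group pair: group names, sizes,
#'   medians, U statistic and two-sided p-value.
#' @export
evaluate_age_groups <- function(scores, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  pa_assert(length(groups) == nrow(scores),
            "groups must align with scores", "peptiage_validation_error")
  lv <- levels(groups)
  empty <- lv[!lv %in% levels(droplevels(groups))]
  if (length(empty) > 0) {
    warning(sprintf("skipping empty group(s): %s",
                    paste(empty, collapse = ", ")))
    lv <- setdiff(lv, empty)
  }
  if (length(lv) < 2)
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      median_a = numeric(0), median_b = numeric(0),
                      u_statistic = numeric(0), p_two_sided = numeric(0)))
  pairs <- combn(lv, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    a <- scores$score[groups == ga]; b <- scores$score[groups == gb]
    mw <- mann_whitney(a, b)
    data.frame(group_a = ga, group_b = gb,
               n_a = length(a), n_b = length(b),
               median_a = unname(mw$medians["a"]),
               median_b = unname(mw$medians["b"]),
               u_statistic = mw$u_statistic,
               p_two_sided = mw$p_two_sided,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
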