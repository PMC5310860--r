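#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation on mid-ranks (average ranks for ties) with the
#' large-sample t approximation for the p-value.  Peptide intensity profiles
#' are not normally distributed across samples, so the non-parametric rank
#' coefficient is used throughout the screening stage.
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be constant.
#' @return list with `rho` and `p_raw`.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho  # 0.8
spearman <- function(x, y) {
  pa_assert(length(x) == length(y), "x and y must have equal length",
            "peptiage_validation_error")
  pa_assert(length(x) >= 3, "need at least 3 observations",
            "peptiage_validation_error")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    pa_stop("correlation undefined for a constant vector",
            "peptiage_constant_error")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_raw = ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate: sort
#' ascending, take `q_(i) = min over j >= i of (m * p_(j) / j)` capped at 1,
#' and return in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bh_adjust <- function(p) {
  pa_assert(all(is.finite(p) & p >= 0 & p <= 1),
            "p-values must lie in [0, 1]", "peptiage_validation_error")
  p.adjust(p, method = "BH")
}

#' Screen cohort features for correlation with age
#'
#' Every feature of the cohort matrix is tested for Spearman correlation
#' between its intensity profile and sample age as a continuous variable.
#' No detection-frequency threshold is applied: by default all samples enter
#' each test, with non-detections included as intensity 0 (mid-ranked ties
#' at the bottom).  Raw p-values are Benjamini-Hochberg adjusted across all
#' tested features and significance is called at `p_adjusted <= alpha`
#' (inclusive).  Constant features (e.g. all-zero) have no defined
#' correlation and are reported as skipped, never as significant.
#'
#' @param matrix a [cohort_matrix()] whose sample table carries `age`.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param detected_only if `TRUE`, correlate each feature only over the
#'   samples in which it was detected (intensity > 0) instead of including
#'   zeros.
#' @return list with `results` (data frame: `feature_id`, `rho`, `p_raw`,
#'   `p_adjusted`, `direction`, `n_samples`, `significant`, `skipped`,
#'   `skip_reason`) and `significant` (the subset data frame with
#'   `p_adjusted <= alpha`, sorted by `rho`).
#' @export
correlate_with_age <- function(matrix, alpha = 0.05, detected_only = FALSE) {
  ages <- matrix$samples$age
  pa_assert(!is.null(ages) && length(ages) >= 3,
            "need sample ages for at least 3 samples",
            "peptiage_validation_error")
  if (length(unique(ages)) < 2)
    pa_stop("all samples have the same age: correlation design is degenerate",
            "peptiage_design_error")
  X <- matrix$intensities
  nfeat <- nrow(X)
  rho <- rep(NA_real_, nfeat); p_raw <- rep(NA_real_, nfeat)
  ns <- rep(NA_integer_, nfeat); reason <- rep(NA_character_, nfeat)
  for (i in seq_len(nfeat)) {
    y <- X[i, ]
    a <- ages
    if (detected_only) {
      keep <- y > 0
      y <- y[keep]; a <- a[keep]
    }
    if (length(y) < 3) {
      reason[i] <- "fewer than 3 samples"
      next
    }
    if (length(unique(y)) < 2) {
      reason[i] <- "constant intensity profile"
      next
    }
    if (length(unique(a)) < 2) {
      reason[i] <- "constant age among detected samples"
      next
    }
    s <- spearman(a, y)
    rho[i] <- s$rho; p_raw[i] <- s$p_raw; ns[i] <- length(y)
  }
  p_adj <- rep(NA_real_, nfeat)
  tested <- !is.na(p_raw)
  p_adj[tested] <- bh_adjust(p_raw[tested])
  res <- data.frame(
    feature_id = matrix$features$feature_id,
    rho = rho, p_raw = p_raw, p_adjusted = p_adj,
    direction = ifelse(is.na(rho), 0L, as.integer(sign(rho))),
    n_samples = ns,
    significant = !is.na(p_adj) & p_adj <= alpha,
    skipped = !tested,
    skip_reason = reason,
    stringsAsFactors = FALSE)
  sig <- res[res$significant, , drop = FALSE]
  sig <- sig[order(sig$rho), , drop = FALSE]
  list(results = res, significant = sig)
}
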