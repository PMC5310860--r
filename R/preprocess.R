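#' Fit an axis calibration map by locally weighted regression
#'
#' CE-MS runs are calibrated against reference data points (published runs
#' used 150 reference masses and 452 reference migration times).  The
#' calibration curve is fitted by tricube-weighted local linear regression
#' (one pass, no robustness iterations) of the reference values on the
#' observed values; the fitted curve is evaluated at the control points and
#' applied elsewhere by linear interpolation, with linear extrapolation from
#' the boundary segments outside the control range.
#'
#' @param observed numeric vector of observed control values.
#' @param reference numeric vector of matching reference values.
#' @param smoothing_fraction span of the local regression in (0, 1];
#'   default 0.3.
#' @param axis which axis the map corrects: `"mass"` or `"migration_time"`.
#' @return an object of class `calibration_map`.
#' @export
#' @examples
#' cal <- fit_calibration(1:10, 2 * (1:10))
#' predict(cal, 5)  # 10
fit_calibration <- function(observed, reference, smoothing_fraction = 0.3,
                            axis = c("mass", "migration_time")) {
  axis <- match.arg(axis)
  pa_assert(length(observed) == length(reference),
            "observed and reference must have equal length",
            "peptiage_validation_error")
  keep <- is.finite(observed) & is.finite(reference)
  observed <- observed[keep]; reference <- reference[keep]
  if (length(observed) < 2)
    pa_stop("need at least 2 finite calibration pairs",
            "peptiage_insufficient_data_error")
  pa_assert(smoothing_fraction > 0 && smoothing_fraction <= 1,
            "smoothing_fraction must be in (0, 1]", "peptiage_config_error")
  if (anyDuplicated(observed)) {
    sp <- split(reference, observed)
    conflict <- vapply(sp, function(v) length(unique(v)) > 1, logical(1))
    if (any(conflict))
      pa_stop("duplicate observed values with conflicting references",
              "peptiage_degeneracy_error")
    observed <- as.numeric(names(sp))
    reference <- vapply(sp, function(v) v[1], numeric(1))
  }
  o <- order(observed)
  observed <- observed[o]; reference <- reference[o]
  fit <- lowess(observed, reference, f = smoothing_fraction, iter = 0)
  y <- fit$y
  # the physical calibration curve is monotone; guard against local noise
  # wiggles in the smoothed fit
  if (any(diff(y) < 0)) y <- cummax(y)
  structure(list(axis = axis, x = fit$x, y = y,
                 smoothing_fraction = smoothing_fraction,
                 residual_rms = sqrt(mean((y - reference)^2))),
            class = "calibration_map")
}

#' @export
predict.calibration_map <- function(object, newdata, ...) {
  x <- object$x; y <- object$y
  n <- length(x)
  out <- approx(x, y, xout = newdata, rule = 1, ties = "ordered")$y
  lo_slope <- (y[2] - y[1]) / (x[2] - x[1])
  hi_slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  below <- newdata < x[1]
  above <- newdata > x[n]
  out[below] <- y[1] + lo_slope * (newdata[below] - x[1])
  out[above] <- y[n] + hi_slope * (newdata[above] - x[n])
  out
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration_map (%s): %d control points, span %.2f, residual RMS %.3g\n",
              x$axis, length(x$x), x$smoothing_fraction, x$residual_rms))
  invisible(x)
}

#' Apply a calibration map to one axis of a peak table
#'
#' Only the mapped axis changes; the record count and the other columns are
#' preserved.
#'
#' @param map a [fit_calibration()] result.
#' @param table a [peak_table()].
#' @return the corrected `peak_table`.
#' @export
apply_calibration <- function(map, table) {
  pa_assert(inherits(map, "calibration_map"), "map must be a calibration_map",
            "peptiage_validation_error")
  if (nrow(table) == 0) return(table)
  col <- if (map$axis == "mass") "mass_da" else "migration_min"
  table[[col]] <- predict(map, table[[col]])
  validate_peak_table(table, where = "calibrated table")
  table
}

#' Normalise a sample's intensities against internal-standard peptides
#'
#' Analytical and urine-dilution variance is removed by scaling each
#' sample's intensities so that a set of internal-standard peptides
#' (peptides assumed age-stable and present in essentially every sample; 29
#' in the published workflow) return to their reference amplitudes.  Each
#' standard is located in the peak table through the clustering tolerance
#' windows; the per-sample scale factor is the median of
#' `reference / observed` intensity ratios over the matched standards, a
#' robust and idempotent dilution correction.  Standards observed at zero
#' intensity are excluded from the median; a sample matching no standards is
#' an error (flagged, never silently passed through).
#'
#' @param table a [peak_table()] for one sample.
#' @param standards data frame with columns `mass_da`, `migration_min`,
#'   `reference_intensity`.
#' @param model a [tolerance_model()] used to match standards to peaks.
#' @return a list with elements `table` (the rescaled `peak_table`) and
#'   `result` (list: `scale_factor`, `n_standards_found`, `standards_used`).
#' @export
normalize_sample <- function(table, standards, model = tolerance_model()) {
  pa_assert(nrow(standards) > 0, "no internal standards supplied",
            "peptiage_validation_error")
  pa_assert(all(c("mass_da", "migration_min", "reference_intensity") %in%
                  names(standards)),
            "standards need mass_da, migration_min, reference_intensity",
            "peptiage_format_error")
  ratios <- numeric(0)
  used <- integer(0)
  for (j in seq_len(nrow(standards))) {
    dm <- abs(table$mass_da - standards$mass_da[j])
    dt <- abs(table$migration_min - standards$migration_min[j])
    ok <- dm <= mass_tolerance_da(standards$mass_da[j], model) &
      dt <= time_half_window(standards$migration_min[j], model)
    if (!any(ok)) next
    sel <- which(ok)[which.min(dm[ok])]
    obs <- table$intensity[sel]
    used <- c(used, j)
    if (obs > 0) ratios <- c(ratios, standards$reference_intensity[j] / obs)
  }
  if (length(ratios) == 0)
    pa_stop("no internal standards matched with non-zero intensity; sample cannot be normalised",
            "peptiage_normalization_error")
  scale_factor <- median(ratios)
  table$intensity <- table$intensity * scale_factor
  list(table = table,
       result = list(scale_factor = scale_factor,
                     n_standards_found = length(used),
                     standards_used = used))
}

#' Normalise every sample of a cohort
#'
#' Convenience wrapper applying [normalize_sample()] to each peak table in a
#' named list.
#'
#' @param tables named list of [peak_table()] objects.
#' @param standards see [normalize_sample()].
#' @param model a [tolerance_model()].
#' @return list with `tables` (rescaled peak tables) and `results` (data
#'   frame of per-sample scale factors and standard counts).
#' @export
normalize_cohort <- function(tables, standards, model = tolerance_model()) {
  res <- lapply(tables, normalize_sample, standards = standards, model = model)
  list(tables = lapply(res, `[[`, "table"),
       results = data.frame(
         sample_id = names(tables),
         scale_factor = vapply(res, function(r) r$result$scale_factor,
                               numeric(1)),
         n_standards_found = vapply(res, function(r) r$result$n_standards_found,
                                    integer(1)),
         row.names = NULL, stringsAsFactors = FALSE))
}
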