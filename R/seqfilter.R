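# monoisotopic residue masses (Da), standard values; lowercase entries are
# the modified residues: hydroxylation/oxidation adds one oxygen (15.994915)
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_O <- 15.994915
MASS_H2O <- 18.010565

#' Theoretical monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water.  Hydroxyproline
#' (lowercase `p`), oxidised methionine (`m`) and hydroxylysine (`k`) add
#' one oxygen to the parent residue mass.
#'
#' @param seq peptide string.
#' @return mass in Daltons.
#' @export
#' @examples
#' peptide_mass("G")  # 75.03203
peptide_mass <- function(seq) {
  ns <- normalize_sequence(seq)
  chars <- strsplit(ns$original, "")[[1]]
  base <- RESIDUE_MASS[toupper(chars)]
  sum(base) + MASS_O * length(ns$modification_positions) + MASS_H2O
}

#' Peptide charge at pH 2
#'
#' At the acidic pH of the CE separation, a peptide's net charge is driven
#' by its number of basic amino acids: the N-terminal amine plus every
#' lysine, arginine and histidine (all protonated at pH 2).  Modified
#' residues count as their parent amino acid.
#'
#' @param seq peptide string.
#' @return integer charge: `1 + #K + #R + #H` (case-insensitive).
#' @export
#' @examples
#' charge_at_ph2("KRHAA")  # 4
charge_at_ph2 <- function(seq) {
  ns <- normalize_sequence(seq)
  chars <- strsplit(ns$canonical, "")[[1]]
  1L + sum(chars %in% c("K", "R", "H"))
}

#' Fit a CE migration-time predictor from sequenced training peptides
#'
#' CE migration time correlates strictly with peptide charge at pH 2 and,
#' more weakly, with peptide size.  The predictor is an ordinary
#' least-squares fit of `time ~ a + b * charge + c * ln(mass)` on training
#' peptides with known sequence, observed migration time and mass.
#'
#' @param training data frame with columns `sequence`, `observed_time`,
#'   `mass` (Da).
#' @return an object of class `migration_model` with elements
#'   `coefficients`, `residuals`, `fit`.
#' @export
fit_migration_model <- function(training) {
  pa_assert(all(c("sequence", "observed_time", "mass") %in% names(training)),
            "training needs sequence, observed_time, mass columns",
            "peptiage_format_error")
  if (nrow(training) < 5)
    pa_stop("need at least 5 training pairs", "peptiage_insufficient_data_error")
  charge <- vapply(training$sequence, charge_at_ph2, integer(1))
  if (length(unique(charge)) < 2)
    pa_stop("training peptides span a single charge level; charge coefficient is not identifiable",
            "peptiage_fitting_error")
  df <- data.frame(time = training$observed_time, charge = charge,
                   lmass = log(training$mass))
  fit <- lm(time ~ charge + lmass, data = df)
  if (anyNA(coef(fit)))
    pa_stop("rank-deficient design: migration model cannot be fitted",
            "peptiage_fitting_error")
  structure(list(coefficients = coef(fit),
                 residuals = unname(fit$residuals),
                 fit = fit),
            class = "migration_model")
}

#' @export
predict.migration_model <- function(object, sequence, mass, ...) {
  charge <- vapply(as.character(sequence), charge_at_ph2, integer(1))
  co <- object$coefficients
  unname(co[1] + co[2] * charge + co[3] * log(mass))
}

#' @export
print.migration_model <- function(x, ...) {
  cat(sprintf("migration_model: time = %.3f + %.3f * charge + %.3f * ln(mass); residual SD %.3f\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              sd(x$residuals)))
  invisible(x)
}

#' Validate a candidate peptide identification
#'
#' A sequence assignment for an observed CE-MS signal is accepted only when
#' the observed mass agrees with the theoretical mass within +/- 80 ppm and
#' the observed migration time agrees with the time predicted from the
#' candidate's charge and size within +/- 2 min.  Both bounds are inclusive:
#' the acceptance region is a closed rectangle in (ppm, minutes).
#'
#' @param sequence candidate peptide sequence.
#' @param observed_mass observed mass (Da).
#' @param observed_time observed migration time (min).
#' @param model a fitted [fit_migration_model()].
#' @param theoretical_mass theoretical mass of the candidate; computed from
#'   the sequence by [peptide_mass()] when omitted.
#' @param max_ppm mass-deviation bound in ppm (default 80).
#' @param max_minutes migration-time deviation bound in minutes (default 2).
#' @return list with `mass_deviation_ppm`, `time_deviation_min`,
#'   `predicted_time`, `accepted`.
#' @export
validate_identification <- function(sequence, observed_mass, observed_time,
                                    model, theoretical_mass = NULL,
                                    max_ppm = 80, max_minutes = 2) {
  pa_assert(inherits(model, "migration_model"),
            "model must be a fitted migration_model",
            "peptiage_validation_error")
  if (is.null(theoretical_mass)) theoretical_mass <- peptide_mass(sequence)
  ppm <- 1e6 * (observed_mass - theoretical_mass) / theoretical_mass
  pred <- predict(model, sequence, theoretical_mass)
  dt <- observed_time - pred
  # inclusive bounds with a tiny guard so the closed boundary survives
  # floating-point round-off in the ppm computation
  eps <- 1e-9
  list(mass_deviation_ppm = ppm,
       time_deviation_min = dt,
       predicted_time = pred,
       accepted = abs(ppm) <= max_ppm * (1 + eps) &&
         abs(dt) <= max_minutes + eps)
}

#' Validate a table of candidate identifications
#'
#' @param candidates data frame with columns `sequence`, `observed_mass`,
#'   `observed_time` and optionally `theoretical_mass`.
#' @param model a fitted [fit_migration_model()].
#' @param max_ppm,max_minutes acceptance bounds, see
#'   [validate_identification()].
#' @return the candidates with `mass_deviation_ppm`, `time_deviation_min`
#'   and `accepted` columns appended.
#' @export
validate_candidates <- function(candidates, model, max_ppm = 80,
                                max_minutes = 2) {
  tm <- if ("theoretical_mass" %in% names(candidates))
    candidates$theoretical_mass else
      vapply(candidates$sequence, peptide_mass, numeric(1))
  out <- candidates
  out$theoretical_mass <- tm
  verdicts <- lapply(seq_len(nrow(candidates)), function(i)
    validate_identification(candidates$sequence[i],
                            candidates$observed_mass[i],
                            candidates$observed_time[i],
                            model, theoretical_mass = tm[i],
                            max_ppm = max_ppm, max_minutes = max_minutes))
  out$mass_deviation_ppm <- vapply(verdicts, `[[`, numeric(1),
                                   "mass_deviation_ppm")
  out$time_deviation_min <- vapply(verdicts, `[[`, numeric(1),
                                   "time_deviation_min")
  out$accepted <- vapply(verdicts, `[[`, logical(1), "accepted")
  out
}
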