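#' Configuration for the synthetic cohort generator
#'
#' Defines a mouse-like (or human-like) urinary peptidome cohort with known
#' ground truth.  Defaults mirror the mouse study design: six age groups at
#' 4, 12, 48, 61, 84 and 96 weeks, a few thousand peptide features of which
#' a programmed subset drifts with age (collagen-like markers decreasing,
#' uromodulin-like markers increasing on the log scale), 29 age-stable
#' internal-standard peptides, per-sample multiplicative dilution,
#' log-normal measurement noise and random missed detections.
#'
#' @param n_samples_per_age_group samples per age group (default 10).
#' @param age_groups ages, one per group (default `c(4, 12, 48, 61, 84, 96)`
#'   weeks).
#' @param age_unit `"weeks"` or `"years"`.
#' @param species `"mouse"` or `"human"`.
#' @param n_features total number of peptide features (default 2000).
#' @param n_negative_markers features with a programmed negative age trend
#'   (default 50).
#' @param n_positive_markers features with a programmed positive age trend
#'   (default 20).
#' @param effect_slope_range interval for the absolute per-unit-age
#'   log-intensity slope of markers (default `c(0.01, 0.03)` per week: over
#'   the 4-96 week design this moves a marker by about 1-3 natural-log
#'   units).
#' @param noise_sd log-scale measurement noise SD (default 0.3).
#' @param dropout_prob probability that a true signal is missed (recorded as
#'   absent) in a sample (default 0.1); internal standards never drop out.
#' @param dilution_factor_range interval for the per-sample multiplicative
#'   dilution factor (default `c(0.5, 2)`).
#' @param n_internal_standards age-stable standard peptides (default 29).
#' @param accelerated_group optional list describing a premature-ageing
#'   genotype group, with elements `n` (samples), `age` (chronological age),
#'   `slope_multiplier` (applied to every marker slope; default 2) and
#'   `genotype` (default `"terc_ko"`).  The multiplier models an organism
#'   whose molecular age runs ahead of its chronological age.
#' @param seed integer seed making the cohort reproducible.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_per_age_group = 10,
                              age_groups = c(4, 12, 48, 61, 84, 96),
                              age_unit = "weeks",
                              species = "mouse",
                              n_features = 2000,
                              n_negative_markers = 50,
                              n_positive_markers = 20,
                              effect_slope_range = c(0.01, 0.03),
                              noise_sd = 0.3,
                              dropout_prob = 0.1,
                              dilution_factor_range = c(0.5, 2),
                              n_internal_standards = 29,
                              accelerated_group = NULL,
                              seed = 1L) {
  cfg <- list(n_samples_per_age_group = as.integer(n_samples_per_age_group),
              age_groups = as.numeric(age_groups),
              age_unit = match.arg(age_unit, c("weeks", "years")),
              species = match.arg(species, c("mouse", "human")),
              n_features = as.integer(n_features),
              n_negative_markers = as.integer(n_negative_markers),
              n_positive_markers = as.integer(n_positive_markers),
              effect_slope_range = as.numeric(effect_slope_range),
              noise_sd = as.numeric(noise_sd),
              dropout_prob = as.numeric(dropout_prob),
              dilution_factor_range = as.numeric(dilution_factor_range),
              n_internal_standards = as.integer(n_internal_standards),
              accelerated_group = accelerated_group,
              seed = as.integer(seed))
  if (cfg$n_negative_markers + cfg$n_positive_markers +
        cfg$n_internal_standards > cfg$n_features)
    pa_stop("markers plus internal standards exceed n_features",
            "peptiage_config_error")
  pa_assert(cfg$dropout_prob >= 0 && cfg$dropout_prob <= 1,
            "dropout_prob must be in [0, 1]", "peptiage_config_error")
  pa_assert(cfg$noise_sd >= 0, "noise_sd must be non-negative",
            "peptiage_config_error")
  pa_assert(all(cfg$age_groups > 0), "ages must be positive",
            "peptiage_config_error")
  pa_assert(length(cfg$effect_slope_range) == 2 &&
              all(cfg$effect_slope_range > 0) &&
              diff(cfg$effect_slope_range) >= 0,
            "effect_slope_range must be a positive increasing interval",
            "peptiage_config_error")
  pa_assert(length(cfg$dilution_factor_range) == 2 &&
              all(cfg$dilution_factor_range > 0) &&
              diff(cfg$dilution_factor_range) >= 0,
            "dilution_factor_range must be a positive increasing interval",
            "peptiage_config_error")
  if (!is.null(cfg$accelerated_group)) {
    ag <- cfg$accelerated_group
    cfg$accelerated_group <- list(
      n = as.integer(ag$n %||% 5L),
      age = as.numeric(ag$age %||% 61),
      slope_multiplier = as.numeric(ag$slope_multiplier %||% 2),
      genotype = as.character(ag$genotype %||% "terc_ko"))
    pa_assert(cfg$accelerated_group$n > 0 && cfg$accelerated_group$age > 0 &&
                cfg$accelerated_group$slope_multiplier > 0,
              "invalid accelerated_group", "peptiage_config_error")
  }
  structure(cfg, class = "simulation_config")
}

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces per-sample peak tables, sample metadata and a ground-truth table
#' from a [simulation_config()].  Each feature has a fixed true mass in
#' \[800, 20000\] Da (features are kept at least 4 Da apart so the tolerance
#' windows cannot merge neighbours) and a true migration time in \[19, 50\]
#' min; per-sample observed coordinates are the true values plus uniform
#' perturbations within half the clustering tolerance.  Log-intensities
#' follow `base + slope * age + noise`, are exponentiated and scaled by the
#' sample's dilution factor; dropout is applied after dilution.  Internal
#' standards have zero slope and never drop out; their noiseless amplitudes
#' are exported as the reference intensities for [normalize_sample()].
#'
#' The generator is deterministic given `config$seed` and restores the
#' caller's RNG state.
#'
#' @param config a [simulation_config()].
#' @param model the [tolerance_model()] whose windows bound the coordinate
#'   perturbations.
#' @return list of class `synthetic_cohort` with elements `tables` (named
#'   list of [peak_table()]s, each carrying a `true_feature` attribute),
#'   `samples` (metadata frame), `truth` (data frame: `feature_id`, `role`,
#'   `trend_sign`, `true_slope`, `true_mass`, `true_time`, `base_log`),
#'   `standards` (reference definitions for normalisation) and `config`.
#' @export
generate_cohort <- function(config = simulation_config(),
                            model = tolerance_model()) {
  pa_assert(inherits(config, "simulation_config"),
            "config must be a simulation_config", "peptiage_config_error")
  with_preserved_seed(config$seed, {
    nf <- config$n_features
    n_neg <- config$n_negative_markers
    n_pos <- config$n_positive_markers
    n_std <- config$n_internal_standards

    # true feature coordinates; resample until all masses are >= 4 Da apart
    mass <- sort(runif(nf, 800, 20000))
    for (it in 1:100) {
      close <- which(diff(mass) < 4)
      if (length(close) == 0) break
      mass[close + 1] <- runif(length(close), 800, 20000)
      mass <- sort(mass)
    }
    pa_assert(all(diff(mass) >= 4),
              "could not place features 4 Da apart; reduce n_features",
              "peptiage_config_error")
    mass <- sample(mass)  # decouple feature role from mass order
    time <- runif(nf, 19, 50)

    role <- rep("null", nf)
    role[seq_len(n_neg)] <- "negative_marker"
    role[seq_len(n_pos) + n_neg] <- "positive_marker"
    role[seq_len(n_std) + n_neg + n_pos] <- "internal_standard"
    trend <- ifelse(role == "negative_marker", -1L,
                    ifelse(role == "positive_marker", 1L, 0L))
    slope <- trend * runif(nf, config$effect_slope_range[1],
                           config$effect_slope_range[2])
    base_log <- rnorm(nf, mean = log(500), sd = 1)

    ages <- rep(config$age_groups, each = config$n_samples_per_age_group)
    genotype <- rep("wild_type", length(ages))
    mult <- rep(1, length(ages))
    if (!is.null(config$accelerated_group)) {
      ag <- config$accelerated_group
      ages <- c(ages, rep(ag$age, ag$n))
      genotype <- c(genotype, rep(ag$genotype, ag$n))
      mult <- c(mult, rep(ag$slope_multiplier, ag$n))
    }
    ns <- length(ages)
    sample_id <- sprintf("S%03d", seq_len(ns))
    dilution <- runif(ns, config$dilution_factor_range[1],
                      config$dilution_factor_range[2])

    mass_jit_half <- 0.5 * mass_tolerance_da(mass, model)
    time_jit_half <- 0.5 * time_half_window(time, model)

    tables <- vector("list", ns)
    for (s in seq_len(ns)) {
      noise <- if (config$noise_sd > 0) rnorm(nf, 0, config$noise_sd) else 0
      log_int <- base_log + slope * (mult[s] * ages[s]) + noise
      intensity <- exp(log_int) * dilution[s]
      obs_mass <- mass + runif(nf, -1, 1) * mass_jit_half
      obs_time <- time + runif(nf, -1, 1) * time_jit_half
      detected <- rep(TRUE, nf)
      if (config$dropout_prob > 0) {
        drop <- runif(nf) < config$dropout_prob
        drop[role == "internal_standard"] <- FALSE
        detected <- !drop
      }
      tb <- peak_table(obs_mass[detected], obs_time[detected],
                       intensity[detected])
      attr(tb, "true_feature") <- which(detected)
      tables[[s]] <- tb
    }
    names(tables) <- sample_id

    meta <- sample_meta(sample_id, config$species, ages, config$age_unit,
                        genotype)
    truth <- data.frame(
      feature_id = sprintf("T%05d", seq_len(nf)),
      role = role, trend_sign = trend, true_slope = slope,
      true_mass = mass, true_time = time, base_log = base_log,
      stringsAsFactors = FALSE)
    std_idx <- which(role == "internal_standard")
    standards <- data.frame(
      mass_da = mass[std_idx],
      migration_min = time[std_idx],
      reference_intensity = exp(base_log[std_idx]))
    structure(list(tables = tables, samples = meta, truth = truth,
                   standards = standards, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples, %d features (%d neg / %d pos markers, %d standards)\n",
    length(x$tables), nrow(x$truth),
    sum(x$truth$role == "negative_marker"),
    sum(x$truth$role == "positive_marker"),
    sum(x$truth$role == "internal_standard")))
  invisible(x)
}

#' Check generated peaks against the clustering windows of their truth
#'
#' Generator self-check: verifies that every observed replicate of a feature
#' lies within the clustering tolerance window of its true (mass, time).
#' Because the generator caps coordinate perturbations at half the window,
#' a well-formed cohort reports 100% within tolerance.
#'
#' @param cohort a [generate_cohort()] result (peak tables must carry their
#'   `true_feature` attributes).
#' @param model the [tolerance_model()] to check against.
#' @return list with `fraction_within` and `violations` (data frame of
#'   out-of-window peaks: sample, feature, deviations).
#' @export
truth_mass_within_tolerance_report <- function(cohort,
                                               model = tolerance_model()) {
  viol <- list()
  n_total <- 0L
  for (s in names(cohort$tables)) {
    tb <- cohort$tables[[s]]
    idx <- attr(tb, "true_feature")
    pa_assert(!is.null(idx) && length(idx) == nrow(tb),
              "peak tables lack true_feature attributes",
              "peptiage_validation_error")
    n_total <- n_total + nrow(tb)
    dm <- abs(tb$mass_da - cohort$truth$true_mass[idx])
    dt <- abs(tb$migration_min - cohort$truth$true_time[idx])
    bad <- dm > mass_tolerance_da(cohort$truth$true_mass[idx], model) |
      dt > time_half_window(cohort$truth$true_time[idx], model)
    if (any(bad)) {
      viol[[s]] <- data.frame(sample_id = s,
                              feature_id = cohort$truth$feature_id[idx[bad]],
                              mass_deviation_da = dm[bad],
                              time_deviation_min = dt[bad])
    }
  }
  violations <- if (length(viol) > 0) do.call(rbind, c(viol, list(make.row.names = FALSE))) else
    data.frame(sample_id = character(0), feature_id = character(0),
               mass_deviation_da = numeric(0), time_deviation_min = numeric(0))
  list(fraction_within = if (n_total > 0) 1 - nrow(violations) / n_total else NA_real_,
       violations = violations)
}

#' Match clustered features back to generator ground truth
#'
#' Links each clustered feature of a cohort matrix to the synthetic true
#' feature whose (mass, time) lies within the tolerance windows of the
#' feature's consensus, taking the nearest mass when several qualify.
#'
#' @param matrix a [cohort_matrix()] produced by [cluster_samples()].
#' @param truth the `truth` data frame of a [generate_cohort()] result.
#' @param model a [tolerance_model()].
#' @return the feature table of `matrix` with `truth_id`, `role`,
#'   `trend_sign` and `true_slope` columns appended (`NA` where no true
#'   feature matches).
#' @export
match_features_to_truth <- function(matrix, truth,
                                    model = tolerance_model()) {
  ft <- matrix$features
  o <- order(truth$true_mass)
  tm <- truth$true_mass[o]; tt <- truth$true_time[o]
  idx <- rep(NA_integer_, nrow(ft))
  tol <- mass_tolerance_da(ft$consensus_mass, model)
  lo <- findInterval(ft$consensus_mass - tol, tm)
  hi <- findInterval(ft$consensus_mass + tol, tm)
  for (i in seq_len(nrow(ft))) {
    if (lo[i] >= hi[i]) next
    cand <- seq.int(lo[i] + 1L, hi[i])
    dm <- abs(ft$consensus_mass[i] - tm[cand])
    dt <- abs(ft$consensus_time[i] - tt[cand])
    ok <- dm <= tol[i] & dt <= time_half_window(ft$consensus_time[i], model)
    if (!any(ok)) next
    idx[i] <- o[cand[ok][which.min(dm[ok])]]
  }
  ft$truth_id <- truth$feature_id[idx]
  ft$role <- truth$role[idx]
  ft$trend_sign <- truth$trend_sign[idx]
  ft$true_slope <- truth$true_slope[idx]
  ft
}

#' Write a synthetic cohort to a directory
#'
#' Writes one peak-table TSV per sample plus `samples.tsv`, `truth.tsv` and
#' `standards.tsv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$tables))
    write_peak_table(cohort$tables[[s]], file.path(dir, paste0(s, ".tsv")))
  write.table(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$standards, file.path(dir, "standards.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
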