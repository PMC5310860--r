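# independent brute-force oracles used by property tests

# Benjamini-Hochberg step-up, straight from the definition:
# sort ascending, q_(i) = min_{j >= i} m * p_(j) / j, cap at 1, unsort
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q[order(o)]
}

# exhaustive best ungapped overlap: enumerate every offset and every window,
# keep windows whose mismatches are all internal (window starts/ends with a
# match whenever it contains any mismatch) and count at most k mismatches;
# maximise length, then fewer mismatches, then smaller |offset|
overlap_oracle <- function(a, b, k = 1) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- list(overlap_length = 0L, mismatches = 0L, offset = 0L)
  for (off in seq(-(nb - 1L), na - 1L)) {
    i1 <- max(1L, off + 1L); i2 <- min(na, nb + off)
    if (i2 < i1) next
    m <- ca[i1:i2] == cb[(i1:i2) - off]
    L <- length(m)
    for (s in seq_len(L)) {
      for (e in s:L) {
        w <- m[s:e]
        mm <- sum(!w)
        if (mm > k) next
        if (mm > 0 && (!w[1] || !w[length(w)])) next
        # no two adjacent mismatches (each must be flanked by matches)
        if (mm > 1 && any(!w[-1] & !w[-length(w)])) next
        len <- length(w)
        if (len > best$overlap_length ||
            (len == best$overlap_length &&
               (mm < best$mismatches ||
                  (mm == best$mismatches && abs(off) < abs(best$offset))))) {
          best <- list(overlap_length = len, mismatches = mm, offset = off)
        }
      }
    }
  }
  best
}

# Mann-Whitney normal approximation with tie correction, written from the
# textbook formulas (independent of wilcox.test)
mw_normal_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
  z <- (u - n1 * n2 / 2) / sigma
  2 * pnorm(-abs(z))
}

# random valid peak table for round-trip properties
random_peak_table <- function(n, seed) {
  set.seed(seed)
  peak_table(mass_da = runif(n, 800, 20000),
             migration_min = runif(n, 19, 50),
             intensity = round(c(0, rexp(n - 1, 1 / 500)), 4))
}

# a clustering instance whose features are far apart relative to the
# tolerance windows: each feature gets one near-coincident peak in a random
# subset of samples
separated_instance <- function(n_features, n_samples, seed,
                               model = tolerance_model()) {
  set.seed(seed)
  mass <- sort(runif(n_features, 1000, 15000))
  while (any(diff(mass) < 6 * mass_tolerance_da(mass[-1], model))) {
    mass <- sort(runif(n_features, 1000, 15000))
  }
  time <- runif(n_features, 19, 50)
  tables <- lapply(seq_len(n_samples), function(s) {
    present <- runif(n_features) < 0.8
    if (!any(present)) present[1] <- TRUE
    idx <- which(present)
    peak_table(
      mass[idx] + runif(length(idx), -0.4, 0.4) *
        mass_tolerance_da(mass[idx], model),
      time[idx] + runif(length(idx), -0.4, 0.4) *
        time_half_window(time[idx], model),
      rexp(length(idx), 1 / 100))
  })
  names(tables) <- sprintf("S%02d", seq_len(n_samples))
  list(tables = tables, mass = mass, time = time)
}

# number of features an optimal assignment must produce on a well-separated
# instance: connected components of the peak compatibility graph
component_count <- function(tables, model = tolerance_model()) {
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm <- abs(pooled$mass_da[i] - pooled$mass_da[j])
      dt <- abs(pooled$migration_min[i] - pooled$migration_min[j])
      tol <- max(mass_tolerance_da(pooled$mass_da[i], model),
                 mass_tolerance_da(pooled$mass_da[j], model))
      tw <- max(time_half_window(pooled$migration_min[i], model),
                time_half_window(pooled$migration_min[j], model))
      if (dm <= tol && dt <= tw) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# compact generator configuration for fast unit tests
small_config <- function(...) {
  defaults <- list(n_samples_per_age_group = 3, n_features = 80,
                   n_negative_markers = 8, n_positive_markers = 4,
                   n_internal_standards = 10, seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
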