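toy_matrix <- function() {
  meta <- sample_meta(sprintf("S%d", 1:4), "mouse", c(4, 4, 96, 96), "weeks")
  X <- rbind(F1 = c(exp(1) - 1, 0, 0, 0),
             F2 = c(0, 1, 2, 3),
             F3 = c(5, 5, 0, 0))
  cohort_matrix(X, data.frame(feature_id = c("F1", "F2", "F3")), meta)
}

test_that("feature vectors are ln(intensity + 1) in panel order", {
  m <- toy_matrix()
  v <- feature_vector(m, c("F1", "F2"), "S1")
  expect_equal(unname(v), c(1, 0))  # ln(e) = 1, ln(1) = 0
  expect_identical(length(feature_vector(m, c("F3", "F1", "F2"), "S2")), 3L)
  zero <- feature_vector(m, c("F1", "F2", "F3"), "S4")["F1"]
  expect_identical(unname(zero), 0)
  expect_error(classifier_design(m, c("F1", "missing")),
               class = "peptiage_config_error")
  expect_error(classifier_design(m, c("F1", "F1")),
               class = "peptiage_config_error")
})

separable_toy <- function() {
  x <- rbind(c(0, 0), c(0.5, 0), c(4, 4), c(4.5, 4))
  rownames(x) <- sprintf("S%d", 1:4)
  list(x = x, labels = factor(c("young", "young", "old", "old"),
                              levels = c("young", "old")))
}

test_that("a linearly separable toy set is classified perfectly", {
  toy <- separable_toy()
  clf <- train_ageing_classifier(toy$x, toy$labels, folds = 2, seed = 5)
  sc <- score_samples(clf, toy$x)
  expect_true(all(sc$score[1:2] < 0))
  expect_true(all(sc$score[3:4] > 0))
})

test_that("conflicting labels on identical inputs degrade gracefully", {
  x <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  labels <- factor(c("young", "old", "young", "old"))
  clf <- train_ageing_classifier(x, labels, folds = 2, seed = 5)
  sc <- score_samples(clf, x)
  pred_old <- sc$score > 0
  acc <- mean(pred_old == (labels == "old"))
  expect_lte(acc, 0.5)
})

test_that("single-class training is an error", {
  x <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(train_ageing_classifier(x, factor(rep("old", 3))),
               class = "peptiage_single_class_error")
})

test_that("swapping young/old labels negates all scores", {
  toy <- separable_toy()
  clf <- train_ageing_classifier(toy$x, toy$labels, folds = 2, seed = 5)
  flipped <- factor(ifelse(toy$labels == "young", "old", "young"),
                    levels = c("young", "old"))
  clf2 <- train_ageing_classifier(toy$x, flipped, folds = 2, seed = 5)
  s1 <- score_samples(clf, toy$x)$score
  s2 <- score_samples(clf2, toy$x)$score
  expect_equal(s1, -s2, tolerance = 1e-9)
})

test_that("an identically-zero panel feature leaves scores unchanged", {
  m <- toy_matrix()
  labels <- factor(c("young", "young", "old", "old"),
                   levels = c("young", "old"))
  clf <- train_ageing_classifier(m, labels, panel = c("F1", "F2"),
                                 folds = 2, seed = 5)
  m2 <- m
  m2$features <- rbind(m2$features, data.frame(feature_id = "F0"))
  m2$intensities <- rbind(m2$intensities, F0 = rep(0, 4))
  clf2 <- train_ageing_classifier(m2, labels, panel = c("F1", "F2", "F0"),
                                  folds = 2, seed = 5)
  expect_equal(score_samples(clf, m)$score,
               score_samples(clf2, m2)$score, tolerance = 1e-9)
})

test_that("scoring is deterministic: duplicates get identical scores", {
  toy <- separable_toy()
  clf <- train_ageing_classifier(toy$x, toy$labels, folds = 2, seed = 5)
  dup <- toy$x[c(1, 1, 3, 3), ]
  sc <- score_samples(clf, dup)
  expect_identical(sc$score[1], sc$score[2])
  expect_identical(sc$score[3], sc$score[4])
})

test_that("mann_whitney matches enumeration and handles degenerate input", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(mw$u_statistic), 0)
  expect_equal(mw$p_two_sided, 0.1)  # 2 / choose(6, 3)

  same <- mann_whitney(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$p_two_sided, 1.0)

  expect_error(mann_whitney(numeric(0), 1:3),
               class = "peptiage_validation_error")

  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    u <- mann_whitney(a, b)$u_statistic
    expect_gte(u, 0)
    expect_lte(u, length(a) * length(b))
  }
})

test_that("mann_whitney rejection rate agrees with an independent oracle", {
  set.seed(82)
  reject_pkg <- 0L; reject_oracle <- 0L
  reps <- 200
  for (i in seq_len(reps)) {
    a <- rnorm(15); b <- rnorm(15, mean = 1.5)
    if (mann_whitney(a, b)$p_two_sided <= 0.05) reject_pkg <- reject_pkg + 1L
    if (mw_normal_oracle(a, b) <= 0.05) reject_oracle <- reject_oracle + 1L
  }
  expect_lt(abs(reject_pkg - reject_oracle) / reps, 0.05)
})

test_that("evaluate_age_groups produces all pairwise contrasts", {
  scores <- data.frame(sample_id = sprintf("S%d", 1:9),
                       score = c(-2, -2.2, -1.8, 0, 0.1, -0.1, 2, 2.2, 1.9))
  groups <- factor(rep(c("young", "mature", "old"), each = 3),
                   levels = c("young", "mature", "old"))
  ev <- evaluate_age_groups(scores, groups)
  expect_identical(nrow(ev), 3L)
  expect_setequal(paste(ev$group_a, ev$group_b),
                  c("young mature", "young old", "mature old"))
  yo <- ev[ev$group_a == "young" & ev$group_b == "old", ]
  expect_lt(yo$median_a, yo$median_b)

  single <- evaluate_age_groups(scores[1:3, ], factor(rep("young", 3)))
  expect_identical(nrow(single), 0L)

  expect_warning(
    ev2 <- evaluate_age_groups(scores[1:6, ],
                               factor(rep(c("young", "mature"), each = 3),
                                      levels = c("young", "mature", "old"))),
    "empty")
  expect_identical(nrow(ev2), 1L)
})
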