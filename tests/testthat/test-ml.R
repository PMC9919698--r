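test_that("median imputation fills from the training partition only", {
  tab <- data.frame(a = c(1, 2, NA, 3), Injury = c(0, 1, 0, 1))
  expect_equal(impute_median(tab)$a, c(1, 2, 2, 3))
  full <- data.frame(a = 1:4, Injury = 0:3)
  expect_identical(impute_median(full), full)
  train <- data.frame(a = c(10, 20, 30))
  test <- data.frame(a = c(1, NA, 5))      # test median would be 3
  expect_equal(impute_median(test, statistics_from = train)$a,
               c(1, 20, 5))
  allna <- data.frame(a = c(NA_real_, NA_real_))
  expect_error(impute_median(data.frame(a = c(NA_real_, 1)),
                             statistics_from = allna),
               "imputation error")
})

test_that("SMOTE interpolates between minority neighbours", {
  minority <- data.frame(x = c(0, 1))
  syn <- smote_oversample(minority, majority_count = 30, k = 1, seed = 4L)
  expect_identical(nrow(syn), 28L)
  expect_true(all(syn$x >= 0 & syn$x <= 1))
  expect_error(smote_oversample(minority, 30, k = 5), "parameter error")
  # exact balancing count for the published class sizes
  set.seed(99)
  m36 <- as.data.frame(matrix(rnorm(36 * 3), 36, 3))
  expect_identical(nrow(smote_oversample(m36, 657, seed = 1L)), 621L)
  s1 <- smote_oversample(m36, 100, seed = 7L)
  s2 <- smote_oversample(m36, 100, seed = 7L)
  expect_identical(s1, s2)
})

test_that("SMOTE points lie in the minority convex hull", {
  # collinear minority: synthetics must stay on the segment
  set.seed(5)
  t0 <- sort(runif(12))
  minority <- data.frame(x = t0, y = 2 * t0 + 1)
  syn <- smote_oversample(minority, majority_count = 120, k = 3, seed = 2L)
  expect_true(all(abs(syn$y - (2 * syn$x + 1)) < 1e-10))
  expect_true(all(syn$x >= min(t0) - 1e-12 & syn$x <= max(t0) + 1e-12))
})

test_that("the configuration carries the published defaults and validates ranges", {
  cfg <- ml_config()
  expect_identical(cfg$nrounds, 500L)
  expect_identical(cfg$max_depth, 7L)
  expect_equal(cfg$eta, 0.05)
  expect_equal(cfg$gamma, 0.01)
  expect_equal(cfg$colsample_bytree, 0.75)
  expect_equal(cfg$min_child_weight, 0)
  expect_equal(cfg$subsample, 0.50)
  expect_identical(cfg$cv_folds, 10L)
  expect_identical(cfg$cv_repeats, 5L)
  expect_error(ml_config(eta = 2), "out of range")
  expect_error(ml_config(cv_folds = 1), "cv_folds")
})

test_that("a separable signal is learned and a shuffled one is not", {
  ds <- simulate_dataset(small_config(seed = 31L, n_players = 12L,
                                      round_lengths = c(10L, 5L)))
  f <- ds$features
  f$Injury <- as.integer(!is.na(f$REG_ACWR) & f$REG_ACWR > 1.3)
  f <- f[!is.na(f$REG_ACWR), ]
  cfg <- ml_config(nrounds = 60L, cv_folds = 4L, cv_repeats = 1L,
                   seed = 3L, feature_variant = "all_without_rules")
  fit <- train_and_tune(f, cfg)
  acc_sep <- mean(fit$cv$accuracy)
  expect_gt(acc_sep, 0.9)
  set.seed(8)
  f$Injury <- sample(f$Injury)
  fit2 <- train_and_tune(f, cfg)
  expect_lt(mean(fit2$cv$accuracy), acc_sep)
  expect_gt(mean(fit2$cv$accuracy), 0.4)
})

test_that("feature variants select the documented column sets", {
  ds <- simulate_dataset(small_config(seed = 33L))
  f <- apply_ruleset(ds$features)
  cfg <- function(v) ml_config(nrounds = 20L, cv_folds = 3L,
                               cv_repeats = 1L, feature_variant = v)
  m_rules <- train_and_tune(f, cfg("rules_only"))
  expect_setequal(m_rules$feature_names,
                  c(names(default_ruleset()), "rule_mean"))
  m_all <- train_and_tune(f, cfg("all_plus_rules"))
  expect_true(all(m_rules$feature_names %in% m_all$feature_names))
  expect_true(any(grepl("^REG_", m_all$feature_names)))
  m_no <- train_and_tune(f, cfg("all_without_rules"))
  expect_false(any(grepl("^RULE_", m_no$feature_names)))
  expect_true(any(grepl("^REG_", m_no$feature_names)))
  expect_false("player_id" %in% m_all$feature_names)
})

test_that("degenerate training inputs raise errors", {
  ds <- simulate_dataset(small_config(seed = 35L))
  f <- ds$features
  f$Injury <- 0L
  expect_error(train_and_tune(f, ml_config(nrounds = 10L)),
               "single class")
  expect_error(train_and_tune(f[, setdiff(names(f), "Injury")]),
               "label column")
})

test_that("importance is gain-based, non-negative and rescaled to max 100", {
  ds <- simulate_dataset(small_config(seed = 37L))
  f <- ds$features
  f$Injury <- as.integer(!is.na(f$REG_ACWR) & f$REG_ACWR > 1.2)
  fit <- train_and_tune(f[!is.na(f$REG_ACWR), ],
                        ml_config(nrounds = 30L, cv_folds = 3L,
                                  cv_repeats = 1L,
                                  feature_variant = "all_without_rules"))
  imp <- feature_importance(fit)
  expect_equal(max(imp$importance), 100)
  expect_true(all(imp$importance >= 0))
  expect_error(feature_importance(list()), "state error")
  # a label driven solely by one column puts that column first
  one <- data.frame(REG_ACWR = runif(300, 0.3, 2))
  one$noise <- runif(300)
  one$Injury <- as.integer(one$REG_ACWR > 1.2)
  fit1 <- train_and_tune(one, ml_config(nrounds = 30L, cv_folds = 3L,
                                        cv_repeats = 1L,
                                        feature_variant = "all_without_rules"))
  expect_identical(feature_importance(fit1)$feature[1], "REG_ACWR")
})

test_that("grid search selects the better hyperparameter point", {
  ds <- simulate_dataset(small_config(seed = 39L))
  f <- ds$features
  f$Injury <- as.integer(!is.na(f$REG_ACWR) & f$REG_ACWR > 1.3)
  f <- f[!is.na(f$REG_ACWR), ]
  grid <- data.frame(nrounds = c(1L, 80L), eta = c(0.001, 0.1))
  fit <- train_and_tune(f, ml_config(cv_folds = 3L, cv_repeats = 1L,
                                     grid = grid, seed = 2L,
                                     feature_variant = "all_without_rules"))
  expect_identical(fit$best_params$nrounds, 80L)
  expect_equal(fit$best_params$eta, 0.1)
})

test_that("prediction imputes new data with training medians", {
  tr <- data.frame(a = c(rep(1, 40), rep(5, 40)),
                   b = runif(80),
                   Injury = rep(c(0L, 1L), each = 40))
  fit <- train_and_tune(tr, ml_config(nrounds = 20L, cv_folds = 3L,
                                      cv_repeats = 1L, smote_k = 3L,
                                      feature_variant = "all_without_rules"))
  nd <- data.frame(a = c(NA, 5), b = c(0.5, NA), Injury = c(NA, NA))
  p <- predict(fit, nd, type = "prob")
  expect_length(p, 2L)
  expect_true(all(p >= 0 & p <= 1))
  nd_filled <- nd
  nd_filled$a[1] <- fit$medians[["a"]]
  nd_filled$b[2] <- fit$medians[["b"]]
  expect_identical(p, predict(fit, nd_filled, type = "prob"))
})
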