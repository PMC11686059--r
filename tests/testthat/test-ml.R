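test_that("feature tables have the documented shapes", {
  et <- fake_energy_table(30)
  mt <- fake_measures_table(30)
  ftc <- build_features(et, task = "classify_state", subset = "NE")
  expect_equal(dim(ftc$x), c(30 * 7, 11))
  expect_setequal(levels(ftc$y),
                  c("working_memory", "inhibitory_control",
                    "cognitive_flexibility", "rest"))
  ft4 <- build_features(et, mt, task = "classify_state")
  expect_equal(ncol(ft4$x), 4 * 11)
  ages <- data.frame(subject_id = sprintf("s%02d", 1:30), age = 20:49)
  ftr <- build_features(et, task = "predict_age", subset = "NE", ages = ages)
  expect_equal(dim(ftr$x), c(30, 7 * 11))
  expect_equal(ftr$y, 20:49)
  # gaps are reported
  et_gap <- et[!(et$subject_id == "s01" & et$condition == "rest"), ]
  expect_error(build_features(et_gap, task = "classify_state",
                              subset = "NE"), "gap")
  expect_error(build_features(et, task = "predict_age", subset = "NE",
                              ages = ages[-1, ]), "s01")
})

test_that("state labels follow the condition mapping", {
  expect_equal(condition_state(c("nback0", "nback2", "gng_initiation",
                                 "shifting", "rest")),
               c("working_memory", "working_memory", "inhibitory_control",
                 "cognitive_flexibility", "rest"))
  expect_error(condition_state("naptime"), "naptime")
})

test_that("the separable cohort is classified perfectly", {
  rep <- separable_report()
  expect_equal(rep$balanced_accuracy, 1.0)
  expect_equal(unname(rowSums(rep$confusion)), rep(100, 4))
  expect_true(all(rep$tuned_C %in% 2^(-2:7)))
})

test_that("no training-fold statistic uses the held-out subject", {
  rep <- separable_report()
  ft <- rep$ft
  for (s in names(rep$folds)[1:3]) {
    f <- rep$folds[[s]]
    train <- ft$x[ft$subject != s, , drop = FALSE]
    expect_equal(unname(f$center), unname(colMeans(train)), tolerance = 1e-12)
    expect_equal(unname(f$scale), unname(apply(train, 2, sd)), tolerance = 1e-12)
    # and they differ from the all-data statistics
    expect_false(isTRUE(all.equal(unname(f$center), unname(colMeans(ft$x)))))
  }
})

test_that("a null cohort stays within the permutation chance band", {
  co <- null_cohort()
  et <- energy_table(co, co$parcellation)
  ft <- build_features(et, task = "classify_state", subset = "NE")
  rep <- classify_states(ft, seed = 12)
  band <- permutation_chance_band(rep, n_perms = 200, seed = 13)
  expect_true(band$within_chance)
  expect_lt(abs(mean(band$null) - 0.25), 0.05)
})

test_that("energy features outperform noise comparators when only energy is informative", {
  co <- separable_cohort()
  et <- energy_table(co, co$parcellation)
  mt <- fake_measures_table(12)                     # pure noise comparators
  mt$subject_id <- sprintf("sub%03d", as.integer(sub("^s", "", mt$subject_id)))
  ft_ne <- build_features(et, task = "classify_state", subset = "NE")
  ft_gcc <- build_features(et, mt, task = "classify_state", subset = "GCC")
  rep_ne <- classify_states(ft_ne, seed = 21)
  rep_gcc <- classify_states(ft_gcc, seed = 21)
  expect_gt(rep_ne$balanced_accuracy, rep_gcc$balanced_accuracy)
})

test_that("the planted feature dominates permutation importance", {
  set.seed(30)
  n_sub <- 10
  subj <- rep(sprintf("s%02d", 1:n_sub), each = 4)
  y <- factor(rep(c("a", "b", "c", "d"), n_sub))
  x <- cbind(signal = as.integer(y) + rnorm(length(y), 0, 0.05),
             noise1 = rnorm(length(y)), noise2 = rnorm(length(y)))
  ft <- structure(list(x = x, y = y, subject = subj, condition = NULL,
                       task = "classify_state", subset = "NE"),
                  class = "feature_table")
  rep <- classify_states(ft, seed = 31)
  imp <- feature_importance(rep, n_shuffles = 20, seed = 32)
  expect_equal(imp$feature[1], "signal")
  expect_lt(max(abs(imp$importance[imp$feature != "signal"])), 0.1)
  imp2 <- feature_importance(rep, n_shuffles = 20, seed = 32)
  expect_identical(imp, imp2)
})

test_that("age regression reaches the separable limit and fails on noise", {
  set.seed(40)
  age <- runif(16, 20, 86)
  ft <- structure(list(x = matrix(age, ncol = 1,
                                  dimnames = list(NULL, "NE.whole_brain.rest")),
                       y = age, subject = sprintf("s%02d", 1:16),
                       condition = NULL, task = "predict_age", subset = "NE"),
                  class = "feature_table")
  rep <- predict_age(ft, seed = 41)
  expect_gte(rep$r2, 0.99)
  expect_lte(rep$mae, 1)
  # feature rescaling changes nothing (per-fold z-scoring contract)
  ft2 <- ft; ft2$x <- ft2$x * 1000
  rep2 <- predict_age(ft2, seed = 41)
  # invariance holds to the SMO duality-gap tolerance, not exactly
  expect_equal(rep2$predictions$predicted, rep$predictions$predicted,
               tolerance = 1e-3)
  expect_equal(rep2$mae, rep$mae, tolerance = 0.02)
  # pure-noise features carry no age signal
  ftn <- ft
  ftn$x <- matrix(rnorm(16 * 5), 16, 5,
                  dimnames = list(NULL, paste0("NE.n", 1:5)))
  repn <- predict_age(ftn, seed = 42)
  expect_lt(repn$r2, 0.5)     # squared correlation is noisy at n = 16
  ftc <- ft; ftc$y <- rep(50, 16)
  expect_error(predict_age(ftc, seed = 43), "constant")
})
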