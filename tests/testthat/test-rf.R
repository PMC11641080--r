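# Small planted four-class cohort used across RF tests: clear single-site
# shifts per class plus the study-like treatment covariates.
planted_rf_cohort <- function(n_per_class = 40L, seed = 91L,
                              sex_indep = TRUE) {
  spec <- cohort_spec_study(
    class_sizes = setNames(rep(n_per_class, 4), c("CTRL", "BD", "SZ", "SA")),
    site_panel = default_site_panel(sites_per_gene = 2),
    group_effects = list(
      BD = c(CAMK1D_s1 = -2, GAB2_s1 = 2),
      SZ = c(KCNJ15_s1 = 2, LYN_s1 = 2),
      SA = c(KCNJ15_s1 = 2, IFNAR1_s1 = -2, PDE8A_s1 = 2)
    ),
    sex_prevalence = if (sex_indep) {
      c(CTRL = 0.5, BD = 0.5, SZ = 0.5, SA = 0.5)
    } else NULL,
    seed = seed
  )
  generate_cohort(spec)
}

test_that("the stratified split takes the per-class ceiling exactly", {
  labels <- factor(rep(c("CTRL", "BD", "SZ", "SA"),
                       times = c(85, 39, 31, 14)),
                   levels = c("CTRL", "BD", "SZ", "SA"))
  sp <- stratified_split(labels, 0.7, seed = 1L)
  expect_length(sp$train, 120)  # 60 + 28 + 22 + 10
  expect_length(sp$test, 49)
  per_class <- table(labels[sp$train])
  expect_equal(as.integer(per_class[c("CTRL", "BD", "SZ", "SA")]),
               c(60, 28, 22, 10))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # reproducible given the seed, different otherwise
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1L))
  expect_false(identical(sp$train,
                         stratified_split(labels, 0.7, seed = 2L)$train))
})

test_that("split edge cases behave", {
  sp <- stratified_split(factor(rep(c("A", "B"), each = 10)), 0.5, seed = 3L)
  expect_equal(as.integer(table(factor(rep(c("A", "B"), each = 10))[sp$train])),
               c(5, 5))
  expect_error(stratified_split(factor(c("A", "B", "C", "D")), 0.7),
               "empty test set")
})

test_that("covariate encoding is a six-column binary block", {
  cohort <- tibble::tibble(
    sample = c("P1", "P2"), sex = c("M", "F"),
    antipsychotics = c(1L, 0L), antidepressants = c(0L, 0L),
    anxiolytics = c(0L, 0L), antiepileptics = c(0L, 1L),
    hypnotics = c(0L, 0L)
  )
  enc <- encode_covariates(cohort)
  expect_equal(ncol(enc), 6)
  expect_equal(unname(unlist(enc[1, ])), c(1, 1, 0, 0, 0, 0))
  expect_error(encode_covariates(dplyr::mutate(cohort, sex = c("M", "x"))),
               "P2")
  expect_error(encode_covariates(cohort[, -3]), "antipsychotics")
})

test_that("generated covariates match the configured prevalences", {
  co <- generate_cohort(cohort_spec_study(
    site_panel = default_site_panel(1), seed = 92L))
  enc <- encode_covariates(co$cohort)
  spec <- cohort_spec_study()
  for (cl in diagnosis_levels()) {
    idx <- co$cohort$diagnosis == cl
    n <- sum(idx)
    for (tc in treatment_classes()) {
      prev <- spec$treatment_prevalence[[cl]][[tc]]
      expect_lte(abs(mean(enc[[tc]][idx]) - prev),
                 3 * sqrt(prev * (1 - prev) / n) + 1e-9)
    }
  }
})

test_that("vote vectors are normalized probabilities with schema invariance", {
  co <- planted_rf_cohort(30L)
  X <- dplyr::bind_cols(co$biomarkers[, -1], encode_covariates(co$cohort))
  y <- co$cohort$diagnosis
  cfg <- rf_config(ntree = 200, mtry_grid = c(2, 4), seed = 5L)
  model <- train_rf(X, y, cfg)
  votes <- predict_votes(model, X)
  expect_true(all(abs(rowSums(votes) - 1) < 1e-9))
  expect_true(all(votes >= 0))
  # shuffled column order leaves predictions unchanged
  votes2 <- predict_votes(model, X[, rev(seq_len(ncol(X)))])
  expect_identical(votes, votes2)
  expect_error(predict_votes(model, X[, -3]),
               names(X)[3])
  # training points deep inside pure clusters get confident votes
  expect_gt(mean(apply(votes, 1, max)), 0.7)
})

test_that("mtry is chosen from the grid by OOB accuracy", {
  co <- planted_rf_cohort(25L)
  X <- dplyr::bind_cols(co$biomarkers[, -1], encode_covariates(co$cohort))
  cfg <- rf_config(ntree = 150, mtry_grid = c(1, 4, 8), seed = 6L)
  model <- train_rf(X, co$cohort$diagnosis, cfg)
  expect_true(model$mtry %in% c(1, 4, 8))
  expect_equal(unname(model$oob_accuracy[as.character(model$mtry)]),
               max(model$oob_accuracy))
  expect_error(train_rf(X[1:5, ], factor(rep("CTRL", 5))), ">= 2 classes")
})

test_that("multiclass evaluation computes confusion, accuracy and per-class rates", {
  truth <- factor(rep(c("CTRL", "BD", "SZ", "SA"), each = 5),
                  levels = c("CTRL", "BD", "SZ", "SA"))
  perfect <- evaluate_multiclass(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(sum(diag(perfect$confusion)), 20)
  expect_true(all(perfect$per_class$sensitivity == 1))
  all_ctrl <- evaluate_multiclass(factor(rep("CTRL", 20),
                                         levels = levels(truth)), truth)
  expect_equal(all_ctrl$per_class$sensitivity,
               c(1, 0, 0, 0))
  expect_error(evaluate_multiclass(rep("XX", 20), truth), "outside")
  # random predictions on balanced classes hover near 1/4
  withr::with_seed(7L, {
    pred <- factor(sample(levels(truth), 400, replace = TRUE),
                   levels = levels(truth))
    truth400 <- factor(rep(levels(truth), each = 100),
                       levels = levels(truth))
  })
  acc <- evaluate_multiclass(pred, truth400)$accuracy
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
})

test_that("the integrated protocol reaches high held-out accuracy on strong signal", {
  co <- planted_rf_cohort(40L, seed = 93L)
  cfg <- rf_config(ntree = 500, mtry_grid = c(2, 4, 6, 8), seed = 8L)
  rep <- rf_integrate(co$biomarkers, co$cohort, config = cfg)
  expect_gte(rep$accuracy, 0.9)
  expect_true(all(abs(rowSums(rep$votes) - 1) < 1e-9))
  g <- glance(rep)
  expect_equal(g$n_train + g$n_test, nrow(co$cohort))
})

test_that("pure-noise features give chance-level held-out accuracy", {
  withr::with_seed(94L, {
    n <- 160
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    y <- factor(rep(c("A", "B"), each = n / 2))
  })
  sp <- stratified_split(y, 0.7, seed = 9L)
  model <- train_rf(X[sp$train, ], y[sp$train],
                    rf_config(ntree = 300, mtry_grid = 1:3, seed = 9L))
  votes <- predict_votes(model, X[sp$test, ])
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  acc <- mean(pred == y[sp$test])
  n_test <- length(sp$test)
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / n_test) + 1e-9)
})

test_that("importance indicators expose planted structure", {
  # every biomarker and treatment informative, sex independent of class:
  # the near-universal antipsychotics flag should dominate the tree roots
  # and sex should fall to the bottom of the permutation ranking
  co <- generate_cohort(importance_design_spec(903L))
  X <- dplyr::bind_cols(co$biomarkers[, -1], encode_covariates(co$cohort))
  y <- co$cohort$diagnosis
  sp <- stratified_split(y, 0.7, seed = 10L)
  model <- train_rf(X[sp$train, ], y[sp$train],
                    rf_config(ntree = 500, mtry_grid = 4, seed = 10L))
  imp <- feature_importance(model, X[sp$test, ], y[sp$test], seed = 10L)
  expect_setequal(imp$feature, names(X))
  sex_v <- imp$permutation_importance[imp$feature == "sex_male"]
  expect_lte(sex_v, min(imp$permutation_importance[imp$feature != "sex_male"]))
  # the dominant binary covariate also sits shallow in the trees
  expect_lt(imp$mean_min_depth[imp$feature == "antipsychotics"],
            median(imp$mean_min_depth))
  expect_equal(sum(imp$times_a_root), model$model$ntree)

  # sparse-signal design: the near-deterministic antipsychotics flag is
  # the most frequent root split
  co2 <- generate_cohort(root_dominance_spec(901L))
  X2 <- dplyr::bind_cols(co2$biomarkers[, -1], encode_covariates(co2$cohort))
  y2 <- co2$cohort$diagnosis
  sp2 <- stratified_split(y2, 0.7, seed = 11L)
  model2 <- train_rf(X2[sp2$train, ], y2[sp2$train],
                     rf_config(ntree = 500, mtry_grid = 4, seed = 11L))
  imp2 <- feature_importance(model2, X2[sp2$test, ], y2[sp2$test],
                             seed = 11L)
  expect_equal(imp2$feature[which.max(imp2$times_a_root)], "antipsychotics")
})

test_that("constant features get zero importance and never split a root", {
  withr::with_seed(96L, {
    X <- data.frame(flat = rep(0.5, 120),
                    signal = c(rnorm(60), rnorm(60, 2)))
    y <- factor(rep(c("A", "B"), each = 60))
  })
  model <- train_rf(X, y, rf_config(ntree = 200, mtry_grid = 1:2, seed = 11L))
  imp <- feature_importance(model, X, y, seed = 11L)
  expect_equal(imp$times_a_root[imp$feature == "flat"], 0)
  expect_lte(abs(imp$permutation_importance[imp$feature == "flat"]), 0.02)
})
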