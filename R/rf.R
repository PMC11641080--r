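#' Random-forest protocol configuration
#'
#' Mirrors the study protocol: 1000 trees, terminal nodes of size 1, mtry
#' tuned on the 1..20 grid by out-of-bag accuracy, and a stratified 70/30
#' train/test split.
#'
#' @param ntree Trees per forest.
#' @param nodesize Minimal terminal node size.
#' @param mtry_grid Candidate numbers of variables tried at each split
#'   (clipped to the number of features at fit time).
#' @param train_fraction Per-class training fraction of the stratified
#'   split.
#' @param seed Integer seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(ntree = 1000, nodesize = 1, mtry_grid = 1:20,
                      train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, all(mtry_grid >= 1))
  structure(list(ntree = as.integer(ntree), nodesize = as.integer(nodesize),
                 mtry_grid = as.integer(mtry_grid),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "rf_config")
}

#' Stratified train/test split
#'
#' Per class, draws `ceiling(fraction * n_class)` samples without
#' replacement into the training set; the remainder form the test set.
#'
#' @param labels Class labels.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, fraction = 0.7, seed = 1L) {
  labels <- factor(labels)
  if (any(table(labels) == 0)) abort("every class must be non-empty")
  train <- integer(0)
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_train <- ceiling(fraction * length(idx))
      # sample() would misread a length-1 idx as 1:idx
      picked <- if (length(idx) == 1L) idx else sample(idx, n_train)
      train <- c(train, sort(picked))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  if (length(test) == 0) {
    abort("split leaves an empty test set; lower the training fraction")
  }
  list(train = train, test = test)
}

#' Encode cohort covariates for modeling
#'
#' @param cohort Cohort tibble with `sex` (`"M"`/`"F"`) and the five
#'   treatment flag columns.
#' @return Tibble with 6 binary columns: `sex_male` plus the five ATC
#'   treatment classes.
#' @export
encode_covariates <- function(cohort) {
  need <- c("sex", TREATMENT_CLASSES)
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort lacks covariate column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- !cohort$sex %in% c("M", "F")
  if (any(bad)) {
    abort(paste0("unknown sex category for sample(s): ",
                 paste(cohort$sample[bad], collapse = ", ")))
  }
  out <- tibble(sex_male = as.integer(cohort$sex == "M"))
  for (tc in TREATMENT_CLASSES) {
    v <- cohort[[tc]]
    if (any(!v %in% c(0, 1))) {
      abort(paste0("treatment flag ", tc, " must be binary (0/1)"))
    }
    out[[tc]] <- as.integer(v)
  }
  out
}

#' Train the multiclass random forest with OOB mtry tuning
#'
#' For each candidate mtry, fits a forest (`ntree` trees, `nodesize` 1)
#' and records its out-of-bag accuracy; the mtry maximizing OOB accuracy
#' is chosen (ties to the smallest value) and the final model refit at it.
#' Missing feature values are median-imputed (medians learned on the
#' supplied training data and stored for prediction).
#'
#' @param features Data frame of numeric features (biomarkers +
#'   covariates), training samples in rows.
#' @param labels Training class labels (>= 2 classes).
#' @param config An [rf_config()].
#' @return A list of class `rf_model`: the fitted `randomForest`, chosen
#'   mtry, the OOB accuracy grid, feature schema and imputation medians.
#' @export
train_rf <- function(features, labels, config = rf_config()) {
  X <- feature_block(features)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("training labels must span >= 2 classes")
  stopifnot(nrow(X) == length(labels))
  medians <- vapply(X, function(v) median(v, na.rm = TRUE), numeric(1))
  for (j in seq_along(X)) {
    v <- X[[j]]
    if (anyNA(v)) X[[j]] <- ifelse(is.na(v), medians[[j]], v)
  }
  grid <- unique(pmin(config$mtry_grid, ncol(X)))
  oob <- vapply(grid, function(m) {
    fit <- withr::with_seed(config$seed, randomForest::randomForest(
      x = X, y = labels, ntree = config$ntree,
      nodesize = config$nodesize, mtry = m
    ))
    1 - fit$err.rate[config$ntree, "OOB"]
  }, numeric(1))
  chosen <- grid[which.max(oob)]  # which.max takes the first = smallest mtry
  model <- withr::with_seed(config$seed, randomForest::randomForest(
    x = X, y = labels, ntree = config$ntree,
    nodesize = config$nodesize, mtry = chosen, importance = TRUE
  ))
  structure(list(model = model, mtry = chosen,
                 oob_accuracy = setNames(oob, grid),
                 schema = names(X), medians = medians,
                 classes = levels(labels), config = config),
            class = "rf_model")
}

#' Per-sample class vote probabilities
#'
#' Returns the fraction of the forest's trees voting for each class;
#' vote vectors are non-negative and sum to one, and the predicted class
#' is the argmax.
#'
#' @param object An `rf_model`.
#' @param newdata Feature data frame (columns may be in any order; must
#'   contain the training schema).
#' @return Matrix (samples x classes) of vote fractions.
#' @export
predict_votes <- function(object, newdata) {
  X <- feature_block(newdata)
  missing <- setdiff(object$schema, names(X))
  if (length(missing) > 0) {
    abort(paste0("missing feature column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- X[, object$schema, drop = FALSE]
  for (j in seq_along(X)) {
    v <- X[[j]]
    if (anyNA(v)) X[[j]] <- ifelse(is.na(v), object$medians[[j]], v)
  }
  votes <- predict(object$model, X, type = "vote", norm.votes = TRUE)
  unclass(votes)
}

#' Multiclass confusion and performance
#'
#' @param predictions Predicted class labels.
#' @param truth True class labels over the same label set.
#' @return A list: `confusion` (truth in rows), `accuracy`, `per_class`
#'   (tibble with one-vs-rest sensitivity and specificity).
#' @export
evaluate_multiclass <- function(predictions, truth) {
  truth <- factor(truth)
  lev <- levels(truth)
  bad <- setdiff(unique(as.character(predictions)), lev)
  if (length(bad) > 0) {
    abort(paste0("prediction label(s) outside the truth set: ",
                 paste(bad, collapse = ", ")))
  }
  predictions <- factor(as.character(predictions), levels = lev)
  if (length(predictions) != length(truth)) {
    abort("predictions and truth must have the same length")
  }
  confusion <- table(truth = truth, predicted = predictions)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  per_class <- purrr::map_dfr(lev, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- sum(confusion) - tp - fn - fp
    tibble(class = cl,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  list(confusion = confusion, accuracy = accuracy, per_class = per_class)
}

#' Multi-indicator feature importance
#'
#' Reports complementary importance indicators per feature: permutation
#' importance (the forest's out-of-bag accuracy drop when the feature is
#' permuted, averaged over trees), an accuracy drop on held-out data when
#' the feature's column is permuted, mean impurity (Gini) decrease, mean
#' minimal depth of the feature's first split over trees (trees not using
#' it contribute the tree's depth + 1 as a penalty), and the number of
#' trees whose root splits on it.
#'
#' @param object An `rf_model`.
#' @param newdata Held-out feature data for the held-out permutation drop.
#' @param truth Held-out labels.
#' @param n_perm Permutation repetitions averaged per feature for the
#'   held-out drop.
#' @param seed Seed for the held-out permutations.
#' @return Tibble: `feature`, `permutation_importance`,
#'   `test_accuracy_drop`, `impurity_decrease`, `mean_min_depth`,
#'   `times_a_root`.
#' @export
feature_importance <- function(object, newdata, truth, n_perm = 5L,
                               seed = 1L) {
  X <- feature_block(newdata)[, object$schema, drop = FALSE]
  truth <- factor(truth, levels = object$classes)
  base_acc <- mean(predict_class(object, X) == truth)
  perm <- withr::with_seed(seed, vapply(object$schema, function(f) {
    drops <- vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[[f]] <- sample(Xp[[f]])
      base_acc - mean(predict_class(object, Xp) == truth)
    }, numeric(1))
    mean(drops)
  }, numeric(1)))

  oob_perm <- randomForest::importance(object$model, type = 1,
                                       scale = FALSE)[, 1]
  gini <- randomForest::importance(object$model, type = 2)[, 1]

  depth_stats <- tree_depth_stats(object)
  tibble(
    feature = object$schema,
    permutation_importance = unname(oob_perm[object$schema]),
    test_accuracy_drop = unname(perm[object$schema]),
    impurity_decrease = unname(gini[object$schema]),
    mean_min_depth = unname(depth_stats$mean_min_depth[object$schema]),
    times_a_root = unname(depth_stats$times_a_root[object$schema])
  )
}

predict_class <- function(object, X) {
  votes <- predict_votes(object, X)
  factor(colnames(votes)[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

## Walk every tree of the forest: node depths by parent traversal, first
## (minimal) split depth per variable, and root-variable counts.
tree_depth_stats <- function(object) {
  schema <- object$schema
  ntree <- object$model$ntree
  min_depth_sum <- setNames(rep(0, length(schema)), schema)
  root_count <- setNames(rep(0L, length(schema)), schema)
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(object$model, k, labelVar = TRUE)
    n_nodes <- nrow(tr)
    depth <- rep(NA_real_, n_nodes)
    depth[1] <- 0
    for (i in seq_len(n_nodes)) {
      l <- tr[i, "left daughter"]; r <- tr[i, "right daughter"]
      if (l > 0) depth[l] <- depth[i] + 1
      if (r > 0) depth[r] <- depth[i] + 1
    }
    split_var <- as.character(tr[, "split var"])
    is_split <- tr[, "status"] == 1
    tree_depth <- max(depth, na.rm = TRUE)
    md <- tapply(depth[is_split], split_var[is_split], min)
    used <- intersect(names(md), schema)
    penalty <- setNames(rep(tree_depth + 1, length(schema)), schema)
    penalty[used] <- md[used]
    min_depth_sum <- min_depth_sum + penalty
    rv <- split_var[1]
    if (!is.na(rv) && rv %in% schema) root_count[rv] <- root_count[rv] + 1L
  }
  list(mean_min_depth = min_depth_sum / ntree, times_a_root = root_count)
}

#' Run the full integrated random-forest protocol
#'
#' Combines the selected biomarkers with the encoded covariates, applies
#' the stratified 70/30 split, tunes and fits the forest on the training
#' set, and evaluates once on the held-out test set.
#'
#' @param data Biomarker values (wide tibble or `biomarker_matrix`).
#' @param cohort Cohort tibble (`sample`, `diagnosis`, `sex`, treatment
#'   flags).
#' @param features Biomarker ids to use (default: all feature columns).
#' @param config An [rf_config()].
#' @return A list of class `rf_report`: `split`, `model`, `votes` (test-set
#'   vote matrix), `confusion`, `accuracy`, `per_class`, `importance`.
#' @export
rf_integrate <- function(data, cohort, features = NULL,
                         config = rf_config()) {
  values <- as_biomarker_values(data)
  stopifnot(identical(values$sample, cohort$sample))
  features <- features %||% names(feature_block(values))
  X <- bind_cols(values[, features, drop = FALSE],
                 encode_covariates(cohort))
  y <- as_diagnosis(cohort$diagnosis)
  split <- stratified_split(y, config$train_fraction, config$seed)
  model <- train_rf(X[split$train, , drop = FALSE], y[split$train], config)
  votes <- predict_votes(model, X[split$test, , drop = FALSE])
  pred <- factor(colnames(votes)[max.col(votes, ties.method = "first")],
                 levels = levels(y))
  eval <- evaluate_multiclass(pred, y[split$test])
  imp <- feature_importance(model, X[split$test, , drop = FALSE],
                            y[split$test], seed = config$seed)
  structure(list(split = split, model = model, votes = votes,
                 predictions = pred, truth = y[split$test],
                 confusion = eval$confusion, accuracy = eval$accuracy,
                 per_class = eval$per_class, importance = imp),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("<rf_report> test accuracy ", sprintf("%.3f", x$accuracy),
      " (mtry ", x$model$mtry, ")\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.rf_report <- function(x, ...) {
  arrange(x$importance, dplyr::desc(.data$permutation_importance))
}

#' @export
glance.rf_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, mtry = x$model$mtry,
         ntree = x$model$config$ntree,
         n_train = length(x$split$train), n_test = length(x$split$test))
}
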