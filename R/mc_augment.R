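#' Fit the Monte-Carlo synthetic-data generator
#'
#' Learns, per diagnostic class, the mean vector and covariance of the
#' logit-transformed biomarkers (proportions clamped away from 0/1), with
#' ridge-style shrinkage towards the diagonal,
#' `(1 - gamma) S + gamma diag(S)`, taking the smallest shrinkage weight
#' that brings the condition number at or below `cond_max`. Covariates
#' (sex, treatments) are modeled as independent Bernoulli at the observed
#' per-class prevalence. Class allocation weights are the observed class
#' fractions.
#'
#' @param data Biomarker values in `[0, 1]` (wide tibble,
#'   `biomarker_matrix` or `synthetic_cohort`).
#' @param cohort Cohort tibble aligned with the data rows.
#' @param clamp Clamping epsilon before the logit (default 1e-4).
#' @param cond_max Maximal tolerated covariance condition number.
#' @return A list of class `mc_generator`.
#' @export
fit_mc_generator <- function(data, cohort, clamp = 1e-4, cond_max = 1e6) {
  values <- as_biomarker_values(data)
  stopifnot(nrow(values) == nrow(cohort))
  X <- as.matrix(feature_block(values))
  y <- as_diagnosis(cohort$diagnosis)
  tab <- table(y)
  small <- names(tab)[tab < 5 & tab > 0]
  if (length(small) > 0) {
    abort(paste0("class(es) below 5 samples: ", paste(small, collapse = ", ")))
  }
  classes <- names(tab)[tab > 0]
  cov_cols <- intersect(c("sex", TREATMENT_CLASSES), names(cohort))

  per_class <- lapply(classes, function(cl) {
    Xi <- logit(clamp01(X[y == cl, , drop = FALSE], clamp))
    S <- var(Xi)
    gammas <- seq(0, 1, by = 0.01)
    gamma <- NA_real_
    for (g in gammas) {
      Sg <- (1 - g) * S + g * diag(diag(S))
      if (kappa(Sg, exact = TRUE) <= cond_max) { gamma <- g; break }
    }
    if (is.na(gamma)) { gamma <- 1; Sg <- diag(diag(S)) }
    Sg <- (1 - gamma) * S + gamma * diag(diag(S))
    prev <- list()
    if ("sex" %in% cov_cols) prev$sex_male <- mean(cohort$sex[y == cl] == "M")
    for (tc in intersect(TREATMENT_CLASSES, cov_cols)) {
      prev[[tc]] <- mean(cohort[[tc]][y == cl])
    }
    list(mean = colMeans(Xi), cov = Sg, gamma = gamma, prevalence = prev)
  })
  names(per_class) <- classes
  structure(list(classes = per_class,
                 weights = as.numeric(tab[classes]) / sum(tab[classes]),
                 class_names = classes,
                 features = colnames(X), clamp = clamp),
            class = "mc_generator")
}

#' Largest-remainder apportionment
#'
#' Allocates `n` integer draws across classes proportionally to `weights`:
#' each class gets the floor of its quota, and leftover units go to the
#' largest fractional remainders.
#'
#' @param n Total count.
#' @param weights Non-negative weights (normalized internally).
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  quota <- n * w
  alloc <- floor(quota)
  left <- n - sum(alloc)
  if (left > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(left)]
    alloc[extra] <- alloc[extra] + 1
  }
  as.integer(alloc)
}

#' Draw synthetic samples from a fitted generator
#'
#' Class counts follow largest-remainder apportionment of `n` over the
#' generator's class weights. Biomarkers are multivariate-normal draws on
#' the logit scale mapped back through the inverse logit; covariates are
#' independent Bernoulli draws at the fitted prevalences.
#'
#' @param gen An `mc_generator`.
#' @param n Number of synthetic samples (default 500).
#' @param seed Integer seed.
#' @return A list with `biomarkers` (wide tibble; values in `[0, 1]`) and
#'   `cohort` (tibble `sample`, `diagnosis`, `sex`, treatment flags).
#' @export
sample_synthetic <- function(gen, n = 500, seed = 1L) {
  stopifnot(inherits(gen, "mc_generator"))
  if (n < length(gen$class_names)) {
    abort("n must be at least the number of classes")
  }
  counts <- largest_remainder(n, gen$weights)
  withr::with_seed(seed, {
    parts <- purrr::map2(gen$class_names, counts, function(cl, k) {
      if (k == 0) return(NULL)
      g <- gen$classes[[cl]]
      Z <- MASS::mvrnorm(k, mu = g$mean, Sigma = g$cov)
      if (k == 1) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, names(g$mean)))
      P <- inv_logit(Z)
      cov <- tibble(diagnosis = cl)
      cov <- cov[rep(1, k), , drop = FALSE]
      if (!is.null(g$prevalence$sex_male)) {
        cov$sex <- ifelse(runif(k) < g$prevalence$sex_male, "M", "F")
      }
      for (tc in intersect(TREATMENT_CLASSES, names(g$prevalence))) {
        cov[[tc]] <- as.integer(runif(k) < g$prevalence[[tc]])
      }
      list(P = P, cov = cov)
    })
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  P <- do.call(rbind, lapply(parts, `[[`, "P"))
  colnames(P) <- gen$features
  cov <- bind_rows(lapply(parts, `[[`, "cov"))
  ids <- sprintf("MC%04d", seq_len(nrow(P)))
  list(
    biomarkers = bind_cols(tibble(sample = ids),
                           as_tibble(P, .name_repair = "minimal")),
    cohort = bind_cols(tibble(sample = ids), cov) |>
      mutate(diagnosis = factor(.data$diagnosis, levels = gen$class_names))
  )
}

#' Validate synthetic data against the original
#'
#' Per class and feature, compares synthetic against original data on
#' three fidelity metrics: absolute mean difference in pooled-SD units,
#' SD ratio (synthetic / original), and the maximum absolute difference of
#' the feature's correlations with the other features. A cell passes when
#' all three fall within the thresholds.
#'
#' @param original,synthetic Lists with aligned `biomarkers` and `cohort`
#'   elements (e.g. a `synthetic_cohort` and the output of
#'   [sample_synthetic()]), or wide value tibbles plus `labels_*`
#'   arguments.
#' @param max_mean_shift Mean-difference threshold in pooled-SD units
#'   (default 0.3).
#' @param sd_ratio_range Allowed SD ratio interval (default 0.7..1.4).
#' @param max_corr_delta Allowed correlation difference (default 0.25).
#' @return A tibble of class `mc_fidelity` (`class`, `feature`, `mean_z`,
#'   `sd_ratio`, `max_corr_delta`, `pass`) with attribute `pass` (all
#'   cells pass).
#' @export
validate_synthetic <- function(original, synthetic,
                               max_mean_shift = 0.3,
                               sd_ratio_range = c(0.7, 1.4),
                               max_corr_delta = 0.25) {
  ov <- as_biomarker_values(if (is.list(original) && !is.data.frame(original))
    original$biomarkers else original)
  sv <- as_biomarker_values(if (is.list(synthetic) && !is.data.frame(synthetic))
    synthetic$biomarkers else synthetic)
  ol <- original$cohort$diagnosis
  sl <- synthetic$cohort$diagnosis
  feats <- setdiff(names(ov), "sample")
  if (!setequal(feats, setdiff(names(sv), "sample"))) {
    abort("original and synthetic tables must share the same feature schema")
  }
  sv <- sv[, c(intersect(names(sv), "sample"), feats)]

  classes <- intersect(unique(as.character(ol)), unique(as.character(sl)))
  out <- purrr::map_dfr(classes, function(cl) {
    O <- as.matrix(ov[ol == cl, feats, drop = FALSE])
    S <- as.matrix(sv[sl == cl, feats, drop = FALSE])
    mo <- colMeans(O, na.rm = TRUE); ms <- colMeans(S, na.rm = TRUE)
    so <- apply(O, 2, sd, na.rm = TRUE); ss <- apply(S, 2, sd, na.rm = TRUE)
    pooled <- sqrt((so^2 + ss^2) / 2)
    co <- suppressWarnings(cor(O, use = "pairwise.complete.obs"))
    cs <- suppressWarnings(cor(S, use = "pairwise.complete.obs"))
    dc <- abs(co - cs)
    diag(dc) <- 0
    dc[!is.finite(dc)] <- 0
    tibble(
      class = cl, feature = feats,
      mean_z = abs(ms - mo) / ifelse(pooled > 0, pooled, 1),
      sd_ratio = ifelse(so > 0, ss / so, 1),
      max_corr_delta = apply(dc, 1, max)
    )
  }) |>
    mutate(pass = .data$mean_z <= max_mean_shift &
             .data$sd_ratio >= sd_ratio_range[1] &
             .data$sd_ratio <= sd_ratio_range[2] &
             .data$max_corr_delta <= !!max_corr_delta)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("mc_fidelity", class(out))
  out
}

#' Prediction-error estimate on synthetic data
#'
#' Scores the fitted classifier on Monte-Carlo synthetic samples and
#' reports the misclassification rate overall and per class with exact
#' binomial 95% confidence intervals.
#'
#' @param model An `rf_model` (or `rf_report`, whose model is used).
#' @param synthetic Output of [sample_synthetic()].
#' @return Tibble with `1 + n_classes` rows: `scope`, `n`, `error`,
#'   `ci_lower`, `ci_upper`.
#' @export
estimate_prediction_error <- function(model, synthetic) {
  if (inherits(model, "rf_report")) model <- model$model
  stopifnot(inherits(model, "rf_model"))
  X <- bind_cols(synthetic$biomarkers[, -1, drop = FALSE],
                 encode_covariates(synthetic$cohort))
  pred <- predict_class(model, X)
  truth <- factor(as.character(synthetic$cohort$diagnosis),
                  levels = model$classes)
  wrong <- pred != truth
  ci <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(k, n)$conf.int)
  }
  overall <- ci(sum(wrong), length(wrong))
  out <- tibble(scope = "overall", n = length(wrong),
                error = mean(wrong), ci_lower = overall[1],
                ci_upper = overall[2])
  per <- purrr::map_dfr(model$classes, function(cl) {
    idx <- truth == cl
    cc <- ci(sum(wrong[idx]), sum(idx))
    tibble(scope = cl, n = sum(idx),
           error = if (any(idx)) mean(wrong[idx]) else NA_real_,
           ci_lower = cc[1], ci_upper = cc[2])
  })
  bind_rows(out, per)
}
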