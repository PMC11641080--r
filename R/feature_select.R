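#' Feature-selection configuration
#'
#' @param corr_cutoff Absolute Pearson correlation above which one member
#'   of a feature pair is pruned (default 0.6).
#' @param raw_p_cutoff Raw p-value cutoff for the univariate filter
#'   (default 0.05).
#' @param fdr_cutoff BH-adjusted significance level used in reports
#'   (default 0.1).
#' @param boruta_max_runs Maximum shadow-importance runs (default 100).
#' @param boruta_alpha Two-sided binomial-test level for Confirmed /
#'   Rejected decisions (default 0.01).
#' @param boruta_ntree Trees per shadow-importance forest (default 100).
#' @param normality_alpha Level of the Shapiro-Wilk and variance-ratio
#'   gates in the adaptive differential test (default 0.05).
#' @return A list of class `fs_config`.
#' @export
fs_config <- function(corr_cutoff = 0.6, raw_p_cutoff = 0.05,
                      fdr_cutoff = 0.1, boruta_max_runs = 100,
                      boruta_alpha = 0.01, boruta_ntree = 100,
                      normality_alpha = 0.05) {
  stopifnot(corr_cutoff > 0, corr_cutoff < 1,
            raw_p_cutoff > 0, raw_p_cutoff < 1,
            fdr_cutoff > 0, fdr_cutoff < 1)
  structure(as.list(environment()), class = "fs_config")
}

#' Adaptive two-group differential test
#'
#' Chooses the test from the data: if both groups pass a Shapiro-Wilk
#' normality check, an F-test compares variances and Student's (equal
#' variance) or Welch's t-test is applied; otherwise the two-sided
#' Mann-Whitney rank-sum test with tie correction.
#'
#' @param x,y Numeric values of the two groups (missing values dropped).
#' @param config An [fs_config()]; supplies the gate level.
#' @param test `"auto"` (default) applies the adaptive choice; a specific
#'   test name forces that test.
#' @return A one-row tibble with columns `test` (one of `"mann-whitney"`,
#'   `"student-t"`, `"welch-t"`) and `p`.
#' @export
differential_test <- function(x, y, config = fs_config(),
                              test = c("auto", "mann-whitney", "student-t",
                                       "welch-t")) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("each group needs at least 3 non-missing values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    warn("constant values in both groups; p set to 1")
    return(tibble(test = "mann-whitney", p = 1))
  }
  if (test == "mann-whitney") {
    p <- suppressWarnings(wilcox.test(x, y, correct = TRUE)$p.value)
    return(tibble(test = test, p = p))
  }
  if (test == "student-t") {
    return(tibble(test = test, p = t.test(x, y, var.equal = TRUE)$p.value))
  }
  if (test == "welch-t") {
    return(tibble(test = test, p = t.test(x, y)$p.value))
  }
  alpha <- config$normality_alpha
  normal <- function(v) {
    if (sd(v) == 0 || length(v) > 5000) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }
  if (normal(x) && normal(y)) {
    equal_var <- var.test(x, y)$p.value > alpha
    if (equal_var) {
      tibble(test = "student-t", p = t.test(x, y, var.equal = TRUE)$p.value)
    } else {
      tibble(test = "welch-t", p = t.test(x, y)$p.value)
    }
  } else {
    p <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE)$p.value)
    tibble(test = "mann-whitney", p = p)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, passed
#'   through).
#' @return Adjusted p-values in input order, monotone in raw-p order and
#'   capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Prune highly correlated features
#'
#' Scans feature pairs in deterministic row-major order of the absolute
#' Pearson correlation matrix. For each unflagged pair with `|r|` above the
#' cutoff, the member with the larger mean absolute correlation to all
#' other features is flagged for removal (ties remove the later column);
#' flagged features are ignored in subsequent pairs. Zero-variance features
#' contribute zero correlation and are retained with a warning.
#'
#' @param data Data frame of numeric features (a `sample` id column is
#'   ignored), or a `biomarker_matrix`.
#' @param cutoff Absolute correlation threshold (default 0.6).
#' @return A list with `kept` and `removed` character vectors of feature
#'   names.
#' @export
correlation_filter <- function(data, cutoff = 0.6) {
  X <- feature_block(as_biomarker_values(data))
  if (ncol(X) < 2) return(list(kept = names(X), removed = character(0)))
  if (nrow(X) < 3) abort("correlation filtering needs at least 3 samples")
  sds <- vapply(X, function(v) sd(v, na.rm = TRUE), numeric(1))
  if (any(sds == 0, na.rm = TRUE)) {
    warn("zero-variance feature(s) retained with correlation treated as 0")
  }
  R <- suppressWarnings(abs(cor(X, use = "pairwise.complete.obs")))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  mean_abs <- rowMeans(R) * ncol(R) / max(ncol(R) - 1L, 1L)
  flagged <- rep(FALSE, ncol(X))
  for (i in seq_len(ncol(X) - 1L)) {
    if (flagged[i]) next
    for (j in seq((i + 1L), ncol(X))) {
      if (flagged[j] || R[i, j] <= cutoff) next
      if (mean_abs[i] > mean_abs[j]) flagged[i] <- TRUE else flagged[j] <- TRUE
      if (flagged[i]) break
    }
  }
  list(kept = names(X)[!flagged], removed = names(X)[flagged])
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' Iteratively compares each feature's random-forest permutation importance
#' against the maximum importance of shadow features (permuted copies of
#' the real features). A run scores a hit for a feature whose importance
#' exceeds the shadow maximum. After each run, two-sided binomial tests of
#' the hit counts against 0.5, Bonferroni-corrected over the features still
#' undecided (step-down), confirm clear winners and reject clear losers;
#' features still undecided after `max_runs` are Tentative.
#'
#' @param data Feature data (wide tibble or `biomarker_matrix`).
#' @param labels Class labels (>= 2 classes).
#' @param config An [fs_config()]; `boruta_max_runs`, `boruta_alpha` and
#'   `boruta_ntree` apply.
#' @param seed Integer seed.
#' @return A tibble of class `boruta_result` with columns `feature`,
#'   `decision` (`Confirmed`/`Tentative`/`Rejected`), `hits`, `runs`.
#' @export
boruta_select <- function(data, labels, config = fs_config(), seed = 1L) {
  X <- feature_block(as_biomarker_values(data))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("labels must contain at least 2 classes")
  if (ncol(X) < 1) abort("no features supplied")
  # random forests need complete data; median-impute (rare in practice)
  for (j in seq_along(X)) {
    v <- X[[j]]
    if (anyNA(v)) {
      v[is.na(v)] <- median(v, na.rm = TRUE)
      X[[j]] <- v
    }
  }
  p <- ncol(X)
  status <- setNames(rep("Tentative", p), names(X))
  hits <- setNames(rep(0L, p), names(X))
  runs_at_decision <- setNames(rep(NA_integer_, p), names(X))
  run <- 0L

  withr::with_seed(seed, {
    while (run < config$boruta_max_runs && any(status == "Tentative")) {
      run <- run + 1L
      active <- names(status)[status != "Rejected"]
      Xa <- X[, active, drop = FALSE]
      shadows <- as.data.frame(lapply(Xa, sample), check.names = FALSE)
      names(shadows) <- paste0("shadow_", names(Xa))
      fit <- randomForest::randomForest(
        x = cbind(Xa, shadows), y = labels,
        ntree = config$boruta_ntree, importance = TRUE
      )
      imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
      shadow_max <- max(imp[paste0("shadow_", names(Xa))])
      undecided <- names(status)[status == "Tentative"]
      hits[undecided] <- hits[undecided] +
        as.integer(imp[undecided] > shadow_max)
      if (run >= 5L) {
        m <- sum(status == "Tentative")
        for (f in names(status)[status == "Tentative"]) {
          pv <- binom.test(hits[[f]], run, 0.5)$p.value
          if (pv * m < config$boruta_alpha) {
            status[f] <- if (hits[[f]] > run / 2) "Confirmed" else "Rejected"
            runs_at_decision[f] <- run
          }
        }
      }
    }
  })
  out <- tibble(feature = names(X), decision = unname(status),
                hits = unname(hits),
                runs = unname(ifelse(is.na(runs_at_decision), run,
                                     runs_at_decision)))
  class(out) <- c("boruta_result", class(out))
  out
}

#' Plug-in mutual information between a feature and class labels
#'
#' Discretizes the feature into `ceiling(n^(1/3))` equal-frequency bins and
#' computes the empirical plug-in mutual information with the class labels,
#' in nats.
#'
#' @param x Numeric feature values.
#' @param labels Class labels.
#' @param bins Number of bins; default the cube-root rule.
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, labels,
                               bins = ceiling(length(x)^(1 / 3))) {
  ok <- !is.na(x) & !is.na(labels)
  x <- x[ok]; labels <- droplevels(factor(labels[ok]))
  n <- length(x)
  if (n < 10) abort("mutual information needs n >= 10")
  if (nlevels(labels) < 2) return(0)
  if (length(unique(x)) <= bins) {
    xb <- factor(x)  # few distinct values: bin by value
  } else {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(breaks) < 2) return(0)  # (near-)constant feature
    xb <- cut(x, breaks = breaks, include.lowest = TRUE)
  }
  joint <- table(xb, labels) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Full feature-selection cascade
#'
#' Applies, in order: (1) a univariate filter keeping biomarkers whose best
#' (smallest) raw p over all pairwise group comparisons is at or below
#' `raw_p_cutoff`; (2) correlation pruning at `corr_cutoff`; (3)
#' shadow-feature selection keeping Confirmed features. Mutual information
#' with the class labels is recorded for ranking and reporting, not as a
#' filter.
#'
#' @param data Feature data (wide tibble, `biomarker_matrix` or
#'   `synthetic_cohort`).
#' @param labels Class labels (factor over the diagnostic groups).
#' @param config An [fs_config()].
#' @param seed Integer seed (drives the shadow-feature forests).
#' @return A list of class `feature_selection` with `selected` (character),
#'   `report` (tibble: biomarker, gene, test, p, fdr, kept_after_corr,
#'   boruta_decision, mi, selected), `per_gene` (selected counts), and the
#'   config.
#' @export
select_features <- function(data, labels, config = fs_config(), seed = 1L) {
  values <- as_biomarker_values(data)
  X <- feature_block(values)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("labels must contain at least 2 classes")
  groups <- levels(labels)
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  tests <- purrr::map_dfr(names(X), function(f) {
    res <- purrr::map_dfr(pairs, function(pr) {
      a <- X[[f]][labels == pr[1]]
      b <- X[[f]][labels == pr[2]]
      suppressWarnings(differential_test(a, b, config))
    })
    best <- which.min(res$p)
    tibble(biomarker = f, test = res$test[best], p = res$p[best])
  })
  tests$fdr <- bh_adjust(tests$p)

  pass_p <- tests$biomarker[tests$p <= config$raw_p_cutoff]
  if (length(pass_p) == 0) {
    abort("feature selection emptied at stage: p-value filter")
  }
  corr <- correlation_filter(X[, pass_p, drop = FALSE], config$corr_cutoff)
  if (length(corr$kept) == 0) {
    abort("feature selection emptied at stage: correlation filter")
  }
  bor <- boruta_select(X[, corr$kept, drop = FALSE], labels, config, seed)
  selected <- bor$feature[bor$decision == "Confirmed"]
  if (length(selected) == 0) {
    abort("feature selection emptied at stage: shadow-feature selection")
  }

  mi <- vapply(selected, function(f) mutual_information(X[[f]], labels),
               numeric(1))
  report <- tests |>
    mutate(
      gene = biomarker_gene(.data$biomarker),
      kept_after_corr = .data$biomarker %in% corr$kept,
      boruta_decision = dplyr::coalesce(
        bor$decision[match(.data$biomarker, bor$feature)],
        ifelse(.data$biomarker %in% pass_p, "NotTested", "FailedP")
      ),
      mi = unname(mi[match(.data$biomarker, selected)]),
      selected = .data$biomarker %in% selected
    ) |>
    select("biomarker", "gene", "test", "p", "fdr", "kept_after_corr",
           "boruta_decision", "mi", "selected")
  per_gene <- report |>
    filter(.data$selected) |>
    count(.data$gene, name = "n_selected")

  structure(list(selected = selected, report = report, per_gene = per_gene,
                 config = config, seed = seed),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", length(x$selected), " of ",
      nrow(x$report), " biomarkers selected\n", sep = "")
  print(x$per_gene)
  invisible(x)
}
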