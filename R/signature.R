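## The six pairwise comparisons of the virtual-marker analysis, in Z1..Z6
## order: CTRL|BD, CTRL|SZ+SA, BD|SZ+SA, CTRL|SZ, CTRL|SA, SZ|SA.
SIGNATURE_COMPARISONS <- list(
  Z1 = list(ref = "CTRL", case = "BD"),
  Z2 = list(ref = "CTRL", case = c("SZ", "SA")),
  Z3 = list(ref = "BD", case = c("SZ", "SA")),
  Z4 = list(ref = "CTRL", case = "SZ"),
  Z5 = list(ref = "CTRL", case = "SA"),
  Z6 = list(ref = "SZ", case = "SA")
)

comparison_label <- function(cmp) {
  paste(paste(cmp$ref, collapse = "+"), "vs", paste(cmp$case, collapse = "+"))
}

#' Empirical AUC (Mann-Whitney with tie half-credit)
#'
#' Computes the probability that a randomly chosen case scores above a
#' randomly chosen reference, counting ties as one half:
#' `U / (n0 * n1)` with midranks, which equals the trapezoidal ROC area.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; `TRUE`/1/second factor level marks cases.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- droplevels(factor(labels))
  if (nlevels(f) != 2) abort("labels must have exactly 2 classes")
  f == levels(f)[2]
}

#' Fit a per-comparison mROC virtual marker
#'
#' Computes the Su-Liu AUC-maximizing coefficients over the selected
#' (normalized) biomarkers for one two-group comparison and scores every
#' sample of the comparison with the virtual marker
#' `Z = a x biomarker1 + b x biomarker2 + ...`.
#'
#' @param data Normalized biomarker values (wide tibble or
#'   `biomarker_matrix`).
#' @param labels Diagnosis factor aligned with the data rows.
#' @param comparison A list with `ref` and `case` label vectors, or the
#'   name of a built-in comparison (`"Z1"` ... `"Z6"`).
#' @param features Biomarker ids entering the signature (default: all
#'   feature columns).
#' @param prevalence Prevalence used for predictive values (default: the
#'   observed case fraction).
#' @return A list of class `mroc_signature`: `comparison`, `coefficients`
#'   (unit L2 norm), `scores` (tibble `sample`, `group`, `z`), `roc`
#'   (a `roc_summary` tibble row).
#' @export
fit_signature <- function(data, labels, comparison, features = NULL,
                          prevalence = NULL) {
  values <- as_biomarker_values(data)
  labels <- factor(labels)
  stopifnot(nrow(values) == length(labels))
  if (is.character(comparison) && length(comparison) == 1) {
    comparison <- SIGNATURE_COMPARISONS[[comparison]] %||%
      abort(paste0("unknown comparison: ", comparison))
  }
  features <- features %||% names(feature_block(values))
  in_ref <- labels %in% comparison$ref
  in_case <- labels %in% comparison$case
  if (!any(in_ref) || !any(in_case)) {
    abort("both comparison groups must be present")
  }
  X <- as.matrix(values[, features, drop = FALSE])
  if (anyNA(X)) {
    # median-impute per feature so the covariance is defined
    for (j in seq_len(ncol(X))) {
      v <- X[, j]; v[is.na(v)] <- median(v, na.rm = TRUE); X[, j] <- v
    }
  }
  if (sum(in_ref) + sum(in_case) <= length(features)) {
    warn("fewer samples than features; ridge-regularized covariance in use")
  }
  a <- mroc_coefficients(X[in_ref, , drop = FALSE],
                         X[in_case, , drop = FALSE])
  keep <- in_ref | in_case
  z <- drop(X[keep, , drop = FALSE] %*% a)
  scores <- tibble(
    sample = values$sample[keep] %||% which(keep),
    group = as.character(labels[keep]),
    case = in_case[keep],
    z = z
  )
  roc <- roc_metrics(scores$z, scores$case, prevalence = prevalence)
  structure(list(comparison = comparison_label(comparison),
                 coefficients = a, scores = scores, roc = roc),
            class = "mroc_signature")
}

#' ROC summary at the Youden-optimal cutoff
#'
#' Scans all observed score thresholds (predicting case when
#' `score >= cutoff`), picks the cutoff maximizing Youden's
#' `J = Se + Sp - 1` (ties resolved to the smaller cutoff), and reports
#' AUC, sensitivity, specificity, cutoff, and predictive values at the
#' given prevalence: `PPV = Se*pi / (Se*pi + (1-Sp)(1-pi))`,
#' `NPV = Sp(1-pi) / (Sp(1-pi) + (1-Se)pi)`.
#'
#' @param scores Numeric scores (cases expected to score higher).
#' @param labels Binary labels (cases = `TRUE`/second level).
#' @param prevalence Case prevalence `pi`; default the observed fraction.
#' @return One-row tibble of class `roc_summary`: `auc`, `sensitivity`,
#'   `specificity`, `cutoff`, `ppv`, `npv`, `prevalence`.
#' @export
roc_metrics <- function(scores, labels, prevalence = NULL) {
  pos <- as_binary_labels(labels)
  if (length(unique(scores)) < 2) {
    abort("cutoff undefined: scores are single-valued")
  }
  auc <- empirical_auc(scores, pos)
  cuts <- sort(unique(scores))
  se <- vapply(cuts, function(c) mean(scores[pos] >= c), numeric(1))
  sp <- vapply(cuts, function(c) mean(scores[!pos] < c), numeric(1))
  j <- se + sp - 1
  best <- which(j == max(j))[1]  # cuts ascend, so the first tie is smallest
  pi <- prevalence %||% mean(pos)
  ppv <- se[best] * pi / (se[best] * pi + (1 - sp[best]) * (1 - pi))
  npv <- sp[best] * (1 - pi) / (sp[best] * (1 - pi) + (1 - se[best]) * pi)
  out <- tibble(auc = auc, sensitivity = se[best], specificity = sp[best],
                cutoff = cuts[best], ppv = ppv, npv = npv, prevalence = pi)
  class(out) <- c("roc_summary", class(out))
  out
}

#' Fit all six diagnostic comparisons
#'
#' Builds the six virtual markers Z1..Z6 (CTRL vs BD, CTRL vs SZ+SA, BD vs
#' SZ+SA, CTRL vs SZ, CTRL vs SA, SZ vs SA), their performance table, and
#' per-sample coordinates for the two triplet views (Z1,Z2,Z3) over
#' CTRL/BD/SZ+SA and (Z4,Z5,Z6) over CTRL/SZ/SA.
#'
#' @param data Normalized biomarker values.
#' @param labels Diagnosis factor with the four classes.
#' @param features Biomarker ids entering every signature (default: all).
#' @param prevalence Optional fixed prevalence for predictive values.
#' @return A list of class `signature_set`: `signatures` (named list of
#'   `mroc_signature`), `performance` (6-row tibble: comparison, auc, se,
#'   sp, cutoff, ppv, npv), `coordinates` (per-sample Z scores for the two
#'   triplets).
#' @export
run_all_comparisons <- function(data, labels, features = NULL,
                                prevalence = NULL) {
  labels <- factor(labels)
  sigs <- list()
  for (nm in names(SIGNATURE_COMPARISONS)) {
    cmp <- SIGNATURE_COMPARISONS[[nm]]
    if (!any(labels %in% cmp$ref) || !any(labels %in% cmp$case)) {
      warn(paste0("empty class; comparison skipped: ", comparison_label(cmp)))
      next
    }
    sigs[[nm]] <- fit_signature(data, labels, cmp, features, prevalence)
  }
  performance <- purrr::imap_dfr(sigs, function(s, nm) {
    bind_cols(tibble(signature = nm, comparison = s$comparison), s$roc)
  }) |>
    rename(se = "sensitivity", sp = "specificity")

  values <- as_biomarker_values(data)
  coords <- lapply(list(A = c("Z1", "Z2", "Z3"), B = c("Z4", "Z5", "Z6")),
                   function(axes) {
    if (!all(axes %in% names(sigs))) return(NULL)
    X <- as.matrix(values[, names(sigs[[axes[1]]]$coefficients),
                          drop = FALSE])
    for (j in seq_len(ncol(X))) {
      v <- X[, j]; v[is.na(v)] <- median(v, na.rm = TRUE); X[, j] <- v
    }
    out <- tibble(sample = values$sample, group = as.character(labels))
    for (ax in axes) out[[ax]] <- drop(X %*% sigs[[ax]]$coefficients)
    out
  })
  structure(list(signatures = sigs, performance = performance,
                 coordinates = coords),
            class = "signature_set")
}

#' @export
print.mroc_signature <- function(x, ...) {
  cat("<mroc_signature> ", x$comparison, ": AUC ",
      sprintf("%.3f", x$roc$auc), "\n", sep = "")
  invisible(x)
}

#' @export
print.signature_set <- function(x, ...) {
  print(x$performance)
  invisible(x)
}

#' @export
tidy.mroc_signature <- function(x, ...) {
  tibble(biomarker = names(x$coefficients),
         coefficient = unname(x$coefficients))
}

#' @export
glance.mroc_signature <- function(x, ...) {
  bind_cols(tibble(comparison = x$comparison), x$roc)
}

#' @export
tidy.signature_set <- function(x, ...) {
  purrr::imap_dfr(x$signatures, function(s, nm) {
    tidy(s) |> mutate(signature = nm, .before = 1)
  })
}

#' @export
glance.signature_set <- function(x, ...) x$performance
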