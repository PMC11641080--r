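## Internal numeric helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

## Clamp proportions away from {0, 1} before a logit transform.
clamp01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

## Round half away from zero at `digits` decimals (Table-style percentages;
## base round() uses banker's rounding).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Coerce diagnosis labels to the canonical factor, erroring on strangers.
as_diagnosis <- function(x, levels = DIAGNOSIS_LEVELS) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    abort(paste0("unknown diagnosis label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = levels)
}

## Extract the numeric feature block of a samples-in-rows tibble: drops a
## leading `sample` id column if present, keeps numeric columns only.
feature_block <- function(data) {
  df <- as.data.frame(data, check.names = FALSE)
  if ("sample" %in% names(df)) df$sample <- NULL
  keep <- vapply(df, is.numeric, logical(1))
  df[, keep, drop = FALSE]
}

## Check a correlation matrix is symmetric, unit-diagonal, PSD.
check_correlation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    abort("site correlation must be a square matrix")
  }
  if (max(abs(R - t(R))) > tol) abort("site correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > tol) abort("site correlation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "site correlation is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)
    ))
  }
  invisible(R)
}

## The gene symbol is the biomarker-id prefix before the first underscore.
biomarker_gene <- function(biomarker) sub("_.*$", "", biomarker)
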