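#' Su-Liu AUC-maximizing linear combination
#'
#' For two groups with sample means and covariances, the linear combination
#' maximizing the binormal ROC area is proportional to
#' `(S_ref + S_case)^-1 (mu_case - mu_ref)`. The returned coefficient
#' vector has unit L2 norm and is oriented so the case group's projected
#' mean is at least the reference group's. A ridge term
#' `eps * trace(S) / p * I` is added when the pooled covariance is
#' ill-conditioned.
#'
#' @param x_ref,x_case Numeric matrices (samples x features) for the
#'   reference and case groups.
#' @param ridge Relative ridge factor used when ill-conditioned.
#' @param cond_max Condition-number threshold triggering the ridge.
#' @return Unit-norm numeric coefficient vector (named by feature).
#' @export
mroc_coefficients <- function(x_ref, x_case, ridge = 1e-6,
                              cond_max = 1e10) {
  x_ref <- as.matrix(x_ref); x_case <- as.matrix(x_case)
  if (nrow(x_ref) < 2 || nrow(x_case) < 2) {
    abort("each group needs at least 2 samples")
  }
  p <- ncol(x_ref)
  delta <- colMeans(x_case) - colMeans(x_ref)
  if (p == 1L) {
    a <- sign(delta)
    if (a == 0) a <- 1
    return(setNames(a, colnames(x_ref)))
  }
  S <- var(x_ref) + var(x_case)
  kappa_S <- kappa(S, exact = TRUE)
  if (!is.finite(kappa_S) || kappa_S > cond_max) {
    S <- S + diag(ridge * sum(diag(S)) / p, p)
  }
  a <- tryCatch(solve(S, delta), error = function(e) {
    abort(sprintf(
      "pooled covariance singular even after ridge (condition number %.3g)",
      kappa(S, exact = TRUE)
    ))
  })
  a <- a / sqrt(sum(a^2))
  # orient: cases project at least as high as references
  if (sum(a * delta) < 0) a <- -a
  setNames(a, colnames(x_ref))
}

#' Box-Cox transform with profile-likelihood lambda
#'
#' Shifts the data to positivity (`shift = max(0, 1e-6 - min(x))`), then
#' selects lambda on the grid `[-2, 2]` in steps of 0.01 by maximizing the
#' Box-Cox profile log-likelihood, and applies `(x^lambda - 1) / lambda`
#' (natural log at lambda = 0).
#'
#' @param x Numeric values (>= 5 distinct values required).
#' @param grid Candidate lambda values.
#' @return A list of class `boxcox_params`: `lambda`, `shift`,
#'   `transformed`.
#' @export
boxcox_transform <- function(x, grid = seq(-2, 2, by = 0.01)) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 5) {
    abort("Box-Cox transform needs at least 5 distinct values")
  }
  shift <- max(0, 1e-6 - min(x))
  xs <- x + shift
  n <- length(xs)
  slx <- sum(log(xs))
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(xs) else (xs^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  structure(list(lambda = lambda, shift = shift, transformed = y),
            class = "boxcox_params")
}

apply_boxcox <- function(x, params) {
  xs <- x + params$shift
  if (abs(params$lambda) < 1e-12) log(xs) else (xs^params$lambda - 1) / params$lambda
}

#' Per-gene Target Editing Index
#'
#' For each gene with selected editing variants, computes the Target
#' Editing Index (TEI): variants are standardized (z-scored), combined with
#' the Su-Liu AUC-maximizing coefficients fitted on a reference two-group
#' split (default: controls vs all patients pooled), and the combination is
#' Box-Cox transformed towards normality.
#'
#' @param data Biomarker data (wide tibble, `biomarker_matrix` or
#'   `synthetic_cohort`).
#' @param labels Diagnosis factor aligned with the data rows.
#' @param selected Character vector of selected biomarker ids (genes are
#'   inferred from the `gene_` prefix).
#' @param reference Label(s) forming the reference group of the fitting
#'   split; all other samples form the case group.
#' @return A list of class `tei_result`: `tei` (long tibble `sample`,
#'   `gene`, `tei`), `coefficients` (per-gene named vectors), `boxcox`
#'   (per-gene `boxcox_params`), `reference`.
#' @export
compute_tei <- function(data, labels, selected, reference = "CTRL") {
  values <- as_biomarker_values(data)
  labels <- factor(labels)
  stopifnot(nrow(values) == length(labels))
  selected <- intersect(selected, names(values))
  genes <- unique(biomarker_gene(selected))
  is_ref <- labels %in% reference

  res <- list(); coefs <- list(); bc <- list()
  for (g in genes) {
    vars <- selected[biomarker_gene(selected) == g]
    X <- as.matrix(values[, vars, drop = FALSE])
    X <- scale(X)
    X[is.na(X)] <- 0  # missing standardized values contribute the mean
    a <- mroc_coefficients(X[is_ref, , drop = FALSE],
                           X[!is_ref, , drop = FALSE])
    raw <- drop(X %*% a)
    params <- boxcox_transform(raw)
    res[[g]] <- tibble(sample = values$sample, gene = g,
                       tei = apply_boxcox(raw, params))
    coefs[[g]] <- a
    bc[[g]] <- params
  }
  if (length(res) == 0) {
    warn("no gene had selected variants; empty TEI result")
  }
  structure(list(tei = bind_rows(res), coefficients = coefs, boxcox = bc,
                 reference = reference, labels = labels),
            class = "tei_result")
}

#' Pairwise group tests of the TEI
#'
#' For every pairwise comparison of the diagnostic groups, tests each
#' gene's TEI with the adaptive differential test, adjusts across genes
#' within the comparison (BH), and flags significance at `fdr_cutoff`.
#'
#' @param tei A `tei_result` from [compute_tei()], or its long `tei`
#'   tibble.
#' @param labels Diagnosis factor (required when `tei` is a tibble).
#' @param fdr_cutoff Significance level on the adjusted p (default 0.10).
#' @param config An [fs_config()] for the adaptive test gates.
#' @return Tibble with columns `comparison`, `gene`, `test`, `p`, `fdr`,
#'   `significant` (one row per comparison x gene).
#' @export
tei_group_tests <- function(tei, labels = NULL, fdr_cutoff = 0.10,
                            config = fs_config()) {
  if (inherits(tei, "tei_result")) {
    labels <- labels %||% tei$labels
    tei <- tei$tei
  }
  if (is.null(labels)) abort("labels are required")
  labels <- as.factor(labels)  # keep declared-but-empty groups
  samples <- unique(tei$sample)
  lab <- setNames(as.character(labels), samples)
  groups <- levels(labels)
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  out <- purrr::map_dfr(pairs, function(pr) {
    sub <- tei |> mutate(group = lab[.data$sample]) |>
      filter(.data$group %in% pr)
    if (length(unique(sub$group)) < 2) {
      warn(paste0("group missing; comparison omitted: ",
                  paste(pr, collapse = " vs ")))
      return(tibble())
    }
    res <- sub |>
      group_by(.data$gene) |>
      summarise(res = list(differential_test(
        .data$tei[.data$group == pr[1]],
        .data$tei[.data$group == pr[2]], config
      )), .groups = "drop") |>
      tidyr::unnest("res")
    res |>
      mutate(comparison = paste(pr[1], "vs", pr[2]),
             fdr = bh_adjust(.data$p),
             significant = .data$fdr < fdr_cutoff) |>
      select("comparison", "gene", "test", "p", "fdr", "significant")
  })
  out
}

#' @export
print.tei_result <- function(x, ...) {
  cat("<tei_result> genes:", paste(names(x$coefficients), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.tei_result <- function(x, ...) {
  purrr::imap_dfr(x$coefficients, function(a, g) {
    tibble(gene = g, variant = names(a), coefficient = unname(a),
           lambda = x$boxcox[[g]]$lambda)
  })
}

#' @export
glance.tei_result <- function(x, ...) {
  tibble(
    n_genes = length(x$coefficients),
    n_variants = sum(lengths(x$coefficients)),
    reference = paste(x$reference, collapse = "+")
  )
}
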