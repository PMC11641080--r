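#' Construct a synthetic-cohort specification
#'
#' The generator models per-site editing proportions with a logistic-normal
#' law: a correlated Gaussian on the logit scale with class-shifted means,
#' mapped through the inverse logit, then observed through beta-binomial
#' read noise at a fixed sequencing depth. Demographic covariates (sex, five
#' psychotropic ATC treatment classes, age) are sampled independently per
#' diagnostic class from the configured prevalences.
#'
#' @param class_sizes Named integer vector of samples per diagnosis
#'   (names among `CTRL`, `BD`, `SZ`, `SA`).
#' @param site_panel A site panel tibble (see [default_site_panel()]).
#' @param baseline_logit_means Named numeric vector (per panel biomarker) of
#'   logit-scale baseline means.
#' @param logit_sds Per-site logit-scale standard deviations (scalar or
#'   named vector).
#' @param site_correlation Correlation matrix over panel sites (symmetric,
#'   unit diagonal, positive semi-definite) or `NULL` for the default
#'   within-gene exchangeable block structure.
#' @param within_gene_rho Exchangeable within-gene correlation used when
#'   `site_correlation` is `NULL`.
#' @param group_effects Named list `diagnosis -> named numeric`, giving
#'   logit-scale mean shifts. Names of each inner vector may be biomarker
#'   ids (`gene_site`) or gene symbols (applied to all of the gene's sites).
#' @param overdispersion Beta-binomial concentration (> 0) governing extra-
#'   binomial read noise; larger is closer to pure binomial.
#' @param sex_prevalence Named numeric vector, male fraction per class.
#' @param treatment_prevalence Named list `diagnosis -> named numeric` over
#'   the five ATC classes (see [treatment_classes()]).
#' @param age_mean,age_sd Named numeric vectors per class; ages are drawn
#'   truncated to `age_range`.
#' @param age_range Length-2 inclusive age bounds.
#' @param reads_per_sample Total aligned reads per sample, split evenly
#'   across the panel genes.
#' @param error_rate Per-base symmetric sequencing-error rate used by
#'   [generate_reads()].
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [cohort_spec_study()] for the study-sized default.
#' @export
cohort_spec <- function(class_sizes,
                        site_panel = default_site_panel(),
                        baseline_logit_means = NULL,
                        logit_sds = 0.4,
                        site_correlation = NULL,
                        within_gene_rho = 0.3,
                        group_effects = list(),
                        overdispersion = 200,
                        sex_prevalence = NULL,
                        treatment_prevalence = NULL,
                        age_mean = NULL,
                        age_sd = NULL,
                        age_range = c(18, 65),
                        reads_per_sample = 10000L,
                        error_rate = 1e-3,
                        seed = 1234L) {
  validate_site_panel(site_panel)
  p <- nrow(site_panel)
  ids <- site_panel$biomarker
  classes <- names(class_sizes)
  class_sizes <- setNames(as.integer(class_sizes), classes)
  if (any(class_sizes < 0)) abort("class sizes must be >= 0")
  as_diagnosis(classes)

  if (is.null(baseline_logit_means)) {
    # baselines cycle over editing levels 3%..35% within each gene
    levels <- logit(seq(0.03, 0.35, length.out = max(table(site_panel$gene))))
    baseline_logit_means <- setNames(
      unlist(lapply(split(ids, site_panel$gene)[unique(site_panel$gene)],
                    function(s) levels[seq_along(s)]), use.names = FALSE),
      unlist(split(ids, site_panel$gene)[unique(site_panel$gene)],
             use.names = FALSE)
    )[ids]
  }
  if (!all(ids %in% names(baseline_logit_means))) {
    abort("baseline_logit_means must cover every panel site")
  }
  baseline_logit_means <- baseline_logit_means[ids]

  if (length(logit_sds) == 1L) logit_sds <- setNames(rep(logit_sds, p), ids)
  logit_sds <- logit_sds[ids]
  if (any(logit_sds <= 0)) abort("logit_sds must be positive")

  if (is.null(site_correlation)) {
    site_correlation <- matrix(0, p, p, dimnames = list(ids, ids))
    for (g in unique(site_panel$gene)) {
      idx <- which(site_panel$gene == g)
      site_correlation[idx, idx] <- within_gene_rho
    }
    diag(site_correlation) <- 1
  }
  check_correlation_matrix(site_correlation)
  if (!identical(dim(site_correlation), c(p, p))) {
    abort("site_correlation dimension must match the site panel")
  }

  prev_ok <- function(x) all(x >= 0 & x <= 1)
  if (is.null(sex_prevalence)) sex_prevalence <- setNames(rep(0.5, length(classes)), classes)
  if (!prev_ok(sex_prevalence)) abort("sex prevalences must lie in [0, 1]")
  if (is.null(treatment_prevalence)) {
    treatment_prevalence <- setNames(
      rep(list(setNames(rep(0, 5), TREATMENT_CLASSES)), length(classes)), classes)
  }
  if (!prev_ok(unlist(treatment_prevalence))) {
    abort("treatment prevalences must lie in [0, 1]")
  }
  if (is.null(age_mean)) age_mean <- setNames(rep(42, length(classes)), classes)
  if (is.null(age_sd)) age_sd <- setNames(rep(10, length(classes)), classes)

  if (as.integer(reads_per_sample) < 1L) abort("reads_per_sample must be >= 1")
  if (overdispersion <= 0) abort("overdispersion concentration must be > 0")

  structure(list(
    class_sizes = class_sizes,
    site_panel = site_panel,
    baseline_logit_means = baseline_logit_means,
    logit_sds = logit_sds,
    site_correlation = site_correlation,
    group_effects = group_effects,
    overdispersion = overdispersion,
    sex_prevalence = sex_prevalence,
    treatment_prevalence = treatment_prevalence,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    reads_per_sample = as.integer(reads_per_sample),
    error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Study-sized default cohort specification
#'
#' Returns a [cohort_spec()] whose class sizes, per-class male fractions,
#' psychotropic-treatment prevalences and age summaries equal the published
#' demographics of the four-group study population (85 controls, 39 bipolar,
#' 31 schizophrenia, 14 schizoaffective). Default logit-scale group effects
#' reproduce the qualitative editing structure the downstream analysis
#' expects: SZ and SA share identical shifts on *KCNJ15*, *LYN* and *PRKCB*
#' (so SZ vs SA is null), while BD is shifted downward on the seven genes
#' other than *PRKCB*.
#'
#' @param ... Overrides forwarded to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_spec_study <- function(...) {
  defaults <- list(
    class_sizes = c(CTRL = 85L, BD = 39L, SZ = 31L, SA = 14L),
    sex_prevalence = c(CTRL = 47 / 85, BD = 11 / 39, SZ = 23 / 31, SA = 10 / 14),
    treatment_prevalence = list(
      CTRL = c(antipsychotics = 0, antidepressants = 0, anxiolytics = 0,
               antiepileptics = 0, hypnotics = 0),
      BD = c(antipsychotics = 28 / 39, antidepressants = 5 / 39,
             anxiolytics = 0, antiepileptics = 26 / 39, hypnotics = 0),
      SZ = c(antipsychotics = 29 / 31, antidepressants = 18 / 31,
             anxiolytics = 5 / 31, antiepileptics = 12 / 31,
             hypnotics = 1 / 31),
      SA = c(antipsychotics = 14 / 14, antidepressants = 8 / 14,
             anxiolytics = 2 / 14, antiepileptics = 5 / 14, hypnotics = 0)
    ),
    age_mean = c(CTRL = 40.3, BD = 44.7, SZ = 42.8, SA = 45.6),
    age_sd = c(CTRL = 11.2, BD = 9.7, SZ = 9.8, SA = 6.7),
    group_effects = list(
      BD = c(CAMK1D = -0.5, GAB2 = -0.5, IFNAR1 = -0.5, KCNJ15 = -0.5,
             LYN = -0.5, MDM2 = -0.5, PDE8A = -0.5),
      SZ = c(KCNJ15 = 0.6, LYN = 0.5, PRKCB = 0.5),
      SA = c(KCNJ15 = 0.6, LYN = 0.5, PRKCB = 0.5)
    )
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(cohort_spec, defaults)
}

## Expand gene-level effect entries to per-site logit shifts, one column per
## diagnosis present in the spec.
expand_group_effects <- function(spec) {
  ids <- spec$site_panel$biomarker
  genes <- spec$site_panel$gene
  out <- vapply(names(spec$class_sizes), function(cl) {
    shift <- setNames(rep(0, length(ids)), ids)
    eff <- spec$group_effects[[cl]]
    for (nm in names(eff)) {
      if (nm %in% ids) {
        shift[nm] <- shift[nm] + eff[[nm]]
      } else if (nm %in% genes) {
        shift[genes == nm] <- shift[genes == nm] + eff[[nm]]
      } else {
        abort(paste0("group effect refers to unknown site or gene: ", nm))
      }
    }
    shift
  }, numeric(length(ids)))
  matrix(out, nrow = length(ids),
         dimnames = list(ids, names(spec$class_sizes)))
}

#' Generate a synthetic cohort
#'
#' Draws per-sample editing proportions from the spec's logistic-normal
#' model (correlated Gaussian on the logit scale with class-shifted means,
#' inverse-logit mapped), adds beta-binomial read noise at the configured
#' depth, and samples sex, treatments and age per class. The result is a
#' pure function of the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `biomarkers`
#'   (tibble, `sample` plus one column per panel site, values in `[0, 1]`),
#'   `cohort` (tibble with `sample`, `diagnosis`, `sex`, `age` and the five
#'   treatment flags), and `true_proportions` (latent editing proportions
#'   before read noise).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- spec$site_panel
  ids <- panel$biomarker
  p <- length(ids)
  D <- diag(spec$logit_sds, p)
  Sigma <- D %*% spec$site_correlation %*% D
  shifts <- expand_group_effects(spec)
  depth_per_gene <- site_depths(spec)[ids]

  withr::with_seed(spec$seed, {
    per_class <- lapply(names(spec$class_sizes), function(cl) {
      n <- spec$class_sizes[[cl]]
      if (n == 0L) return(NULL)
      mu <- spec$baseline_logit_means + shifts[, cl]
      Z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
      if (n == 1L) Z <- matrix(Z, nrow = 1)
      P <- inv_logit(Z)
      # beta-binomial observation noise at per-site read depth
      conc <- spec$overdispersion
      obs <- matrix(0, n, p)
      for (j in seq_len(p)) {
        pi_j <- rbeta(n, P[, j] * conc, (1 - P[, j]) * conc)
        obs[, j] <- rbinom(n, depth_per_gene[j], pi_j) / depth_per_gene[j]
      }
      colnames(obs) <- ids
      colnames(P) <- ids
      trt <- spec$treatment_prevalence[[cl]][TREATMENT_CLASSES]
      cov <- tibble(
        diagnosis = cl,
        sex = ifelse(runif(n) < spec$sex_prevalence[[cl]], "M", "F"),
        age = rnorm_truncated(n, spec$age_mean[[cl]], spec$age_sd[[cl]],
                              spec$age_range)
      )
      for (tc in TREATMENT_CLASSES) {
        cov[[tc]] <- as.integer(runif(n) < trt[[tc]])
      }
      list(obs = obs, true = P, cov = cov)
    })
    per_class <- per_class[!vapply(per_class, is.null, logical(1))]
    obs <- do.call(rbind, lapply(per_class, `[[`, "obs"))
    true <- do.call(rbind, lapply(per_class, `[[`, "true"))
    cov <- bind_rows(lapply(per_class, `[[`, "cov"))
  })

  sample_ids <- sprintf("S%03d", seq_len(nrow(obs)))
  biomarkers <- bind_cols(tibble(sample = sample_ids),
                          as_tibble(obs, .name_repair = "minimal"))
  cohort <- bind_cols(tibble(sample = sample_ids), cov) |>
    mutate(diagnosis = as_diagnosis(.data$diagnosis))
  true_proportions <- bind_cols(tibble(sample = sample_ids),
                                as_tibble(true, .name_repair = "minimal"))
  structure(list(biomarkers = biomarkers, cohort = cohort,
                 true_proportions = true_proportions, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$cohort), " samples, ",
      ncol(x$biomarkers) - 1L, " biomarkers\n", sep = "")
  print(table(x$cohort$diagnosis))
  invisible(x)
}

## Per-site read depth: reads are split evenly over genes, each read covers
## all of its gene's sites.
site_depths <- function(spec) {
  genes <- unique(spec$site_panel$gene)
  per_gene <- gene_read_counts(spec$reads_per_sample, genes)
  setNames(per_gene[spec$site_panel$gene], spec$site_panel$biomarker)
}

gene_read_counts <- function(total, genes) {
  k <- length(genes)
  base <- total %/% k
  extra <- total %% k
  setNames(base + as.integer(seq_len(k) <= extra), genes)
}

rnorm_truncated <- function(n, mean, sd, range) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate aligned reads for one sample
#'
#' Each read covers every panel site of one gene and carries a jointly
#' sampled (phased) editing pattern. Under the default `"independent"`
#' phasing, site calls within a read are independent Bernoulli draws at the
#' sample's per-site editing proportions; `"comonotone"` phasing drives all
#' of a read's sites from one latent uniform, producing maximally correlated
#' patterns. Edited calls substitute G at A positions (+ strand) and C at T
#' positions (- strand). A symmetric sequencing error replaces a call with a
#' uniformly chosen different base.
#'
#' @param spec A [cohort_spec()]; supplies panel, depth and error rate.
#' @param sample_editing Named numeric vector of editing proportions in
#'   `[0, 1]`, named by panel biomarker ids.
#' @param sample_id Sample identifier stamped on the reads.
#' @param phasing `"independent"` or `"comonotone"`.
#' @param seed Seed for this sample's reads (defaults to the spec seed).
#' @return A tibble of class `aligned_reads` with columns `sample`, `read`,
#'   `gene`, `site`, `base`, plus attribute `n_reads` (total reads).
#' @export
generate_reads <- function(spec, sample_editing, sample_id = "S001",
                           phasing = c("independent", "comonotone"),
                           seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  phasing <- match.arg(phasing)
  panel <- spec$site_panel
  unknown <- setdiff(names(sample_editing), panel$biomarker)
  if (length(unknown) > 0) {
    abort(paste0("editing proportions given for sites absent from the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(panel$biomarker %in% names(sample_editing))) {
    abort("sample_editing must cover every panel site")
  }
  if (any(sample_editing < 0 | sample_editing > 1)) {
    abort("editing proportions must lie in [0, 1]")
  }
  genes <- unique(panel$gene)
  n_per_gene <- gene_read_counts(spec$reads_per_sample, genes)

  withr::with_seed(seed, {
    reads <- purrr::map_dfr(genes, function(g) {
      sites <- panel[panel$gene == g, ]
      n <- n_per_gene[[g]]
      probs <- sample_editing[sites$biomarker]
      k <- nrow(sites)
      edited <- switch(phasing,
        independent = matrix(runif(n * k), n, k) < rep(probs, each = n),
        comonotone = matrix(runif(n), n, k) < rep(probs, each = n)
      )
      ref <- sites$ref_base
      alt <- ifelse(sites$strand == "+", "G", "C")
      base <- matrix(rep(ref, each = n), n, k)
      base[edited] <- matrix(rep(alt, each = n), n, k)[edited]
      if (spec$error_rate > 0) {
        err <- matrix(runif(n * k) < spec$error_rate, n, k)
        if (any(err)) {
          idx <- which(err)
          base[idx] <- vapply(base[idx], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
      }
      tibble(
        sample = sample_id,
        read = paste0(g, "_r", rep(seq_len(n), times = k)),
        gene = g,
        site = rep(sites$site, each = n),
        base = as.vector(base)
      )
    })
  })
  attr(reads, "n_reads") <- sum(n_per_gene)
  class(reads) <- c("aligned_reads", class(reads))
  reads
}
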