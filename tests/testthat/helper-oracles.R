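# Independent oracles and fixture builders used across the suite.

# Brute-force AUC: average over all case/reference pairs with half credit
# for ties.
auc_bruteforce <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments
# (no ties assumed).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Two-group Gaussian design with exact sample moments unknown but known
# population delta / Sigma; returns matrices for mROC checks.
gaussian_two_group <- function(n, delta, Sigma, seed) {
  p <- length(delta)
  withr::with_seed(seed, {
    ref <- MASS::mvrnorm(n, rep(0, p), Sigma)
    case <- MASS::mvrnorm(n, delta, Sigma)
  })
  list(ref = ref, case = case)
}

# Matrix with an exact prescribed sample correlation matrix (columns have
# zero mean, unit variance).
exact_correlation_data <- function(n, R, seed = 1) {
  p <- ncol(R)
  withr::with_seed(seed, X <- matrix(rnorm(n * p), n, p))
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(X))              # orthonormal columns
  X <- X %*% chol(R)
  X <- scale(X)                 # unit sample variance
  colnames(X) <- paste0("f", seq_len(p))
  as.data.frame(X)
}

# Small synthetic spec used where the full study-sized cohort is overkill.
small_spec <- function(..., sites_per_gene = 2, seed = 11L) {
  cohort_spec_study(
    class_sizes = c(CTRL = 20L, BD = 15L, SZ = 12L, SA = 8L),
    site_panel = default_site_panel(sites_per_gene = sites_per_gene),
    seed = seed,
    ...
  )
}

# Four-class design for importance checks: all eight biomarkers and all
# five treatments carry class signal, sex is independent of class, and
# antipsychotics is near-universal in patients (the dominant covariate).
importance_design_spec <- function(seed, n_per_class = 80L) {
  cohort_spec_study(
    class_sizes = setNames(rep(n_per_class, 4), c("CTRL", "BD", "SZ", "SA")),
    site_panel = default_site_panel(sites_per_gene = 1),
    group_effects = list(
      BD = c(CAMK1D = -1.5, GAB2 = 1.5, MDM2 = 1.2),
      SZ = c(KCNJ15 = 1.5, LYN = 1.5, PRKCB = -1.2, MDM2 = -1.2),
      SA = c(PDE8A = 1.5, IFNAR1 = -1.5, PRKCB = 1.2)
    ),
    treatment_prevalence = list(
      CTRL = c(antipsychotics = 0.02, antidepressants = 0.05,
               anxiolytics = 0.05, antiepileptics = 0.05, hypnotics = 0.05),
      BD = c(antipsychotics = 0.95, antidepressants = 0.2,
             anxiolytics = 0.1, antiepileptics = 0.7, hypnotics = 0.45),
      SZ = c(antipsychotics = 0.95, antidepressants = 0.6,
             anxiolytics = 0.45, antiepileptics = 0.4, hypnotics = 0.1),
      SA = c(antipsychotics = 0.95, antidepressants = 0.65,
             anxiolytics = 0.15, antiepileptics = 0.35, hypnotics = 0.3)
    ),
    sex_prevalence = c(CTRL = 0.5, BD = 0.5, SZ = 0.5, SA = 0.5),
    seed = seed
  )
}

# Sparse design where the antipsychotics flag is the single dominant
# feature: one strong site per class, no treatment in controls.
root_dominance_spec <- function(seed, n_per_class = 35L) {
  cohort_spec_study(
    class_sizes = setNames(rep(n_per_class, 4), c("CTRL", "BD", "SZ", "SA")),
    site_panel = default_site_panel(sites_per_gene = 2),
    group_effects = list(
      BD = c(CAMK1D_s1 = 1),
      SZ = c(KCNJ15_s1 = 1),
      SA = c(PDE8A_s1 = 1)
    ),
    treatment_prevalence = list(
      CTRL = c(antipsychotics = 0, antidepressants = 0, anxiolytics = 0,
               antiepileptics = 0, hypnotics = 0),
      BD = c(antipsychotics = 0.97, antidepressants = 0.13, anxiolytics = 0,
             antiepileptics = 0.5, hypnotics = 0),
      SZ = c(antipsychotics = 0.97, antidepressants = 0.5,
             anxiolytics = 0.16, antiepileptics = 0.39, hypnotics = 0.03),
      SA = c(antipsychotics = 1, antidepressants = 0.57, anxiolytics = 0.14,
             antiepileptics = 0.36, hypnotics = 0)
    ),
    sex_prevalence = c(CTRL = 0.5, BD = 0.5, SZ = 0.5, SA = 0.5),
    seed = seed
  )
}

# Count-table fixture: one sample, arbitrary per-site base counts.
count_fixture <- function(sample, gene, site, bases) {
  purrr::imap_dfr(bases, function(count, base) {
    tibble::tibble(sample = sample, gene = gene, site = site,
                   base = base, count = count)
  })
}
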