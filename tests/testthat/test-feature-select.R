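test_that("forced Mann-Whitney matches exact enumeration of labelings", {
  cases <- list(
    list(x = 1:5, y = 6:10),                    # extreme separation, p = 2/252
    list(x = c(1, 4, 6, 9), y = c(2, 3, 7, 11)),
    list(x = c(0.3, 1.2, 5.4, 2.2, 9.1), y = c(0.1, 0.4, 0.2, 3.3))
  )
  for (cs in cases) {
    res <- differential_test(cs$x, cs$y, test = "mann-whitney")
    expect_equal(res$p, mw_exact_p(cs$x, cs$y), tolerance = 1e-12)
  }
  expect_equal(differential_test(1:5, 6:10, test = "mann-whitney")$p,
               2 / 252, tolerance = 1e-12)
})

test_that("identical groups give p = 1 and constants warn", {
  expect_equal(differential_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))$p, 1)
  expect_warning(res <- differential_test(c(2, 2, 2), c(2, 2, 2)),
                 "constant")
  expect_equal(res$p, 1)
  expect_error(differential_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("the adaptive test picks the expected branch", {
  withr::with_seed(21L, {
    a <- rnorm(30); b <- rnorm(30, 0.5)
    expect_equal(differential_test(a, b)$test, "student-t")
    a2 <- rnorm(40, sd = 1); b2 <- rnorm(40, 1, sd = 4)
    expect_equal(differential_test(a2, b2)$test, "welch-t")
    a3 <- rexp(40); b3 <- rexp(40, 0.5)
    expect_equal(differential_test(a3, b3)$test, "mann-whitney")
  })
})

test_that("BH adjustment applies the step-up rule and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(4L, {
    for (i in 1:10) {
      p <- runif(25)^2
      adj <- bh_adjust(p)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw-p order
    }
  })
})

test_that("correlation pruning removes the member with larger mean |r|", {
  R <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.1,
                0.2, 0.1, 1), 3, 3)
  X <- exact_correlation_data(60, R, seed = 2)
  # mean |r|: f1 = 0.55, f2 = 0.50, f3 = 0.15 -> the f1/f2 pair drops f1
  res <- correlation_filter(X, cutoff = 0.6)
  expect_identical(res$removed, "f1")
  expect_setequal(res$kept, c("f2", "f3"))
})

test_that("pruning leaves no pair above the cutoff and handles edge cases", {
  withr::with_seed(31L, {
    for (i in 1:5) {
      n <- 50; p <- 12
      base <- matrix(rnorm(n * 4), n, 4)
      X <- as.data.frame(base[, sample(4, p, replace = TRUE)] +
                           matrix(rnorm(n * p, sd = 0.8), n, p))
      names(X) <- paste0("v", seq_len(p))
      res <- correlation_filter(X, cutoff = 0.6)
      kept <- abs(cor(X[, res$kept]))
      diag(kept) <- 0
      expect_lt(max(kept), 0.6 + 1e-12)
    }
  })
  # uncorrelated features: nothing removed
  X0 <- exact_correlation_data(40, diag(3), seed = 3)
  expect_length(correlation_filter(X0, 0.6)$removed, 0)
  # exact duplicate: exactly one of the pair removed
  Xd <- X0
  Xd$f4 <- Xd$f1
  resd <- correlation_filter(Xd, 0.6)
  expect_equal(sum(c("f1", "f4") %in% resd$removed), 1)
  # zero-variance feature: retained with a warning
  Xz <- X0
  Xz$flat <- 1
  expect_warning(resz <- correlation_filter(Xz, 0.6), "zero-variance")
  expect_true("flat" %in% resz$kept)
})

test_that("shadow-feature selection separates planted signal from noise", {
  withr::with_seed(77L, {
    n <- 200
    y <- factor(rep(c("A", "B"), each = n / 2))
    X <- as.data.frame(matrix(rnorm(n * 25), n, 25))
    names(X) <- c(paste0("signal", 1:5), paste0("noise", 1:20))
    for (j in 1:5) X[[j]] <- X[[j]] + ifelse(y == "B", 1.5, 0)
  })
  res <- boruta_select(X, y, fs_config(boruta_max_runs = 60), seed = 5L)
  dec <- setNames(res$decision, res$feature)
  expect_true(all(dec[paste0("signal", 1:5)] == "Confirmed"))
  expect_gte(sum(dec[paste0("noise", 1:20)] != "Confirmed"), 18)
  expect_true(all(res$hits <= res$runs))
})

test_that("constant features are rejected and single-class labels error", {
  withr::with_seed(9L, {
    X <- data.frame(flat = rep(1, 80), noise = rnorm(80))
    y <- factor(rep(c("A", "B"), 40))
  })
  res <- boruta_select(X, y, fs_config(), seed = 2L)
  expect_equal(res$decision[res$feature == "flat"], "Rejected")
  expect_error(boruta_select(X, factor(rep("A", 80))), "2 classes")
})

test_that("mutual information behaves on identity, null and degenerate cases", {
  withr::with_seed(12L, {
    y <- factor(rep(c("A", "B"), each = 500))
    # identical to a balanced binary label: MI = H = ln 2
    x_id <- as.integer(y == "B")
    expect_equal(mutual_information(x_id, y), log(2), tolerance = 1e-12)
    # independent feature: plug-in MI stays below the bias bound
    expect_lt(mutual_information(rnorm(1000), y), 0.02)
    # non-negativity across random inputs
    for (i in 1:10) {
      expect_gte(mutual_information(rnorm(60), factor(rbinom(60, 2, 0.4))), 0)
    }
  })
  expect_equal(mutual_information(rnorm(50), factor(rep("A", 50))), 0)
  expect_error(mutual_information(rnorm(5), factor(rep(c("A", "B"), 3))[1:5]),
               "n >= 10")
})

test_that("the cascade runs p-filter, correlation pruning, then shadow selection", {
  withr::with_seed(301L, {
    n <- 60 * 4
    y <- factor(rep(c("CTRL", "BD", "SZ", "SA"), each = 60))
    X <- tibble::tibble(
      GAB2_s1 = rnorm(n) + ifelse(y %in% c("SZ", "SA"), 1.6, 0),
      GAB2_s2 = rnorm(n, sd = 0.1),               # null -> fails p-filter
      LYN_s1 = rnorm(n) + ifelse(y == "BD", -1.6, 0),
      MDM2_s1 = rnorm(n) + ifelse(y == "CTRL", 1.6, 0)
    )
    X$GAB2_s3 <- X$GAB2_s1 + rnorm(n, sd = 0.1)   # near-duplicate of s1
  })
  sel <- select_features(X, y, fs_config(boruta_max_runs = 40), seed = 6L)
  rep <- sel$report
  expect_true(all(c("LYN_s1", "MDM2_s1") %in% sel$selected))
  # one of the near-duplicate GAB2 pair survives and is selected
  expect_equal(sum(c("GAB2_s1", "GAB2_s3") %in% sel$selected), 1)
  expect_false("GAB2_s2" %in% sel$selected)
  # the null feature never reached later stages
  expect_equal(rep$boruta_decision[rep$biomarker == "GAB2_s2"], "FailedP")
  # exactly one of the correlated GAB2 pair was pruned before Boruta
  pair <- rep[rep$biomarker %in% c("GAB2_s1", "GAB2_s3"), ]
  expect_equal(sum(pair$kept_after_corr), 1)
  expect_equal(sum(pair$boruta_decision == "NotTested"), 1)
  # per-gene counts reflect the plant
  pg <- setNames(sel$per_gene$n_selected, sel$per_gene$gene)
  expect_equal(pg[["LYN"]], 1)
  expect_equal(pg[["MDM2"]], 1)
  expect_equal(pg[["GAB2"]], 1)
  # selected features carry an MI value, never-tested ones do not
  expect_true(all(!is.na(rep$mi[rep$selected])))
})

test_that("the cascade is deterministic given a seed", {
  withr::with_seed(302L, {
    y <- factor(rep(c("A", "B"), each = 40))
    X <- as.data.frame(matrix(rnorm(80 * 6), 80, 6))
    names(X) <- paste0("GAB2_s", 1:6)
    X$GAB2_s1 <- X$GAB2_s1 + ifelse(y == "B", 2, 0)
  })
  s1 <- select_features(X, y, fs_config(boruta_max_runs = 30), seed = 9L)
  s2 <- select_features(X, y, fs_config(boruta_max_runs = 30), seed = 9L)
  expect_identical(s1$report, s2$report)
})
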