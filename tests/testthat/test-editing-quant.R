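lenient_qc <- qc_config(min_sample_depth = 1, min_site_depth = 1)

test_that("site editing fractions follow the strand convention", {
  panel <- default_site_panel(sites_per_gene = 1,
                              genes = c("GAB2", "LYN"))  # LYN is - strand
  counts <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 90, G = 10)),
    count_fixture("S1", "LYN", "s1", c(T = 70, C = 30))
  )
  se <- call_site_editing(counts, panel, lenient_qc)
  expect_equal(se$frac[se$gene == "GAB2"], 0.10)
  expect_equal(se$frac[se$gene == "LYN"], 0.30)
  expect_equal(se$depth[se$gene == "GAB2"], 100)
})

test_that("off-target bases are excluded from the denominator", {
  panel <- default_site_panel(sites_per_gene = 1, genes = "GAB2")
  counts <- count_fixture("S1", "GAB2", "s1",
                          c(A = 80, G = 20, C = 50, N = 10))
  se <- call_site_editing(counts, panel, lenient_qc)
  expect_equal(se$frac, 0.20)
  expect_equal(se$depth, 100)
})

test_that("samples below the read-depth floor fail QC with missing values", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  qc <- qc_config(min_sample_depth = 10000, min_site_depth = 1)
  shallow <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 9000, G = 999)),
    count_fixture("S1", "GAB2", "s2", c(A = 9999))
  )
  deep <- dplyr::bind_rows(
    count_fixture("S2", "GAB2", "s1", c(A = 9000, G = 1000)),
    count_fixture("S2", "GAB2", "s2", c(A = 10000))
  )
  se <- call_site_editing(dplyr::bind_rows(shallow, deep), panel, qc)
  expect_true(all(is.na(se$frac[se$sample == "S1"])))
  expect_false(any(se$qc_pass[se$sample == "S1"]))
  expect_equal(se$frac[se$sample == "S2" & se$site == "s1"], 0.1)
  expect_true(all(se$qc_pass[se$sample == "S2"]))
  # an empty input is not a crash
  expect_equal(nrow(call_site_editing(shallow[0, ], panel, qc)), 0)
})

test_that("shallow sites are missing while deep sites are kept", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  qc <- qc_config(min_sample_depth = 1, min_site_depth = 50)
  counts <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 45, G = 4)),   # depth 49
    count_fixture("S1", "GAB2", "s2", c(A = 40, G = 10))   # depth 50
  )
  se <- call_site_editing(counts, panel, qc)
  expect_true(is.na(se$frac[se$site == "s1"]))
  expect_equal(se$frac[se$site == "s2"], 0.2)
})

test_that("isoform frequencies count joint per-read patterns", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  # 10 reads: 4 unedited, 3 edited at s1 only, 2 at s2 only, 1 at both
  states <- rbind(
    matrix(rep(c("A", "A"), 4), ncol = 2, byrow = TRUE),
    matrix(rep(c("G", "A"), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c("A", "G"), 2), ncol = 2, byrow = TRUE),
    matrix(c("G", "G"), ncol = 2)
  )
  reads <- tibble::tibble(
    sample = "S1",
    read = rep(paste0("r", 1:10), times = 2),
    gene = "GAB2",
    site = rep(c("s1", "s2"), each = 10),
    base = c(states[, 1], states[, 2])
  )
  iso <- call_isoforms(reads, "GAB2", panel)
  freq <- setNames(iso$freq, iso$pattern)
  expect_equal(freq[["00"]], 0.4)
  expect_equal(freq[["10"]], 0.3)
  expect_equal(freq[["01"]], 0.2)
  expect_equal(freq[["11"]], 0.1)
  expect_equal(sum(iso$freq), 1)
  # marginals: s1 = 0.4, s2 = 0.3
  expect_equal(sum(freq[c("10", "11")]), 0.4)
  expect_equal(sum(freq[c("01", "11")]), 0.3)
})

test_that("all-unedited reads give a single pattern and ambiguous reads are excluded", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  reads <- tibble::tibble(
    sample = "S1", read = rep(c("r1", "r2", "r3"), 2), gene = "GAB2",
    site = rep(c("s1", "s2"), each = 3),
    base = c("A", "A", "A", "A", "A", "C")  # r3 ambiguous at s2
  )
  iso <- call_isoforms(reads, "GAB2", panel)
  expect_equal(nrow(iso), 1)
  expect_equal(iso$pattern, "00")
  expect_equal(iso$freq, 1)
  expect_equal(iso$n_excluded, 1)
})

test_that("isoform marginal consistency holds exactly on simulated reads", {
  panel <- default_site_panel(sites_per_gene = 3, genes = "GAB2")
  spec <- cohort_spec(c(CTRL = 1L), site_panel = panel,
                      reads_per_sample = 2000L, error_rate = 0, seed = 3L)
  probs <- c(GAB2_s1 = 0.15, GAB2_s2 = 0.4, GAB2_s3 = 0.05)
  reads <- generate_reads(spec, probs, seed = 31L)
  iso <- call_isoforms(reads, "GAB2", panel)
  se <- call_site_editing(reads, panel, lenient_qc)
  for (k in 1:3) {
    marg <- sum(iso$freq[substr(iso$pattern, k, k) == "1"])
    expect_equal(marg, se$frac[se$site == paste0("s", k)])
  }
})

test_that("background biomarkers are dropped by the cohort-median rule", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  # s1 is signal (~0.1), s2 is background (~0.001)
  counts <- purrr::map_dfr(1:6, function(i) {
    dplyr::bind_rows(
      count_fixture(paste0("S", i), "GAB2", "s1", c(A = 900, G = 100)),
      count_fixture(paste0("S", i), "GAB2", "s2", c(A = 999, G = 1))
    )
  })
  se <- call_site_editing(counts, panel, lenient_qc)
  bm <- build_biomarker_matrix(se, qc = qc_config(1, 1, 0.005))
  expect_identical(bm$dropped, "GAB2_s2")
  expect_named(bm$values, c("sample", "GAB2_s1"))
  # threshold 0 is the identity
  bm0 <- build_biomarker_matrix(se, qc = qc_config(1, 1, 0))
  expect_length(bm0$dropped, 0)
  # all-background input is an explicit error
  expect_error(
    build_biomarker_matrix(dplyr::filter(se, site == "s2"),
                           qc = qc_config(1, 1, 0.005)),
    "background")
})

test_that("motif biomarkers average their constituent sites", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  counts <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 80, G = 20)),
    count_fixture("S1", "GAB2", "s2", c(A = 60, G = 40))
  )
  se <- call_site_editing(counts, panel, lenient_qc)
  bm <- build_biomarker_matrix(
    se, qc = qc_config(1, 1, 0),
    motif_groups = list(GAB2_m1 = c("GAB2_s1", "GAB2_s2")))
  expect_equal(bm$values$GAB2_m1, (0.2 + 0.4) / 2)
  expect_equal(bm$info$kind[bm$info$biomarker == "GAB2_m1"], "motif")
})

test_that("global-editing normalization divides by the pooled gene fraction", {
  panel <- default_site_panel(sites_per_gene = 2, genes = "GAB2")
  counts <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 70, G = 30)),   # 0.30
    count_fixture("S1", "GAB2", "s2", c(A = 100, G = 0))    # 0.00
  )
  se <- call_site_editing(counts, panel, lenient_qc)
  bm <- build_biomarker_matrix(se, qc = qc_config(1, 1, 0))
  norm <- normalize_by_global_editing(bm, se)
  # global = 30 / 200 = 0.15; biomarker 0.30 -> 2.0
  expect_equal(norm$GAB2_s1, 2.0)
  expect_equal(norm$GAB2_s2, 0.0)
  # single-site gene: value / itself = 1
  panel1 <- default_site_panel(sites_per_gene = 1, genes = "GAB2")
  se1 <- call_site_editing(
    count_fixture("S1", "GAB2", "s1", c(A = 70, G = 30)), panel1, lenient_qc)
  bm1 <- build_biomarker_matrix(se1, qc = qc_config(1, 1, 0))
  expect_equal(normalize_by_global_editing(bm1, se1)$GAB2_s1, 1.0)
  # zero global editing -> missing with a warning
  se0 <- call_site_editing(
    count_fixture("S1", "GAB2", "s1", c(A = 100)), panel1, lenient_qc)
  bm0 <- build_biomarker_matrix(se0, qc = qc_config(1, 1, 0))
  expect_warning(n0 <- normalize_by_global_editing(bm0, se0),
                 "zero global editing")
  expect_true(is.na(n0$GAB2_s1))
  expect_error(normalize_by_global_editing(bm1, se1[0, ]), "absent")
})

test_that("normalization is invariant to uniform count scaling", {
  panel <- default_site_panel(sites_per_gene = 3, genes = "GAB2")
  base_counts <- dplyr::bind_rows(
    count_fixture("S1", "GAB2", "s1", c(A = 70, G = 30)),
    count_fixture("S1", "GAB2", "s2", c(A = 95, G = 5)),
    count_fixture("S1", "GAB2", "s3", c(A = 50, G = 50))
  )
  scaled <- dplyr::mutate(base_counts, count = count * 7L)
  n1 <- normalize_by_global_editing(
    build_biomarker_matrix(call_site_editing(base_counts, panel, lenient_qc),
                           qc = qc_config(1, 1, 0)),
    call_site_editing(base_counts, panel, lenient_qc))
  n2 <- normalize_by_global_editing(
    build_biomarker_matrix(call_site_editing(scaled, panel, lenient_qc),
                           qc = qc_config(1, 1, 0)),
    call_site_editing(scaled, panel, lenient_qc))
  expect_equal(n1, n2)
})

test_that("read simulation round-trips through site calling", {
  panel <- default_site_panel(sites_per_gene = 2,
                              genes = c("GAB2", "LYN"))
  spec <- cohort_spec(c(CTRL = 1L), site_panel = panel,
                      reads_per_sample = 20000L, error_rate = 0, seed = 8L)
  probs <- c(GAB2_s1 = 0.12, GAB2_s2 = 0.35, LYN_s1 = 0.05, LYN_s2 = 0.5)
  reads <- generate_reads(spec, probs, seed = 81L)
  se <- call_site_editing(reads, panel, qc_config(10000, 50, 0.005))
  expect_true(all(se$qc_pass))
  for (b in names(probs)) {
    depth <- se$depth[se$biomarker == b]
    p <- probs[[b]]
    expect_lt(abs(se$frac[se$biomarker == b] - p),
              3 * sqrt(p * (1 - p) / depth) + 1e-9)
  }
})

test_that("SAM export and import round-trip the read-level table", {
  panel <- default_site_panel(sites_per_gene = 2, genes = c("GAB2", "LYN"))
  spec <- cohort_spec(c(CTRL = 1L), site_panel = panel,
                      reads_per_sample = 200L, error_rate = 1e-2, seed = 6L)
  probs <- c(GAB2_s1 = 0.2, GAB2_s2 = 0.6, LYN_s1 = 0.1, LYN_s2 = 0.4)
  reads <- generate_reads(spec, probs, sample_id = "SAMP7", seed = 61L)
  sam <- file.path(withr::local_tempdir(), "reads.sam")
  write_reads_sam(reads, panel, sam)
  back <- read_reads_sam(sam, panel)
  key <- function(df) dplyr::arrange(
    dplyr::select(tibble::as_tibble(df), sample, read, gene, site, base),
    sample, gene, read, site)
  expect_equal(key(back), key(reads), ignore_attr = TRUE)
})

test_that("site panel BED round-trips", {
  panel <- default_site_panel()
  bed <- file.path(withr::local_tempdir(), "panel.bed")
  write_site_panel_bed(panel, bed)
  back <- read_site_panel_bed(bed)
  expect_equal(back[, c("gene", "site", "biomarker", "pos", "strand",
                        "ref_base")],
               panel[, c("gene", "site", "biomarker", "pos", "strand",
                         "ref_base")])
})
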