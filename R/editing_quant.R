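#' Quality-control configuration for editing quantification
#'
#' @param min_sample_depth Minimal aligned reads per sample; samples below
#'   it fail QC and get missing editing values (default 10,000 reads).
#' @param min_site_depth Minimal informative reads (reference + edited) per
#'   site; shallower sites get a missing fraction (default 50 reads).
#' @param background_threshold Cohort-median editing fraction at or below
#'   which a biomarker is considered background and dropped (default 0.005).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_sample_depth = 10000,
                      min_site_depth = 50,
                      background_threshold = 0.005) {
  if (min_sample_depth <= 0 || min_site_depth <= 0) {
    abort("QC depth thresholds must be > 0")
  }
  structure(list(min_sample_depth = min_sample_depth,
                 min_site_depth = min_site_depth,
                 background_threshold = background_threshold),
            class = "qc_config")
}

## Collapse read-level records (sample, read, gene, site, base) to
## nucleotide counts (sample, gene, site, base, count); count tables pass
## through unchanged.
as_base_counts <- function(x) {
  if (all(c("sample", "gene", "site", "base", "count") %in% names(x))) {
    return(as_tibble(x))
  }
  if (all(c("sample", "read", "gene", "site", "base") %in% names(x))) {
    return(dplyr::count(as_tibble(x), .data$sample, .data$gene, .data$site,
                        .data$base, name = "count"))
  }
  abort(paste0("input must be read-level (sample, read, gene, site, base) ",
               "or a count table (sample, gene, site, base, count)"))
}

#' Call per-site editing fractions
#'
#' Counts nucleotides at each panel site and computes the editing fraction:
#' G/(A+G) on plus-strand sites, C/(T+C) on minus-strand sites. Other bases
#' (sequencing errors, N) are excluded from the denominator. Sites below
#' `min_site_depth` informative reads get a missing fraction; samples whose
#' total aligned reads fall below `min_sample_depth` are flagged failed-QC
#' and all their fractions set missing. Total reads per sample are taken as
#' the sum over genes of the deepest site's total base count (each read
#' covers all of its gene's panel sites).
#'
#' @param x Read-level records (e.g. from [generate_reads()] or
#'   [read_reads_sam()]) or a nucleotide count table with columns `sample`,
#'   `gene`, `site`, `base`, `count`.
#' @param panel Site panel tibble.
#' @param qc A [qc_config()].
#' @return A tibble of class `site_editing` with columns `sample`, `gene`,
#'   `site`, `biomarker`, `edited`, `ref_count`, `depth`, `frac`, `qc_pass`.
#' @export
call_site_editing <- function(x, panel, qc = qc_config()) {
  validate_site_panel(panel)
  counts <- as_base_counts(x)
  counts <- dplyr::semi_join(counts, panel, by = c("gene", "site"))
  if (nrow(counts) == 0) {
    out <- tibble(sample = character(), gene = character(),
                  site = character(), biomarker = character(),
                  edited = integer(), ref_count = integer(),
                  depth = integer(), frac = numeric(), qc_pass = logical())
    class(out) <- c("site_editing", class(out))
    return(out)
  }

  key <- panel |>
    mutate(alt_base = ifelse(.data$strand == "+", "G", "C")) |>
    select("gene", "site", "biomarker", "ref_base", "alt_base")

  per_site <- counts |>
    group_by(.data$sample, .data$gene, .data$site) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    left_join(
      counts |>
        left_join(key, by = c("gene", "site")) |>
        group_by(.data$sample, .data$gene, .data$site) |>
        summarise(
          edited = sum(.data$count[.data$base == .data$alt_base]),
          ref_count = sum(.data$count[.data$base == .data$ref_base]),
          .groups = "drop"
        ),
      by = c("sample", "gene", "site")
    )

  # total aligned reads per sample: deepest site per gene, summed over genes
  sample_depth <- per_site |>
    group_by(.data$sample, .data$gene) |>
    summarise(gene_reads = max(.data$total), .groups = "drop") |>
    group_by(.data$sample) |>
    summarise(sample_reads = sum(.data$gene_reads), .groups = "drop")

  # all (sample, panel site) combinations so absent sites appear as missing
  grid <- tidyr::expand_grid(sample = unique(counts$sample),
                             key[, c("gene", "site", "biomarker")])
  out <- grid |>
    left_join(per_site, by = c("sample", "gene", "site")) |>
    left_join(sample_depth, by = "sample") |>
    mutate(
      edited = dplyr::coalesce(.data$edited, 0L),
      ref_count = dplyr::coalesce(.data$ref_count, 0L),
      depth = .data$edited + .data$ref_count,
      qc_pass = .data$sample_reads >= qc$min_sample_depth,
      frac = ifelse(.data$qc_pass & .data$depth >= qc$min_site_depth,
                    .data$edited / .data$depth, NA_real_)
    ) |>
    select("sample", "gene", "site", "biomarker", "edited", "ref_count",
           "depth", "frac", "qc_pass")
  class(out) <- c("site_editing", class(out))
  out
}

#' Per-read editing isoforms of a gene
#'
#' An editing isoform is the joint per-read binary editing pattern over a
#' gene's panel sites (sites ordered by position; `1` = edited). Reads that
#' lack an unambiguous reference-or-edited call at any site are excluded
#' and counted. Per-sample pattern frequencies sum to one, and the marginal
#' editing fraction of a site equals the summed frequency of patterns
#' edited at that site.
#'
#' @param reads Read-level records (`sample`, `read`, `gene`, `site`,
#'   `base`).
#' @param gene Gene symbol.
#' @param panel Site panel tibble.
#' @return Tibble with columns `sample`, `gene`, `pattern`, `biomarker`
#'   (`<gene>_iso_<pattern>`), `freq`, `n_reads`, `n_excluded`.
#' @export
call_isoforms <- function(reads, gene, panel) {
  validate_site_panel(panel)
  sites <- panel[panel$gene == gene, ]
  if (nrow(sites) == 0) abort(paste0("gene not in panel: ", gene))
  sites <- sites[order(sites$pos), ]
  alt <- ifelse(sites$strand == "+", "G", "C")
  names(alt) <- sites$site
  ref <- setNames(sites$ref_base, sites$site)

  g_reads <- as_tibble(reads) |>
    filter(.data$gene == !!gene, .data$site %in% sites$site) |>
    mutate(state = dplyr::case_when(
      .data$base == alt[.data$site] ~ "1",
      .data$base == ref[.data$site] ~ "0",
      TRUE ~ NA_character_
    ))

  wide <- g_reads |>
    select("sample", "read", "site", "state") |>
    tidyr::pivot_wider(names_from = "site", values_from = "state")
  missing_cols <- setdiff(sites$site, names(wide))
  for (m in missing_cols) wide[[m]] <- NA_character_
  pat_mat <- as.matrix(wide[, sites$site, drop = FALSE])
  ok <- rowSums(is.na(pat_mat)) == 0
  pattern <- apply(pat_mat, 1, paste0, collapse = "")

  excl <- tibble(sample = wide$sample, ok = ok) |>
    group_by(.data$sample) |>
    summarise(n_reads = sum(.data$ok), n_excluded = sum(!.data$ok),
              .groups = "drop")

  out <- tibble(sample = wide$sample[ok], pattern = pattern[ok]) |>
    count(.data$sample, .data$pattern, name = "n_pattern") |>
    group_by(.data$sample) |>
    mutate(freq = .data$n_pattern / sum(.data$n_pattern)) |>
    ungroup() |>
    left_join(excl, by = "sample") |>
    mutate(gene = gene,
           biomarker = paste0(gene, "_iso_", .data$pattern)) |>
    select("sample", "gene", "pattern", "biomarker", "freq",
           "n_reads", "n_excluded")
  out
}

#' Assemble the biomarker matrix with background filtering
#'
#' Pivots site fractions (and optionally isoform frequencies and declared
#' motif groups) to a samples-by-biomarkers table, then drops biomarkers
#' whose cohort-median value is at or below the background threshold. A
#' motif biomarker is the mean editing fraction over a declared group of
#' sites of one gene.
#'
#' @param sites A `site_editing` table from [call_site_editing()].
#' @param isoforms Optional isoform table(s) from [call_isoforms()]
#'   (rows can cover several genes).
#' @param qc A [qc_config()]; supplies `background_threshold`.
#' @param motif_groups Optional named list: motif biomarker id (must be
#'   `<gene>_<name>`) to character vector of constituent site biomarker ids.
#' @return A list of class `biomarker_matrix` with `values` (wide tibble,
#'   `sample` first), `info` (biomarker, gene, kind, n_sites) and `dropped`
#'   (background biomarker ids).
#' @export
build_biomarker_matrix <- function(sites, isoforms = NULL, qc = qc_config(),
                                   motif_groups = NULL) {
  values <- sites |>
    select("sample", "biomarker", "frac") |>
    tidyr::pivot_wider(names_from = "biomarker", values_from = "frac")
  info <- sites |>
    distinct(.data$biomarker, .data$gene) |>
    mutate(kind = "site", n_sites = 1L)

  if (!is.null(isoforms)) {
    iso_wide <- isoforms |>
      select("sample", "biomarker", "freq") |>
      tidyr::pivot_wider(names_from = "biomarker", values_from = "freq",
                         values_fill = 0)
    # samples failing site QC keep missing isoform values too
    failed <- unique(sites$sample[!sites$qc_pass])
    iso_wide[iso_wide$sample %in% failed, -1] <- NA_real_
    values <- left_join(values, iso_wide, by = "sample")
    info <- bind_rows(info, isoforms |>
      distinct(.data$biomarker, .data$gene) |>
      mutate(kind = "isoform", n_sites = nchar(sub(".*_iso_", "", .data$biomarker))))
  }

  if (!is.null(motif_groups)) {
    for (m in names(motif_groups)) {
      members <- motif_groups[[m]]
      if (!all(members %in% names(values))) {
        abort(paste0("motif ", m, " refers to unknown site biomarkers"))
      }
      values[[m]] <- rowMeans(values[, members, drop = FALSE])
      info <- bind_rows(info, tibble(
        biomarker = m, gene = biomarker_gene(m), kind = "motif",
        n_sites = length(members)
      ))
    }
  }

  med <- vapply(values[, -1, drop = FALSE], median, numeric(1), na.rm = TRUE)
  dropped <- names(med)[!is.na(med) & med <= qc$background_threshold]
  if (qc$background_threshold <= 0) dropped <- character(0)
  if (length(dropped) == ncol(values) - 1L) {
    abort("all biomarkers fall at or below the background threshold")
  }
  values <- values[, c("sample", setdiff(names(values)[-1], dropped))]
  info <- filter(info, .data$biomarker %in% names(values))

  structure(list(values = values, info = info, dropped = dropped),
            class = "biomarker_matrix")
}

#' @export
print.biomarker_matrix <- function(x, ...) {
  cat("<biomarker_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values) - 1L, " biomarkers (",
      length(x$dropped), " dropped as background)\n", sep = "")
  print(count(x$info, .data$gene, .data$kind))
  invisible(x)
}

## Accept a biomarker_matrix, a synthetic_cohort, or a plain wide tibble.
as_biomarker_values <- function(x) {
  if (inherits(x, "biomarker_matrix")) return(x$values)
  if (inherits(x, "synthetic_cohort")) return(x$biomarkers)
  as_tibble(x)
}

#' Normalize biomarkers by per-gene global editing
#'
#' The global editing of a gene in a sample is the pooled fraction
#' `sum(edited) / sum(edited + reference)` over the gene's panel sites.
#' Every biomarker of that gene is divided by it, making values relative to
#' the gene's overall editing activity. When no count table is supplied the
#' global editing is taken as the mean of the gene's site fractions (exact
#' for equal site depths). A zero global editing yields missing values.
#'
#' @param x A `biomarker_matrix`, `synthetic_cohort` or wide values tibble.
#' @param sites Optional `site_editing` count table for exact pooled
#'   fractions.
#' @return A wide tibble of normalized values (same shape as the input
#'   values; dimensionless ratios).
#' @export
normalize_by_global_editing <- function(x, sites = NULL) {
  values <- as_biomarker_values(x)
  ids <- setdiff(names(values), "sample")
  genes <- biomarker_gene(ids)
  if (!is.null(sites)) {
    missing_genes <- setdiff(unique(genes), unique(sites$gene))
    if (length(missing_genes) > 0) {
      abort(paste0("gene(s) absent from the site table: ",
                   paste(missing_genes, collapse = ", ")))
    }
    glob <- sites |>
      group_by(.data$sample, .data$gene) |>
      summarise(global = sum(.data$edited) /
                  pmax(sum(.data$edited) + sum(.data$ref_count), 1),
                .groups = "drop") |>
      tidyr::pivot_wider(names_from = "gene", values_from = "global")
    glob <- glob[match(values$sample, glob$sample), ]
  } else {
    site_cols <- ids[grepl("_s[0-9]+$", ids)]
    glob <- tibble(sample = values$sample)
    for (g in unique(genes)) {
      cols <- site_cols[biomarker_gene(site_cols) == g]
      if (length(cols) == 0) {
        abort(paste0("no site biomarkers available to compute global ",
                     "editing for gene ", g))
      }
      glob[[g]] <- rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
    }
  }
  out <- values
  n_zero <- 0L
  for (j in ids) {
    gv <- glob[[biomarker_gene(j)]]
    gv[!is.na(gv) & gv == 0] <- NA_real_
    n_zero <- n_zero + sum(is.na(gv) & !is.na(values[[j]]))
    out[[j]] <- values[[j]] / gv
  }
  if (n_zero > 0) {
    warn(sprintf("%d value(s) set missing due to zero global editing", n_zero))
  }
  out
}
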