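#' Default editing-site panel for the eight-gene blood panel
#'
#' Builds the default targeted-amplicon site panel: a fixed number of A-to-I
#' editing sites per gene, laid out on per-gene amplicon coordinates
#' (0-based). Sites on the plus strand carry reference base A (editing reads
#' as A>G); minus-strand genes carry T (editing reads as T>C on the
#' sequenced strand).
#'
#' @param sites_per_gene Number of editing sites per gene. The default, 6,
#'   gives a 48-site panel across the eight genes.
#' @param genes Gene symbols; defaults to the eight-gene panel.
#' @param minus_strand_genes Genes whose amplicon is sequenced on the minus
#'   strand.
#' @return A tibble with columns `gene`, `site`, `biomarker`, `pos`
#'   (0-based), `strand`, `ref_base`.
#' @export
default_site_panel <- function(sites_per_gene = 6,
                               genes = panel_genes(),
                               minus_strand_genes = c("LYN", "MDM2")) {
  stopifnot(sites_per_gene >= 1)
  purrr::map_dfr(genes, function(g) {
    strand <- if (g %in% minus_strand_genes) "-" else "+"
    tibble(
      gene = g,
      site = paste0("s", seq_len(sites_per_gene)),
      pos = 40L * seq_len(sites_per_gene),  # spread along a ~300 bp amplicon
      strand = strand,
      ref_base = ifelse(strand == "+", "A", "T")
    )
  }) |>
    mutate(biomarker = paste(.data$gene, .data$site, sep = "_"),
           .after = "site")
}

validate_site_panel <- function(panel) {
  req <- c("gene", "site", "biomarker", "pos", "strand", "ref_base")
  missing <- setdiff(req, names(panel))
  if (length(missing) > 0) {
    abort(paste0("site panel lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(panel[, c("gene", "pos")]) > 0) {
    abort("site panel positions must be unique within each gene")
  }
  bad <- (panel$strand == "+" & panel$ref_base != "A") |
    (panel$strand == "-" & panel$ref_base != "T")
  if (any(bad)) {
    abort("reference base must be A on + strand and T on - strand")
  }
  invisible(panel)
}

#' Write / read a site panel as 6-column BED
#'
#' The BED uses per-gene amplicon coordinates: column 1 is the gene symbol,
#' columns 2-3 the 0-based half-open site interval, column 4 the biomarker
#' id (`gene_site`), column 5 a zero score, column 6 the strand.
#'
#' @param panel A site panel tibble (see [default_site_panel()]).
#' @param path File path.
#' @return `write_site_panel_bed()` returns `path` invisibly;
#'   `read_site_panel_bed()` returns a site panel tibble.
#' @export
write_site_panel_bed <- function(panel, path) {
  validate_site_panel(panel)
  bed <- tibble(
    chrom = panel$gene,
    start = as.integer(panel$pos),
    end = as.integer(panel$pos) + 1L,
    name = panel$biomarker,
    score = 0L,
    strand = panel$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_site_panel_bed
#' @export
read_site_panel_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  panel <- tibble(
    gene = bed$chrom,
    site = sub("^[^_]*_", "", bed$name),
    biomarker = bed$name,
    pos = bed$start,
    strand = bed$strand,
    ref_base = ifelse(bed$strand == "+", "A", "T")
  )
  validate_site_panel(panel)
  panel
}
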