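## Amplicon length of a gene: one spacer beyond the last panel site.
amplicon_length <- function(panel, gene) {
  max(panel$pos[panel$gene == gene]) + 40L
}

#' Write simulated reads as SAM
#'
#' Exports read-level records as a minimal SAM file: one `@SQ` line per
#' gene amplicon (per-gene coordinate space), one alignment line per read
#' starting at position 1 with a full-length match CIGAR. Non-site
#' positions carry a constant filler base; panel-site positions carry the
#' read's base calls.
#'
#' @param reads Read-level tibble (`sample`, `read`, `gene`, `site`,
#'   `base`).
#' @param panel Site panel tibble.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, panel, path) {
  validate_site_panel(panel)
  genes <- unique(panel$gene)
  lens <- vapply(genes, function(g) amplicon_length(panel, g), integer(1))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genes, lens))

  wide <- as_tibble(reads) |>
    left_join(panel[, c("gene", "site", "pos")], by = c("gene", "site")) |>
    arrange(.data$sample, .data$gene, .data$read)
  per_read <- split(wide, paste(wide$sample, wide$gene, wide$read, sep = "\r"))
  lines <- vapply(per_read, function(df) {
    g <- df$gene[1]
    len <- lens[[g]]
    seq <- rep("C", len)
    seq[df$pos + 1L] <- df$base  # site pos is 0-based, SAM POS = 1
    paste(paste0(df$sample[1], ":", df$read[1]), 0L, g, 1L, 60L,
          paste0(len, "M"), "*", 0L, 0L, paste(seq, collapse = ""), "*",
          sep = "\t")
  }, character(1))
  writeLines(c(header, unname(lines)), path)
  invisible(path)
}

#' Read panel-site base calls from a SAM/BAM file
#'
#' Parses aligned reads (via Rsamtools) and extracts the base call at
#' every panel site covered by each read, reconstructing the read-level
#' table consumed by [call_site_editing()] and [call_isoforms()]. Read
#' names are expected as `<sample>:<read id>` (as written by
#' [write_reads_sam()]); unprefixed names fall back to `sample_id`.
#'
#' @param path SAM or BAM file path.
#' @param panel Site panel tibble.
#' @param sample_id Sample id used when read names carry none.
#' @return Read-level tibble (`sample`, `read`, `gene`, `site`, `base`).
#' @export
read_reads_sam <- function(path, panel, sample_id = "S001") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM requires the Rsamtools package")
  }
  validate_site_panel(panel)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "seq")))[[1]]
  seqs <- as.character(rec$seq)
  qname <- rec$qname
  has_prefix <- grepl(":", qname, fixed = TRUE)
  sample <- ifelse(has_prefix, sub(":.*$", "", qname), sample_id)
  read_id <- ifelse(has_prefix, sub("^[^:]*:", "", qname), qname)
  gene <- as.character(rec$rname)

  purrr::map_dfr(seq_along(seqs), function(i) {
    sites <- panel[panel$gene == gene[i], ]
    # offset of each 0-based site within the read (alignment start rec$pos)
    off <- sites$pos + 1L - rec$pos[i] + 1L
    ok <- off >= 1 & off <= nchar(seqs[i])
    if (!any(ok)) return(tibble())
    tibble(sample = sample[i], read = read_id[i], gene = gene[i],
           site = sites$site[ok],
           base = substring(seqs[i], off[ok], off[ok]))
  })
}
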