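#' Read exon models from a GTF annotation
#'
#' Parses the `exon` features of an Ensembl-dialect GTF file into a tidy
#' exon table, one row per exon. Transcript biotypes are collapsed to the
#' three classes used downstream: `protein_coding` maps to `"mRNA"`;
#' `lncRNA`, `lincRNA` and `antisense` map to `"lncRNA"`; everything else is
#' `"other"`. The `transcript_biotype` attribute is preferred,
#' `gene_biotype` is the fallback. Exon records lacking a `transcript_id`
#' are skipped with a warning; a file yielding zero transcripts is an error.
#'
#' @param path Path to a GTF file.
#'
#' @return A tibble with columns `transcript_id`, `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `exon_start`, `exon_end`, `biotype`, sorted by
#'   transcript then exon start. Single-exon transcripts are retained.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GTF file not found: ", path), class = "circAS_io_error")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(md)) md$transcript_id else rep(NA_character_, length(gr))
  missing_tid <- is.na(tid) | tid == ""
  if (any(missing_tid)) {
    warn(sprintf("skipping %d exon record(s) without transcript_id", sum(missing_tid)))
    gr <- gr[!missing_tid]
    md <- S4Vectors::mcols(gr)
    tid <- md$transcript_id
  }
  if (length(gr) == 0) {
    abort("no transcripts parsed from GTF", class = "circAS_format_error")
  }
  get_attr <- function(name, default = NA_character_) {
    if (name %in% names(md)) as.character(md[[name]]) else rep(default, length(gr))
  }
  bt_raw <- get_attr("transcript_biotype")
  bt_fallback <- get_attr("gene_biotype")
  bt_raw <- ifelse(is.na(bt_raw), bt_fallback, bt_raw)
  exons <- tibble(
    transcript_id = as.character(tid),
    gene_id = get_attr("gene_id"),
    gene_name = get_attr("gene_name"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_start = GenomicRanges::start(gr),
    exon_end = GenomicRanges::end(gr),
    biotype = map_biotype(bt_raw)
  ) %>%
    mutate(gene_name = if_else(is.na(.data$gene_name), .data$gene_id, .data$gene_name)) %>%
    arrange(.data$transcript_id, .data$exon_start)
  exons
}

map_biotype <- function(x) {
  dplyr::case_when(
    x %in% "protein_coding" ~ "mRNA",
    x %in% c("lncRNA", "lincRNA", "antisense") ~ "lncRNA",
    TRUE ~ "other"
  )
}

#' Derive the intron table of an exon model
#'
#' @param exons Exon tibble as returned by [read_annotation()].
#'
#' @return A tibble with one row per intron: `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `biotype`, `intron_start`, `intron_end`,
#'   `intron_len`, `donor` (last exonic base 5' of the intron on the plus
#'   strand) and `acceptor` (first exonic base 3' of it). Single-exon
#'   transcripts contribute no rows.
#' @export
introns_of <- function(exons) {
  exons %>%
    arrange(.data$transcript_id, .data$exon_start) %>%
    dplyr::reframe(
      donor = head(.data$exon_end, -1),
      acceptor = tail(.data$exon_start, -1),
      .by = c("transcript_id", "gene_id", "gene_name", "chrom", "strand", "biotype")
    ) %>%
    mutate(
      intron_start = .data$donor + 1L,
      intron_end = .data$acceptor - 1L,
      intron_len = .data$intron_end - .data$intron_start + 1L
    )
}
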