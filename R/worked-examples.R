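# Synthetic reconstructions of two RT-PCR-validated circRNA splicing
# events, placed at their published genomic coordinates on synthetic
# contigs (sequence is N up to shortly before the circle, random around
# it). These are simulation fixtures, not real human sequence.

worked_example_fixture <- function(chrom, circ_start, circ_end, exon_mat,
                                   iso_b, gene_name, seed,
                                   params = sim_params(seed = seed)) {
  set.seed(seed)
  pad <- circ_start - 200L
  region_len <- circ_end + 300L - pad

  # plant motifs on the small active region, then N-pad once: in-place
  # edits on a multi-megabase string copy the whole string each time
  region <- setNames(random_seq(region_len), chrom)
  iso_a <- exon_mat
  strand <- "+"
  jx <- dplyr::bind_rows(iso_junctions(iso_a), iso_junctions(iso_b)) %>% distinct()
  for (i in seq_len(nrow(jx))) {
    region <- plant_motif(region, chrom, jx$donor[i] - pad, jx$acceptor[i] - pad,
                          strand)
  }
  region <- plant_motif(region, chrom, circ_end - pad, circ_start - pad, strand)
  buf <- rep(charToRaw("N"), pad + region_len)
  buf[pad + seq_len(region_len)] <- charToRaw(region[[chrom]])
  # hand the pipeline a DNAStringSet directly: converting a contig of this
  # size from character costs more than the whole detection run
  genome <- Biostrings::DNAStringSet(setNames(rawToChar(buf), chrom))

  exons <- tibble(
    transcript_id = paste0(gene_name, ".t1"), gene_id = gene_name,
    gene_name = gene_name, chrom = chrom, strand = strand,
    exon_start = iso_a[, 1L], exon_end = iso_a[, 2L],
    biotype_raw = "protein_coding", biotype = "mRNA"
  )
  circles <- tibble(
    circ_id = gene_name, chrom = chrom, start = circ_start, end = circ_end,
    strand = strand, gene_name = gene_name,
    isoforms = list(list(iso_a, iso_b)), weights = list(c(0.6, 0.4))
  )
  list(genome = genome, exons = exons, circles = circles,
       truth_junctions = tibble(circ_id = gene_name, chrom = chrom,
                                donor = jx$donor, acceptor = jx$acceptor),
       decoys = tibble(circ_id = character(), chrom = character(),
                       kind = character(), pos1 = integer(), pos2 = integer()),
       background = list(), params = params)
}

#' Synthetic circ-UBAP2L alternative 5' splice-site fixture
#'
#' Reconstructs, at the published coordinates of the validated UBAP2L
#' circRNA (chr1:154234591-154235291), a two-isoform circle whose isoforms
#' differ only at one internal 5' splice site: a 33 bp portion of a partial
#' exon is alternatively spliced. The contig is synthetic (N up to the
#' circle neighbourhood, random sequence with canonical planted motifs
#' around it); only the coordinates and the 33 bp segment length are taken
#' from the validated event.
#'
#' @param seed RNG seed for the genome sequence and read sampling.
#' @param params Simulation parameters (see [sim_params()]); read geometry
#'   defaults to 30x coverage of 2x100 bp pairs.
#'
#' @return A fixture list as from [sim_fixture()], with
#'   `truth_events` describing the single planted A5SS event (alt_len 33).
#' @export
sim_circ_ubap2l <- function(seed = 1L, params = sim_params(seed = seed)) {
  chrom <- "chr1"
  circ_start <- 154234591L
  circ_end <- 154235291L
  delta <- 33L
  exon_mat <- rbind(
    c(154234591L, 154234900L),
    c(154235100L, 154235291L)
  )
  iso_b <- exon_mat
  iso_b[1, 2] <- iso_b[1, 2] - delta
  fx <- worked_example_fixture(chrom, circ_start, circ_end, exon_mat, iso_b,
                               "UBAP2L", seed, params)
  fx$truth_events <- tibble(
    circ_id = "UBAP2L", chrom = chrom, circ_start = circ_start,
    circ_end = circ_end, event_type = "A5SS",
    alt_start = exon_mat[1, 2] - delta + 1L, alt_end = exon_mat[1, 2]
  )
  fx
}

#' Synthetic circ-RAB6A exon-skipping fixture
#'
#' Reconstructs, at the published coordinates of the validated RAB6A
#' circRNA (chr11:73707420-73718718), a two-isoform circle in which one
#' isoform skips a single 95 bp annotated internal exon. Synthetic contig;
#' only the coordinates and the 95 bp exon length are taken from the
#' validated event.
#'
#' @inheritParams sim_circ_ubap2l
#' @return A fixture list; `truth_events` holds the single planted SE event
#'   (alt_len 95).
#' @export
sim_circ_rab6a <- function(seed = 1L, params = sim_params(seed = seed)) {
  chrom <- "chr11"
  circ_start <- 73707420L
  circ_end <- 73718718L
  exon_mat <- rbind(
    c(73707420L, 73707719L),
    c(73712000L, 73712094L),   # the 95 bp skipped exon
    c(73718430L, 73718718L)
  )
  iso_b <- exon_mat[-2, , drop = FALSE]
  fx <- worked_example_fixture(chrom, circ_start, circ_end, exon_mat, iso_b,
                               "RAB6A", seed, params)
  fx$truth_events <- tibble(
    circ_id = "RAB6A", chrom = chrom, circ_start = circ_start,
    circ_end = circ_end, event_type = "SE",
    alt_start = 73712000L, alt_end = 73712094L
  )
  fx
}
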