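#' Read a reference genome from FASTA
#'
#' Loads a single- or multi-record FASTA file into a named
#' [Biostrings::DNAStringSet]. Record names are truncated at the first
#' whitespace and sequences are uppercased, so `">c1 some description"`
#' becomes chromosome `"c1"`.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#'
#' @return A [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "circAS_io_error")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    abort(
      paste0(
        "duplicate chromosome name(s) in FASTA: ",
        paste(unique(nms[duplicated(nms)]), collapse = ", ")
      ),
      class = "circAS_format_error"
    )
  }
  names(seqs) <- nms
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Extract a genomic subsequence
#'
#' 1-based inclusive coordinates. Querying an unknown chromosome or
#' coordinates outside `[1, length]` is an error, never an empty string.
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]),
#'   or a named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#'
#' @return A character string of exactly `end - start + 1` bases.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown chromosome: ", chrom), class = "circAS_coord_error")
  }
  len <- length(genome[[chrom]])
  if (start < 1 || end > len || start > end) {
    abort(
      sprintf("coordinates out of range: %s:%d-%d (length %d)", chrom, start, end, len),
      class = "circAS_coord_error"
    )
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Check a junction for the canonical splice motif
#'
#' A splice junction joining a donor (last exonic base on the 5' side of the
#' intron-like gap, in genomic plus-strand coordinates) to an acceptor
#' (first exonic base on the 3' side) is canonical when the gap is flanked by
#' GT..AG on the plus strand, or by CT..AC — the reverse complement pattern,
#' i.e. a minus-strand GT..AG intron read on the plus strand. The same rule
#' applies to back-splice junctions, with `donor_end` the circRNA 3' end and
#' `acceptor_start` its 5' end.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param chrom Chromosome name.
#' @param donor_end Last exonic base upstream of the gap (1-based).
#' @param acceptor_start First exonic base downstream of the gap.
#'
#' @return A list with `ok` (logical), `strand` (`"+"`, `"-"`, or `NA`),
#'   and `motif` (4-character donor+acceptor dinucleotides, e.g. `"GTAG"`).
#' @export
check_splice_motif <- function(genome, chrom, donor_end, acceptor_start) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown chromosome: ", chrom), class = "circAS_coord_error")
  }
  len <- length(genome[[chrom]])
  if (acceptor_start - 2 < 1 || donor_end + 2 > len) {
    warn(sprintf(
      "junction %s:%d-%d within 2 bp of a chromosome edge; motif check fails",
      chrom, donor_end, acceptor_start
    ))
    return(list(ok = FALSE, strand = NA_character_, motif = NA_character_))
  }
  don <- genome_seq(genome, chrom, donor_end + 1, donor_end + 2)
  acc <- genome_seq(genome, chrom, acceptor_start - 2, acceptor_start - 1)
  motif <- paste0(don, acc)
  if (motif == "GTAG") {
    list(ok = TRUE, strand = "+", motif = motif)
  } else if (motif == "CTAC") {
    list(ok = TRUE, strand = "-", motif = motif)
  } else {
    list(ok = FALSE, strand = NA_character_, motif = motif)
  }
}

# coerce a genome argument: DNAStringSet as-is, a single path to a FASTA
# file via read_genome(), a named character vector of sequences directly
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    return(read_genome(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("genome must be a DNAStringSet, a FASTA path, or named sequences",
        class = "circAS_config_error")
}

# vectorised motif lookup used by the detection hot paths; returns a tibble
# with columns ok, strand, motif, aligned with the inputs
motif_table <- function(genome, chrom, donor_end, acceptor_start) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  n <- length(chrom)
  ok <- logical(n)
  strand <- rep(NA_character_, n)
  motif <- rep(NA_character_, n)
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(lens)) next
    if (acceptor_start[i] - 2 < 1 || donor_end[i] + 2 > lens[[chrom[i]]]) next
    m <- paste0(
      as.character(Biostrings::subseq(genome[[chrom[i]]], donor_end[i] + 1, donor_end[i] + 2)),
      as.character(Biostrings::subseq(genome[[chrom[i]]], acceptor_start[i] - 2, acceptor_start[i] - 1))
    )
    motif[i] <- m
    if (m == "GTAG") {
      ok[i] <- TRUE
      strand[i] <- "+"
    } else if (m == "CTAC") {
      ok[i] <- TRUE
      strand[i] <- "-"
    }
  }
  tibble(ok = ok, strand = strand, motif = motif)
}
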