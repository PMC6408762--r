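#' Read RNA-seq alignments from SAM or BAM
#'
#' Loads alignment records into a tidy per-record table suitable for
#' junction and back-splice analysis. Reference-aligned blocks are computed
#' from the CIGAR: match operations consume a block, `N` skips separate
#' blocks, and deletions or skips shorter than `min_intron_len` are merged
#' into one block (small gaps are indels, not splice junctions). Unmapped
#' and secondary records are dropped; supplementary (chimeric) records are
#' kept and share the `read_id` of their primary record so that chimeric
#' segment pairs can be re-assembled by grouping.
#'
#' Query offsets (`query_start`, `query_end`) are the 1-based positions of
#' the aligned segment within the read *as stored* (reference orientation),
#' derived from soft and hard clips. For the two segments of a chimeric
#' read these offsets tile the read, whichever strand it aligned to.
#'
#' @param path Path to a `.sam` or `.bam` file. Plain SAM is converted to
#'   BAM in a temporary file via [Rsamtools::asBam()].
#' @param min_intron_len Reference gaps of at least this many bases are
#'   junction candidates; smaller gaps merge into one block. Default 30.
#'
#' @return A tibble with one row per kept alignment record: `qname`, `mate`
#'   (1 or 2), `read_id` (qname + mate; the unit of "distinct read"
#'   counting), `chrom`, `strand`, `blocks` (list column of two-column
#'   integer matrices, columns start/end, ascending), `ref_start`,
#'   `ref_end`, `query_start`, `query_end`, `supplementary` (logical),
#'   `mate_chrom`, `mate_start`.
#' @export
read_alignments <- function(path, min_intron_len = 30L) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path), class = "circAS_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mrnm", "mpos"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) {
    return(empty_reads())
  }
  flag <- res$flag
  cigar <- res$cigar

  bl <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = res$pos, drop.D.ranges = FALSE
  )
  bl <- IRanges::reduce(bl, min.gapwidth = as.integer(min_intron_len))
  starts <- as.list(IRanges::start(bl))
  ends <- as.list(IRanges::end(bl))
  blocks <- purrr::map2(starts, ends, function(s, e) {
    cbind(start = as.integer(s), end = as.integer(e))
  })

  # aligned-portion query span in stored orientation: leading hard+soft
  # clips offset the start, and the aligned width (M/I/=/X) sets the end
  lead_h <- rep(0L, n)
  has_h <- grepl("^[0-9]+H", cigar)
  lead_h[has_h] <- as.integer(sub("^([0-9]+)H.*$", "\\1", cigar[has_h]))
  lead_s <- rep(0L, n)
  has_s <- grepl("^([0-9]+H)?[0-9]+S", cigar)
  lead_s[has_s] <- as.integer(sub("^([0-9]+H)?([0-9]+)S.*$", "\\2", cigar[has_s]))
  alnw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                                       after.soft.clipping = TRUE)
  qstart <- lead_h + lead_s + 1L
  mate <- if_else(bitwAnd(flag, 128L) > 0L, 2L, 1L)

  tibble(
    qname = res$qname,
    mate = mate,
    read_id = paste0(res$qname, "/", mate),
    chrom = as.character(res$rname),
    strand = if_else(bitwAnd(flag, 16L) > 0L, "-", "+"),
    blocks = blocks,
    ref_start = purrr::map_int(blocks, function(b) b[1L, 1L]),
    ref_end = purrr::map_int(blocks, function(b) b[nrow(b), 2L]),
    query_start = qstart,
    query_end = qstart + alnw - 1L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    mate_chrom = as.character(res$mrnm),
    mate_start = res$mpos
  )
}

empty_reads <- function() {
  tibble(
    qname = character(), mate = integer(), read_id = character(),
    chrom = character(), strand = character(), blocks = list(),
    ref_start = integer(), ref_end = integer(),
    query_start = integer(), query_end = integer(),
    supplementary = logical(), mate_chrom = character(),
    mate_start = integer()
  )
}
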