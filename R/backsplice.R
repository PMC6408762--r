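#' Find back-splice junction candidates in chimeric reads
#'
#' A back-splice junction (BSJ) — the head-to-tail junction diagnostic of a
#' circRNA — shows up in alignments as a chimeric read whose two segments
#' map to the same chromosome and strand in *inverted* order: the segment
#' later in the (stored) read maps upstream of the earlier segment. The two
#' segments must tile the read contiguously, with up to 2 bases of overlap
#' or gap tolerated for aligner end-trimming. The candidate circRNA then
#' spans from the leftmost base of the downstream-in-read segment to the
#' rightmost base of the upstream-in-read segment.
#'
#' @param reads Alignment table from [read_alignments()].
#'
#' @return A tibble of candidates: `read_id`, `qname`, `chrom`, `start`,
#'   `end`. Reads without an inverted segment pair contribute no rows.
#' @export
find_bsj_candidates <- function(reads) {
  empty <- tibble(read_id = character(), qname = character(),
                  chrom = character(), start = integer(), end = integer())
  if (nrow(reads) == 0) return(empty)
  multi <- reads %>%
    group_by(.data$read_id) %>%
    filter(n() >= 2) %>%
    ungroup()
  if (nrow(multi) == 0) return(empty)
  out <- multi %>%
    dplyr::group_split(.data$read_id) %>%
    purrr::map(function(g) {
      g <- g[order(g$query_start), ]
      k <- nrow(g)
      res <- list()
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          a <- g[i, ]  # earlier in stored read
          b <- g[j, ]  # later in stored read
          if (a$chrom != b$chrom || a$strand != b$strand) next
          if (abs(b$query_start - a$query_end - 1L) > 2L) next
          if (b$ref_end >= a$ref_start) next  # not inverted
          res[[length(res) + 1]] <- tibble(
            read_id = a$read_id, qname = a$qname, chrom = a$chrom,
            start = b$ref_start, end = a$ref_end
          )
        }
      }
      bind_rows(res)
    }) %>%
    bind_rows()
  if (nrow(out) == 0) empty else out
}

#' Aggregate BSJ candidates into supported, motif-filtered junctions
#'
#' Candidates are grouped by exact coordinates; each group must pass the
#' canonical splice-motif check (GT..AG on the plus strand or CT..AC, its
#' minus-strand mirror, at the back-splice flanks) and reach
#' `min_bsj_support` distinct supporting reads. The junction strand is
#' assigned by which motif matched (GTAG = `+`, CTAC = `-`), not by read
#' flags.
#'
#' @param candidates Candidate tibble from [find_bsj_candidates()].
#' @param genome Reference genome ([read_genome()] or named character).
#' @param min_bsj_support Minimum distinct BSJ-spanning reads (default 2).
#'
#' @return A tibble of back-splice junctions sorted by `chrom` then
#'   `start`: `chrom`, `start` (circRNA 5' end), `end` (3' end), `strand`,
#'   `support`, `motif`.
#' @export
aggregate_bsj <- function(candidates, genome, min_bsj_support = 2L) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), support = integer(), motif = character())
  if (nrow(candidates) == 0) return(empty)
  grouped <- candidates %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(support = n_distinct(.data$read_id), .groups = "drop")
  mt <- motif_table(genome, grouped$chrom,
                    donor_end = grouped$end, acceptor_start = grouped$start)
  grouped %>%
    mutate(strand = mt$strand, motif = mt$motif, ok = mt$ok) %>%
    filter(.data$ok, .data$support >= min_bsj_support) %>%
    select("chrom", "start", "end", "strand", "support", "motif") %>%
    arrange(.data$chrom, .data$start, .data$end)
}

#' Detect circRNA back-splice junctions in a sample
#'
#' Convenience wrapper: [find_bsj_candidates()] followed by
#' [aggregate_bsj()].
#'
#' @inheritParams find_bsj_candidates
#' @inheritParams aggregate_bsj
#' @return See [aggregate_bsj()].
#' @export
detect_bsj <- function(reads, genome, min_bsj_support = 2L) {
  aggregate_bsj(find_bsj_candidates(reads), genome, min_bsj_support)
}
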