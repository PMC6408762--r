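#' Assign reads to detected circRNAs
#'
#' For each back-splice junction (BSJ), the evidence set for internal
#' splicing analysis is (a) every BSJ-spanning read of that circle and (b)
#' every mate of a BSJ-spanning read whose aligned blocks fall entirely
#' within the circle span. Reads satisfying several nested circles are
#' assigned to every one of them.
#'
#' @param bsj BSJ table from [detect_bsj()].
#' @param reads Alignment table from [read_alignments()].
#' @param candidates Optional precomputed [find_bsj_candidates()] output.
#'
#' @return The read table with three leading key columns `circ_chrom`,
#'   `circ_start`, `circ_end`; one row per (circle, alignment record).
#' @export
assign_reads_to_circ <- function(bsj, reads, candidates = NULL) {
  if (is.null(candidates)) candidates <- find_bsj_candidates(reads)
  empty <- bind_rows(
    tibble(circ_chrom = character(), circ_start = integer(), circ_end = integer()),
    empty_reads()[0, ]
  )[0, ]
  if (nrow(bsj) == 0 || nrow(reads) == 0) return(empty)

  # (a) BSJ-spanning reads: candidate coordinates equal the circle's
  bsj_keys <- bsj %>% select(circ_chrom = "chrom", circ_start = "start", circ_end = "end")
  span_ids <- candidates %>%
    inner_join(bsj_keys,
               by = c(chrom = "circ_chrom", start = "circ_start", end = "circ_end")) %>%
    distinct(circ_chrom = .data$chrom, circ_start = .data$start,
             circ_end = .data$end, read_id = .data$read_id, qname = .data$qname)

  spanning <- span_ids %>%
    select("circ_chrom", "circ_start", "circ_end", "read_id") %>%
    inner_join(reads, by = "read_id")

  # (b) mates of BSJ-spanning reads, fully inside the circle
  read_span <- reads %>%
    group_by(.data$read_id, .data$qname, .data$mate, .data$chrom) %>%
    summarise(lo = min(.data$ref_start), hi = max(.data$ref_end), .groups = "drop")
  mates <- span_ids %>%
    distinct(.data$circ_chrom, .data$circ_start, .data$circ_end, .data$qname) %>%
    inner_join(read_span, by = "qname", relationship = "many-to-many") %>%
    filter(.data$chrom == .data$circ_chrom,
           .data$lo >= .data$circ_start, .data$hi <= .data$circ_end) %>%
    distinct(.data$circ_chrom, .data$circ_start, .data$circ_end, .data$read_id) %>%
    inner_join(reads, by = "read_id")

  bind_rows(spanning, mates) %>%
    distinct(.data$circ_chrom, .data$circ_start, .data$circ_end, .data$read_id,
             .data$supplementary, .keep_all = TRUE) %>%
    arrange(.data$circ_chrom, .data$circ_start, .data$circ_end, .data$read_id)
}

# per-record internal junction gaps: one row per (record, gap)
read_gaps <- function(reads, min_intron_len = 30L) {
  keep <- purrr::map_lgl(reads$blocks, function(b) nrow(b) >= 2)
  r <- reads[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  donor = integer(), acceptor = integer()))
  }
  purrr::pmap(list(r$read_id, r$chrom, r$blocks), function(id, ch, b) {
    k <- nrow(b)
    tibble(read_id = id, chrom = ch,
           donor = unname(b[seq_len(k - 1), 2L]),
           acceptor = unname(b[2:k, 1L]))
  }) %>%
    bind_rows() %>%
    filter(.data$acceptor - .data$donor - 1L >= min_intron_len)
}

#' Extract internal splice junctions from circle-assigned reads
#'
#' Every gap of at least `min_intron_len` bases between consecutive aligned
#' blocks of an assigned read defines a (donor, acceptor) junction: the
#' donor is the last exonic base 5' of the gap, the acceptor the first
#' exonic base 3' of it. Junctions are aggregated by exact coordinates with
#' distinct-read support and only canonical (GT-AG / CT-AC) junctions are
#' kept.
#'
#' @param assigned Reads of one circle (or several; junctions are grouped
#'   within the `circ_*` key columns when present) from
#'   [assign_reads_to_circ()].
#' @param genome Reference genome.
#' @param min_intron_len Minimum junction gap (default 30 bp).
#' @param min_junction_support Minimum distinct reads per junction
#'   (default 1).
#'
#' @return A tibble: circle key columns (if present), `chrom`, `donor`,
#'   `acceptor`, `support`, `strand`, `motif`, `read_ids` (list column).
#' @export
extract_internal_junctions <- function(assigned, genome, min_intron_len = 30L,
                                       min_junction_support = 1L) {
  key <- intersect(c("circ_chrom", "circ_start", "circ_end"), names(assigned))
  empty <- tibble(chrom = character(), donor = integer(), acceptor = integer(),
                  support = integer(), strand = character(), motif = character(),
                  read_ids = list())
  if (nrow(assigned) == 0) return(empty)
  gaps <- assigned %>%
    dplyr::group_split(across(all_of(key))) %>%
    purrr::map(function(g) {
      gg <- read_gaps(g, min_intron_len)
      if (nrow(gg) == 0) return(gg)
      for (k in key) gg[[k]] <- g[[k]][1]
      gg
    }) %>%
    bind_rows()
  if (nrow(gaps) == 0) return(empty)
  jx <- gaps %>%
    group_by(across(all_of(c(key, "chrom", "donor", "acceptor")))) %>%
    summarise(support = n_distinct(.data$read_id),
              read_ids = list(unique(.data$read_id)), .groups = "drop")
  mt <- motif_table(genome, jx$chrom, donor_end = jx$donor, acceptor_start = jx$acceptor)
  jx %>%
    mutate(strand = mt$strand, motif = mt$motif, ok = mt$ok) %>%
    filter(.data$ok, .data$support >= min_junction_support) %>%
    select(-"ok") %>%
    arrange(across(all_of(c(key, "chrom", "donor", "acceptor"))))
}

#' Correct junctions against annotated exon boundaries
#'
#' A read junction is considered annotation-supported ("corrected") when at
#' least one of its boundaries is identical to an annotated exon boundary on
#' the same chromosome: the donor equals some exon end, or the acceptor
#' equals some exon start. Junctions unmatched on both sides are discarded
#' (they are the dominant false-positive class), unless `discard = FALSE`,
#' which keeps them flagged for novel-exon exploration.
#'
#' @param junctions Junction table from [extract_internal_junctions()].
#' @param exons Exon table from [read_annotation()].
#' @param discard Drop junctions with `corrected = FALSE`? Default TRUE.
#'
#' @return The junction table with a logical `corrected` column.
#' @export
correct_junctions <- function(junctions, exons, discard = TRUE) {
  if (nrow(junctions) == 0) {
    junctions$corrected <- logical(0)
    return(junctions)
  }
  ends <- paste(exons$chrom, exons$exon_end)
  starts <- paste(exons$chrom, exons$exon_start)
  out <- junctions %>%
    mutate(corrected = paste(.data$chrom, .data$donor) %in% ends |
             paste(.data$chrom, .data$acceptor) %in% starts)
  if (discard) out <- filter(out, .data$corrected)
  out
}

#' Classify alternative-splicing events within one circRNA
#'
#' Four event classes are called from the corrected junction set of one
#' circle, each requiring read evidence for *both* isoforms:
#'
#' * **A5SS / A3SS** — two junctions sharing one boundary and differing at
#'   the other. The alternative segment is the stretch between the two
#'   competing donor (or acceptor) sites; pairs whose alternative segment
#'   spans an annotated exon boundary are exon-skipping patterns and are
#'   left to the SE caller. Class labels are strand-aware:
#'   on a minus-strand circle a genomic alternative-donor pair is an
#'   alternative *3'* splice site, and vice versa.
#' * **SE** — a junction spanning an annotated exon strictly inside it,
#'   with inclusion evidence: a junction anchored on that exon's boundary,
#'   or a read block overlapping it by at least `min_overlap` bases.
#' * **RI** — a junction coinciding exactly with an annotated intron, plus
#'   at least one read whose single aligned block covers the intron
#'   unspliced (from the donor base through one base past the acceptor).
#'
#' Events are deduplicated by (type, alternative segment).
#'
#' @param junctions Corrected junction table for this circle.
#' @param reads Assigned reads of this circle.
#' @param exons Annotation exon table.
#' @param circ One-row BSJ tibble (`chrom`, `start`, `end`, `strand`).
#' @param params Parameter list from [circ_params()].
#'
#' @return A tibble of events: `circ_chrom`, `circ_start`, `circ_end`,
#'   `circ_strand`, `event_type`, `alt_start`, `alt_end`, `alt_len`,
#'   `incl_reads`, `excl_reads`, `flank_donor`, `flank_acceptor`,
#'   `host_gene`, `host_biotype`, `corrected`.
#' @export
classify_events <- function(junctions, reads, exons, circ, params = circ_params()) {
  empty <- empty_events()
  if (nrow(junctions) == 0) return(empty)
  jx <- junctions %>%
    filter(.data$chrom == circ$chrom,
           .data$donor >= circ$start, .data$acceptor <= circ$end)
  if (nrow(jx) == 0) return(empty)
  strand <- circ$strand
  if (is.na(strand) || !strand %in% c("+", "-")) strand <- "+"
  cex <- exons %>% filter(.data$chrom == circ$chrom)
  events <- list()

  ev_row <- function(type, alt_start, alt_end, incl, excl,
                     flank_donor = NA_integer_, flank_acceptor = NA_integer_,
                     bounds) {
    tibble(
      circ_chrom = circ$chrom, circ_start = circ$start, circ_end = circ$end,
      circ_strand = strand, event_type = type,
      alt_start = as.integer(alt_start), alt_end = as.integer(alt_end),
      alt_len = as.integer(alt_end - alt_start + 1L),
      incl_reads = as.integer(incl), excl_reads = as.integer(excl),
      flank_donor = as.integer(flank_donor),
      flank_acceptor = as.integer(flank_acceptor),
      bounds = list(bounds)
    )
  }

  # a junction pair whose alternative segment spans an annotated exon
  # boundary is an exon-skipping pattern (the short junction skips that
  # exon), not an alternative splice site; leave it to the SE caller
  ann_starts <- unique(cex$exon_start)
  ann_ends <- unique(cex$exon_end)

  # --- alternative donor pairs (shared acceptor) -------------------------
  for (a in unique(jx$acceptor[duplicated(jx$acceptor)])) {
    grp <- jx %>% filter(.data$acceptor == a) %>% arrange(.data$donor)
    ds <- grp$donor
    for (i in seq_len(nrow(grp) - 1)) {
      for (j in (i + 1):nrow(grp)) {
        d1 <- ds[i]; d2 <- ds[j]
        if (any(ann_starts > d1 & ann_starts <= d2)) next
        type <- if (strand == "-") "A3SS" else "A5SS"
        # inclusion isoform carries the alternative segment (exon extends to d2)
        events[[length(events) + 1]] <- ev_row(
          type, d1 + 1L, d2, incl = grp$support[j], excl = grp$support[i],
          flank_acceptor = a, bounds = c(d1, d2, a)
        )
      }
    }
  }

  # --- alternative acceptor pairs (shared donor) -------------------------
  for (d in unique(jx$donor[duplicated(jx$donor)])) {
    grp <- jx %>% filter(.data$donor == d) %>% arrange(.data$acceptor)
    as_ <- grp$acceptor
    for (i in seq_len(nrow(grp) - 1)) {
      for (j in (i + 1):nrow(grp)) {
        a1 <- as_[i]; a2 <- as_[j]
        if (any(ann_ends >= a1 & ann_ends < a2)) next
        type <- if (strand == "-") "A5SS" else "A3SS"
        events[[length(events) + 1]] <- ev_row(
          type, a1, a2 - 1L, incl = grp$support[i], excl = grp$support[j],
          flank_donor = d, bounds = c(d, a1, a2)
        )
      }
    }
  }

  # --- skipped exons -----------------------------------------------------
  ann_exons <- cex %>% distinct(.data$exon_start, .data$exon_end)
  if (nrow(ann_exons) > 0) {
    for (i in seq_len(nrow(jx))) {
      d <- jx$donor[i]; a <- jx$acceptor[i]
      inside <- ann_exons %>% filter(.data$exon_start > d, .data$exon_end < a)
      if (nrow(inside) == 0) next
      for (k in seq_len(nrow(inside))) {
        s <- inside$exon_start[k]; e <- inside$exon_end[k]
        # inclusion evidence: junction anchored on the exon boundary ...
        anch <- jx %>% filter(.data$acceptor == s | .data$donor == e)
        incl_ids <- unique(unlist(anch$read_ids))
        # ... or a read block overlapping the exon by >= min_overlap
        if (nrow(reads) > 0) {
          cov_ids <- reads$read_id[purrr::map_lgl(reads$blocks, function(b) {
            any(pmin(b[, 2L], e) - pmax(b[, 1L], s) + 1L >= params$min_overlap)
          })]
          incl_ids <- unique(c(incl_ids, cov_ids))
        }
        # exclusion reads (the skipping junction) never count as inclusion
        incl_ids <- setdiff(incl_ids, jx$read_ids[[i]])
        if (length(incl_ids) == 0) next
        events[[length(events) + 1]] <- ev_row(
          "SE", s, e, incl = length(incl_ids), excl = jx$support[i],
          flank_donor = d, flank_acceptor = a, bounds = c(d, a, s, e)
        )
      }
    }
  }

  # --- retained introns --------------------------------------------------
  ann_introns <- introns_of(cex) %>% distinct(.data$donor, .data$acceptor)
  if (nrow(ann_introns) > 0 && nrow(reads) > 0) {
    for (i in seq_len(nrow(jx))) {
      d <- jx$donor[i]; a <- jx$acceptor[i]
      if (!any(ann_introns$donor == d & ann_introns$acceptor == a)) next
      span_ids <- reads$read_id[purrr::map_lgl(reads$blocks, function(b) {
        any(b[, 1L] <= d & b[, 2L] >= a + 1L)
      })]
      span_ids <- unique(span_ids)
      if (length(span_ids) == 0) next
      events[[length(events) + 1]] <- ev_row(
        "RI", d + 1L, a - 1L, incl = length(span_ids), excl = jx$support[i],
        flank_donor = d, flank_acceptor = a, bounds = c(d, a)
      )
    }
  }

  if (length(events) == 0) return(empty)
  out <- bind_rows(events) %>%
    distinct(.data$event_type, .data$alt_start, .data$alt_end, .keep_all = TRUE)
  out <- annotate_host(out, cex)
  out %>%
    mutate(corrected = TRUE) %>%
    select(-"bounds") %>%
    arrange(.data$event_type, .data$alt_start, .data$alt_end)
}

empty_events <- function() {
  tibble(
    circ_chrom = character(), circ_start = integer(), circ_end = integer(),
    circ_strand = character(), event_type = character(),
    alt_start = integer(), alt_end = integer(), alt_len = integer(),
    incl_reads = integer(), excl_reads = integer(),
    flank_donor = integer(), flank_acceptor = integer(),
    host_gene = character(), host_biotype = character(), corrected = logical()
  )
}

# host transcript assignment: the transcripts whose exon boundaries match
# the event's defining junction boundaries; ties broken mRNA > lncRNA > other
annotate_host <- function(events, cex) {
  rank <- c(mRNA = 1L, lncRNA = 2L, other = 3L)
  hosts <- purrr::map(events$bounds, function(b) {
    hit <- cex %>% filter(.data$exon_end %in% b | .data$exon_start %in% b)
    if (nrow(hit) == 0) {
      return(c(gene = NA_character_, biotype = "other"))
    }
    hit <- hit %>%
      distinct(.data$gene_name, .data$biotype) %>%
      arrange(rank[.data$biotype], .data$gene_name)
    c(gene = hit$gene_name[1], biotype = hit$biotype[1])
  })
  events$host_gene <- purrr::map_chr(hosts, "gene")
  events$host_biotype <- purrr::map_chr(hosts, "biotype")
  events
}

#' Run the full per-sample detection pipeline
#'
#' Composition of back-splice detection, read assignment, internal-junction
#' extraction, annotation-based correction, and event classification.
#' Deterministic given inputs and parameters.
#'
#' @param alignments Path to a SAM/BAM file, or a read table from
#'   [read_alignments()].
#' @param genome Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param annotation Path to a GTF file, or an exon tibble from
#'   [read_annotation()].
#' @param params Parameter list from [circ_params()].
#' @param sample Sample identifier recorded in the output.
#'
#' @return A list with `events` (tibble, see [classify_events()], plus a
#'   leading `sample` column) and `bsj` (tibble of detected back-splice
#'   junctions).
#' @export
call_sample <- function(alignments, genome, annotation,
                        params = circ_params(), sample = "sample1") {
  reads <- if (is.character(alignments)) {
    read_alignments(alignments, min_intron_len = params$min_intron_len)
  } else alignments
  genome <- as_genome(genome)
  exons <- if (is.character(annotation)) read_annotation(annotation) else annotation

  candidates <- find_bsj_candidates(reads)
  bsj <- aggregate_bsj(candidates, genome, params$min_bsj_support)
  if (nrow(bsj) == 0) {
    ev <- empty_events()
    ev$sample <- character(0)
    return(list(events = ev[, c("sample", setdiff(names(ev), "sample"))], bsj = bsj))
  }
  assigned <- assign_reads_to_circ(bsj, reads, candidates)
  jx_all <- extract_internal_junctions(assigned, genome,
                                       min_intron_len = params$min_intron_len,
                                       min_junction_support = params$min_junction_support)
  jx_all <- correct_junctions(jx_all, exons, discard = !isTRUE(params$no_correct))

  events <- purrr::map(seq_len(nrow(bsj)), function(i) {
    ci <- bsj[i, ]
    jx <- jx_all %>%
      filter(.data$circ_chrom == ci$chrom, .data$circ_start == ci$start,
             .data$circ_end == ci$end)
    rd <- assigned %>%
      filter(.data$circ_chrom == ci$chrom, .data$circ_start == ci$start,
             .data$circ_end == ci$end)
    classify_events(jx, rd, exons, ci, params)
  }) %>%
    bind_rows()
  if (nrow(events) == 0) events <- empty_events()
  events <- events %>%
    mutate(sample = sample, .before = 1) %>%
    arrange(.data$circ_chrom, .data$circ_start, .data$alt_start, .data$event_type)
  list(events = events, bsj = bsj)
}
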