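# Independent brute-force oracle. Re-derives back-splice junctions and
# alternative-splicing events from the *definitions* using plain base R:
# the SAM file is parsed as text, CIGARs are walked token by token, and
# every pairing is enumerated with nested loops. No package internals are
# reused, so agreement with the pipeline is a meaningful cross-check.

oracle_sam <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(ln, "@")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    chrom = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    cigar = vapply(f, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

oracle_ops <- function(cigar) {
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub(".$", "", tok)), op = sub("^[0-9]+", "", tok))
}

# reference-aligned blocks; gaps (N or D) of at least min_intron split
# blocks, shorter gaps are absorbed into the enclosing block
oracle_blocks <- function(pos, cigar, min_intron = 30L) {
  o <- oracle_ops(cigar)
  blocks <- NULL
  cur_s <- pos
  ref <- pos
  for (i in seq_along(o$op)) {
    if (o$op[i] %in% c("M", "=", "X")) {
      ref <- ref + o$len[i]
    } else if (o$op[i] %in% c("D", "N")) {
      if (o$len[i] >= min_intron) {
        blocks <- rbind(blocks, c(cur_s, ref - 1L))
        cur_s <- ref + o$len[i]
      }
      ref <- ref + o$len[i]
    }
  }
  rbind(blocks, c(cur_s, ref - 1L))
}

# 1-based query span of the aligned part, in stored-read orientation
oracle_qspan <- function(cigar) {
  o <- oracle_ops(cigar)
  lead <- 0L
  i <- 1L
  while (i <= length(o$op) && o$op[i] %in% c("H", "S")) {
    lead <- lead + o$len[i]
    i <- i + 1L
  }
  aln <- sum(o$len[o$op %in% c("M", "I", "=", "X")])
  c(lead + 1L, lead + aln)
}

oracle_records <- function(path, min_intron = 30L) {
  s <- oracle_sam(path)
  s <- s[bitwAnd(s$flag, 4L) == 0L & bitwAnd(s$flag, 256L) == 0L, , drop = FALSE]
  mate <- ifelse(bitwAnd(s$flag, 128L) > 0L, 2L, 1L)
  s$read_id <- paste0(s$qname, "/", mate)
  s$strand <- ifelse(bitwAnd(s$flag, 16L) > 0L, "-", "+")
  qs <- t(vapply(s$cigar, oracle_qspan, integer(2)))
  s$qstart <- qs[, 1L]
  s$qend <- qs[, 2L]
  s$blocks <- lapply(seq_len(nrow(s)), function(i) {
    oracle_blocks(s$pos[i], s$cigar[i], min_intron)
  })
  s
}

# "+" for GT..AG, "-" for CT..AC, NA otherwise; genome is named character
oracle_motif <- function(genome_chr, chrom, donor, acceptor) {
  m <- paste0(substr(genome_chr[[chrom]], donor + 1L, donor + 2L),
              substr(genome_chr[[chrom]], acceptor - 2L, acceptor - 1L))
  if (m == "GTAG") "+" else if (m == "CTAC") "-" else NA_character_
}

oracle_bsj_candidates <- function(rec) {
  out <- NULL
  for (id in unique(rec$read_id)) {
    g <- rec[rec$read_id == id, , drop = FALSE]
    if (nrow(g) < 2) next
    g <- g[order(g$qstart), , drop = FALSE]
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in (i + 1L):nrow(g)) {
        if (g$chrom[i] != g$chrom[j] || g$strand[i] != g$strand[j]) next
        if (abs(g$qstart[j] - g$qend[i] - 1L) > 2L) next
        if (max(g$blocks[[j]][, 2L]) >= min(g$blocks[[i]][, 1L])) next
        out <- rbind(out, data.frame(
          read_id = id, qname = g$qname[i], chrom = g$chrom[i],
          start = min(g$blocks[[j]][, 1L]), end = max(g$blocks[[i]][, 2L]),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  out
}

oracle_bsj <- function(rec, genome_chr, min_support = 2L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), support = integer(),
                      stringsAsFactors = FALSE)
  cand <- oracle_bsj_candidates(rec)
  if (is.null(cand)) return(empty)
  key <- paste(cand$chrom, cand$start, cand$end)
  out <- NULL
  for (k in unique(key)) {
    rows <- cand[key == k, , drop = FALSE]
    st <- oracle_motif(genome_chr, rows$chrom[1], rows$end[1], rows$start[1])
    supp <- length(unique(rows$read_id))
    if (!is.na(st) && supp >= min_support) {
      out <- rbind(out, data.frame(
        chrom = rows$chrom[1], start = rows$start[1], end = rows$end[1],
        strand = st, support = supp, stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) return(empty)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# events of one circle: data.frame(event_type, alt_start, alt_end), sorted
oracle_events <- function(rec, genome_chr, exons, circ,
                          min_intron = 30L, min_overlap = 8L) {
  empty <- data.frame(event_type = character(), alt_start = integer(),
                      alt_end = integer(), stringsAsFactors = FALSE)

  # --- read assignment: BSJ-spanning reads + their fully-inside mates ---
  cand <- oracle_bsj_candidates(rec)
  span_ids <- unique(cand$read_id[cand$chrom == circ$chrom &
                                    cand$start == circ$start &
                                    cand$end == circ$end])
  if (length(span_ids) == 0) return(empty)
  span_qn <- unique(rec$qname[rec$read_id %in% span_ids])
  mate_ids <- character(0)
  for (id in unique(rec$read_id[rec$qname %in% span_qn])) {
    g <- rec[rec$read_id == id & rec$chrom == circ$chrom, , drop = FALSE]
    if (nrow(g) == 0) next
    lo <- min(vapply(g$blocks, function(b) min(b[, 1L]), integer(1)))
    hi <- max(vapply(g$blocks, function(b) max(b[, 2L]), integer(1)))
    if (lo >= circ$start && hi <= circ$end) mate_ids <- c(mate_ids, id)
  }
  assigned <- rec[rec$read_id %in% union(span_ids, mate_ids), , drop = FALSE]

  # --- internal junctions: canonical, annotation-corrected, in-circle ---
  jraw <- NULL
  for (i in seq_len(nrow(assigned))) {
    b <- assigned$blocks[[i]]
    if (nrow(b) < 2) next
    for (k in seq_len(nrow(b) - 1L)) {
      if (b[k + 1L, 1L] - b[k, 2L] - 1L >= min_intron) {
        jraw <- rbind(jraw, data.frame(
          read_id = assigned$read_id[i], donor = b[k, 2L],
          acceptor = b[k + 1L, 1L], stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (is.null(jraw)) return(empty)
  cex <- exons[exons$chrom == circ$chrom, , drop = FALSE]
  jx <- NULL
  for (k in unique(paste(jraw$donor, jraw$acceptor))) {
    rows <- jraw[paste(jraw$donor, jraw$acceptor) == k, , drop = FALSE]
    d <- rows$donor[1]
    a <- rows$acceptor[1]
    if (is.na(oracle_motif(genome_chr, circ$chrom, d, a))) next
    if (!(d %in% cex$exon_end || a %in% cex$exon_start)) next
    if (d < circ$start || a > circ$end) next
    jx <- rbind(jx, data.frame(donor = d, acceptor = a,
                               support = length(unique(rows$read_id)),
                               stringsAsFactors = FALSE))
  }
  if (is.null(jx)) return(empty)
  jx$read_ids <- lapply(seq_len(nrow(jx)), function(i) {
    unique(jraw$read_id[jraw$donor == jx$donor[i] &
                          jraw$acceptor == jx$acceptor[i]])
  })

  strand <- if (!is.na(circ$strand) && circ$strand %in% c("+", "-")) {
    circ$strand
  } else "+"
  ev <- NULL
  add <- function(type, s, e) {
    ev <<- rbind(ev, data.frame(event_type = type, alt_start = as.integer(s),
                                alt_end = as.integer(e), stringsAsFactors = FALSE))
  }

  # alternative donors (shared acceptor)
  for (a in unique(jx$acceptor)) {
    ds <- sort(jx$donor[jx$acceptor == a])
    if (length(ds) < 2) next
    for (i in seq_len(length(ds) - 1L)) {
      for (j in (i + 1L):length(ds)) {
        if (any(cex$exon_start > ds[i] & cex$exon_start <= ds[j])) next
        add(if (strand == "-") "A3SS" else "A5SS", ds[i] + 1L, ds[j])
      }
    }
  }
  # alternative acceptors (shared donor)
  for (d in unique(jx$donor)) {
    as_ <- sort(jx$acceptor[jx$donor == d])
    if (length(as_) < 2) next
    for (i in seq_len(length(as_) - 1L)) {
      for (j in (i + 1L):length(as_)) {
        if (any(cex$exon_end >= as_[i] & cex$exon_end < as_[j])) next
        add(if (strand == "-") "A5SS" else "A3SS", as_[i], as_[j] - 1L)
      }
    }
  }
  # skipped exons
  ann <- unique(cex[, c("exon_start", "exon_end")])
  for (i in seq_len(nrow(jx))) {
    d <- jx$donor[i]
    a <- jx$acceptor[i]
    hit <- ann[ann$exon_start > d & ann$exon_end < a, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      s <- hit$exon_start[k]
      e <- hit$exon_end[k]
      incl <- unique(unlist(jx$read_ids[jx$acceptor == s | jx$donor == e]))
      for (r in seq_len(nrow(assigned))) {
        b <- assigned$blocks[[r]]
        if (any(pmin(b[, 2L], e) - pmax(b[, 1L], s) + 1L >= min_overlap)) {
          incl <- union(incl, assigned$read_id[r])
        }
      }
      incl <- setdiff(incl, jx$read_ids[[i]])
      if (length(incl) > 0) add("SE", s, e)
    }
  }
  # retained introns (junction identical to an annotated intron)
  intr <- NULL
  for (t in unique(cex$transcript_id)) {
    te <- cex[cex$transcript_id == t, , drop = FALSE]
    te <- te[order(te$exon_start), , drop = FALSE]
    if (nrow(te) < 2) next
    intr <- rbind(intr, data.frame(d = te$exon_end[-nrow(te)],
                                   a = te$exon_start[-1]))
  }
  if (!is.null(intr)) {
    for (i in seq_len(nrow(jx))) {
      d <- jx$donor[i]
      a <- jx$acceptor[i]
      if (!any(intr$d == d & intr$a == a)) next
      covered <- FALSE
      for (r in seq_len(nrow(assigned))) {
        b <- assigned$blocks[[r]]
        if (any(b[, 1L] <= d & b[, 2L] >= a + 1L)) covered <- TRUE
      }
      if (covered) add("RI", d + 1L, a - 1L)
    }
  }

  if (is.null(ev)) return(empty)
  ev <- unique(ev)
  ev[order(ev$event_type, ev$alt_start, ev$alt_end), , drop = FALSE]
}
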