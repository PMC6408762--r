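#' Simulation parameters
#'
#' Parameters of the deterministic synthetic-data generator. Defaults
#' emulate an RNase-R-enriched circRNA sequencing experiment at desk scale:
#' 20 circRNAs with two isoforms each (five planted events of each of the
#' four classes), 30-fold read coverage of each circle with 2x100 bp paired
#' reads and a broad 300 +/- 80 bp fragment size, on a 3 x 200 kb mini-genome with
#' roughly 80% protein-coding and 20% lncRNA host genes.
#'
#' @param seed Integer RNG seed; a fixed seed yields byte-identical output.
#' @param read_len Read length in bp (>= 50).
#' @param fragment_mean,fragment_sd Fragment length distribution in bp
#'   (normal, truncated to `[read_len + 20, circumference]`; the broad
#'   default emulates a library without tight size selection, so mates of
#'   back-splice-spanning reads sample the whole circle).
#' @param coverage Fold coverage of each circle.
#' @param bsj_read_fraction Floor on the fraction of fragments whose first
#'   read spans the back-splice junction (enforced by stratified sampling).
#' @param background_reads Number of linear background reads.
#' @param n_circles Number of circRNAs (planted event types cycle
#'   SE, RI, A5SS, A3SS across circles).
#' @param n_contigs,contig_len Mini-genome geometry.
#' @param lnc_fraction Fraction of lncRNA host genes.
#' @param minus_fraction Fraction of minus-strand host genes.
#' @param decoys Plant decoy junctions (non-canonical motif;
#'   canonical-but-unannotated; shifted and singleton back-splices)?
#'
#' @return A named parameter list.
#' @export
sim_params <- function(seed = 1L, read_len = 100L, fragment_mean = 300,
                       fragment_sd = 80, coverage = 30,
                       bsj_read_fraction = 0.25, background_reads = 200L,
                       n_circles = 20L, n_contigs = 3L, contig_len = 200000L,
                       lnc_fraction = 0.2, minus_fraction = 0.3,
                       decoys = TRUE) {
  stopifnot(read_len >= 50, coverage > 0, seed == as.integer(seed))
  list(seed = as.integer(seed), read_len = as.integer(read_len),
       fragment_mean = fragment_mean, fragment_sd = fragment_sd,
       coverage = coverage, bsj_read_fraction = bsj_read_fraction,
       background_reads = as.integer(background_reads),
       n_circles = as.integer(n_circles), n_contigs = as.integer(n_contigs),
       contig_len = as.integer(contig_len), lnc_fraction = lnc_fraction,
       minus_fraction = minus_fraction, decoys = isTRUE(decoys))
}

# sample one element of x (safe for length-1 x, unlike sample())
pick1 <- function(x) x[sample.int(length(x), 1L)]

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# overwrite genome bases in place; genome is a named character vector
plant <- function(genome, chrom, pos, nt) {
  substr(genome[[chrom]], pos, pos + nchar(nt) - 1L) <- nt
  genome
}

# plant the canonical (or, with canonical = FALSE, an explicitly
# non-canonical) splice motif around a (donor, acceptor) gap
plant_motif <- function(genome, chrom, donor, acceptor, strand = "+",
                        canonical = TRUE) {
  if (!canonical) {
    genome <- plant(genome, chrom, donor + 1L, "AA")
    genome <- plant(genome, chrom, acceptor - 2L, "AA")
  } else if (strand == "+") {
    genome <- plant(genome, chrom, donor + 1L, "GT")
    genome <- plant(genome, chrom, acceptor - 2L, "AG")
  } else {
    genome <- plant(genome, chrom, donor + 1L, "CT")
    genome <- plant(genome, chrom, acceptor - 2L, "AC")
  }
  genome
}

# isoform junction list: gaps between consecutive exons of an exon matrix
iso_junctions <- function(iso) {
  k <- nrow(iso)
  if (k < 2) return(tibble(donor = integer(), acceptor = integer()))
  tibble(donor = iso[seq_len(k - 1), 2L], acceptor = iso[2:k, 1L])
}

#' Generate a seeded mini-genome, annotation, and circRNA truth set
#'
#' Builds host genes of 5-6 exons on random contigs, defines one circRNA
#' per gene over three consecutive internal exons, derives two circle
#' isoforms that differ by exactly one planted event (SE, RI, A5SS or A3SS,
#' strand-aware label), plants canonical GT-AG (CT-AC on minus genes)
#' motifs at every isoform junction and back-splice flank, and optionally
#' plants decoy junctions for negative controls. Retained introns are drawn
#' short (35-60 bp) so that a single read block can cover them; all other
#' introns are 150-1500 bp.
#'
#' @param params Parameter list from [sim_params()].
#'
#' @return A list: `genome` (named character vector of contig sequences),
#'   `exons` (annotation tibble, one transcript per gene), `circles`
#'   (tibble with `circ_id`, coordinates, strand, isoform exon matrices and
#'   weights as list columns), `truth_events`, `truth_junctions`, `decoys`,
#'   `params`.
#' @export
sim_fixture <- function(params = sim_params()) {
  set.seed(params$seed)
  genome <- setNames(
    vapply(seq_len(params$n_contigs), function(i) random_seq(params$contig_len),
           character(1)),
    paste0("ctg", seq_len(params$n_contigs))
  )
  cursor <- setNames(rep(1500L, params$n_contigs), names(genome))

  types <- rep(c("SE", "RI", "A5SS", "A3SS"), length.out = params$n_circles)
  n_background <- max(2L, ceiling(params$n_circles / 5))

  exon_rows <- list()
  circle_rows <- list()
  truth_event_rows <- list()
  truth_jx_rows <- list()
  decoy_rows <- list()
  background_genes <- list()

  make_gene <- function(chrom, n_exons, short_intron_at = NA) {
    widths <- sample(90:200, n_exons, replace = TRUE)
    introns <- sample(150:1500, n_exons - 1, replace = TRUE)
    if (!is.na(short_intron_at)) introns[short_intron_at] <- sample(35:60, 1)
    starts <- integer(n_exons)
    starts[1] <- cursor[[chrom]]
    for (i in 2:n_exons) starts[i] <- starts[i - 1] + widths[i - 1] + introns[i - 1]
    ends <- starts + widths - 1L
    span <- ends[n_exons] - starts[1] + 1L
    if (ends[n_exons] + 2000L > nchar(genome[[chrom]])) {
      abort(sprintf("gene layout overflows contig %s", chrom),
            class = "circAS_sim_error")
    }
    cursor[[chrom]] <<- ends[n_exons] + sample(2000:4000, 1)
    cbind(start = starts, end = ends)
  }

  all_genes <- params$n_circles + n_background
  gene_chroms <- rep(names(genome), length.out = all_genes)

  for (g in seq_len(params$n_circles)) {
    type <- types[g]
    chrom <- gene_chroms[g]
    strand <- if (runif(1) < params$minus_fraction) "-" else "+"
    biotype_raw <- if (runif(1) < params$lnc_fraction) "lincRNA" else "protein_coding"
    # geometry is genomic; on minus genes the A5SS/A3SS labels swap
    geom <- type
    if (strand == "-" && type %in% c("A5SS", "A3SS")) {
      geom <- if (type == "A5SS") "A3SS" else "A5SS"
    }
    n_exons <- sample(5:6, 1)
    c1 <- 2L; c2 <- 4L  # compact circle over three consecutive exons
    # pick the altered junction/exon among the circle-internal ones
    k <- pick1((c1 + 1):(c2 - 1))  # internal exon index (SE) or junction k-1|k
    ex <- make_gene(chrom, n_exons,
                    short_intron_at = if (geom == "RI") k - 1L else NA)
    circ_start <- ex[c1, 1L]; circ_end <- ex[c2, 2L]
    iso_a <- ex[c1:c2, , drop = FALSE]
    delta <- sample(20:60, 1)

    if (geom == "SE") {
      iso_b <- iso_a[-(k - c1 + 1L), , drop = FALSE]
      alt <- c(ex[k, 1L], ex[k, 2L])
    } else if (geom == "RI") {
      iso_b <- iso_a
      ki <- k - c1  # row index of exon k-1 within iso
      iso_b[ki, 2L] <- iso_b[ki + 1L, 2L]
      iso_b <- iso_b[-(ki + 1L), , drop = FALSE]
      alt <- c(ex[k - 1L, 2L] + 1L, ex[k, 1L] - 1L)
    } else if (geom == "A5SS") {  # genomic alternative donor at junction k-1|k
      iso_b <- iso_a
      ki <- k - c1
      iso_b[ki, 2L] <- iso_b[ki, 2L] - delta
      alt <- c(ex[k - 1L, 2L] - delta + 1L, ex[k - 1L, 2L])
    } else {  # genomic alternative acceptor
      iso_b <- iso_a
      ki <- k - c1 + 1L
      iso_b[ki, 1L] <- iso_b[ki, 1L] + delta
      alt <- c(ex[k, 1L], ex[k, 1L] + delta - 1L)
    }

    # plant motifs: all junctions of both isoforms, plus the full
    # transcript's flanking introns, plus the back-splice flanks
    jx <- dplyr::bind_rows(
      iso_junctions(ex), iso_junctions(iso_a), iso_junctions(iso_b)
    ) %>% distinct()
    for (i in seq_len(nrow(jx))) {
      genome <- plant_motif(genome, chrom, jx$donor[i], jx$acceptor[i], strand)
    }
    genome <- plant_motif(genome, chrom, circ_end, circ_start, strand)

    gene_id <- sprintf("g%03d", g)
    exon_rows[[g]] <- tibble(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      gene_name = toupper(gene_id), chrom = chrom, strand = strand,
      exon_start = ex[, 1L], exon_end = ex[, 2L],
      biotype_raw = biotype_raw
    )
    circle_rows[[g]] <- tibble(
      circ_id = gene_id, chrom = chrom, start = circ_start, end = circ_end,
      strand = strand, gene_name = toupper(gene_id),
      isoforms = list(list(iso_a, iso_b)), weights = list(c(0.6, 0.4))
    )
    truth_event_rows[[g]] <- tibble(
      circ_id = gene_id, chrom = chrom, circ_start = circ_start,
      circ_end = circ_end, event_type = type,
      alt_start = alt[1], alt_end = alt[2]
    )
    circ_jx <- dplyr::bind_rows(iso_junctions(iso_a), iso_junctions(iso_b)) %>%
      distinct()
    truth_jx_rows[[g]] <- tibble(circ_id = gene_id, chrom = chrom,
                                 donor = circ_jx$donor, acceptor = circ_jx$acceptor)

    if (params$decoys) {
      d0 <- circ_jx$donor[1]; a0 <- circ_jx$acceptor[1]
      # non-canonical motif at a shifted junction
      genome <- plant_motif(genome, chrom, d0 + 5L, a0 + 5L, canonical = FALSE)
      # canonical motif at boundaries matching no annotated exon
      genome <- plant_motif(genome, chrom, d0 + 12L, a0 + 12L, strand)
      # non-canonical shifted back-splice
      genome <- plant_motif(genome, chrom, circ_end + 6L, circ_start + 6L,
                            canonical = FALSE)
      decoy_rows[[length(decoy_rows) + 1]] <- tibble(
        circ_id = gene_id, chrom = chrom,
        kind = c("junction_noncanonical", "junction_unannotated",
                 "bsj_noncanonical", "bsj_singleton"),
        pos1 = c(d0 + 5L, d0 + 12L, circ_start + 6L, circ_start),
        pos2 = c(a0 + 5L, a0 + 12L, circ_end + 6L, ex[c2 - 1L, 2L])
      )
    }
  }

  for (b in seq_len(n_background)) {
    g <- params$n_circles + b
    chrom <- gene_chroms[g]
    ex <- make_gene(chrom, sample(4:6, 1))
    for (i in seq_len(nrow(ex) - 1)) {
      genome <- plant_motif(genome, chrom, ex[i, 2L], ex[i + 1L, 1L], "+")
    }
    gene_id <- sprintf("bg%02d", b)
    exon_rows[[length(exon_rows) + 1]] <- tibble(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      gene_name = toupper(gene_id), chrom = chrom, strand = "+",
      exon_start = ex[, 1L], exon_end = ex[, 2L],
      biotype_raw = "protein_coding"
    )
    background_genes[[b]] <- list(gene_id = gene_id, chrom = chrom, exons = ex)
  }

  exons <- bind_rows(exon_rows) %>%
    mutate(biotype = map_biotype(.data$biotype_raw))
  empty_circles <- tibble(circ_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), gene_name = character(),
                          isoforms = list(), weights = list())
  empty_truth <- tibble(circ_id = character(), chrom = character(),
                        circ_start = integer(), circ_end = integer(),
                        event_type = character(), alt_start = integer(),
                        alt_end = integer())
  list(
    genome = genome,
    exons = exons,
    circles = if (length(circle_rows)) bind_rows(circle_rows) else empty_circles,
    truth_events = if (length(truth_event_rows)) bind_rows(truth_event_rows) else empty_truth,
    truth_junctions = if (length(truth_jx_rows)) bind_rows(truth_jx_rows) else
      tibble(circ_id = character(), chrom = character(),
             donor = integer(), acceptor = integer()),
    decoys = if (length(decoy_rows)) bind_rows(decoy_rows) else
      tibble(circ_id = character(), chrom = character(), kind = character(),
             pos1 = integer(), pos2 = integer()),
    background = background_genes,
    params = params
  )
}

# map a transcript-coordinate interval [p1, p2] (1 <= p1 <= p2 <= L, no
# wrap) onto genomic blocks of an isoform exon matrix
map_to_blocks <- function(iso, p1, p2) {
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  w <- iso[, 2L] - iso[, 1L] + 1L
  cum <- cumsum(w)
  first <- which(cum >= p1)[1]
  last <- which(cum >= p2)[1]
  off0 <- c(0L, cum)[seq_len(nrow(iso))]
  out <- matrix(integer(0), ncol = 2)
  for (i in first:last) {
    s <- iso[i, 1L] + max(p1 - off0[i] - 1L, 0L)
    e <- iso[i, 1L] + min(p2 - off0[i], w[i]) - 1L
    out <- rbind(out, c(s, e))
  }
  colnames(out) <- c("start", "end")
  out
}

cigar_of <- function(blocks, lead_clip, trail_clip) {
  k <- nrow(blocks)
  parts <- character(0)
  if (lead_clip > 0) parts <- c(parts, paste0(lead_clip, "S"))
  for (i in seq_len(k)) {
    parts <- c(parts, paste0(blocks[i, 2L] - blocks[i, 1L] + 1L, "M"))
    if (i < k) parts <- c(parts, paste0(blocks[i + 1L, 1L] - blocks[i, 2L] - 1L, "N"))
  }
  if (trail_clip > 0) parts <- c(parts, paste0(trail_clip, "S"))
  paste(parts, collapse = "")
}

# contig subsequence; genome may be a named character vector or DNAStringSet
contig_seq <- function(genome, chrom, start, end) {
  if (is.character(genome)) {
    substr(genome[[chrom]], start, end)
  } else {
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  }
}

seq_of_blocks <- function(genome, chrom, blocks) {
  paste(vapply(seq_len(nrow(blocks)), function(i) {
    contig_seq(genome, chrom, blocks[i, 1L], blocks[i, 2L])
  }, character(1)), collapse = "")
}

sam_line <- function(qname, flag, chrom, pos, cigar, rnext, pnext, seq) {
  paste(qname, flag, chrom, pos, 60L, cigar, rnext, pnext, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# emit the 1-2 SAM records of one read sampled from a circular isoform.
# tpos1 is the 1-based transcript start; the read may wrap the circle.
circle_read_records <- function(genome, chrom, iso, L, tpos1, read_len,
                                qname, flag_base, mate_pos) {
  tpos1 <- as.integer(tpos1)
  p2 <- tpos1 + read_len - 1L
  if (p2 <= L) {
    parts <- list(c(tpos1, p2))
  } else {
    parts <- list(c(tpos1, L), c(1L, p2 - L))
  }
  blocks <- lapply(parts, function(p) map_to_blocks(iso, p[1], p[2]))
  lens <- vapply(parts, function(p) p[2] - p[1] + 1L, integer(1))
  seq <- paste(vapply(blocks, function(b) seq_of_blocks(genome, chrom, b),
                      character(1)), collapse = "")
  if (length(parts) == 1) {
    return(sam_line(qname, flag_base, chrom, blocks[[1]][1, 1L],
                    cigar_of(blocks[[1]], 0L, 0L), "=", mate_pos, seq))
  }
  primary <- if (lens[1] >= lens[2]) 1L else 2L
  offs <- c(0L, lens[1])  # stored-read offset of each part
  out <- character(2)
  for (i in 1:2) {
    fl <- flag_base + if (i == primary) 0L else 2048L
    out[i] <- sam_line(qname, fl, chrom, blocks[[i]][1, 1L],
                       cigar_of(blocks[[i]], offs[i], read_len - offs[i] - lens[i]),
                       "=", mate_pos, seq)
  }
  out
}

# primary mapping position of a read (for PNEXT bookkeeping)
read_primary_pos <- function(iso, L, tpos1, read_len) {
  tpos1 <- as.integer(tpos1)
  p2 <- tpos1 + read_len - 1L
  if (p2 <= L) {
    return(map_to_blocks(iso, tpos1, p2)[1, 1L])
  }
  l1 <- L - tpos1 + 1L
  if (l1 >= read_len - l1) {
    map_to_blocks(iso, tpos1, L)[1, 1L]
  } else {
    map_to_blocks(iso, 1L, p2 - L)[1, 1L]
  }
}

#' Simulate SAM reads from a synthetic circRNA fixture
#'
#' Fragments are sampled by rolling the circle: fragment starts are uniform
#' on the isoform circumference (with a stratified floor of fragments whose
#' first read crosses the back-splice junction), fragment lengths are
#' normal, and each fragment yields one 2x`read_len` read pair. Reads
#' crossing the back-splice are emitted as chimeric primary+supplementary
#' record pairs with consistent stored-read offsets; reads crossing
#' internal junctions get `N`-gapped CIGARs. Linear background reads are
#' drawn from the non-circle genes, and decoy reads (non-canonical or
#' unannotated junctions, shifted and singleton back-splices) are attached
#' to back-splice-linked pairs so they reach the event caller and must be
#' rejected there.
#'
#' @param fixture Output of [sim_fixture()].
#' @param params Parameter list; defaults to `fixture$params`.
#'
#' @return A list: `sam` (character vector of SAM lines, header included),
#'   `n_fragments`.
#' @export
sim_reads <- function(fixture, params = fixture$params) {
  set.seed(params$seed + 1L)
  genome <- fixture$genome
  rl <- params$read_len
  contig_len <- if (is.character(genome)) {
    nchar(genome)
  } else {
    Biostrings::width(genome)
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), contig_len))
  lines <- list()
  n_frag <- 0L

  for (ci in seq_len(nrow(fixture$circles))) {
    crc <- fixture$circles[ci, ]
    isoforms <- crc$isoforms[[1]]
    weights <- crc$weights[[1]]
    for (ii in seq_along(isoforms)) {
      iso <- isoforms[[ii]]
      L <- sum(iso[, 2L] - iso[, 1L] + 1L)
      if (L <= rl + 1L) {
        warn(sprintf("circle %s isoform %d shorter than a read; skipped",
                     crc$circ_id, ii))
        next
      }
      nf <- ceiling(params$coverage * L * weights[ii] / (2 * rl))
      nb <- min(nf, max(2L, ceiling(params$bsj_read_fraction * nf)))
      s_bsj <- sample(seq(L - rl + 2L, L), nb, replace = TRUE)
      s_rest <- if (nf > nb) sample.int(L, nf - nb, replace = TRUE) else integer(0)
      starts <- c(s_bsj, s_rest)
      flens <- pmin(L, pmax(rl + 20L,
                            round(rnorm(nf, params$fragment_mean, params$fragment_sd))))
      for (fi in seq_len(nf)) {
        n_frag <- n_frag + 1L
        qname <- sprintf("frag_%s_i%d_%04d", crc$circ_id, ii, fi)
        t1 <- starts[fi]
        t2 <- ((t1 + flens[fi] - rl - 1L) %% L) + 1L
        pos1 <- read_primary_pos(iso, L, t1, rl)
        pos2 <- read_primary_pos(iso, L, t2, rl)
        lines[[length(lines) + 1]] <- circle_read_records(
          genome, crc$chrom, iso, L, t1, rl, qname, 97L, pos2)
        lines[[length(lines) + 1]] <- circle_read_records(
          genome, crc$chrom, iso, L, t2, rl, qname, 145L, pos1)
      }
    }
  }

  # linear background reads from non-circle genes
  if (params$background_reads > 0 && length(fixture$background) > 0) {
    per_gene <- ceiling(params$background_reads / length(fixture$background))
    for (bg in fixture$background) {
      iso <- bg$exons
      L <- sum(iso[, 2L] - iso[, 1L] + 1L)
      if (L <= rl) next
      starts <- sample.int(L - rl, per_gene, replace = TRUE)
      for (fi in seq_along(starts)) {
        b <- map_to_blocks(iso, starts[fi], starts[fi] + rl - 1L)
        lines[[length(lines) + 1]] <- sam_line(
          sprintf("lin_%s_%04d", bg$gene_id, fi), 0L, bg$chrom, b[1, 1L],
          cigar_of(b, 0L, 0L), "*", 0L, seq_of_blocks(genome, bg$chrom, b))
      }
    }
  }

  # decoy reads, paired with genuine BSJ-spanning mates so they enter the
  # per-circle evidence set
  if (nrow(fixture$decoys) > 0) {
    for (di in seq_len(nrow(fixture$decoys))) {
      d <- fixture$decoys[di, ]
      crc <- fixture$circles[fixture$circles$circ_id == d$circ_id, ]
      iso <- crc$isoforms[[1]][[1]]
      L <- sum(iso[, 2L] - iso[, 1L] + 1L)
      if (d$kind %in% c("junction_noncanonical", "junction_unannotated")) {
        half <- 50L
        b <- rbind(c(d$pos1 - half + 1L, d$pos1), c(d$pos2, d$pos2 + half - 1L))
        for (r in 1:2) {
          qname <- sprintf("decoy_%s_%s_%d", d$circ_id, d$kind, r)
          bsj_rec <- circle_read_records(genome, crc$chrom, iso, L,
                                         L - half + 1L, rl, qname, 97L, b[1, 1L])
          mate_rec <- sam_line(qname, 145L, crc$chrom, b[1, 1L],
                               cigar_of(b, 0L, 0L), "=",
                               read_primary_pos(iso, L, L - half + 1L, rl),
                               seq_of_blocks(genome, crc$chrom, b))
          lines[[length(lines) + 1]] <- c(bsj_rec, mate_rec)
        }
      } else {
        n_reads <- if (d$kind == "bsj_singleton") 1L else 2L
        for (r in seq_len(n_reads)) {
          qname <- sprintf("decoy_%s_%s_%d", d$circ_id, d$kind, r)
          half <- 50L
          bl_right <- c(d$pos2 - half + 1L, d$pos2)
          bl_left <- c(d$pos1, d$pos1 + half - 1L)
          seq <- paste0(contig_seq(genome, crc$chrom, bl_right[1], bl_right[2]),
                        contig_seq(genome, crc$chrom, bl_left[1], bl_left[2]))
          lines[[length(lines) + 1]] <- c(
            sam_line(qname, 0L, crc$chrom, bl_right[1],
                     sprintf("%dM%dS", half, half), "*", 0L, seq),
            sam_line(qname, 2048L, crc$chrom, bl_left[1],
                     sprintf("%dS%dM", half, half), "*", 0L, seq)
          )
        }
      }
    }
  }

  list(sam = c(header, unlist(lines)), n_fragments = n_frag)
}

#' Write a GTF annotation
#'
#' Ensembl-dialect exon features carrying `gene_id`, `transcript_id`,
#' `gene_name` and `transcript_biotype` attributes.
#'
#' @param exons Exon tibble; if it has a `biotype_raw` column that is the
#'   biotype written, otherwise `biotype` is reverse-mapped
#'   (mRNA = protein_coding, lncRNA = lincRNA, other = misc_RNA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  raw <- if ("biotype_raw" %in% names(exons)) {
    exons$biotype_raw
  } else {
    c(mRNA = "protein_coding", lncRNA = "lincRNA", other = "misc_RNA")[exons$biotype]
  }
  lines <- sprintf(
    "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; transcript_biotype \"%s\";",
    exons$chrom, exons$exon_start, exons$exon_end, exons$strand,
    exons$gene_id, exons$transcript_id, exons$gene_name, raw
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a fixture bundle to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `reads.sam`, and plain-text truth
#' tables (`truth_events.tsv`, `circles.tsv`, `decoys.tsv`) under `dir`.
#'
#' @param fixture Output of [sim_fixture()].
#' @param dir Output directory (created if needed).
#' @param reads Optional precomputed [sim_reads()] output.
#'
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reads)) reads <- sim_reads(fixture)
  fa <- file.path(dir, "genome.fa")
  gset <- if (methods::is(fixture$genome, "DNAStringSet")) {
    fixture$genome
  } else {
    Biostrings::DNAStringSet(fixture$genome)
  }
  Biostrings::writeXStringSet(gset, fa)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(fixture$exons, gtf)
  sam <- file.path(dir, "reads.sam")
  writeLines(reads$sam, sam)
  te <- file.path(dir, "truth_events.tsv")
  readr::write_tsv(fixture$truth_events, te)
  cc <- file.path(dir, "circles.tsv")
  readr::write_tsv(fixture$circles %>% select(-"isoforms", -"weights"), cc)
  dc <- file.path(dir, "decoys.tsv")
  readr::write_tsv(fixture$decoys, dc)
  invisible(list(genome = fa, gtf = gtf, sam = sam, truth_events = te,
                 circles = cc, decoys = dc))
}

#' Score detected events against a planted truth table
#'
#' Exact-coordinate matching on (chrom, circle span, event type,
#' alternative segment).
#'
#' @param detected Event tibble from [call_sample()].
#' @param truth Truth table from [sim_fixture()] (`truth_events`).
#'
#' @return A tibble with one row per event type plus an `overall` row:
#'   `event_type`, `n_truth`, `n_detected`, `tp`, `precision`, `recall`.
#'   Precision is NA when nothing was detected.
#' @export
score_against_truth <- function(detected, truth) {
  key <- c("chrom", "circ_start", "circ_end", "event_type", "alt_start", "alt_end")
  det <- detected %>%
    mutate(chrom = .data$circ_chrom) %>%
    distinct(across(all_of(key)))
  tru <- truth %>% distinct(across(all_of(key)))
  per_type <- purrr::map(c(EVENT_TYPES, "overall"), function(t) {
    dt <- if (t == "overall") det else filter(det, .data$event_type == t)
    tr <- if (t == "overall") tru else filter(tru, .data$event_type == t)
    tp <- nrow(dplyr::inner_join(dt, tr, by = key))
    tibble(
      event_type = t, n_truth = nrow(tr), n_detected = nrow(dt), tp = tp,
      precision = if (nrow(dt) > 0) tp / nrow(dt) else NA_real_,
      recall = if (nrow(tr) > 0) tp / nrow(tr) else NA_real_
    )
  })
  bind_rows(per_type)
}
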