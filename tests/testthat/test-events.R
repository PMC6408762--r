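toy_jx <- function(donor, acceptor, support, read_ids, chrom = "c1") {
  tibble::tibble(chrom = chrom, donor = as.integer(donor),
                 acceptor = as.integer(acceptor), support = as.integer(support),
                 read_ids = read_ids)
}

toy_circ <- function(start, end, strand = "+", chrom = "c1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

toy_reads <- function(read_ids, blocks) {
  tibble::tibble(read_id = read_ids, blocks = blocks)
}

no_reads <- toy_reads(character(0), list())

test_that("read assignment keeps BSJ-spanning reads and fully-inside mates", {
  g <- toy_genome(5000, list(list(pos = 1060, nt = "GT"), list(pos = 498, nt = "AG")))
  sam <- write_sam_file(c(
    # qA: chimeric first read spans the back-splice; mate inside the circle
    sam_record("qA", 97L, "c1", 1000L, "60M40S"),
    sam_record("qA", 97L + 2048L, "c1", 500L, "60S40M"),
    sam_record("qA", 145L, "c1", 600L, "100M"),
    # qB: spanning first read; mate outside the circle
    sam_record("qB", 97L, "c1", 1000L, "60M40S"),
    sam_record("qB", 97L + 2048L, "c1", 500L, "60S40M"),
    sam_record("qB", 145L, "c1", 2000L, "100M"),
    # qC: unrelated read inside the span, no back-splice evidence
    sam_record("qC", 0L, "c1", 700L, "100M")
  ), c(c1 = 5000L))
  rd <- read_alignments(sam)
  bsj <- detect_bsj(rd, g, min_bsj_support = 2L)
  expect_identical(nrow(bsj), 1L)
  asg <- assign_reads_to_circ(bsj, rd)
  expect_setequal(unique(asg$read_id), c("qA/1", "qA/2", "qB/1"))
  expect_identical(asg$circ_start[1], 500L)
  # both records of a chimeric read are carried
  expect_identical(sum(asg$read_id == "qA/1"), 2L)
})

test_that("junction extraction aggregates gaps with distinct-read support and motif filter", {
  # canonical junction donor 650 / acceptor 750; non-canonical at 350/450
  g <- toy_genome(2000, list(list(pos = 651, nt = "GT"), list(pos = 748, nt = "AG")))
  sam <- write_sam_file(c(
    sam_record("j1", 0L, "c1", 601L, "50M99N50M"),
    sam_record("j2", 0L, "c1", 611L, "40M99N60M"),
    sam_record("j2", 0L, "c1", 611L, "40M99N60M"),  # duplicate qname/mate
    sam_record("k1", 0L, "c1", 301L, "50M99N50M")   # AA..AA flanks
  ), c(c1 = 2000L))
  rd <- read_alignments(sam)
  jx <- extract_internal_junctions(rd, g)
  expect_identical(nrow(jx), 1L)
  expect_identical(jx$donor, 650L)
  expect_identical(jx$acceptor, 750L)
  expect_identical(jx$support, 2L)  # distinct reads, not records
  expect_identical(jx$motif, "GTAG")
  expect_setequal(jx$read_ids[[1]], c("j1/1", "j2/1"))
})

test_that("annotation correction keeps junctions matched on either boundary", {
  ex <- toy_exons("c1", c(100, 300), c(200, 400))
  jx <- toy_jx(donor = c(200L, 150L, 210L, 210L),
               acceptor = c(300L, 300L, 300L, 290L),
               support = 1L, read_ids = list("a", "b", "c", "d"))
  out <- correct_junctions(jx, ex)
  # donor+acceptor matched, acceptor-only, acceptor-only; both-unmatched dropped
  expect_identical(nrow(out), 3L)
  expect_true(all(out$corrected))
  kept <- correct_junctions(jx, ex, discard = FALSE)
  expect_identical(nrow(kept), 4L)
  expect_identical(sum(kept$corrected), 3L)
})

test_that("competing donors give an A5SS call with strand-aware labelling", {
  ex <- toy_exons("c1", c(450, 900), c(733, 1100))
  jx <- dplyr::bind_rows(
    toy_jx(700, 900, 3, list(c("r1", "r2", "r3"))),
    toy_jx(733, 900, 2, list(c("r4", "r5")))
  )
  ev <- classify_events(jx, no_reads, ex, toy_circ(400, 1200, "+"))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_type, "A5SS")
  expect_identical(ev$alt_start, 701L)
  expect_identical(ev$alt_end, 733L)
  expect_identical(ev$alt_len, 33L)
  expect_identical(ev$incl_reads, 2L)  # junction at the longer-exon donor
  expect_identical(ev$excl_reads, 3L)

  ev_minus <- classify_events(jx, no_reads, ex, toy_circ(400, 1200, "-"))
  expect_identical(ev_minus$event_type, "A3SS")
  expect_identical(ev_minus$alt_start, 701L)
  expect_identical(ev_minus$alt_end, 733L)
})

test_that("competing acceptors give an A3SS call with strand-aware labelling", {
  ex <- toy_exons("c1", c(450, 940), c(700, 1100))
  jx <- dplyr::bind_rows(
    toy_jx(700, 900, 2, list(c("r1", "r2"))),
    toy_jx(700, 940, 4, list(c("r3", "r4", "r5", "r6")))
  )
  ev <- classify_events(jx, no_reads, ex, toy_circ(400, 1200, "+"))
  expect_identical(ev$event_type, "A3SS")
  expect_identical(ev$alt_start, 900L)
  expect_identical(ev$alt_end, 939L)
  expect_identical(ev$incl_reads, 2L)
  expect_identical(ev$excl_reads, 4L)
  ev_minus <- classify_events(jx, no_reads, ex, toy_circ(400, 1200, "-"))
  expect_identical(ev_minus$event_type, "A5SS")
})

test_that("exon skipping requires inclusion evidence and never counts skipping reads", {
  ex <- toy_exons("c1", c(450, 700, 900), c(600, 794, 1100))
  skip <- toy_jx(600, 900, 2, list(c("s1", "s2")))
  incl <- dplyr::bind_rows(
    toy_jx(600, 700, 1, list("i1")),
    toy_jx(794, 900, 1, list("i2"))
  )
  circ <- toy_circ(400, 1200, "+")

  ev <- classify_events(dplyr::bind_rows(skip, incl), no_reads, ex, circ)
  se <- ev[ev$event_type == "SE", ]
  expect_identical(nrow(se), 1L)
  expect_identical(se$alt_start, 700L)
  expect_identical(se$alt_end, 794L)
  expect_identical(se$alt_len, 95L)
  expect_identical(se$incl_reads, 2L)
  expect_identical(se$excl_reads, 2L)

  # no inclusion evidence at all: no call
  expect_identical(nrow(classify_events(skip, no_reads, ex, circ)), 0L)

  # block-overlap evidence alone suffices ...
  cover <- toy_reads("c1", list(cbind(start = 700L, end = 750L)))
  ev2 <- classify_events(skip, cover, ex, circ)
  expect_identical(ev2$event_type, "SE")
  expect_identical(ev2$incl_reads, 1L)

  # ... but an overlap below min_overlap does not
  graze <- toy_reads("c1", list(cbind(start = 788L, end = 794L)))
  expect_identical(nrow(classify_events(skip, graze, ex, circ)), 0L)

  # and the skipping read's own blocks never count as inclusion
  self_cover <- toy_reads("s1", list(cbind(start = 700L, end = 750L)))
  expect_identical(nrow(classify_events(skip, self_cover, ex, circ)), 0L)
})

test_that("junction pairs spanning an annotated exon boundary are left to the SE caller", {
  ex <- toy_exons("c1", c(450, 700, 900), c(600, 794, 1100))
  jx <- dplyr::bind_rows(
    toy_jx(600, 700, 2, list(c("i1", "i2"))),  # inclusion junction
    toy_jx(600, 900, 2, list(c("s1", "s2")))   # skipping junction, shared donor
  )
  ev <- classify_events(jx, no_reads, ex, toy_circ(400, 1200, "+"))
  expect_false("A3SS" %in% ev$event_type)
  expect_identical(ev$event_type, "SE")
})

test_that("retained introns need an unspliced covering read", {
  ex <- toy_exons("c1", c(500, 720), c(650, 900))
  jx <- toy_jx(650, 720, 3, list(c("r1", "r2", "r3")))
  circ <- toy_circ(450, 1000, "+")

  cover <- toy_reads("u1", list(cbind(start = 600L, end = 760L)))
  ev <- classify_events(jx, cover, ex, circ)
  expect_identical(ev$event_type, "RI")
  expect_identical(ev$alt_start, 651L)
  expect_identical(ev$alt_end, 719L)
  expect_identical(ev$alt_len, 69L)
  expect_identical(ev$incl_reads, 1L)
  expect_identical(ev$excl_reads, 3L)

  # a block ending exactly on the donor does not cover the intron
  short <- toy_reads("u1", list(cbind(start = 600L, end = 650L)))
  expect_identical(nrow(classify_events(jx, short, ex, circ)), 0L)
  expect_identical(nrow(classify_events(jx, no_reads, ex, circ)), 0L)
})

test_that("event invariants hold on the simulated fixture", {
  ev <- small_fixture()$res$events
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$event_type %in% c("SE", "RI", "A5SS", "A3SS")))
  # containment: the alternative segment lies inside its circle
  expect_true(all(ev$circ_start <= ev$alt_start))
  expect_true(all(ev$alt_start <= ev$alt_end))
  expect_true(all(ev$alt_end <= ev$circ_end))
  expect_identical(ev$alt_len, ev$alt_end - ev$alt_start + 1L)
  # dual-isoform requirement: evidence for both isoforms
  expect_true(all(ev$incl_reads > 0L))
  expect_true(all(ev$excl_reads > 0L))
  expect_true(all(ev$corrected))
  expect_true(all(ev$host_biotype %in% c("mRNA", "lncRNA", "other")))
  expect_true(all(ev$circ_strand %in% c("+", "-")))
})

test_that("event calls match the brute-force oracle on every circle", {
  sf <- small_fixture()
  rec <- oracle_records(sf$paths$sam)
  for (i in seq_len(nrow(sf$res$bsj))) {
    circ <- sf$res$bsj[i, ]
    want <- oracle_events(rec, sf$fx$genome, sf$exons, circ)
    got <- sf$res$events[sf$res$events$circ_chrom == circ$chrom &
                           sf$res$events$circ_start == circ$start &
                           sf$res$events$circ_end == circ$end,
                         c("event_type", "alt_start", "alt_end")]
    got <- got[order(got$event_type, got$alt_start, got$alt_end), ]
    rownames(want) <- NULL
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 label = sprintf("circle %s:%d-%d", circ$chrom, circ$start, circ$end))
  }
})

test_that("a sample with no back-splices yields empty, well-typed results", {
  g <- toy_genome(2000)
  sam <- write_sam_file(sam_record("r1", 0L, "c1", 100L, "100M"), c(c1 = 2000L))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(toy_exons("c1", 100, 400), gtf)
  res <- call_sample(sam, g, gtf, sample = "none")
  expect_identical(nrow(res$bsj), 0L)
  expect_identical(nrow(res$events), 0L)
  expect_true("sample" %in% names(res$events))
})
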