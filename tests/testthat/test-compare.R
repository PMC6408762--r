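mk_ev <- function(sample, type, alt_start, alt_end, circ_start = 1000L,
                  circ_end = 5000L, chrom = "c1", host_gene = "G1",
                  host_biotype = "mRNA", flank_donor = NA_integer_,
                  flank_acceptor = NA_integer_) {
  tibble::tibble(
    sample = sample, circ_chrom = chrom, circ_start = as.integer(circ_start),
    circ_end = as.integer(circ_end), circ_strand = "+", event_type = type,
    alt_start = as.integer(alt_start), alt_end = as.integer(alt_end),
    alt_len = as.integer(alt_end - alt_start + 1L),
    incl_reads = 3L, excl_reads = 2L,
    flank_donor = as.integer(flank_donor),
    flank_acceptor = as.integer(flank_acceptor),
    host_gene = host_gene, host_biotype = host_biotype, corrected = TRUE
  )
}

two_cond_events <- function() {
  dplyr::bind_rows(
    # common in both samples
    mk_ev("s1", "SE", 2000, 2100), mk_ev("s2", "SE", 2000, 2100),
    mk_ev("s1", "RI", 2500, 2550), mk_ev("s2", "RI", 2500, 2550),
    mk_ev("s1", "A5SS", 3000, 3030), mk_ev("s2", "A5SS", 3000, 3030),
    # A-only
    mk_ev("s1", "SE", 4000, 4090), mk_ev("s1", "A3SS", 4200, 4240),
    # B-only
    mk_ev("s2", "SE", 4500, 4580)
  )
}

test_that("comparison classes partition the event keys", {
  ev <- two_cond_events()
  cmp <- compare_conditions(ev, c(s1 = "T", s2 = "N"), "T", "N")
  expect_identical(nrow(cmp), 6L)
  expect_identical(sum(cmp$class == "common"), 3L)
  expect_identical(sum(cmp$class == "A_specific"), 2L)
  expect_identical(sum(cmp$class == "B_specific"), 1L)
  expect_identical(sum(table(cmp$class)), nrow(cmp))
  expect_identical(attr(cmp, "cond_a"), "T")
  # every key appears exactly once
  key <- paste(cmp$chrom, cmp$circ_start, cmp$event_type, cmp$alt_start, cmp$alt_end)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("swapping the condition labels mirrors the specific classes", {
  ev <- two_cond_events()
  ab <- compare_conditions(ev, c(s1 = "T", s2 = "N"), "T", "N")
  ba <- compare_conditions(ev, c(s1 = "T", s2 = "N"), "N", "T")
  key <- function(d) paste(d$chrom, d$circ_start, d$event_type, d$alt_start, d$alt_end)
  m <- match(key(ab), key(ba))
  swap <- c(A_specific = "B_specific", B_specific = "A_specific", common = "common")
  expect_identical(unname(swap[ab$class]), ba$class[m])
})

test_that("comparison rejects unlabeled samples and non-binary designs", {
  ev <- two_cond_events()
  expect_error(compare_conditions(ev, c(s1 = "T")), class = "circAS_config_error")
  expect_error(compare_conditions(ev, c(s1 = "T", s2 = "N", s3 = "X")),
               class = "circAS_config_error")
  expect_error(compare_conditions(ev, c(s1 = "T", s2 = "N"), "T", "T"),
               class = "circAS_config_error")
})

test_that("a merge window tolerates small coordinate jitter", {
  ev <- dplyr::bind_rows(
    mk_ev("s1", "SE", 2000, 2100),
    mk_ev("s2", "SE", 2000, 2102)  # 2 bp off in one coordinate
  )
  exact <- compare_conditions(ev, c(s1 = "T", s2 = "N"))
  expect_identical(nrow(exact), 2L)
  expect_setequal(exact$class, c("A_specific", "B_specific"))
  fuzzy <- compare_conditions(ev, c(s1 = "T", s2 = "N"), merge_window = 3L)
  expect_identical(nrow(fuzzy), 1L)
  expect_identical(fuzzy$class, "common")
})

test_that("flanking-intron lengths follow the event geometry", {
  ex <- toy_exons("c1", c(100, 300, 500), c(200, 394, 600))
  ev <- dplyr::bind_rows(
    # alternative-donor geometry: intron = flank_acceptor - alt_end - 1
    mk_ev("s", "A5SS", 501, 533, flank_acceptor = 2000L),
    # alternative-acceptor geometry: intron = alt_start - flank_donor - 1
    mk_ev("s", "A3SS", 220, 260, flank_donor = 100L),
    # RI: the retained intron itself
    mk_ev("s", "RI", 651, 706),
    # SE: mean of the two flanking introns in the host transcript
    mk_ev("s", "SE", 300, 394, flank_donor = 200L, flank_acceptor = 500L),
    # SE with no annotated transcript containing the exon: NA
    mk_ev("s", "SE", 310, 380, flank_donor = 200L, flank_acceptor = 500L)
  )
  len <- circ_intron_length(ev, ex)
  expect_identical(len[1], 1466L)
  expect_identical(len[2], 119L)
  expect_identical(len[3], 56L)
  expect_identical(len[4], 102L)  # mean(99, 105) rounded
  expect_true(is.na(len[5]))
})

test_that("host biotype ties break towards coding genes", {
  ex <- dplyr::bind_rows(
    toy_exons("c1", c(1900, 2000), c(1950, 2100), "tl", "LNC1", biotype = "lncRNA"),
    toy_exons("c1", c(1900, 2000), c(1950, 2100), "tm", "COD1", biotype = "mRNA")
  )
  ev <- mk_ev("s", "SE", 2000, 2100, flank_donor = 1950L, flank_acceptor = 2200L,
              host_gene = NA_character_, host_biotype = "other")
  out <- host_biotype(ev, ex)
  expect_identical(out$host_gene, "COD1")
  expect_identical(out$host_biotype, "mRNA")

  # no matching boundary at all: biotype "other", gene NA
  ev2 <- mk_ev("s", "SE", 7000, 7100, flank_donor = 6900L, flank_acceptor = 7200L)
  out2 <- host_biotype(ev2, ex)
  expect_true(is.na(out2$host_gene))
  expect_identical(out2$host_biotype, "other")
})

test_that("gene-list overlap restricts to one class and matches case-insensitively", {
  ev <- two_cond_events()
  cmp <- compare_conditions(ev, c(s1 = "T", s2 = "N"), "T", "N")
  # the two A-specific events are hosted by G1; list uses lowercase
  ov <- overlap_gene_list(cmp, ev, c("g1", "NOTAGENE"), class = "A_specific")
  expect_identical(sum(ov$n), 2L)
  expect_setequal(ov$event_type, c("SE", "A3SS"))
  expect_identical(unique(ov$gene), "G1")
  ov_b <- overlap_gene_list(cmp, ev, "g1", class = "B_specific")
  expect_identical(sum(ov_b$n), 1L)
  expect_error(overlap_gene_list(cmp, ev, character(0)),
               class = "circAS_config_error")
})

test_that("summary percentages are within-class and empty classes are zero-filled", {
  ev <- dplyr::bind_rows(
    mk_ev("s1", "SE", 2000, 2100), mk_ev("s1", "SE", 2300, 2390),
    mk_ev("s1", "RI", 2500, 2550), mk_ev("s1", "A5SS", 3000, 3030,
                                         host_biotype = "lncRNA")
  )
  # sX carries the second condition label but contributes no events
  cmp <- compare_conditions(ev, c(s1 = "T", sX = "N"), "T", "N")
  tc <- summarize_comparison(cmp, ev)$type_counts
  a <- tc[tc$class == "A_specific", ]
  expect_identical(a$n[a$event_type == "SE"], 2L)
  expect_equal(a$pct[a$event_type == "SE"], 50)
  expect_equal(a$pct[a$event_type == "RI"], 25)
  expect_equal(a$pct[a$event_type == "A5SS"], 25)
  expect_equal(a$pct[a$event_type == "A3SS"], 0)
  b <- tc[tc$class == "B_specific", ]
  expect_identical(sum(b$n), 0L)
  expect_true(all(b$pct == 0))  # no division-by-zero artifacts

  bt <- summarize_comparison(cmp, ev)$biotype
  a_bt <- bt[bt$class == "A_specific", ]
  expect_equal(a_bt$pct[a_bt$biotype == "mRNA"], 75)
  expect_equal(a_bt$pct[a_bt$biotype == "lncRNA"], 25)
})
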