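---
title: "circAS: methods, parameters, and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circAS: methods, parameters, and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents what circAS computes, why each parameter has the
default it has, how the synthetic-data generator is constructed, and what
the synthetic validation does and does not demonstrate.

## Coordinate conventions

All coordinates are 1-based and inclusive, everywhere: inputs (SAM, GTF),
internal tables, and outputs (`events.tsv`, `comparison.tsv`). The single
exception is the BED export (`write_bed()`), which converts to 0-based
half-open at write time, because that is what BED is. A junction is stored
as `(donor, acceptor)` where `donor` is the last exonic base before the
gap and `acceptor` is the first exonic base after it; the excised segment
is `donor + 1 .. acceptor - 1`.

## Back-splice junction detection

A back-splice junction (BSJ) is read off a chimeric alignment: one read
stored as two segments (a primary plus a supplementary alignment) on the
same chromosome and strand, where the segment that comes *later* in the
stored read maps genomically *left* of the earlier segment.

The pairing test works in stored-read (query) coordinates. For each
segment we compute its query span from the CIGAR string: leading hard and
soft clips give the query start, and the aligned width along the query
gives the span. For two segments `a` (query-earlier) and `b`
(query-later), the pair is a BSJ candidate when

- both map to the same chromosome and the same strand,
- `b` ends genomically before `a` starts (`b.ref_end < a.ref_start`), and
- the query coordinates are contiguous:
  `|b.query_start - a.query_end - 1| <= 2`.

Working in stored orientation is the load-bearing trick: clips in a SAM
record are given in stored orientation regardless of strand, so one
uniform contiguity test is valid for plus- and minus-strand chimeras
without any per-strand case analysis. The ±2 slack absorbs the small
overlaps and gaps aligners leave at chimeric breakpoints.

The candidate junction is `(start = b.ref_start, end = a.ref_end)` — the
genomic span of the circle. Candidates are aggregated exactly (no
positional fuzz), support is counted as the number of *distinct* read
names, and a candidate becomes a call only if:

- support ≥ `min_bsj_support` (default **2**: a single chimeric read is
  indistinguishable from a ligation or alignment artifact, while requiring
  3+ discards real low-abundance circles; the simulator plants a
  single-read decoy BSJ specifically to exercise this floor), and
- the back-splice flanks are canonical: the two bases after `end` and the
  two before `start` read GT…AG (circle on "+") or CT…AC (circle on "−").
  The strand of the circle is *assigned* from the motif rather than taken
  from the read, since the chimeric segments' stored strand reflects
  library chemistry, not the transcript.

## Internal event calling

Reads are assigned to a circle if they span its BSJ, plus their mates when
the mate's aligned blocks fall entirely inside the circle span. Within the
assigned reads, every alignment gap of at least `min_intron_len` bases
(default **30**, below the shortest credible spliceosomal intron; smaller
gaps are treated as deletions and the flanking blocks merged) is a
candidate internal junction. Junctions are kept when:

- supported by at least `min_junction_support` distinct reads (default
  **1** — inside an already support-filtered circle, single-read junction
  evidence is informative and the motif and annotation filters below do
  the false-positive control),
- canonical (same GT–AG / CT–AC test as above), and
- annotation-consistent: the donor matches some annotated exon end or the
  acceptor matches some annotated exon start on that chromosome. This
  "exon correction" can be disabled (`no_correct = TRUE`); corrected
  status is reported per event.

Four event types are then called per circle, each requiring evidence for
*both* isoforms:

- **SE** — a junction spans an annotated exon strictly inside the circle
  (both exon edges strictly between donor and acceptor), and inclusion is
  supported by reads *not* carrying the skipping junction, either via a
  junction anchored on the exon's edge or an aligned block overlapping the
  exon by at least `min_overlap` bases (default **8**: enough to rule out
  1–7 bp alignment slop at block edges while still accepting short
  overhangs). A guard suppresses SE calls where the "skipping" junction
  is actually a pair of annotated exon boundaries that the A5SS/A3SS logic
  should explain.
- **RI** — a kept junction coincides exactly with an annotated intron,
  and at least one read has a single contiguous block covering the entire
  intron plus one base on each side (the retention isoform).
- **A5SS / A3SS** — two kept junctions share one end and differ at the
  other. Labels are strand-aware: junctions sharing an acceptor differ at
  the donor side, which is the 5' splice site on a "+" circle but the 3'
  splice site on a "−" circle, and vice versa. The alternative segment is
  the interval between the two competing sites; inclusion support is the
  read count of the longer-exon junction, exclusion the shorter.

Events are deduplicated on `(type, alt_start, alt_end)` per circle, and
`alt_len = alt_end - alt_start + 1` always.

## Comparing conditions

`compare_conditions()` takes event tables from two groups of samples,
merges event keys (optionally clustering boundaries within
`merge_window` bases, default **0** — exact matching, since both
conditions are processed by the same deterministic caller and positional
fuzz would conflate genuinely distinct splice sites), and classifies each
merged event as `A_specific`, `B_specific`, or `common`. The classes
partition the catalog and are symmetric under label swap.

Downstream characterization:

- `circ_intron_length()` reports, per event, the length of the intron the
  event modifies. These definitions are this package's own choices: for
  RI it is the retained intron itself (`alt_len`); for an alternative
  donor it is the distance from the alternative segment to the next
  acceptor (`flank_acceptor - alt_end - 1`); for an alternative acceptor,
  `alt_start - flank_donor - 1`; for SE, the mean of the two flanking
  introns (skipping fuses them, so neither alone is "the" intron).
- `host_biotype()` maps each event's host gene to mRNA/lncRNA/other from
  the GTF biotype, breaking multi-transcript ties in that priority order.
- `overlap_gene_list()` intersects host genes of a chosen class with a
  user list, case-insensitively.

## The simulator

`sim_fixture()` is first-class, tested code, not a throwaway script. It
generates a mini-genome (default 3 contigs × 200 kb of uniform random
sequence), a gene annotation, circles with two isoforms each, and truth
tables; `sim_reads()` generates paired-end SAM records. Everything is a
pure function of the seed, down to file bytes.

Geometry: each gene has 5–6 exons and the circle always spans three
consecutive internal exons (exons 2–4), with exon widths 90–200 bp, so
circumferences are 270–600 bp. One planted event per circle, cycling
through SE/RI/A5SS/A3SS, always modifying the *middle* circle exon:
SE skips it; RI retains a deliberately short intron (35–60 bp, just above
`min_intron_len`) next to it; A5SS/A3SS move its donor/acceptor by
20–60 bp. Canonical motifs are planted at every junction both isoforms
use and at the BSJ flanks (reverse-complement pattern for minus-strand
circles).

Library model: fragment lengths are Normal(300, 80) truncated to
`[read_len + 20, circumference]` — a broad, loosely size-selected
library. This choice is part of the simulation's *model*, not a tuning
knob: with a tight insert distribution, the mates of BSJ-spanning reads
all land in a narrow band past the circle boundary and mid-circle
retained introns are structurally unobservable, which says nothing about
the caller. With broad inserts the mates sample the whole circumference,
so every planted event is in principle visible at realistic coverage. At
least 25% of each circle's fragments span the BSJ (positions stratified
around the junction); the rest start uniformly on the rolled-out circle.

Decoys, planted per fixture to verify each filter does its job:

- a junction with non-canonical (AA…AA) flanks → removed by the motif
  filter;
- a canonical but unannotated junction → removed by exon correction;
- a BSJ with non-canonical flanks → removed by the BSJ motif filter;
- a canonical BSJ supported by exactly one read → removed by the support
  floor.

Decoy junction reads are paired with genuine BSJ-spanning mates so they
enter the per-circle read sets and must be rejected by the filters, not
by assignment.

`score_against_truth()` matches called events to truth on exact
`(type, alt_start, alt_end)` and reports per-type precision and recall.

## Worked examples

`sim_circ_ubap2l()` and `sim_circ_rab6a()` reconstruct two
experimentally validated events at their published human coordinates — an
A5SS with a 33 bp alternative segment in a UBAP2L circle
(chr1:154,234,591–154,235,291) and a 95 bp skipped exon in a RAB6A circle
(chr11:73,707,420–73,718,718). The contigs are synthetic: N up to shortly
before the circle, random sequence with planted canonical motifs around
it. Only the coordinates and segment lengths come from the validated
events; sequence and reads are simulated. The fixtures exist so that the
pipeline's output can be checked against externally known numbers rather
than against its own simulator.

## Numerical and engineering choices

- Support counts use distinct read names, so a read and its supplementary
  line never double-count.
- Aggregation and comparison sort deterministically; reruns are
  byte-identical, which the tests assert at the output-file level.
- Large synthetic contigs are assembled in a raw byte buffer and handed
  to the pipeline as a `DNAStringSet`; per-base string surgery on
  multi-megabase R character vectors copies the whole string per edit.
- Derived seeds stay below 2^31; all randomness flows from the single
  user seed.

## Limitations

Synthetic validation demonstrates *internal consistency*: that the
implementation finds exactly what its own generative model plants, rejects
the decoy classes it was designed to reject, and matches an independent
brute-force reimplementation on the same inputs. It does **not**
demonstrate:

- performance on real aligner output, where chimeric breakpoints are
  noisy, multi-mappers abound, and soft-clip boundaries wobble beyond the
  ±2 slack modelled here;
- robustness to annotation errors — exon correction assumes the GTF is
  right, and will discard genuinely novel splice sites;
- calibration of support thresholds to real expression levels; the
  defaults are justified structurally (see above), not fit to data;
- rolling-circle or multi-lap fragments, trans-splicing, or circles
  sharing a boundary, none of which the generator produces.

Quantities reported on real data should be treated as candidate calls for
experimental follow-up, not as validated events.
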