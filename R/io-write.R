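#' Write circ-AS events to TSV
#'
#' Fixed column set, one header line, 1-based inclusive coordinates,
#' `corrected` encoded 0/1. Rows are sorted by chromosome, circle start,
#' event start, then type, so identical inputs produce byte-identical
#' files.
#'
#' @param events Event tibble (see [call_sample()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("sample", "circ_chrom", "circ_start", "circ_end", "circ_strand",
            "event_type", "alt_start", "alt_end", "alt_len",
            "incl_reads", "excl_reads", "host_gene", "host_biotype", "corrected")
  if (!"sample" %in% names(events)) events$sample <- "sample1"
  out <- events %>%
    mutate(corrected = as.integer(.data$corrected)) %>%
    select(all_of(cols)) %>%
    arrange(.data$circ_chrom, .data$circ_start, .data$alt_start, .data$event_type)
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read an events TSV written by [write_events()]
#'
#' @param path Path to an events TSV.
#' @return An event tibble; `flank_donor`/`flank_acceptor` are NA because
#'   the TSV does not carry them.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("events file not found: ", path), class = "circAS_io_error")
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      circ_chrom = readr::col_character(),
      circ_start = readr::col_integer(),
      circ_end = readr::col_integer(),
      circ_strand = readr::col_character(),
      event_type = readr::col_character(),
      alt_start = readr::col_integer(),
      alt_end = readr::col_integer(),
      alt_len = readr::col_integer(),
      incl_reads = readr::col_integer(),
      excl_reads = readr::col_integer(),
      host_gene = readr::col_character(),
      host_biotype = readr::col_character(),
      corrected = readr::col_integer()
    )
  ) %>%
    mutate(corrected = .data$corrected == 1L,
           flank_donor = NA_integer_, flank_acceptor = NA_integer_)
}

#' Write a condition comparison to TSV
#'
#' One row per event key, columns `event_key` (chrom:circ_start-circ_end
#' pipe type pipe alt_start-alt_end), `n_samples_A`, `n_samples_B`,
#' `class`. Sorted by key; byte-identical across runs on identical input.
#'
#' @param records Comparison tibble from [compare_conditions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(records, path) {
  out <- records %>%
    mutate(event_key = sprintf("%s:%d-%d|%s|%d-%d",
                               .data$chrom, .data$circ_start, .data$circ_end,
                               .data$event_type, .data$alt_start, .data$alt_end)) %>%
    select("event_key", "n_samples_A", "n_samples_B", "class") %>%
    arrange(.data$event_key)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write circRNA spans as BED6
#'
#' Coordinates are converted from the in-memory 1-based inclusive
#' convention to BED's 0-based half-open exactly here.
#'
#' @param bsj BSJ tibble from [detect_bsj()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bsj, path) {
  out <- bsj %>%
    mutate(
      bed_start = .data$start - 1L,
      name = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)
    ) %>%
    select("chrom", "bed_start", end = "end", "name", score = "support",
           "strand") %>%
    arrange(.data$chrom, .data$bed_start)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a human-readable summary report
#'
#' @param summary Output of [summarize_comparison()].
#' @param path Output path.
#' @param cond_a,cond_b Display names for the two conditions.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(summary, path, cond_a = "A", cond_b = "B") {
  lines <- c(
    "circ-AS comparison summary",
    sprintf("condition A = %s, condition B = %s", cond_a, cond_b),
    "",
    "Event-type counts per class:"
  )
  tc <- summary$type_counts
  for (cl in unique(tc$class)) {
    g <- tc[tc$class == cl, ]
    lines <- c(lines, sprintf("  %-11s %s", cl,
                              paste(sprintf("%s %d (%.1f%%)", g$event_type, g$n, g$pct),
                                    collapse = ", ")))
  }
  il <- summary$intron_length
  if (nrow(il) > 0) {
    lines <- c(lines, "", "Mean flanking-intron length (bp) per class and type:")
    for (i in seq_len(nrow(il))) {
      lines <- c(lines, sprintf("  %-11s %-4s n=%d mean=%.1f se=%s",
                                il$class[i], il$event_type[i], il$n[i], il$mean_len[i],
                                ifelse(is.na(il$se[i]), "NA", sprintf("%.1f", il$se[i]))))
    }
  }
  bt <- summary$biotype
  if (nrow(bt) > 0) {
    lines <- c(lines, "", "Host biotype per class (pct within mRNA/lncRNA):")
    for (i in seq_len(nrow(bt))) {
      lines <- c(lines, sprintf("  %-11s %-6s n=%d%s",
                                bt$class[i], bt$biotype[i], bt$n[i],
                                ifelse(is.na(bt$pct[i]), "",
                                       sprintf(" (%.1f%%)", bt$pct[i]))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
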