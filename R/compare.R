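#' Compare circ-AS event catalogs between two conditions
#'
#' Events are keyed by exact coordinates — (chrom, circle span, event type,
#' alternative segment) — and classified by presence/absence across the two
#' conditions: detected only in condition A samples is `A_specific`, only in
#' B is `B_specific`, in both is `common`. The three classes partition the
#' distinct event keys. No expression-level test is performed. With
#' `merge_window > 0`, events whose four coordinates each differ by at most
#' that many bases are greedily merged (first-seen event anchors the
#' cluster) before classification.
#'
#' @param events Event tibble with a `sample` column, e.g. `bind_rows()` of
#'   per-sample [call_sample()] results.
#' @param labels Named character vector mapping sample id to condition.
#'   Exactly two distinct conditions are required.
#' @param cond_a,cond_b Which condition is "A"/"B"; default the two label
#'   values in sorted order.
#' @param merge_window Coordinate slack in bases for cross-sample matching
#'   (default 0 = exact).
#'
#' @return A tibble sorted by event key: `chrom`, `circ_start`, `circ_end`,
#'   `event_type`, `alt_start`, `alt_end`, `samples_A`, `samples_B` (list
#'   columns), `n_samples_A`, `n_samples_B`, `class`. Attributes `cond_a`
#'   and `cond_b` record the condition names.
#' @export
compare_conditions <- function(events, labels, cond_a = NULL, cond_b = NULL,
                               merge_window = 0L) {
  stray <- setdiff(unique(events$sample), names(labels))
  if (length(stray) > 0) {
    abort(paste0("sample(s) without condition label: ",
                 paste(stray, collapse = ", ")), class = "circAS_config_error")
  }
  conds <- sort(unique(unname(labels)))
  if (length(conds) != 2) {
    abort("exactly two conditions are required", class = "circAS_config_error")
  }
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- setdiff(conds, cond_a)[1]
  if (!all(c(cond_a, cond_b) %in% conds) || cond_a == cond_b) {
    abort("cond_a/cond_b must name the two distinct conditions",
          class = "circAS_config_error")
  }

  keyed <- events %>%
    mutate(chrom = .data$circ_chrom, cond = unname(labels[.data$sample])) %>%
    select("chrom", "circ_start", "circ_end", "event_type",
           "alt_start", "alt_end", "sample", "cond")
  if (merge_window > 0 && nrow(keyed) > 0) {
    keyed <- merge_event_keys(keyed, merge_window)
  }
  out <- keyed %>%
    group_by(.data$chrom, .data$circ_start, .data$circ_end,
             .data$event_type, .data$alt_start, .data$alt_end) %>%
    summarise(
      samples_A = list(sort(unique(.data$sample[.data$cond == cond_a]))),
      samples_B = list(sort(unique(.data$sample[.data$cond == cond_b]))),
      .groups = "drop"
    ) %>%
    mutate(
      n_samples_A = lengths(.data$samples_A),
      n_samples_B = lengths(.data$samples_B),
      class = case_when(
        .data$n_samples_A > 0 & .data$n_samples_B == 0 ~ "A_specific",
        .data$n_samples_B > 0 & .data$n_samples_A == 0 ~ "B_specific",
        TRUE ~ "common"
      )
    ) %>%
    arrange(.data$chrom, .data$circ_start, .data$circ_end,
            .data$event_type, .data$alt_start, .data$alt_end)
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  out
}

# greedy coordinate-slack clustering of event keys within (chrom, type)
merge_event_keys <- function(keyed, window) {
  keyed %>%
    dplyr::group_split(.data$chrom, .data$event_type) %>%
    purrr::map(function(g) {
      g <- g %>% arrange(.data$circ_start, .data$circ_end, .data$alt_start, .data$alt_end)
      anchors <- g[0, c("circ_start", "circ_end", "alt_start", "alt_end")]
      idx <- integer(nrow(g))
      for (i in seq_len(nrow(g))) {
        hit <- which(
          abs(anchors$circ_start - g$circ_start[i]) <= window &
            abs(anchors$circ_end - g$circ_end[i]) <= window &
            abs(anchors$alt_start - g$alt_start[i]) <= window &
            abs(anchors$alt_end - g$alt_end[i]) <= window
        )
        if (length(hit) > 0) {
          idx[i] <- hit[1]
        } else {
          anchors <- bind_rows(anchors, g[i, c("circ_start", "circ_end",
                                               "alt_start", "alt_end")])
          idx[i] <- nrow(anchors)
        }
      }
      g$circ_start <- anchors$circ_start[idx]
      g$circ_end <- anchors$circ_end[idx]
      g$alt_start <- anchors$alt_start[idx]
      g$alt_end <- anchors$alt_end[idx]
      g
    }) %>%
    bind_rows()
}

#' Flanking-intron length of circ-AS events
#'
#' Computes, per event, the intron length relevant to its splicing choice:
#' for alternative-donor pairs the intron downstream of the alternative
#' region (`shared acceptor - max donor - 1`); for alternative-acceptor
#' pairs the intron upstream of it (`min acceptor - shared donor - 1`); for
#' SE the mean of the skipped exon's two flanking intron lengths in its
#' host transcript (NA when no annotated transcript contains the exon with
#' both neighbours); for RI the retained intron's own length. Dispatch for
#' A5SS/A3SS is by junction geometry, so strand-aware labels do not change
#' the value.
#'
#' @param events Event tibble from [classify_events()]/[call_sample()].
#' @param exons Exon table from [read_annotation()].
#'
#' @return An integer vector aligned with `events` rows (NA allowed).
#' @export
circ_intron_length <- function(events, exons) {
  n <- nrow(events)
  out <- rep(NA_integer_, n)
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    e <- events[i, ]
    out[i] <- if (e$event_type == "RI") {
      e$alt_len
    } else if (!is.na(e$flank_acceptor) && is.na(e$flank_donor)) {
      e$flank_acceptor - e$alt_end - 1L       # alternative-donor geometry
    } else if (!is.na(e$flank_donor) && is.na(e$flank_acceptor)) {
      e$alt_start - e$flank_donor - 1L        # alternative-acceptor geometry
    } else if (e$event_type == "SE") {
      se_flank_mean(e, exons)
    } else {
      NA_integer_
    }
  }
  as.integer(out)
}

se_flank_mean <- function(e, exons) {
  tx <- exons %>%
    filter(.data$chrom == e$circ_chrom,
           .data$exon_start == e$alt_start, .data$exon_end == e$alt_end) %>%
    pull("transcript_id")
  if (length(tx) == 0) return(NA_integer_)
  if (!is.na(e$host_gene)) {
    tx_host <- exons %>%
      filter(.data$transcript_id %in% tx, .data$gene_name == e$host_gene) %>%
      pull("transcript_id")
    if (length(tx_host) > 0) tx <- tx_host
  }
  for (t in sort(unique(tx))) {
    ex <- exons %>% filter(.data$transcript_id == t) %>% arrange(.data$exon_start)
    k <- which(ex$exon_start == e$alt_start & ex$exon_end == e$alt_end)
    if (length(k) == 0) next
    k <- k[1]
    if (k == 1 || k == nrow(ex)) next  # no flanking intron on one side
    up <- e$alt_start - ex$exon_end[k - 1] - 1L
    down <- ex$exon_start[k + 1] - e$alt_end - 1L
    return(as.integer(round(mean(c(up, down)))))
  }
  NA_integer_
}

#' Host transcript biotype of circ-AS events
#'
#' Recomputes the host gene and biotype of each event from the annotated
#' transcripts whose exon boundaries match the event's defining junction
#' boundaries. When several transcripts match, a coding-gene overlap
#' dominates: ties are broken mRNA > lncRNA > other. Events matched by no
#' transcript get biotype `"other"` and host gene `NA`.
#'
#' @param events Event tibble.
#' @param exons Exon table from [read_annotation()].
#'
#' @return `events` with refreshed `host_gene` and `host_biotype` columns.
#' @export
host_biotype <- function(events, exons) {
  if (nrow(events) == 0) return(events)
  events$bounds <- purrr::pmap(
    list(events$event_type, events$alt_start, events$alt_end,
         events$flank_donor, events$flank_acceptor),
    function(type, as_, ae, fd, fa) {
      b <- switch(type,
        SE = c(fd, fa, as_, ae),
        RI = c(as_ - 1L, ae + 1L),
        c(fd, fa, as_ - 1L, ae, as_, ae + 1L)  # A5SS/A3SS: competing boundaries
      )
      b[!is.na(b)]
    }
  )
  out <- events %>%
    dplyr::group_split(.data$circ_chrom) %>%
    purrr::map(function(g) {
      annotate_host(g, exons %>% filter(.data$chrom == g$circ_chrom[1]))
    }) %>%
    bind_rows()
  out$bounds <- NULL
  out
}

#' Read a gene list
#'
#' One gene symbol per line; blank lines and leading/trailing whitespace
#' are ignored.
#'
#' @param path Path to a plain-text gene list.
#' @return A character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("gene list not found: ", path), class = "circAS_io_error")
  }
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[x != ""]
  if (length(x) == 0) {
    abort("gene list is empty", class = "circAS_config_error")
  }
  x
}

#' Overlap condition-specific events with a gene list
#'
#' Restricts events to one comparison class (typically the
#' condition-specific one), keeps those hosted by genes in the given list
#' (case-insensitive symbol match), and tabulates occurrences per gene and
#' event type — the machine-readable form of an oncogene/tumour-suppressor
#' occurrence panel.
#'
#' @param comparison Output of [compare_conditions()].
#' @param events The event tibble the comparison was built from.
#' @param gene_list Character vector of gene symbols, or a file path for
#'   [read_gene_list()].
#' @param class Comparison class to keep (default `"A_specific"`).
#'
#' @return A tibble `gene`, `event_type`, `n`, sorted by gene then type.
#' @export
overlap_gene_list <- function(comparison, events, gene_list, class = "A_specific") {
  if (is.character(gene_list) && length(gene_list) == 1 && file.exists(gene_list)) {
    gene_list <- read_gene_list(gene_list)
  }
  if (length(gene_list) == 0) {
    abort("gene list is empty", class = "circAS_config_error")
  }
  keys <- comparison %>%
    filter(.data$class == .env$class) %>%
    select("chrom", "circ_start", "circ_end", "event_type", "alt_start", "alt_end")
  events %>%
    mutate(chrom = .data$circ_chrom) %>%
    distinct(.data$chrom, .data$circ_start, .data$circ_end, .data$event_type,
             .data$alt_start, .data$alt_end, .keep_all = TRUE) %>%
    semi_join(keys, by = c("chrom", "circ_start", "circ_end", "event_type",
                           "alt_start", "alt_end")) %>%
    filter(!is.na(.data$host_gene),
           tolower(.data$host_gene) %in% tolower(gene_list)) %>%
    count(gene = .data$host_gene, .data$event_type, name = "n") %>%
    arrange(.data$gene, .data$event_type)
}

EVENT_TYPES <- c("SE", "RI", "A5SS", "A3SS")

#' Summarize a condition comparison
#'
#' Produces the per-class characterization tables: event-type counts with
#' within-class percentages, per-type mean flanking-intron length with its
#' standard error (sample SD divided by the square root of n), and the
#' mRNA/lncRNA host split (events of biotype `"other"` are reported
#' separately and excluded from the two-way percentage).
#'
#' @param comparison Output of [compare_conditions()].
#' @param events The event tibble the comparison was built from.
#' @param exons Optional exon table; when supplied, intron lengths are
#'   (re)computed with [circ_intron_length()].
#'
#' @return A list of tibbles: `type_counts` (class, event_type, n, pct),
#'   `intron_length` (class, event_type, n, mean_len, se), `biotype`
#'   (class, biotype, n, pct).
#' @export
summarize_comparison <- function(comparison, events, exons = NULL) {
  key <- c("chrom", "circ_start", "circ_end", "event_type", "alt_start", "alt_end")
  ev <- events %>%
    mutate(chrom = .data$circ_chrom) %>%
    distinct(across(all_of(key)), .keep_all = TRUE)
  if (!is.null(exons)) ev$intron_len <- circ_intron_length(ev, exons)
  if (!"intron_len" %in% names(ev)) ev$intron_len <- NA_integer_
  joined <- comparison %>%
    select(all_of(key), "class") %>%
    left_join(ev %>% select(all_of(key), "intron_len", "host_biotype"), by = key)

  classes <- c("A_specific", "B_specific", "common")
  grid <- tidyr::expand_grid(class = classes, event_type = EVENT_TYPES)

  type_counts <- joined %>%
    count(.data$class, .data$event_type, name = "n") %>%
    dplyr::right_join(grid, by = c("class", "event_type")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    group_by(.data$class) %>%
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else
      rep(0, dplyr::n())) %>%
    ungroup() %>%
    arrange(.data$class, match(.data$event_type, EVENT_TYPES))

  intron_length <- joined %>%
    filter(!is.na(.data$intron_len)) %>%
    group_by(.data$class, .data$event_type) %>%
    summarise(
      n = n(),
      mean_len = mean(.data$intron_len),
      se = if (n() > 1) sd(.data$intron_len) / sqrt(n()) else NA_real_,
      .groups = "drop"
    ) %>%
    arrange(.data$class, match(.data$event_type, EVENT_TYPES))

  biotype <- joined %>%
    mutate(host_biotype = tidyr::replace_na(.data$host_biotype, "other")) %>%
    count(.data$class, biotype = .data$host_biotype, name = "n") %>%
    group_by(.data$class) %>%
    mutate(
      two_way = sum(.data$n[.data$biotype %in% c("mRNA", "lncRNA")]),
      pct = if_else(.data$biotype %in% c("mRNA", "lncRNA") & .data$two_way > 0,
                    100 * .data$n / .data$two_way, NA_real_)
    ) %>%
    ungroup() %>%
    select(-"two_way") %>%
    arrange(.data$class, .data$biotype)

  list(type_counts = type_counts, intron_length = intron_length, biotype = biotype)
}
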