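# 5'UTR reconstruction from TSSs, start codons and splicing patterns.

#' Percent-spliced-in with annotation pseudo-reads
#'
#' Splice-in reads support retention of the event's region in the mature
#' transcript, splice-out reads support its removal. Annotated constitutive
#' events receive 10 pseudo splice-out reads, annotated alternative events 5
#' pseudo splice-in plus 5 pseudo splice-out reads, novel events none. The
#' PSI is then splice-in / (splice-in + splice-out); events with
#' PSI <= 0.1 are called `"removed"`, PSI >= 0.9 `"retained"`, anything in
#' between (including novel events with no informative reads) `"ambiguous"`.
#' Isoforms whose 5'UTR overlaps an ambiguous event are excluded from
#' sequence-feature analyses.
#'
#' @param events Tibble with columns `status` (one of
#'   `"annotated-constitutive"`, `"annotated-alternative"`, `"novel"`),
#'   `reads_splicein`, `reads_spliceout` (other columns pass through).
#' @return `events` with `psi` and `call` columns.
#' @export
compute_psi <- function(events) {
  stopifnot(all(c("status", "reads_splicein", "reads_spliceout") %in% names(events)))
  if (any(events$reads_splicein < 0 | events$reads_spliceout < 0)) {
    abort("read counts must be non-negative")
  }
  bad <- setdiff(unique(events$status),
                 c("annotated-constitutive", "annotated-alternative", "novel"))
  if (length(bad)) abort(paste0("unknown event status: ", paste(bad, collapse = ", ")))
  events |>
    mutate(
      pseudo_in = dplyr::case_when(
        .data$status == "annotated-alternative" ~ 5, TRUE ~ 0),
      pseudo_out = dplyr::case_when(
        .data$status == "annotated-constitutive" ~ 10,
        .data$status == "annotated-alternative" ~ 5, TRUE ~ 0),
      total = .data$reads_splicein + .data$reads_spliceout +
        .data$pseudo_in + .data$pseudo_out,
      psi = ifelse(.data$total == 0, NA_real_,
                   (.data$reads_splicein + .data$pseudo_in) / .data$total),
      call = dplyr::case_when(
        is.na(.data$psi) ~ "ambiguous",
        .data$psi <= 0.1 ~ "removed",
        .data$psi >= 0.9 ~ "retained",
        TRUE ~ "ambiguous")) |>
    select(-"pseudo_in", -"pseudo_out", -"total")
}

#' Reconstruct the mature 5'UTR sequence of a TSS isoform
#'
#' Without splicing the 5'UTR is the genomic sequence between the TSS and
#' the main start codon (exclusive); events called `"removed"` are excised
#' and the remaining exonic segments concatenated. Any overlapping
#' `"ambiguous"` event makes the isoform `ambiguous-excluded` (no sequence).
#' The sequence is returned 5'->3' in transcript orientation
#' (reverse-complemented on the minus strand).
#'
#' @param tss 0-based genomic position of the TSS (the cap site base).
#' @param start_codon 0-based genomic position of the main AUG's A (on the
#'   minus strand this is the highest coordinate of the codon).
#' @param genome Named [Biostrings::DNAStringSet] (or named character).
#' @param chrom,strand Contig and strand of the isoform.
#' @param events Optional tibble of classified splice events for this
#'   contig/strand with columns `donor0`, `acceptor0` (0-based half-open
#'   genomic intron bounds, `donor0 < acceptor0`) and `call` from
#'   [compute_psi()].
#' @return One-row tibble: `status` (`"resolved"` or `"ambiguous-excluded"`),
#'   `utr_seq`, `utr_length`, and a list-column `segments` of kept genomic
#'   intervals.
#' @export
reconstruct_utr <- function(tss, start_codon, genome, chrom, strand = "+",
                            events = NULL) {
  if (strand == "+") {
    span <- c(tss, start_codon)
  } else {
    span <- c(start_codon + 1L, tss + 1L)
  }
  if (span[2] <= span[1]) {
    abort("TSS must lie strictly 5' of the start codon on the given strand")
  }
  ev <- if (!is.null(events) && nrow(events)) {
    filter(events, .data$acceptor0 > span[1], .data$donor0 < span[2])
  } else NULL
  if (!is.null(ev) && nrow(ev) && any(ev$call == "ambiguous")) {
    return(tibble(status = "ambiguous-excluded", utr_seq = NA_character_,
                  utr_length = NA_integer_, segments = list(NULL)))
  }
  cuts <- if (!is.null(ev)) filter(ev, .data$call == "removed") else NULL
  segs <- tibble(lo = span[1], hi = span[2])
  if (!is.null(cuts) && nrow(cuts)) {
    cuts <- arrange(cuts, .data$donor0)
    lo <- span[1]; pieces <- list()
    for (i in seq_len(nrow(cuts))) {
      a <- max(cuts$donor0[i], span[1]); b <- min(cuts$acceptor0[i], span[2])
      if (a > lo) pieces[[length(pieces) + 1L]] <- tibble(lo = lo, hi = a)
      lo <- max(lo, b)
    }
    if (lo < span[2]) pieces[[length(pieces) + 1L]] <- tibble(lo = lo, hi = span[2])
    segs <- if (length(pieces)) list_rbind(pieces) else tibble(lo = integer(), hi = integer())
  }
  ctg <- as.character(genome[[chrom]])
  seq_parts <- purrr::map2_chr(segs$lo, segs$hi, function(a, b) substr(ctg, a + 1, b))
  seq <- paste(seq_parts, collapse = "")
  if (strand == "-") seq <- revcomp(seq)
  tibble(status = "resolved", utr_seq = seq, utr_length = nchar(seq),
         segments = list(segs))
}

#' Sequence unique to the longer isoform of a pair
#'
#' For two resolved mature 5'UTRs of the same gene the shorter must be a
#' suffix of the longer (shared 3' portion identical); the divergent region
#' is the 5' prefix present only in the longer isoform. Pairs whose shorter
#' UTR is not a suffix (e.g. alternative splicing downstream of the
#' proximal TSS) are flagged and excluded from divergent-feature analyses.
#'
#' @param long_utr,short_utr Mature 5'UTR sequences (transcript
#'   orientation).
#' @return One-row tibble: `divergent_seq`, `divergent_length`, `ok`
#'   (FALSE when flagged or the region is empty).
#' @export
divergent_region <- function(long_utr, short_utr) {
  if (is.na(long_utr) || is.na(short_utr)) {
    return(tibble(divergent_seq = NA_character_, divergent_length = NA_integer_,
                  ok = FALSE))
  }
  if (nchar(short_utr) >= nchar(long_utr)) {
    return(tibble(divergent_seq = "", divergent_length = 0L, ok = FALSE))
  }
  if (!endsWith(long_utr, short_utr)) {
    return(tibble(divergent_seq = NA_character_, divergent_length = NA_integer_,
                  ok = FALSE))
  }
  d <- substr(long_utr, 1, nchar(long_utr) - nchar(short_utr))
  tibble(divergent_seq = d, divergent_length = nchar(d), ok = nchar(d) > 0L)
}
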