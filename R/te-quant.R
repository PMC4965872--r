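# Translational-efficiency quantification from fraction-resolved tag counts.
#
# The seven sucrose-gradient fractions carry characteristic mean ribosome
# loads; weighting the (normalized) tag counts of an isoform by those loads
# gives the average number of ribosomes per mRNA, and dividing by ORF length
# the translational efficiency TE = R / l / T.

#' Mean ribosome load per gradient fraction
#'
#' Returns the fixed per-fraction ribosome weights used in all TE
#' computations: free RNP and 40S/60S fractions carry 0 ribosomes, the 80S
#' monosome fraction 1, and the four polysome fractions 2.5, 4.5, 7.5 and 12
#' ribosomes per mRNA on average.
#'
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' ribosome_weights()
ribosome_weights <- function() {
  c(free = 0, sub40_60 = 0, mono80 = 1,
    poly2_3 = 2.5, poly4_5 = 4.5, poly6_9 = 7.5, poly10p = 12)
}

#' Across-fraction normalization factors from spike-in cluster counts
#'
#' Spike-in RNA from another species is added in equal amounts to every
#' fraction, so its cluster counts measure per-fraction library distortions.
#' Spike clusters are kept only if they have strictly more than `min_tags`
#' tags in every fraction of every replicate; the per-fraction factor is the
#' upper quartile of the qualifying cluster counts. Factors are rescaled by
#' their within-replicate geometric mean so that normalization preserves the
#' overall count scale (TE ratios are scale-free either way).
#'
#' @param spike_counts Tibble with columns `cluster`, `replicate`, `fraction`
#'   (1-7) and `count`.
#' @param min_tags Strict lower bound on tags per fraction for a spike
#'   cluster to qualify (default 10, i.e. clusters need > 10 tags).
#' @param prob Quantile used as the factor (default 0.75, the upper quartile).
#' @return Tibble with columns `replicate`, `fraction`, `factor` (raw upper
#'   quartile) and `size_factor` (geometric-mean-rescaled; divide raw counts
#'   by `size_factor` to normalize).
#' @export
spike_factors <- function(spike_counts, min_tags = 10, prob = 0.75) {
  stopifnot(all(c("cluster", "replicate", "fraction", "count") %in% names(spike_counts)))
  n_rep <- dplyr::n_distinct(spike_counts$replicate)
  qualifying <- spike_counts |>
    group_by(.data$cluster) |>
    filter(dplyr::n() == 7L * n_rep, all(.data$count > min_tags)) |>
    ungroup()
  if (nrow(qualifying) == 0L) {
    abort(paste0(
      "No spike-in cluster has > ", min_tags, " tags in every fraction of ",
      "every replicate. Lower `min_tags` explicitly if your spike-in ",
      "coverage is shallow."
    ))
  }
  qualifying |>
    group_by(.data$replicate, .data$fraction) |>
    summarise(factor = stats::quantile(.data$count, prob, names = FALSE),
              .groups = "drop_last") |>
    mutate(size_factor = .data$factor / geomean(.data$factor)) |>
    ungroup()
}

#' Normalize per-fraction counts by spike-in size factors
#'
#' @param counts Tibble with columns `replicate`, `fraction` and `count`
#'   (additional columns are carried through).
#' @param factors Output of [spike_factors()].
#' @return `counts` with a `norm_count` column (`count / size_factor`).
#' @export
normalize_counts <- function(counts, factors) {
  counts |>
    left_join(select(factors, "replicate", "fraction", "size_factor"),
              by = c("replicate", "fraction")) |>
    mutate(norm_count = .data$count / .data$size_factor) |>
    select(-"size_factor")
}

#' Isoform translational efficiency from a 7-fraction count vector
#'
#' Computes total abundance `T = sum(C_j)`, ribosome total
#' `R = sum(r_j * C_j)`, mean ribosomes per mRNA `R/T` and
#' `TE = R / orf_length / T` for one isoform.
#'
#' @param counts Numeric length-7 vector of (normalized) tag counts, ordered
#'   by fraction.
#' @param orf_length ORF length in nt (CDS including the stop codon).
#' @return One-row tibble with columns `total`, `ribosomes`,
#'   `ribosomes_per_mrna` and `te`. If `total` is 0 the isoform is
#'   unquantifiable and the load/TE columns are `NA` (with a warning).
#' @export
#' @examples
#' isoform_te(c(0, 0, 0, 0, 0, 0, 10), orf_length = 100)  # TE = 0.12
isoform_te <- function(counts, orf_length) {
  assert_counts7(counts)
  if (!is.numeric(orf_length) || length(orf_length) != 1L || orf_length <= 0) {
    abort("`orf_length` must be a single positive number (nt).")
  }
  total <- sum(counts)
  if (total == 0) {
    warn("all-zero count vector: isoform is unquantifiable (TE set to NA)")
    return(tibble(total = 0, ribosomes = 0,
                  ribosomes_per_mrna = NA_real_, te = NA_real_))
  }
  ribo <- sum(ribosome_weights() * counts)
  tibble(total = total, ribosomes = ribo,
         ribosomes_per_mrna = ribo / total,
         te = ribo / orf_length / total)
}

#' Gene-level translational efficiency
#'
#' Counts of all TSS isoforms of a gene are summed per fraction and TE is
#' computed on the pooled vector with the gene's ORF length.
#'
#' @param counts_list List of length-7 count vectors, one per isoform.
#' @param orf_length ORF length in nt.
#' @return One-row tibble as in [isoform_te()].
#' @export
gene_te <- function(counts_list, orf_length) {
  if (length(counts_list) == 0L) abort("no isoforms supplied")
  pooled <- Reduce(`+`, lapply(counts_list, assert_counts7))
  isoform_te(pooled, orf_length)
}

#' Leave-one-fraction-out translational efficiency
#'
#' Recomputes TE after dropping one of the seven fractions (ribosome weights
#' of the remaining fractions unchanged), used to check that no single
#' fraction dominates a TE estimate.
#'
#' @inheritParams isoform_te
#' @param leave Fraction index (1-7) to leave out.
#' @return One-row tibble as in [isoform_te()] plus a `left_out` column.
#' @export
leave_one_fraction_out <- function(counts, orf_length, leave) {
  assert_counts7(counts)
  if (!leave %in% FRACTION_IDS) abort("`leave` must be a fraction index in 1..7")
  kept <- counts
  kept[leave] <- 0
  total <- sum(kept)
  if (total == 0) {
    warn("remaining fractions have zero counts: isoform dropped under LOFO")
    return(tibble(total = 0, ribosomes = 0, ribosomes_per_mrna = NA_real_,
                  te = NA_real_, left_out = as.integer(leave)))
  }
  ribo <- sum(ribosome_weights() * kept)
  tibble(total = total, ribosomes = ribo, ribosomes_per_mrna = ribo / total,
         te = ribo / orf_length / total, left_out = as.integer(leave))
}

#' Monosome-to-polysome abundance ratio
#'
#' Ratio of the 80S monosome fraction count to the summed polysome fraction
#' counts, `C_3 / (C_4 + C_5 + C_6 + C_7)`.
#'
#' @inheritParams isoform_te
#' @return A single number, or `NA` (with a warning) when the polysome sum
#'   is zero.
#' @export
monosome_polysome_ratio <- function(counts) {
  assert_counts7(counts)
  denom <- sum(counts[4:7])
  if (denom == 0) {
    warn("zero polysome counts: monosome/polysome ratio undefined")
    return(NA_real_)
  }
  counts[3] / denom
}

#' Quantify TE for a table of isoforms
#'
#' Tidy driver over [isoform_te()]: takes long-format counts and returns one
#' row per isoform per replicate.
#'
#' @param counts Tibble with columns `gene`, `isoform`, `replicate`,
#'   `fraction`, and a count column (`norm_count` if present, else `count`).
#' @param orf_lengths Tibble with columns `gene` and `orf_length`.
#' @return Tibble with per-isoform `total`, `ribosomes`,
#'   `ribosomes_per_mrna`, `te`; unquantifiable isoforms (zero totals) are
#'   dropped with a message.
#' @export
te_quantify <- function(counts, orf_lengths) {
  val <- if ("norm_count" %in% names(counts)) "norm_count" else "count"
  wide <- counts |>
    group_by(.data$gene, .data$isoform, .data$replicate, .data$fraction) |>
    summarise(count = sum(.data[[val]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "count",
                       names_prefix = "f", values_fill = 0)
  for (j in FRACTION_IDS) {
    nm <- paste0("f", j)
    if (!nm %in% names(wide)) wide[[nm]] <- 0
  }
  cmat <- as.matrix(wide[paste0("f", FRACTION_IDS)])
  wide <- left_join(wide, orf_lengths, by = "gene")
  if (anyNA(wide$orf_length)) abort("missing ORF length for some genes")
  r <- ribosome_weights()
  total <- rowSums(cmat)
  ribo <- as.numeric(cmat %*% r)
  out <- wide |>
    select("gene", "isoform", "replicate", "orf_length") |>
    mutate(total = total, ribosomes = ribo,
           ribosomes_per_mrna = ribo / total,
           te = ribo / .data$orf_length / total)
  dropped <- sum(out$total == 0)
  if (dropped > 0) {
    inform(sprintf("dropping %d isoform/replicate rows with zero total counts", dropped))
    out <- filter(out, .data$total > 0)
  }
  out
}
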