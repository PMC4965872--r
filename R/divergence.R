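# Bootstrap testing of TE divergence between alternative TSS isoform pairs.
#
# Each bootstrap replicate resamples each fraction's tags at the original
# sequencing depth. For per-cluster counts this is exactly a multinomial
# draw per fraction over the categories {cluster A, cluster B, all other
# tags} with probabilities proportional to the observed counts, which is
# what is implemented; the log2 TE fold change is then recomputed on the
# resampled counts. The bootstrap mean and standard deviation summarise the
# B values; significance comes from the Z score mu/sigma against a standard
# normal, BH-adjusted across pairs within each replicate.

#' Bootstrap the log2 TE fold change of one isoform pair
#'
#' @param counts_a,counts_b Raw length-7 fraction count vectors of the two
#'   clusters (distal/longer isoform first by convention).
#' @param fraction_totals Per-fraction sequencing depths to resample at;
#'   defaults to `counts_a + counts_b` (no other tags).
#' @param orf_length_a,orf_length_b ORF lengths (enter the fold change as a
#'   constant offset; default 1).
#' @param size_factors Optional length-7 spike-in size factors; resampled
#'   counts are re-normalized inside every draw.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: plug-in `log2fc`, bootstrap `boot_mean`,
#'   `boot_sd`, and `n_dropped` (draws with zero resampled totals or
#'   non-finite fold changes, excluded from the summaries).
#' @export
bootstrap_pair <- function(counts_a, counts_b, fraction_totals = NULL,
                           orf_length_a = 1, orf_length_b = 1,
                           size_factors = NULL, B = 1000, seed = NULL) {
  assert_counts7(counts_a, "counts_a"); assert_counts7(counts_b, "counts_b")
  if (B < 2) abort("`B` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  tot <- fraction_totals %||% (counts_a + counts_b)
  assert_counts7(tot, "fraction_totals")
  if (any(tot < counts_a + counts_b)) {
    abort("`fraction_totals` must be at least counts_a + counts_b in every fraction")
  }
  sf <- size_factors %||% rep(1, 7)
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    abort("both clusters need nonzero totals for a TE fold change")
  }
  A <- matrix(0, 7, B); Bm <- matrix(0, 7, B)
  for (j in FRACTION_IDS) {
    if (tot[j] == 0) next
    pr <- c(counts_a[j], counts_b[j], tot[j] - counts_a[j] - counts_b[j]) / tot[j]
    m <- rmultinom(B, tot[j], pr)
    A[j, ] <- m[1, ]; Bm[j, ] <- m[2, ]
  }
  A <- A / sf; Bm <- Bm / sf
  r <- ribosome_weights()
  te_a <- colSums(A * r) / colSums(A) / orf_length_a
  te_b <- colSums(Bm * r) / colSums(Bm) / orf_length_b
  v <- log2(te_a / te_b)
  ok <- is.finite(v)
  plug <- {
    na <- counts_a / sf; nb <- counts_b / sf
    log2((sum(na * r) / sum(na) / orf_length_a) /
           (sum(nb * r) / sum(nb) / orf_length_b))
  }
  tibble(log2fc = plug,
         boot_mean = mean(v[ok]), boot_sd = sd(v[ok]),
         n_dropped = sum(!ok))
}

#' Two-sided normal p-value from a bootstrap Z score
#'
#' `p = 2 * (1 - Phi(|mu/sigma|))`; a zero standard deviation gives p = 0
#' for a nonzero mean and p = 1 otherwise.
#'
#' @param mu,sigma Bootstrap means and standard deviations (vectorized).
#' @return p-values in `[0, 1]`.
#' @export
z_pvalue <- function(mu, sigma) {
  if (any(sigma < 0, na.rm = TRUE)) abort("`sigma` must be non-negative")
  p <- 2 * pnorm(-abs(mu / sigma))
  p[sigma == 0 & mu != 0] <- 0
  p[sigma == 0 & mu == 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Step-up adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test TE divergence for all isoform pairs of a study
#'
#' Runs [bootstrap_pair()] for every within-gene isoform pair in every
#' replicate, converts bootstrap summaries to Z-score p-values, BH-adjusts
#' within replicate, and applies the dual-replicate significance rule.
#' Isoforms are ordered so that the distal (longer-5'UTR) isoform is the
#' fold-change numerator.
#'
#' @param counts Long tibble of raw cluster counts: `gene`, `isoform`,
#'   `replicate`, `fraction`, `count`, plus a per-isoform `utr_length`
#'   column (used to order pairs) and optionally `orf_length` per gene.
#' @param orf_lengths Tibble `gene`, `orf_length`.
#' @param size_factors Optional [spike_factors()] output.
#' @param B Bootstrap replicates per pair and replicate.
#' @param p_thresh,fc_thresh Significance thresholds (defaults: BH-adjusted
#'   p < 0.01 and fold change > 1.5 in both replicates, same direction).
#' @param seed Integer seed (a single RNG stream drives all pairs).
#' @return Tibble with one row per pair: per-replicate `log2fc_repK`,
#'   `boot_mean_repK`, `boot_sd_repK`, `p_repK`, `padj_repK`, plus
#'   `significant` and `direction` (`"longer_lower"`/`"longer_higher"`).
#' @export
te_divergence_test <- function(counts, orf_lengths, size_factors = NULL,
                               B = 1000, p_thresh = 0.01, fc_thresh = 1.5,
                               seed = 1L) {
  set.seed(seed)
  val <- "count"
  wide <- counts |>
    group_by(.data$gene, .data$isoform, .data$utr_length, .data$replicate,
             .data$fraction) |>
    summarise(count = sum(.data[[val]]), .groups = "drop") |>
    pivot_wider(names_from = "fraction", values_from = "count",
                names_prefix = "f", values_fill = 0)
  for (j in FRACTION_IDS) {
    nm <- paste0("f", j)
    if (!nm %in% names(wide)) wide[[nm]] <- 0
  }
  reps <- sort(unique(wide$replicate))
  rows <- list()
  for (g in unique(wide$gene)) {
    iso <- wide |> filter(.data$gene == g) |> distinct(.data$isoform, .data$utr_length)
    iso <- arrange(iso, dplyr::desc(.data$utr_length))
    if (nrow(iso) < 2L) next
    cmb <- utils::combn(iso$isoform, 2)
    ol <- orf_lengths$orf_length[match(g, orf_lengths$gene)]
    for (ci in seq_len(ncol(cmb))) {
      distal <- cmb[1, ci]; proximal <- cmb[2, ci]
      pr <- list(gene = g, distal = distal, proximal = proximal,
                 delta_utr_length =
                   iso$utr_length[iso$isoform == distal] -
                   iso$utr_length[iso$isoform == proximal])
      ok <- TRUE
      for (r in reps) {
        ca <- wide |> filter(.data$isoform == distal, .data$replicate == r)
        cb <- wide |> filter(.data$isoform == proximal, .data$replicate == r)
        if (nrow(ca) == 0L || nrow(cb) == 0L) { ok <- FALSE; break }
        va <- as.numeric(ca[paste0("f", FRACTION_IDS)])
        vb <- as.numeric(cb[paste0("f", FRACTION_IDS)])
        if (sum(va) == 0 || sum(vb) == 0) { ok <- FALSE; break }
        sf <- if (!is.null(size_factors)) {
          sfr <- filter(size_factors, .data$replicate == r) |> arrange(.data$fraction)
          sfr$size_factor
        } else NULL
        bt <- bootstrap_pair(va, vb, orf_length_a = ol, orf_length_b = ol,
                             size_factors = sf, B = B)
        pr[[paste0("log2fc_rep", r)]] <- bt$log2fc
        pr[[paste0("boot_mean_rep", r)]] <- bt$boot_mean
        pr[[paste0("boot_sd_rep", r)]] <- bt$boot_sd
        pr[[paste0("n_dropped_rep", r)]] <- bt$n_dropped
      }
      if (ok) rows[[length(rows) + 1L]] <- as_tibble(pr)
    }
  }
  if (!length(rows)) {
    abort("no testable isoform pairs (need >= 2 quantified isoforms per gene in every replicate)")
  }
  out <- list_rbind(rows)
  for (r in reps) {
    mu <- out[[paste0("boot_mean_rep", r)]]
    sg <- out[[paste0("boot_sd_rep", r)]]
    out[[paste0("p_rep", r)]] <- z_pvalue(mu, sg)
    out[[paste0("padj_rep", r)]] <- bh_adjust(out[[paste0("p_rep", r)]])
  }
  call_significant(out, p_thresh = p_thresh, fc_thresh = fc_thresh,
                   replicates = reps)
}

#' Bootstrap-test a table of pre-assembled pair count vectors
#'
#' Driver for pair-level simulations (see [simulate_pair_counts()]): runs
#' [bootstrap_pair()] on every row, computes Z-score p-values, BH-adjusts
#' within replicate and applies the dual-replicate rule.
#'
#' @param pair_counts Tibble with columns `pair`, `replicate`, list-columns
#'   `counts_a`/`counts_b` and `len_a`/`len_b`.
#' @inheritParams te_divergence_test
#' @return One row per pair with the same columns as
#'   [te_divergence_test()].
#' @export
pair_counts_test <- function(pair_counts, B = 1000, p_thresh = 0.01,
                             fc_thresh = 1.5, seed = 1L) {
  set.seed(seed)
  res <- pair_counts |>
    mutate(bt = pmap(list(.data$counts_a, .data$counts_b, .data$len_a,
                          .data$len_b),
                     function(a, b, la, lb)
                       bootstrap_pair(a, b, orf_length_a = la,
                                      orf_length_b = lb, B = B))) |>
    select("pair", "replicate", "bt") |>
    unnest("bt") |>
    group_by(.data$replicate) |>
    mutate(p = z_pvalue(.data$boot_mean, .data$boot_sd),
           padj = bh_adjust(.data$p)) |>
    ungroup() |>
    pivot_wider(names_from = "replicate",
                values_from = c("log2fc", "boot_mean", "boot_sd",
                                "n_dropped", "p", "padj"),
                names_glue = "{.value}_rep{replicate}")
  call_significant(res, p_thresh = p_thresh, fc_thresh = fc_thresh)
}

#' Apply the dual-replicate significance rule to pair tests
#'
#' A pair is significant when the BH-adjusted p-value is below `p_thresh`
#' and the absolute TE fold change exceeds `fc_thresh` in every replicate,
#' with the fold change pointing the same way in all replicates.
#'
#' @param pairs Pair tibble with `log2fc_repK` and `padj_repK` columns.
#' @param p_thresh Adjusted p-value threshold (default 0.01).
#' @param fc_thresh Fold-change threshold on the natural scale (default 1.5).
#' @param replicates Replicate ids (default: inferred from column names).
#' @return `pairs` with `significant` and `direction` columns.
#' @export
call_significant <- function(pairs, p_thresh = 0.01, fc_thresh = 1.5,
                             replicates = NULL) {
  reps <- replicates %||%
    as.integer(sub("^padj_rep", "", grep("^padj_rep", names(pairs), value = TRUE)))
  if (!length(reps)) abort("no `padj_rep*` columns found")
  fc <- as.matrix(pairs[paste0("log2fc_rep", reps)])
  padj <- as.matrix(pairs[paste0("padj_rep", reps)])
  pass_fc <- rowSums(abs(fc) > log2(fc_thresh)) == length(reps)
  pass_p <- rowSums(padj < p_thresh) == length(reps)
  concord <- apply(sign(fc), 1, function(s) length(unique(s[s != 0])) == 1 && all(s != 0))
  pairs |>
    mutate(significant = pass_fc & pass_p & concord,
           direction = dplyr::case_when(
             !(pass_fc & pass_p & concord) ~ NA_character_,
             rowMeans(fc) < 0 ~ "longer_lower",
             TRUE ~ "longer_higher"))
}

#' Label-permutation false discovery rate for the dual-replicate rule
#'
#' The pairing between replicate-1 and replicate-2 results is shuffled
#' `n_shuffles` times, breaking the cross-replicate concordance that real
#' biology produces; the FDR is the mean number of shuffled pairs passing
#' the full significance rule (|FC| > `fc_thresh`, adjusted p < `p_thresh`,
#' same direction in both pseudo-replicates) divided by the number of real
#' pairs passing it.
#'
#' @param pairs Pair tibble from [te_divergence_test()] (two replicates).
#' @param fc_thresh,p_thresh Thresholds x and y of the rule.
#' @param n_shuffles Number of label shuffles (default 100).
#' @param seed Integer seed.
#' @return A list with `fdr`, `n_real`, and `fp` (mean shuffled count).
#' @export
permutation_fdr <- function(pairs, fc_thresh = 1.5, p_thresh = 0.01,
                            n_shuffles = 100, seed = 1L) {
  if (nrow(pairs) < 2L) abort("need at least 2 pairs")
  if (n_shuffles < 1L) abort("`n_shuffles` must be positive")
  set.seed(seed)
  lfc <- log2(fc_thresh)
  pass1 <- abs(pairs$log2fc_rep1) > lfc & pairs$padj_rep1 < p_thresh
  pass2 <- abs(pairs$log2fc_rep2) > lfc & pairs$padj_rep2 < p_thresh
  s1 <- sign(pairs$log2fc_rep1); s2 <- sign(pairs$log2fc_rep2)
  n_real <- sum(pass1 & pass2 & s1 == s2 & s1 != 0)
  fp <- mean(vapply(seq_len(n_shuffles), function(i) {
    idx <- sample.int(nrow(pairs))
    sum(pass1 & pass2[idx] & s1 == s2[idx] & s1 != 0)
  }, numeric(1)))
  if (n_real == 0L) {
    warn("no real pairs pass the thresholds: FDR undefined")
    return(list(fdr = NA_real_, n_real = 0L, fp = fp))
  }
  list(fdr = fp / n_real, n_real = n_real, fp = fp)
}
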