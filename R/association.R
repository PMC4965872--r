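# Group-level statistics linking 5'UTR features to TE divergence.
#
# Because 5'UTR length difference is itself associated with TE divergence,
# every two-group comparison is preceded by matching of the length-difference
# distributions (random down-sampling within length-difference bins).

#' Match 5'UTR length-difference distributions between two groups
#'
#' Bins the `delta_length` column of both groups on a common grid and
#' randomly down-samples within each bin to the per-bin minimum; bins empty
#' in either group are dropped from both.
#'
#' @param group_a,group_b Tibbles with a `delta_length` column.
#' @param bin_width Bin width in nt (default 100).
#' @param seed Optional integer seed for the down-sampling.
#' @return List with elements `a` and `b` (matched subsets).
#' @export
match_length_diff <- function(group_a, group_b, bin_width = 100, seed = NULL) {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) abort("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  top <- max(group_a$delta_length, group_b$delta_length)
  breaks <- seq(0, top + bin_width, by = bin_width)
  ba <- findInterval(group_a$delta_length, breaks, rightmost.closed = TRUE)
  bb <- findInterval(group_b$delta_length, breaks, rightmost.closed = TRUE)
  common <- intersect(unique(ba), unique(bb))
  if (!length(common)) abort("no length-difference bin is occupied in both groups")
  take <- function(g, bins) {
    idx <- unlist(lapply(common, function(k) {
      ia <- which(bins == k)
      n <- min(sum(ba == k), sum(bb == k))
      if (length(ia) > n) sample(ia, n) else ia
    }))
    g[sort(idx), , drop = FALSE]
  }
  list(a = take(group_a, ba), b = take(group_b, bb))
}

#' Mann-Whitney comparison of TE divergence between two groups
#'
#' Rank-sum test on the per-pair log2 TE fold changes; exact null for small
#' tie-free groups (n <= 20 each), normal approximation with tie correction
#' otherwise.
#'
#' @param x,y Numeric vectors (e.g. log2 fold changes of matched groups).
#' @return One-row tibble: `statistic` (U), `p_value`, `n_x`, `n_y`,
#'   `median_x`, `median_y`.
#' @export
group_compare <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) abort("each group needs at least 3 values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_x = length(x), n_y = length(y),
         median_x = median(x), median_y = median(y))
}

#' TE divergence as a function of uORF dose in the divergent region
#'
#' Stratifies pairs by the number of uORFs unique to the longer isoform
#' (0, 1, 2, >= 3), reports the median log2 TE fold change per stratum,
#' pairwise Mann-Whitney p-values between strata, and whether the medians
#' decrease monotonically with uORF count.
#'
#' @param pairs Tibble with `n_uorf_div` (uORFs in the divergent region) and
#'   `log2fc` columns.
#' @return List with `strata` (tibble: stratum, n, median_log2fc),
#'   `tests` (tibble of pairwise comparisons) and `monotone_decreasing`.
#' @export
uorf_dose_response <- function(pairs) {
  d <- pairs |>
    mutate(stratum = cut(.data$n_uorf_div, c(-Inf, 0, 1, 2, Inf),
                         labels = c("0", "1", "2", ">=3")))
  lv <- levels(droplevels(d$stratum))
  if (length(lv) < 2L) abort("need at least 2 occupied uORF strata")
  strata <- d |>
    group_by(.data$stratum) |>
    summarise(n = dplyr::n(), median_log2fc = median(.data$log2fc),
              .groups = "drop") |>
    filter(.data$n > 0)
  cmb <- utils::combn(lv, 2)
  tests <- map(seq_len(ncol(cmb)), function(i) {
    xa <- d$log2fc[d$stratum == cmb[1, i]]
    xb <- d$log2fc[d$stratum == cmb[2, i]]
    if (length(xa) < 3L || length(xb) < 3L) return(NULL)
    group_compare(xa, xb) |>
      mutate(stratum_a = cmb[1, i], stratum_b = cmb[2, i], .before = 1)
  }) |> purrr::compact() |> list_rbind()
  list(strata = strata, tests = tests,
       monotone_decreasing = !is.unsorted(rev(strata$median_log2fc)))
}

#' Fisher enrichment of a feature in longer-isoform-lower pairs
#'
#' Exact test on the 2x2 table of {divergent-region feature present/absent}
#' x {longer isoform translated lower / remaining pairs}.
#'
#' @param pairs Tibble with a logical feature column and a `direction`
#'   column (`"longer_lower"` vs anything else).
#' @param feature Name of the logical feature column.
#' @return One-row tibble: `odds_ratio`, `p_value`, the four cell counts and
#'   the two presence percentages.
#' @export
fisher_direction_enrichment <- function(pairs, feature) {
  present <- as.logical(pairs[[feature]])
  lower <- pairs$direction == "longer_lower" & !is.na(pairs$direction)
  tab <- table(factor(present, c(TRUE, FALSE)), factor(lower, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 margin: feature or direction does not vary")
  }
  ft <- fisher.test(tab)
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         present_lower = tab[1, 1], present_other = tab[1, 2],
         absent_lower = tab[2, 1], absent_other = tab[2, 2],
         pct_present_lower = 100 * tab[1, 1] / sum(tab[, 1]),
         pct_present_other = 100 * tab[1, 2] / sum(tab[, 2]))
}

#' Scan all AUG-free hexamers for association with TE divergence
#'
#' For each hexamer occurring in the divergent region of at least
#' `min_count` (and at most n - `min_count`) pairs, compares the log2 TE
#' fold changes of pairs containing vs lacking it (after length-difference
#' matching) by Mann-Whitney, BH-adjusts across tested hexamers, and
#' reports the direction as the sign of the median difference.
#'
#' @param pairs Tibble with `log2fc`, `delta_length` and `divergent_seq`
#'   columns (one row per pair).
#' @param min_count Presence/absence floor for a hexamer to be testable.
#' @param bin_width Length-matching bin width (nt).
#' @param seed Integer seed for the matching down-samples.
#' @return Tibble: `hexamer`, `n_present`, `p_value`, `padj`, `direction`
#'   (-1 = presence associated with lower TE of the longer isoform),
#'   sorted by `padj`.
#' @export
hexamer_scan <- function(pairs, min_count = 3, bin_width = 100, seed = 1L) {
  if (nrow(pairs) < 20L) abort("need at least 20 pairs for the hexamer scan")
  set.seed(seed)
  hm <- hexamer_matrix(pairs$divergent_seq) > 0
  n <- nrow(pairs)
  testable <- which(colSums(hm) >= min_count & colSums(hm) <= n - min_count)
  if (!length(testable)) {
    return(tibble(hexamer = character(), n_present = integer(),
                  p_value = double(), padj = double(), direction = double()))
  }
  res <- map(testable, function(k) {
    pres <- hm[, k]
    m <- tryCatch(
      match_length_diff(pairs[pres, ], pairs[!pres, ], bin_width = bin_width),
      error = function(e) NULL)
    if (is.null(m) || nrow(m$a) < min_count || nrow(m$b) < min_count) return(NULL)
    gc <- group_compare(m$a$log2fc, m$b$log2fc)
    tibble(hexamer = colnames(hm)[k], n_present = sum(pres),
           p_value = gc$p_value,
           direction = sign(gc$median_x - gc$median_y))
  }) |> purrr::compact() |> list_rbind()
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(hexamer = character(), n_present = integer(),
                  p_value = double(), padj = double(), direction = double()))
  }
  res |>
    mutate(padj = bh_adjust(.data$p_value)) |>
    arrange(.data$padj, .data$p_value) |>
    select("hexamer", "n_present", "p_value", "padj", "direction")
}

#' Compare TOP-isoform TE ratios against random-orientation controls
#'
#' For genes with exactly one TOP isoform and at least one non-TOP isoform,
#' the TE fold change log2(TE_TOP / TE_nonTOP) is compared by Mann-Whitney
#' against control genes (no TOP isoform) whose numerator/denominator
#' orientation is assigned at random.
#'
#' @param iso_te Tibble with `gene`, `isoform`, `te`, `total` and a logical
#'   `has_top` column (one row per isoform; replicate-averaged TE).
#' @param seed Integer seed for the control orientation.
#' @return List with `top_log2fc`, `control_log2fc`, and `test` (a
#'   [group_compare()] row).
#' @export
top_comparison <- function(iso_te, seed = 1L) {
  set.seed(seed)
  by_gene <- iso_te |> group_by(.data$gene) |>
    summarise(n_top = sum(.data$has_top), n_iso = dplyr::n(), .groups = "drop")
  top_genes <- by_gene$gene[by_gene$n_top == 1 & by_gene$n_iso >= 2 &
                              by_gene$n_top < by_gene$n_iso]
  ctrl_genes <- by_gene$gene[by_gene$n_top == 0 & by_gene$n_iso >= 2]
  if (length(top_genes) < 3L) abort("need at least 3 genes with one TOP and one non-TOP isoform")
  top_fc <- vapply(top_genes, function(g) {
    d <- iso_te[iso_te$gene == g, ]
    num <- d$te[d$has_top][1]
    den <- d$te[!d$has_top][which.max(d$total[!d$has_top])]
    log2(num / den)
  }, numeric(1))
  ctrl_fc <- vapply(ctrl_genes, function(g) {
    d <- iso_te[iso_te$gene == g, ]
    pick <- sample(nrow(d), 2)
    log2(d$te[pick[1]] / d$te[pick[2]])
  }, numeric(1))
  top_fc <- top_fc[is.finite(top_fc)]; ctrl_fc <- ctrl_fc[is.finite(ctrl_fc)]
  list(top_log2fc = top_fc, control_log2fc = ctrl_fc,
       test = group_compare(top_fc, ctrl_fc))
}
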