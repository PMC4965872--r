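# TSS cluster calling from pooled 5'-end tag tracks.
#
# Positions with tags strictly above the local background are merged into
# clusters when separated by at most 20 nt; the background is the maximum of
# (i) the local expectation (mean tag coverage over a 500-nt window centered
# at the position) and (ii) the depth-normalized RNA-seq coverage over a
# strand-oriented window from 500 nt upstream to 1,500 nt downstream. Wide
# clusters are refined by stepwise raising the background; clusters must
# additionally beat a one-sided Poisson test against the summed local
# background, which is what suppresses calls on featureless background.

#' Pool a tag table over replicates and fractions
#'
#' @param tags Tibble with columns `chrom`, `pos`, `strand`, `count`
#'   (and optionally `replicate`, `fraction`).
#' @return Tibble with one row per (chrom, strand, pos) and pooled `count`.
#' @export
pool_tags <- function(tags) {
  tags |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pos)
}

# windowed sum of sparse counts: total count at positions in [lo, hi)
window_sum <- function(pos, cs, lo, hi) {
  # pos sorted ascending; cs = cumsum(count)
  i_hi <- findInterval(hi - 1, pos)       # last index with pos <= hi-1
  i_lo <- findInterval(lo - 1, pos)       # last index with pos <  lo
  cs0 <- c(0, cs)
  cs0[i_hi + 1L] - cs0[i_lo + 1L]
}

# mean of a step-function coverage over [lo, hi)
coverage_mean <- function(cov_start, cov_end, cov_depth, lo, hi) {
  if (length(cov_start) == 0L) return(rep(0, length(lo)))
  vapply(seq_along(lo), function(i) {
    if (hi[i] <= lo[i]) return(0)
    a <- pmax(cov_start, lo[i]); b <- pmin(cov_end, hi[i])
    w <- pmax(b - a, 0)
    sum(w * cov_depth) / (hi[i] - lo[i])
  }, numeric(1))
}

#' Local background rate at genomic positions
#'
#' The background at a position is the larger of the local tag expectation
#' (mean pooled tag coverage in the 500-nt window centered on the position)
#' and the depth-normalized RNA-seq coverage averaged over a strand-oriented
#' window from 500 nt upstream to 1,500 nt downstream.
#'
#' @param track Pooled tag tibble for one (chrom, strand):
#'   columns `pos`, `count`, sorted by `pos`.
#' @param pos Positions at which to evaluate the background.
#' @param strand `"+"` or `"-"` (orients the expression window).
#' @param coverage Optional RNA-seq coverage tibble for the same contig:
#'   columns `start`, `end`, `depth`.
#' @param depth_norm Scalar multiplier applied to the RNA-seq coverage
#'   (sequencing-depth normalization), default 1.
#' @param local_window,expr_window Window sizes in nt (defaults 500 and
#'   500/1500 up/downstream).
#' @return Numeric background rate (tags per nt) per position.
#' @export
local_background <- function(track, pos, strand = "+", coverage = NULL,
                             depth_norm = 1, local_window = 500,
                             expr_window = c(500, 1500)) {
  if (nrow(track) == 0L) abort("empty tag track")
  p <- sort(track$pos)
  cs <- cumsum(track$count[order(track$pos)])
  half <- local_window %/% 2L
  # windows are clipped at the contig start (position 0)
  lo_l <- pmax(pos - half, 0)
  hi_l <- pos - half + local_window
  local_exp <- window_sum(p, cs, lo_l, hi_l) / (hi_l - lo_l)
  expr <- 0
  if (!is.null(coverage) && nrow(coverage) > 0L) {
    if (strand == "+") {
      lo <- pmax(pos - expr_window[1], 0); hi <- pos + expr_window[2]
    } else {
      lo <- pmax(pos - expr_window[2], 0); hi <- pos + expr_window[1] + 1
    }
    expr <- depth_norm * coverage_mean(coverage$start, coverage$end,
                                       coverage$depth, lo, hi)
  }
  pmax(local_exp, expr)
}

# group sorted positions into clusters with inter-position gaps <= merge_gap
gap_cluster <- function(pos, merge_gap) {
  if (length(pos) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) > merge_gap)))
}

summit_of <- function(pos, count, strand) {
  mx <- pos[count == max(count)]
  most5(mx, strand)
}

# refine one wide cluster by stepwise raising the per-position background
refine_positions <- function(pos, count, bg, merge_gap, max_width) {
  for (mult in c(1.5, 2, 2.5, 3)) {
    keep <- count > mult * bg
    if (!any(keep)) next
    grp <- gap_cluster(pos[keep], merge_gap)
    widths <- tapply(pos[keep], grp, function(x) max(x) - min(x) + 1L)
    if (all(widths <= max_width)) {
      return(list(pos = pos[keep], count = count[keep], bg = bg[keep],
                  grp = grp, flagged = FALSE))
    }
  }
  keep <- count > 3 * bg
  if (!any(keep)) keep <- count == max(count)  # degenerate: keep the summit
  grp <- gap_cluster(pos[keep], merge_gap)
  list(pos = pos[keep], count = count[keep], bg = bg[keep], grp = grp,
       flagged = TRUE)
}

#' Call TSS clusters from a tag table
#'
#' Pools tags (across fractions/replicates present in the input), computes
#' the local background at every tagged position, keeps positions strictly
#' above background, merges them into clusters (gap <= `merge_gap`), refines
#' clusters wider than `max_width` by raising the background in steps of
#' 0.5x up to 3x (clusters still too wide after 3x are emitted flagged), and
#' finally requires cluster tag totals to beat a one-sided Poisson test
#' against the summed background at `cluster_alpha`.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`, `count`, ...).
#' @param coverage Optional RNA-seq coverage tibble (`chrom`, `start`,
#'   `end`, `depth`).
#' @param merge_gap Maximum inter-position gap within a cluster (nt).
#' @param max_width Target maximum cluster width (nt).
#' @param cluster_alpha Significance level of the per-cluster Poisson filter.
#' @param depth_norm Depth normalization scalar for the RNA-seq coverage.
#' @param refine Apply stepwise refinement to wide clusters.
#' @return Tibble of clusters: `cluster`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `summit`, `pooled_count`, `n_positions`, `width`,
#'   `flagged`.
#' @export
call_tss_clusters <- function(tags, coverage = NULL, merge_gap = 20,
                              max_width = 100, cluster_alpha = 1e-5,
                              depth_norm = 1, refine = TRUE) {
  pooled <- pool_tags(tags)
  if (nrow(pooled) == 0L) {
    return(tibble(cluster = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), pooled_count = double(),
                  n_positions = integer(), width = integer(),
                  flagged = logical()))
  }
  out <- pooled |>
    group_by(.data$chrom, .data$strand) |>
    group_map(function(trk, key) {
      cov <- if (!is.null(coverage)) filter(coverage, .data$chrom == key$chrom) else NULL
      bg <- local_background(trk, trk$pos, strand = key$strand, coverage = cov,
                             depth_norm = depth_norm)
      keep <- trk$count > bg
      if (!any(keep)) return(NULL)
      pos <- trk$pos[keep]; cnt <- trk$count[keep]; bgk <- bg[keep]
      grp <- gap_cluster(pos, merge_gap)
      res <- list()
      for (gi in unique(grp)) {
        sel <- grp == gi
        pieces <- list(list(pos = pos[sel], count = cnt[sel], bg = bgk[sel],
                            grp = rep(1L, sum(sel)), flagged = FALSE))
        w <- max(pos[sel]) - min(pos[sel]) + 1L
        if (refine && w > max_width) {
          rp <- refine_positions(pos[sel], cnt[sel], bgk[sel], merge_gap, max_width)
          pieces <- list(rp)
        }
        for (pc in pieces) {
          for (sg in unique(pc$grp)) {
            s2 <- pc$grp == sg
            res[[length(res) + 1L]] <- tibble(
              chrom = key$chrom, strand = key$strand,
              start = min(pc$pos[s2]), end = max(pc$pos[s2]) + 1L,
              summit = summit_of(pc$pos[s2], pc$count[s2], key$strand),
              pooled_count = sum(pc$count[s2]),
              n_positions = sum(s2),
              mean_bg = mean(pc$bg[s2]),
              flagged = pc$flagged && (max(pc$pos[s2]) - min(pc$pos[s2]) + 1L) > max_width
            )
          }
        }
      }
      if (length(res)) list_rbind(res) else NULL
    }, .keep = FALSE) |>
    purrr::compact() |>
    list_rbind()
  if (nrow(out) == 0L) {
    return(tibble(cluster = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), pooled_count = double(),
                  n_positions = integer(), width = integer(),
                  flagged = logical()))
  }
  out <- out |>
    mutate(width = .data$end - .data$start,
           expected_bg = .data$mean_bg * .data$width,
           pois_p = ppois(.data$pooled_count - 1, .data$expected_bg,
                          lower.tail = FALSE)) |>
    filter(.data$pois_p <= cluster_alpha) |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    mutate(cluster = sprintf("cl%05d", dplyr::row_number())) |>
    select("cluster", "chrom", "strand", "start", "end", "summit",
           "pooled_count", "n_positions", "width", "flagged")
  out
}

#' Count tags per cluster per replicate and fraction
#'
#' @param clusters Cluster tibble from [call_tss_clusters()].
#' @param tags Raw tag tibble with `replicate` and `fraction` columns.
#' @return Long tibble: `cluster`, `replicate`, `fraction`, `count` (all
#'   cluster x replicate x fraction combinations, zero-filled).
#' @export
count_cluster_tags <- function(clusters, tags) {
  if (nrow(clusters) == 0L) {
    return(tibble(cluster = character(), replicate = integer(),
                  fraction = integer(), count = double()))
  }
  key <- paste(clusters$chrom, clusters$strand)
  hits <- map(unique(key), function(k) {
    cl <- clusters[key == k, ]
    tg <- tags[paste(tags$chrom, tags$strand) == k, ]
    if (nrow(tg) == 0L) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(tg$pos, width = 1L),
      IRanges::IRanges(cl$start, cl$end - 1L))
    if (length(ov) == 0L) return(NULL)
    tibble(cluster = cl$cluster[S4Vectors::subjectHits(ov)],
           replicate = tg$replicate[S4Vectors::queryHits(ov)],
           fraction = tg$fraction[S4Vectors::queryHits(ov)],
           count = tg$count[S4Vectors::queryHits(ov)])
  }) |> purrr::compact() |> list_rbind()
  reps <- sort(unique(tags$replicate))
  grid <- expand_grid(cluster = clusters$cluster, replicate = reps,
                      fraction = FRACTION_IDS)
  hits |>
    group_by(.data$cluster, .data$replicate, .data$fraction) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    right_join(grid, by = c("cluster", "replicate", "fraction")) |>
    mutate(count = tidyr::replace_na(.data$count, 0)) |>
    arrange(.data$cluster, .data$replicate, .data$fraction)
}

#' Assign clusters to genes and genomic region classes
#'
#' Classifies each cluster summit with precedence annotated-5'UTR > up-1kb >
#' CDS > 3'UTR > intergenic (strand-aware; intron classification applies
#' only when an exon table is provided). Only the first two classes (the
#' "gross 5'UTR": annotated TSS to most-3' start codon, plus 1 kb upstream
#' of the most-5' annotated TSS) feed the TE analysis.
#'
#' @param clusters Cluster tibble with `chrom`, `strand`, `summit`.
#' @param annotation Gene tibble with `gene`, `chrom`, `strand`, `ann_tss`,
#'   `start_codon`, `cds_lo`, `cds_hi`, `gene_lo`, `gene_hi`.
#' @param exons Optional exon tibble (`gene`, `start`, `end`) enabling the
#'   intron class.
#' @return `clusters` with `gene` and `region` columns appended.
#' @export
assign_region <- function(clusters, annotation, exons = NULL) {
  if (nrow(clusters) == 0L) {
    return(mutate(clusters, gene = character(0), region = character(0)))
  }
  regions <- purrr::pmap(annotation, function(gene, chrom, strand, ann_tss,
                                              start_codon, cds_lo, cds_hi,
                                              gene_lo, gene_hi, ...) {
    utr5 <- if (strand == "+") c(ann_tss, start_codon)
            else c(start_codon + 1L, ann_tss + 1L)
    up1k <- if (strand == "+") c(ann_tss - 1000L, ann_tss)
            else c(ann_tss + 1L, ann_tss + 1001L)
    utr3 <- if (strand == "+") c(cds_hi, gene_hi) else c(gene_lo, cds_lo)
    tibble(gene = gene, chrom = chrom, strand = strand,
           region = c("utr5", "up1kb", "cds", "utr3"),
           lo = c(utr5[1], up1k[1], cds_lo, utr3[1]),
           hi = c(utr5[2], up1k[2], cds_hi, utr3[2]))
  }) |>
    list_rbind() |>
    filter(.data$hi > .data$lo)
  prec <- c(utr5 = 1, up1kb = 2, cds = 3, intron = 4, utr3 = 5)
  assigned <- clusters |>
    left_join(regions, by = c("chrom", "strand"),
              relationship = "many-to-many") |>
    filter(.data$summit >= .data$lo, .data$summit < .data$hi) |>
    mutate(rank = prec[.data$region]) |>
    group_by(.data$cluster) |>
    slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("cluster", "gene", "region")
  out <- clusters |>
    left_join(assigned, by = "cluster") |>
    mutate(region = tidyr::replace_na(.data$region, "intergenic"))
  # intron reclassification: summit inside gene span but outside all exons
  if (!is.null(exons) && nrow(exons)) {
    in_exon <- function(g, s) {
      ex <- exons[exons$gene == g, ]
      any(s >= ex$start & s < ex$end)
    }
    idx <- which(out$region == "cds")
    for (i in idx) {
      if (!in_exon(out$gene[i], out$summit[i])) out$region[i] <- "intron"
    }
  }
  out
}
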