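# Reproducibility filtering across replicates via the irreproducible
# discovery rate (IDR).
#
# Cluster signals from the two replicates are rank-transformed to normal
# scores and modelled as a two-component bivariate normal mixture: a null
# component (standard normal, uncorrelated) for irreproducible clusters and
# a reproducible component with elevated mean and positive correlation. The
# local idr of a pair is its posterior null probability; the (global) IDR is
# the running mean of local idr over pairs sorted by increasing local idr.
# Because the input is rank-based, the result is invariant to monotone
# transformations of the signal.

#' Estimate irreproducible discovery rates for paired signals
#'
#' @param x,y Signal values (e.g. pooled tag counts) of the same clusters in
#'   replicates 1 and 2.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return Tibble with `idr_local` (posterior null probability) and `idr`
#'   (expected rate of irreproducible discoveries among pairs at or below
#'   this local idr), plus the fitted mixture parameters as attributes.
#' @export
est_idr <- function(x, y, max_iter = 100, tol = 1e-6) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (n < 10L) abort("fewer than 10 matched pairs: the mixture is unidentifiable; use the fallback filter")
  z1 <- qnorm(rank(x, ties.method = "average") / (n + 1))
  z2 <- qnorm(rank(y, ties.method = "average") / (n + 1))
  p <- 0.5; mu <- 1; s2 <- 1; rho <- 0.5
  ll_old <- -Inf
  dbvn <- function(z1, z2, mu, s2, rho) {
    d1 <- z1 - mu; d2 <- z2 - mu
    q <- (d1^2 - 2 * rho * d1 * d2 + d2^2) / (s2 * (1 - rho^2))
    exp(-q / 2) / (2 * pi * s2 * sqrt(1 - rho^2))
  }
  for (it in seq_len(max_iter)) {
    f1 <- dbvn(z1, z2, mu, s2, rho)
    f0 <- dbvn(z1, z2, 0, 1, 0)
    num <- p * f1
    den <- num + (1 - p) * f0
    g <- num / pmax(den, .Machine$double.xmin)
    sg <- sum(g)
    p <- min(max(mean(g), 0.01), 0.99)
    mu <- max(sum(g * (z1 + z2)) / (2 * sg), 0)
    d1 <- z1 - mu; d2 <- z2 - mu
    s2 <- max(sum(g * (d1^2 + d2^2)) / (2 * sg), 1e-4)
    rho <- min(max(sum(g * d1 * d2) / (s2 * sg), 0), 0.998)
    ll <- sum(log(pmax(den, .Machine$double.xmin)))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  idr_local <- 1 - g
  o <- order(idr_local)
  idr_global <- numeric(n)
  idr_global[o] <- cummean(idr_local[o])
  out <- tibble(idr_local = idr_local, idr = idr_global)
  attr(out, "params") <- c(p = p, mu = mu, sigma2 = s2, rho = rho)
  out
}

#' Match clusters between replicates and keep reproducible ones
#'
#' Clusters are matched across replicates by any strand-aware overlap
#' (1:1, resolved by the widest overlap); unmatched clusters are
#' irreproducible by definition. Matched pairs are scored either by the
#' copula-mixture IDR of their pooled tag counts (`mode = "idr"`, kept when
#' IDR <= `alpha`) or by a simple evidence fallback (`mode = "fallback"`,
#' kept when the summed pooled count reaches `min_pooled`).
#'
#' @param rep1,rep2 Cluster tibbles from [call_tss_clusters()].
#' @param alpha IDR threshold (default 0.05).
#' @param mode `"idr"` or `"fallback"`.
#' @param min_pooled Minimum combined pooled count in fallback mode.
#' @return Tibble of reproducible clusters with the union span of each
#'   matched pair, replicate-1 summit, per-replicate pooled counts, and the
#'   `idr` column (`NA` in fallback mode).
#' @export
idr_filter <- function(rep1, rep2, alpha = 0.05,
                       mode = c("idr", "fallback"), min_pooled = 10) {
  mode <- match.arg(mode)
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) {
    return(tibble(cluster = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), count_rep1 = double(),
                  count_rep2 = double(), idr = double()))
  }
  gr <- function(cl) GenomicRanges::GRanges(
    cl$chrom, IRanges::IRanges(cl$start + 1L, cl$end), strand = cl$strand)
  ov <- GenomicRanges::findOverlaps(gr(rep1), gr(rep2))
  if (length(ov) == 0L) {
    if (mode == "idr") abort("no clusters overlap between replicates")
    return(tibble(cluster = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), count_rep1 = double(),
                  count_rep2 = double(), idr = double()))
  }
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- pmin(rep1$end[q], rep2$end[s]) - pmax(rep1$start[q], rep2$start[s])
  pairs <- tibble(i = q, j = s, w = w) |>
    group_by(.data$i) |> slice_max(.data$w, n = 1, with_ties = FALSE) |>
    ungroup() |>
    group_by(.data$j) |> slice_max(.data$w, n = 1, with_ties = FALSE) |>
    ungroup()
  matched <- tibble(
    chrom = rep1$chrom[pairs$i], strand = rep1$strand[pairs$i],
    start = pmin(rep1$start[pairs$i], rep2$start[pairs$j]),
    end = pmax(rep1$end[pairs$i], rep2$end[pairs$j]),
    summit = rep1$summit[pairs$i],
    count_rep1 = rep1$pooled_count[pairs$i],
    count_rep2 = rep2$pooled_count[pairs$j])
  if (mode == "idr") {
    if (nrow(matched) < 10L) {
      abort("fewer than 10 matched cluster pairs: IDR EM unidentifiable; rerun with mode = \"fallback\"")
    }
    sc <- est_idr(matched$count_rep1, matched$count_rep2)
    matched$idr <- sc$idr
    matched <- filter(matched, .data$idr <= alpha)
  } else {
    matched$idr <- NA_real_
    matched <- filter(matched, .data$count_rep1 + .data$count_rep2 >= min_pooled)
  }
  matched |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    mutate(cluster = sprintf("cl%05d", dplyr::row_number()), .before = 1)
}
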