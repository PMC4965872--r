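test_that("length-difference matching equalises binned histograms", {
  a <- tibble::tibble(delta_length = c(rep(50, 10), rep(150, 5)), id = 1:15)
  b <- tibble::tibble(delta_length = c(rep(60, 2), rep(160, 20)), id = 1:22)
  m <- match_length_diff(a, b, bin_width = 100, seed = 1)
  # per-bin minimum: (10,5) vs (2,20) -> (2,5) each
  expect_equal(sum(m$a$delta_length < 100), 2)
  expect_equal(sum(m$b$delta_length < 100), 2)
  expect_equal(sum(m$a$delta_length >= 100), 5)
  expect_equal(sum(m$b$delta_length >= 100), 5)

  # identical distributions survive intact
  m2 <- match_length_diff(a, a, bin_width = 100, seed = 1)
  expect_equal(nrow(m2$a), nrow(a)); expect_equal(nrow(m2$b), nrow(a))

  # disjoint bins are an error
  expect_error(match_length_diff(
    tibble::tibble(delta_length = rep(50, 5)),
    tibble::tibble(delta_length = rep(150, 5)), bin_width = 100),
    "no length-difference bin")

  # matched output passes a KS sanity check on binned deltas
  set.seed(2)
  big_a <- tibble::tibble(delta_length = rexp(300, 1 / 150))
  big_b <- tibble::tibble(delta_length = rexp(300, 1 / 350))
  mb <- match_length_diff(big_a, big_b, bin_width = 100, seed = 3)
  ks <- suppressWarnings(stats::ks.test(mb$a$delta_length, mb$b$delta_length))
  expect_gt(ks$p.value, 0.2)
})

test_that("group comparison uses the exact Mann-Whitney null when it can", {
  gc <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$p_value, 0.1)
  expect_equal(gc$statistic, 0)
  gc_same <- group_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(gc_same$p_value, 1)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50) + 1.2
  expect_lt(group_compare(x, y)$p_value, 0.01)
  expect_error(group_compare(1:2, 1:5), "at least 3")
})

test_that("uORF dose-response recovers a planted monotone penalty", {
  set.seed(5)
  n_uorf <- sample(0:4, 400, replace = TRUE, prob = c(.4, .25, .2, .1, .05))
  fc <- -0.8 * n_uorf + rnorm(400, 0, 0.5)
  d <- tibble::tibble(n_uorf_div = n_uorf, log2fc = fc)
  res <- uorf_dose_response(d)
  expect_true(res$monotone_decreasing)
  expect_lt(res$tests$p_value[res$tests$stratum_a == "0" &
                                res$tests$stratum_b == ">=3"], 1e-6)
  expect_error(uorf_dose_response(dplyr::filter(d, n_uorf_div == 0)),
               "strata")
})

test_that("Fisher direction enrichment matches the hypergeometric oracle", {
  d <- tibble::tibble(
    feat = rep(c(TRUE, FALSE), each = 10),
    direction = rep(c("longer_lower", "longer_higher"), each = 10))
  fe <- fisher_direction_enrichment(d, "feat")
  expect_equal(fe$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_true(is.infinite(fe$odds_ratio) || fe$odds_ratio > 100)
  # independence: p near 1
  d2 <- tibble::tibble(feat = rep(c(TRUE, TRUE, FALSE, FALSE), 10),
                       direction = rep(c("longer_lower", "longer_higher"), 20))
  expect_gt(fisher_direction_enrichment(d2, "feat")$p_value, 0.5)
  expect_error(fisher_direction_enrichment(
    dplyr::mutate(d, feat = TRUE), "feat"), "margin")
})

test_that("the hexamer scan finds a planted motif and nothing under the null", {
  set.seed(6)
  n <- 120
  bg <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G"), 150, TRUE), collapse = ""), character(1))
  has <- seq_len(n) <= 50
  seqs <- ifelse(has, paste0(substr(bg, 1, 70), "AATCCC", substr(bg, 77, 150)), bg)
  fc <- rnorm(n, 0, 0.4) - 1.4 * has
  pairs <- tibble::tibble(divergent_seq = seqs, log2fc = fc,
                          delta_length = nchar(seqs))
  res <- hexamer_scan(pairs, seed = 2)
  expect_equal(res$hexamer[1], "AATCCC")
  expect_lt(res$padj[1], 0.01)
  expect_equal(res$direction[1], -1)
  # null: no BH-significant hexamers
  null_pairs <- dplyr::mutate(pairs, log2fc = rnorm(n, 0, 0.4))
  res0 <- hexamer_scan(null_pairs, seed = 3)
  expect_lte(sum(res0$padj < 0.01), 1)
  expect_error(hexamer_scan(pairs[1:10, ]), "at least 20")
})

test_that("TOP comparison contrasts TOP genes against random-orientation controls", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:40)
  iso <- purrr::map(genes, function(g) {
    te <- rlnorm(2, -3, 0.3)
    top <- g <= "g10"
    if (top) te[1] <- te[1] * 0.5  # 2-fold TOP penalty
    tibble::tibble(gene = g, isoform = paste0(g, ".", 1:2), te = te,
                   total = c(100, 100), has_top = c(top, FALSE))
  }) |> purrr::list_rbind()
  res <- top_comparison(iso, seed = 8)
  expect_lt(median(res$top_log2fc), -0.5)
  expect_lt(abs(median(res$control_log2fc)), 0.4)
  expect_lt(res$test$p_value, 0.05)
  expect_error(top_comparison(dplyr::mutate(iso, has_top = FALSE)), "TOP")
})
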