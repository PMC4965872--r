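test_that("bootstrap means sit at the expected fold changes", {
  set.seed(1)
  deep <- as.integer(rmultinom(1, 5000, rep(1 / 7, 7)))
  # identical clusters: symmetric null
  bt <- bootstrap_pair(deep, deep, B = 1000, seed = 1)
  expect_lt(abs(bt$boot_mean), 4 * bt$boot_sd / sqrt(1000) + 0.01)
  # doubling abundance leaves TE untouched
  bt2 <- bootstrap_pair(2L * deep, deep, B = 1000, seed = 2)
  expect_lt(abs(bt2$boot_mean), 0.02)
  # all tags in fraction 7 vs all in the monosome: log2(12/1)
  bt3 <- bootstrap_pair(c(0, 0, 0, 0, 0, 0, 1000), c(0, 0, 1000, 0, 0, 0, 0),
                        fraction_totals = c(0, 0, 2000, 0, 0, 0, 2000),
                        B = 1000, seed = 3)
  expect_equal(bt3$boot_mean, log2(12), tolerance = 0.01)
  expect_lt(bt3$boot_sd, 0.1)
})

test_that("bootstrap is reproducible and validates inputs", {
  a <- c(10, 10, 50, 80, 40, 20, 10); b <- rev(a)
  r1 <- bootstrap_pair(a, b, B = 200, seed = 9)
  r2 <- bootstrap_pair(a, b, B = 200, seed = 9)
  expect_identical(r1, r2)
  expect_error(bootstrap_pair(a, b, B = 1), "at least 2")
  expect_error(bootstrap_pair(rep(0, 7), b), "nonzero")
  expect_error(bootstrap_pair(a, b, fraction_totals = rep(1, 7)), "at least")
})

test_that("bootstrap noise shrinks like one over root depth", {
  base <- c(5, 5, 30, 60, 40, 15, 5) * 4L
  sds <- vapply(c(1L, 2L), function(m) {
    r <- bootstrap_pair(base * m, rev(base) * m, B = 4000, seed = m)
    r$boot_sd
  }, numeric(1))
  expect_equal(sds[1] / sds[2], sqrt(2), tolerance = 0.15)
})

test_that("Z p-values follow the standard normal", {
  expect_equal(z_pvalue(0, 1), 1)
  expect_equal(z_pvalue(1.959964, 1), 0.05, tolerance = 1e-5)
  expect_equal(z_pvalue(3, 1), 0.0027, tolerance = 1e-3)
  expect_equal(z_pvalue(c(1, 0), c(0, 0)), c(0, 1))
  expect_error(z_pvalue(1, -1), "non-negative")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the dual-replicate significance rule is applied literally", {
  mk <- function(fc1, fc2, p1, p2) {
    tibble::tibble(log2fc_rep1 = fc1, log2fc_rep2 = fc2,
                   padj_rep1 = p1, padj_rep2 = p2)
  }
  out <- call_significant(mk(-1.0, -1.2, 0.005, 0.005))
  expect_true(out$significant); expect_equal(out$direction, "longer_lower")
  expect_false(call_significant(mk(-1.0, -1.2, 0.005, 0.02))$significant)
  expect_false(call_significant(mk(0.7, -0.7, 0.005, 0.005))$significant)
  # fold change below 1.5x in one replicate fails
  expect_false(call_significant(mk(-1.0, -0.3, 0.005, 0.005))$significant)
})

test_that("permutation FDR is near 1 under the null and small under signal", {
  null_pairs <- simulate_pair_counts(150, depth = 800, null = TRUE, seed = 5)
  null_res <- pair_counts_test(null_pairs, B = 300, seed = 5)
  # almost nothing passes under the null; shuffles then give comparable counts
  sig_pairs <- simulate_pair_counts(80, depth = 3000, null = FALSE,
                                    lambda_range = c(0.5, 10),
                                    log2_length_ratio_range = c(-2, 2), seed = 6)
  sig_res <- pair_counts_test(sig_pairs, B = 300, seed = 6)
  expect_gt(sum(sig_res$significant), 20)
  fdr <- permutation_fdr(sig_res, seed = 1)
  expect_lt(fdr$fdr, 0.5)
  expect_error(permutation_fdr(sig_res, n_shuffles = 0), "positive")
  expect_error(permutation_fdr(sig_res[1, ]), "at least 2")
})

test_that("type-I error of the full rule is controlled on null pairs", {
  null_pairs <- simulate_pair_counts(300, depth = 600, null = TRUE, seed = 7)
  res <- pair_counts_test(null_pairs, B = 400, seed = 7)
  expect_lte(mean(res$significant), 0.01)
})
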