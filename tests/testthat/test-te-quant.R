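test_that("ribosome weights are the fixed gradient profile", {
  r <- ribosome_weights()
  expect_length(r, 7)
  expect_equal(unname(r), c(0, 0, 1, 2.5, 4.5, 7.5, 12))
  expect_false(is.unsorted(r))
})

test_that("isoform TE reproduces the fixed worked examples exactly", {
  q <- isoform_te(c(0, 0, 0, 0, 0, 0, 10), orf_length = 100)
  expect_equal(q$ribosomes_per_mrna, 12)
  expect_equal(q$te, 0.12)

  q <- isoform_te(c(5, 5, 0, 0, 0, 0, 0), orf_length = 100)
  expect_equal(q$ribosomes_per_mrna, 0)
  expect_equal(q$te, 0)

  q <- isoform_te(rep(10, 7), orf_length = 100)
  expect_equal(q$ribosomes_per_mrna, 27.5 / 7)
  expect_equal(q$te, 27.5 / 7 / 100)
})

test_that("TE is invariant to uniform count scaling and degenerate inputs error", {
  counts <- c(3, 1, 4, 1, 5, 9, 2)
  base <- isoform_te(counts, 300)
  for (s in c(0.1, 7, 1e3)) {
    expect_equal(isoform_te(counts * s, 300)$te, base$te)
  }
  expect_error(isoform_te(counts, 0), "positive")
  expect_error(isoform_te(counts[-1], 300), "length 7")
  expect_warning(q0 <- isoform_te(rep(0, 7), 300), "unquantifiable")
  expect_true(is.na(q0$te))
})

test_that("gene-level TE pools counts before normalising by ORF length", {
  one <- list(c(0, 0, 0, 10, 0, 0, 0))
  expect_equal(gene_te(one, 200)$te, isoform_te(one[[1]], 200)$te)
  # equal-count isoforms riding at 2.5 and 7.5 ribosomes -> gene load 5.0
  two <- list(c(0, 0, 0, 10, 0, 0, 0), c(0, 0, 0, 0, 0, 10, 0))
  expect_equal(gene_te(two, 200)$ribosomes_per_mrna, 5.0)
  # a zero-count isoform contributes nothing
  expect_equal(gene_te(list(c(0, 0, 0, 10, 0, 0, 0), rep(0, 7)), 200)$te,
               isoform_te(c(0, 0, 0, 10, 0, 0, 0), 200)$te)
})

test_that("leave-one-fraction-out recomputes TE over six fractions", {
  # counts concentrated elsewhere: unchanged
  counts <- c(0, 0, 0, 0, 0, 0, 10)
  expect_equal(leave_one_fraction_out(counts, 100, 3)$te,
               isoform_te(counts, 100)$te)
  # equal counts, leave the heaviest polysome fraction
  expect_equal(leave_one_fraction_out(rep(10, 7), 100, 7)$ribosomes_per_mrna,
               15.5 / 6)
  # proportional vectors keep zero fold change for every left-out fraction
  a <- c(1, 2, 3, 4, 5, 6, 7); b <- 3 * a
  for (j in 1:7) {
    expect_equal(leave_one_fraction_out(a, 100, j)$te,
                 leave_one_fraction_out(b, 100, j)$te)
  }
})

test_that("monosome/polysome ratio follows C3 over polysome sum", {
  expect_equal(monosome_polysome_ratio(c(0, 0, 10, 10, 0, 0, 0)), 1.0)
  expect_equal(monosome_polysome_ratio(c(0, 0, 30, 10, 10, 10, 0)), 1.0)
  expect_equal(monosome_polysome_ratio(c(0, 0, 0, 10, 0, 0, 0)), 0)
  expect_warning(r <- monosome_polysome_ratio(c(0, 0, 10, 0, 0, 0, 0)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("spike factors use the strict >10 filter and the upper quartile", {
  mk <- function(counts_by_cluster) {
    purrr::imap(counts_by_cluster, function(m, cl) {
      tidyr::expand_grid(replicate = 1:2, fraction = 1:7) |>
        dplyr::mutate(cluster = cl, count = as.vector(t(m)))
    }) |> purrr::list_rbind()
  }
  # equal counts across fractions: identity normalization
  flat <- mk(list(a = matrix(50, 2, 7), b = matrix(80, 2, 7)))
  sf <- spike_factors(flat)
  expect_true(all(abs(sf$size_factor - 1) < 1e-12))

  # doubling fraction 4 in every cluster doubles that factor
  m <- matrix(40, 2, 7); m[, 4] <- 80
  sf2 <- spike_factors(mk(list(a = m, b = 2 * m)))
  f <- sf2 |> dplyr::filter(replicate == 1)
  expect_equal(f$factor[f$fraction == 4] / f$factor[f$fraction == 1], 2)

  # a cluster with exactly 10 tags in one fraction is excluded
  m10 <- matrix(50, 2, 7); m10[1, 3] <- 10
  sf3 <- spike_factors(mk(list(a = m10, b = matrix(60, 2, 7))))
  expect_equal(unique(sf3$factor), 60)  # only cluster b qualifies

  # normalization undoes the fraction-4 distortion on real counts
  counts <- tidyr::expand_grid(replicate = 1:2, fraction = 1:7) |>
    dplyr::mutate(count = 100 * ifelse(fraction == 4, 2, 1))
  norm <- normalize_counts(counts, sf2)
  expect_equal(dplyr::n_distinct(round(norm$norm_count, 9)), 1)

  expect_error(spike_factors(mk(list(a = matrix(5, 2, 7)))), "spike")
})

test_that("te_quantify matches isoform_te row-wise and drops zero totals", {
  counts <- tidyr::expand_grid(gene = "g1", isoform = c("i1", "i2"),
                               replicate = 1L, fraction = 1:7) |>
    dplyr::mutate(count = ifelse(isoform == "i1", 10, 0))
  expect_message(q <- te_quantify(counts, tibble::tibble(gene = "g1", orf_length = 100)),
                 "zero total")
  expect_equal(nrow(q), 1)
  expect_equal(q$te, 27.5 / 7 / 100)
})
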