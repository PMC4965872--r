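test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "at least 1")
  expect_error(sim_config(tss_per_gene = c(0.5, 0.6, 0.1)), "summing to 1")
  expect_error(sim_config(utr_length_range = c(-10, 100)), "positive")
  expect_error(sim_config(background_rate = -1), "non-negative")
  expect_error(sim_config(spike_factors = matrix(1, 6, 2)), "7 x n_replicates")
  expect_error(sim_config(feature_plant_probs = c(uorf = 1.2, uaug_out = 0,
                                                  uaug_in = 0, top = 0,
                                                  hairpin = 0, hexamer = 0)),
               "\\[0, 1\\]")
  expect_error(sim_config(effect_hexamer = "AATGCC"), "AUG-free")
})

test_that("fraction map matches the censored-Poisson oracle", {
  for (lam in c(0, 0.5, 1, 3, 6.5, 12)) {
    expect_equal(as.numeric(fraction_probs(lam)), oracle_fraction_split(lam),
                 tolerance = 1e-12)
    expect_equal(sum(fraction_probs(lam)), 1, tolerance = 1e-12)
  }
})

test_that("degenerate loads land where the gradient says they must", {
  no_plant <- c(uorf = 0, uaug_out = 0, uaug_in = 0, top = 0, hairpin = 0,
                hexamer = 0)
  cfg <- sim_config(n_genes = 12, lambda_range = c(0, 0), tag_scatter = 0,
                    background_rate = 0, splice_prob = 0,
                    feature_plant_probs = no_plant,
                    spike_factors = matrix(1, 7, 2), seed = 5)
  sim <- simulate_dataset(cfg)
  by_frac <- sim$tags |> dplyr::count(fraction, wt = count)
  expect_setequal(by_frac$fraction, 1:2)   # lambda = 0: free + 40S/60S only
  q <- te_quantify(sim$tags |>
                     dplyr::inner_join(sim$truth$isoforms[c("chrom", "tss", "isoform", "gene")],
                                       by = c("chrom", "pos" = "tss")),
                   dplyr::select(sim$annotation, gene, orf_length))
  expect_true(all(q$te == 0))

  cfg12 <- sim_config(n_genes = 12, lambda_range = c(12, 12), tag_scatter = 0,
                      background_rate = 0, splice_prob = 0,
                      feature_plant_probs = no_plant,
                      spike_factors = matrix(1, 7, 2), seed = 6)
  sim12 <- simulate_dataset(cfg12)
  share7 <- sim12$tags |> dplyr::count(fraction, wt = count)
  expect_gt(share7$n[share7$fraction == 7] / sum(share7$n),
            oracle_fraction_split(12)[7] - 0.05)
})

test_that("estimated ribosome load is consistent with the truncated-Poisson expectation", {
  cfg <- sim_config(n_genes = 60, abundance_meanlog = log(12000),
                    abundance_sdlog = 0.05, tag_scatter = 0,
                    background_rate = 0, splice_prob = 0,
                    feature_plant_probs = c(uorf = 0, uaug_out = 0, uaug_in = 0,
                                            top = 0, hairpin = 0, hexamer = 0),
                    spike_factors = matrix(1, 7, 2), seed = 8)
  sim <- simulate_dataset(cfg)
  counts <- sim$tags |>
    dplyr::inner_join(sim$truth$isoforms[c("chrom", "tss", "isoform", "gene")],
                      by = c("chrom", "pos" = "tss"))
  q <- te_quantify(counts, dplyr::select(sim$annotation, gene, orf_length))
  tr <- sim$truth$isoforms
  q$expected <- tr$expected_load[match(q$isoform, tr$isoform)]
  expect_true(all(abs(q$ribosomes_per_mrna - q$expected) / pmax(q$expected, 0.1) < 0.02))
})

test_that("identity distortion emits the multinomial split exactly", {
  cfg <- sim_config(n_genes = 10, tag_scatter = 0, background_rate = 0,
                    splice_prob = 0, spike_factors = matrix(1, 7, 2), seed = 9)
  sim <- simulate_dataset(cfg)
  # with no scatter and no background every tag sits exactly on a true TSS
  expect_true(all(sim$tags$pos %in% sim$truth$isoforms$tss))
  per_iso <- sim$tags |>
    dplyr::inner_join(sim$truth$isoforms[c("chrom", "tss", "isoform", "abundance")],
                      by = c("chrom", "pos" = "tss")) |>
    dplyr::count(isoform, replicate, abundance, wt = count)
  expect_true(all(per_iso$n == per_iso$abundance))
})

test_that("identical seeds give byte-identical datasets", {
  a <- simulate_dataset(sim_config(n_genes = 8, seed = 42))
  b <- simulate_dataset(sim_config(n_genes = 8, seed = 42))
  expect_identical(a$tags, b$tags)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$isoforms, b$truth$isoforms)
  c2 <- simulate_dataset(sim_config(n_genes = 8, seed = 43))
  expect_false(identical(a$tags, c2$tags))
})

test_that("planted features are recovered verbatim by the feature counters", {
  set.seed(1)
  for (i in 1:25) {
    feats <- list(n_uorf = sample(0:3, 1), n_uaug_out = sample(0:2, 1),
                  n_uaug_in = sample(0:1, 1), top = runif(1) < 0.5,
                  n_hairpin = sample(0:1, 1),
                  hexamers = if (runif(1) < 0.5) "AATCCC" else character(0))
    s <- plant_utr_features(random_utr_background(400), feats)
    got <- find_uorfs(s)
    expect_equal(got$n_uorf, feats$n_uorf)
    expect_equal(got$n_uaug_out, feats$n_uaug_out)
    expect_equal(got$n_uaug_in, feats$n_uaug_in)
    expect_equal(detect_top(s), isTRUE(feats$top))
    if (length(feats$hexamers)) {
      expect_gte(count_hexamers(s)[feats$hexamers], 1L)
    }
  }
})

test_that("planting fails loudly when the sequence cannot host the features", {
  expect_error(plant_utr_features(random_utr_background(30),
                                  list(n_uorf = 3, n_hairpin = 2)),
               "too short")
  expect_error(plant_utr_features("ATGAAA", list(top = TRUE)), "AUG-free")
})

test_that("truth table feature counts agree with counters run on truth sequences", {
  sim <- simulate_dataset(sim_config(n_genes = 50, seed = 21))
  tr <- sim$truth$isoforms |> dplyr::filter(!excluded)
  for (i in seq_len(nrow(tr))) {
    got <- find_uorfs(tr$utr_seq[i])
    expect_equal(got$n_uorf, tr$n_uorf[i], info = tr$isoform[i])
    expect_equal(got$n_uaug_in, tr$n_uaug_in[i], info = tr$isoform[i])
    expect_equal(got$n_uaug_out, tr$n_uaug_out[i], info = tr$isoform[i])
    expect_equal(detect_top(tr$utr_seq[i]), tr$has_top[i], info = tr$isoform[i])
  }
})

test_that("written dataset round-trips through plain-text files", {
  sim <- simulate_dataset(sim_config(n_genes = 4, seed = 2))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "tags.tsv", "spikes.tsv", "junctions.tsv",
    "annotation.tsv", "truth_isoforms.tsv", "coverage.bedGraph")))))
  tags <- readr::read_tsv(file.path(dir, "tags.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tags), nrow(sim$tags))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa), as.character(sim$genome))
})
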