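mk_track <- function(pos, count, chrom = "c1", strand = "+") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                 replicate = 1L, fraction = 1L, count = count)
}

test_that("local background takes the max of local and expression terms", {
  # uniform tag coverage c over the window -> bg = c
  trk <- tibble::tibble(pos = 0:999, count = 2)
  bg <- local_background(trk, pos = 500L)
  expect_equal(bg, 2)
  # expression floor: sparse tags, RNA-seq coverage r
  cov <- tibble::tibble(chrom = "c1", start = 0, end = 5000, depth = 3)
  trk2 <- tibble::tibble(pos = c(100L, 4000L), count = c(1, 1))
  bg2 <- local_background(trk2, pos = 100L, coverage = cov, depth_norm = 1)
  expect_equal(bg2, 3)
  # single tower of height h: local expectation h/500 (plus the tower itself)
  trk3 <- tibble::tibble(pos = 1000L, count = 50)
  expect_equal(local_background(trk3, pos = 1000L), 50 / 500)
  expect_error(local_background(trk3[0, ], pos = 1L), "empty")
})

test_that("the 20-nt merge rule joins and separates towers as specified", {
  expect_equal(nrow(call_tss_clusters(mk_track(integer(0), integer(0)))), 0)
  one <- call_tss_clusters(mk_track(c(1000L, 1015L), c(50, 30)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1000); expect_equal(one$end, 1016)
  expect_equal(one$summit, 1000)  # argmax
  two <- call_tss_clusters(mk_track(c(1000L, 1050L), c(50, 30)))
  expect_equal(nrow(two), 2)
})

test_that("summit ties break to the most 5' position, strand-aware", {
  plus <- call_tss_clusters(mk_track(c(1000L, 1010L), c(40, 40)))
  expect_equal(plus$summit, 1000)
  minus <- call_tss_clusters(mk_track(c(1000L, 1010L), c(40, 40), strand = "-"))
  expect_equal(minus$summit, 1010)
})

test_that("pure background produces no clusters", {
  # uniform background at a realistic sparse tag rate (0.02 tags/nt pooled)
  set.seed(4)
  pos <- sort(sample.int(50000L, 1000L, replace = TRUE))
  tb <- table(pos)
  bgtrk <- mk_track(as.integer(names(tb)), as.integer(tb))
  expect_equal(nrow(call_tss_clusters(bgtrk)), 0)
})

test_that("stepwise refinement splits shoulders and flags plateaus", {
  # narrow cluster untouched
  narrow <- call_tss_clusters(mk_track(1000:1079, rep(5, 80)))
  # two sharp towers joined by a plateau just above bg: towers survive 1.5x
  pos <- 1000:1149
  count <- rep(2, 150)
  count[6:15] <- 60; count[136:145] <- 60
  res <- call_tss_clusters(mk_track(pos, count))
  expect_gte(nrow(res), 2)
  expect_true(all(res$width <= 100))
  expect_false(any(res$flagged))
  # parent summit survives refinement
  parent_summit <- pos[which.max(count)]
  expect_true(any(res$start <= parent_summit & res$end > parent_summit))
  # refinement never increases total cluster length
  expect_lte(sum(res$width), 150)

  # a flat 150-nt plateau at 10x bg never splits: flagged at full width
  flat <- call_tss_clusters(mk_track(1000:1149, rep(50, 150)))
  expect_equal(nrow(flat), 1)
  expect_true(flat$flagged)
  expect_equal(flat$width, 150)
})

test_that("region assignment follows the gross-5'UTR precedence", {
  ann <- tibble::tibble(gene = "g1", chrom = "c1", strand = "+",
                        ann_tss = 5000L, start_codon = 5400L,
                        orf_length = 900L, cds_lo = 5400L, cds_hi = 6300L,
                        gene_lo = 4000L, gene_hi = 6500L)
  cl <- tibble::tibble(cluster = c("a", "b", "c", "d", "e"),
                       chrom = "c1", strand = "+",
                       start = c(4700L, 5100L, 3500L, 5800L, 6400L),
                       end = c(4701L, 5101L, 3501L, 5801L, 6401L),
                       summit = c(4700L, 5100L, 3500L, 5800L, 6400L))
  out <- assign_region(cl, ann)
  expect_equal(out$region[out$cluster == "a"], "up1kb")     # 300 nt upstream
  expect_equal(out$region[out$cluster == "b"], "utr5")      # between TSS and start
  expect_equal(out$region[out$cluster == "c"], "intergenic") # 1,500 nt upstream
  expect_equal(out$region[out$cluster == "d"], "cds")
  expect_equal(out$region[out$cluster == "e"], "utr3")

  # minus strand mirror
  annm <- tibble::tibble(gene = "g2", chrom = "c2", strand = "-",
                         ann_tss = 5000L, start_codon = 4600L,
                         orf_length = 900L, cds_lo = 3701L, cds_hi = 4601L,
                         gene_lo = 3500L, gene_hi = 5600L)
  clm <- tibble::tibble(cluster = c("a", "b"), chrom = "c2", strand = "-",
                        start = c(5300L, 4800L), end = c(5301L, 4801L),
                        summit = c(5300L, 4800L))
  outm <- assign_region(clm, annm)
  expect_equal(outm$region[outm$cluster == "a"], "up1kb")
  expect_equal(outm$region[outm$cluster == "b"], "utr5")
})

test_that("planted TSSs are recovered on simulated data with summits on target", {
  sim <- simulate_dataset(sim_config(n_genes = 60, seed = 14))
  cl <- call_tss_clusters(dplyr::filter(sim$tags, replicate == 1),
                          coverage = sim$coverage)
  tr <- sim$truth$isoforms
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(cl$chrom == tr$chrom[i] & cl$strand == tr$strand[i] &
          abs(cl$summit - tr$tss[i]) <= 10)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # spanning counts cover at least the above-background cluster members
  cc <- count_cluster_tags(cl, sim$tags)
  tot <- sum(cc$count[cc$replicate == 1])
  expect_gte(tot, sum(cl$pooled_count))
  expect_lte(tot, sum(cl$pooled_count) * 1.01)
})
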