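test_that("PSI pseudo-read rules reproduce the worked examples", {
  ev <- tibble::tibble(
    status = c("annotated-constitutive", "annotated-alternative", "novel",
               "novel"),
    reads_splicein = c(0, 0, 1, 0),
    reads_spliceout = c(0, 0, 9, 0))
  out <- compute_psi(ev)
  expect_equal(out$psi[1], 0)          # 0 / (0 + 10)
  expect_equal(out$call[1], "removed")
  expect_equal(out$psi[2], 0.5)        # 5 / 10
  expect_equal(out$call[2], "ambiguous")
  expect_equal(out$psi[3], 0.1)        # inclusive threshold
  expect_equal(out$call[3], "removed")
  expect_equal(out$call[4], "ambiguous")  # no informative reads at all
  expect_error(compute_psi(dplyr::mutate(ev, reads_splicein = -1)),
               "non-negative")
  expect_error(compute_psi(dplyr::mutate(ev, status = "whatever")), "unknown")
})

test_that("5'UTR reconstruction excises removed introns and respects strand", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 400), collapse = "")))
  # plain span
  r <- reconstruct_utr(100, 300, genome, "c1", "+")
  expect_equal(r$status, "resolved")
  expect_equal(r$utr_length, 200)
  expect_equal(r$utr_seq, substr(as.character(genome[[1]]), 101, 300))
  # an 88-nt removed region shrinks the mature UTR by 88
  ev <- tibble::tibble(donor0 = 150L, acceptor0 = 238L, call = "removed")
  r2 <- reconstruct_utr(100, 300, genome, "c1", "+", events = ev)
  expect_equal(r2$utr_length, 200 - 88)
  expect_equal(r2$utr_seq, paste0(substr(as.character(genome[[1]]), 101, 150),
                                  substr(as.character(genome[[1]]), 239, 300)))
  # ambiguous event overlapping the span: excluded
  ev_amb <- tibble::tibble(donor0 = 150L, acceptor0 = 238L, call = "ambiguous")
  r3 <- reconstruct_utr(100, 300, genome, "c1", "+", events = ev_amb)
  expect_equal(r3$status, "ambiguous-excluded")
  expect_true(is.na(r3$utr_seq))
  # retained events change nothing
  ev_ret <- tibble::tibble(donor0 = 150L, acceptor0 = 238L, call = "retained")
  expect_equal(reconstruct_utr(100, 300, genome, "c1", "+", events = ev_ret)$utr_seq,
               r$utr_seq)
  # minus strand: reverse complement of the genomic span
  rm <- reconstruct_utr(300, 100, genome, "c1", "-")
  expect_equal(rm$utr_seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(as.character(genome[[1]]), 102, 301)))))
  # downstream TSS is a hard error
  expect_error(reconstruct_utr(300, 100, genome, "c1", "+"), "strictly 5'")
})

test_that("divergent region is the 5' prefix unique to the longer isoform", {
  expect_equal(divergent_region("XXXAACCGG", "AACCGG")$divergent_seq, "XXX")
  d <- divergent_region("GGGAAA", "GGGAAA")
  expect_false(d$ok)
  d2 <- divergent_region("AAACCC", "GGG")
  expect_true(is.na(d2$divergent_seq)); expect_false(d2$ok)
})

test_that("uORF/uAUG classification matches the brute-force oracle", {
  # hand-checked examples
  expect_equal(find_uorfs(paste0("ATGAAATAA", strrep("C", 30)))$n_uorf, 1)
  aug_in <- paste0(strrep("C", 21), "ATG", strrep("C", 6))  # distance 9
  expect_equal(find_uorfs(aug_in)$n_uaug_in, 1)
  expect_equal(find_uorfs(strrep("CAG", 20))$n_uorf, 0)
  # RNA alphabet accepted
  expect_equal(find_uorfs("AUGAAAUAACCCCCC")$n_uorf, 1)
  expect_error(find_uorfs("ATGNNNTAA"), "non-nucleotide")
  # randomised agreement
  set.seed(11)
  for (i in 1:300) {
    s <- random_dna(sample(20:300, 1))
    got <- find_uorfs(s)
    exp <- oracle_uorf_scan(s)
    expect_equal(unlist(got), exp, ignore_attr = TRUE,
                 info = paste("seq", i))
  }
})

test_that("TOP detection requires a cap C followed by 4+ pyrimidines", {
  expect_true(detect_top("CUUUCAAAA"))
  expect_true(detect_top("CTTTCAAAA"))
  expect_false(detect_top("CAAAAUUUU"))
  expect_false(detect_top("UUUUUAAAA"))
  expect_false(detect_top("CUU"))
  expect_true(detect_top("CCCCC"))
})

test_that("hexamer counting matches the naive oracle on random sequences", {
  expect_length(aug_free_hexamers(), 3841)
  expect_false(any(grepl("ATG", aug_free_hexamers())))
  expect_equal(sum(count_hexamers("AAAA")), 0)
  one <- count_hexamers(paste0(strrep("G", 10), "AAAAAT", strrep("G", 10)))
  expect_equal(unname(one["AAAAAT"]), 1L)
  set.seed(12)
  for (i in 1:20) {
    s <- random_dna(sample(6:400, 1))
    expect_identical(count_hexamers(s), oracle_hexamer_count(s),
                     info = paste("seq", i))
  }
  # vector total = number of AUG-free windows
  for (i in 1:20) {
    s <- random_dna(200)
    wins <- vapply(1:(200 - 5), function(j) substr(s, j, j + 5), character(1))
    expect_equal(sum(count_hexamers(s)), sum(!grepl("ATG", wins)))
  }
})
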