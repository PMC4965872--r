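# Independent brute-force oracles used to freeze expected values.

# character-by-character uORF/uAUG scanner, no shared code with the package
oracle_uorf_scan <- function(seq, dist_to_start = 0L) {
  s <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  L <- length(s)
  codon_at <- function(i) paste(s[i:(i + 2)], collapse = "")
  n_uorf <- n_in <- n_out <- 0L
  for (i in seq_len(max(L - 2, 0))) {
    if (codon_at(i) != "ATG") next
    stopped <- FALSE
    j <- i + 3
    while (j + 2 <= L) {
      if (codon_at(j) %in% c("TAA", "TAG", "TGA")) { stopped <- TRUE; break }
      j <- j + 3
    }
    if (stopped) {
      n_uorf <- n_uorf + 1L
    } else if (((L - i + 1) + dist_to_start) %% 3 == 0) {
      n_in <- n_in + 1L
    } else {
      n_out <- n_out + 1L
    }
  }
  c(n_uorf = n_uorf, n_uaug_in = n_in, n_uaug_out = n_out)
}

# naive O(L * 4096) hexamer counter
oracle_hexamer_count <- function(seq) {
  s <- gsub("U", "T", toupper(seq))
  b <- c("A", "C", "G", "T")
  all_hx <- sort(do.call(paste0, expand.grid(b, b, b, b, b, b,
                                             stringsAsFactors = FALSE)))
  free <- all_hx[!grepl("ATG", all_hx)]
  L <- nchar(s)
  counts <- setNames(integer(length(free)), free)
  if (L >= 6) {
    wins <- vapply(1:(L - 5), function(i) substr(s, i, i + 5), character(1))
    tb <- table(wins)
    hit <- intersect(names(tb), free)
    counts[hit] <- as.integer(tb[hit])
  }
  counts
}

# expected fraction split for mean load lambda under the censored-Poisson map
oracle_fraction_split <- function(lambda) {
  pk <- dpois(0:9, lambda)
  c(pk[1] / 2, pk[1] / 2, pk[2], pk[3] + pk[4], pk[5] + pk[6], sum(pk[7:10]),
    1 - sum(pk))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
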