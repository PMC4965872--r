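# cis-element feature extraction from 5'UTR sequences.

#' Count uORFs and upstream AUGs in a 5'UTR
#'
#' Every AUG in the UTR is scanned: if an in-frame stop codon (UAA/UAG/UGA)
#' lies fully within the UTR downstream of it, it heads a uORF; otherwise it
#' is an upstream AUG, in frame with the main ORF when its distance to the
#' main AUG (= UTR length minus AUG position, plus `dist_to_start` when the
#' sequence is a sub-region) is a multiple of 3. uAUGs whose open frame runs
#' past the main start are thereby classified as uAUGs, not uORFs.
#'
#' @param utr 5'UTR sequence (A/C/G/T/U; the sequence ends immediately
#'   before the main start codon unless `dist_to_start` says otherwise).
#' @param dist_to_start Additional distance (nt) from the end of `utr` to
#'   the main AUG, for sub-regions such as divergent regions (default 0).
#' @return One-row tibble: `n_uorf`, `n_uaug_in`, `n_uaug_out`.
#' @export
find_uorfs <- function(utr, dist_to_start = 0L) {
  s <- as_dna(utr)
  L <- nchar(s)
  hits <- str_locate_all(s, "ATG")[[1]][, 1]        # 1-based
  # alternation in one pattern would miss overlapping stops; scan each
  stops <- sort(unique(c(
    str_locate_all(s, "TAA")[[1]][, 1],
    str_locate_all(s, "TAG")[[1]][, 1],
    str_locate_all(s, "TGA")[[1]][, 1])))
  n_uorf <- 0L; n_in <- 0L; n_out <- 0L
  for (p in hits) {
    instop <- stops[stops > p & (stops - p) %% 3L == 0L & stops + 2L <= L]
    if (length(instop)) {
      n_uorf <- n_uorf + 1L
    } else {
      dist <- (L - (p - 1L)) + dist_to_start
      if (dist %% 3L == 0L) n_in <- n_in + 1L else n_out <- n_out + 1L
    }
  }
  tibble(n_uorf = n_uorf, n_uaug_in = n_in, n_uaug_out = n_out)
}

#' Detect a 5'-terminal oligopyrimidine (TOP) tract
#'
#' TRUE iff the first base is C and at least the next 4 bases are all
#' pyrimidines (C/U).
#'
#' @param utr 5'UTR sequence starting at the cap site.
#' @param min_pyr Minimum pyrimidine run after the cap C (default 4).
#' @return Logical scalar.
#' @export
detect_top <- function(utr, min_pyr = 4L) {
  s <- as_dna(utr)
  if (nchar(s) < 1L + min_pyr) return(FALSE)
  if (substr(s, 1, 1) != "C") return(FALSE)
  run <- strsplit(substr(s, 2, 1 + min_pyr), "")[[1]]
  all(run %in% c("C", "T"))
}

#' The AUG-free hexamer universe
#'
#' All 4^6 = 4096 hexamers minus the 255 containing AUG as a substring,
#' leaving 3,841.
#'
#' @return Character vector of 3,841 hexamers (DNA alphabet, sorted).
#' @export
aug_free_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  hx <- do.call(paste0, expand.grid(b, b, b, b, b, b,
                                    stringsAsFactors = FALSE)[, 6:1])
  sort(hx[!grepl("ATG", hx)])
}

#' Count overlapping hexamer occurrences in a sequence
#'
#' @param utr Sequence (A/C/G/T/U).
#' @return Named integer vector over the 3,841 AUG-free hexamers; sequences
#'   shorter than 6 nt give an all-zero vector.
#' @export
count_hexamers <- function(utr) {
  hx <- aug_free_hexamers()
  s <- as_dna(utr)
  if (nchar(s) < 6L) return(setNames(integer(length(hx)), hx))
  freq <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), 6)
  out <- freq[hx]
  storage.mode(out) <- "integer"
  setNames(out, hx)
}

# hexamer presence/count matrix for a set of sequences (rows = sequences)
hexamer_matrix <- function(seqs) {
  hx <- aug_free_hexamers()
  valid <- !is.na(seqs) & nchar(seqs) >= 6
  m <- matrix(0L, length(seqs), length(hx), dimnames = list(NULL, hx))
  if (any(valid)) {
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(vapply(seqs[valid], as_dna, character(1))), 6)
    m[valid, ] <- freq[, hx, drop = FALSE]
  }
  m
}

#' Full cis-element feature vector of one 5'UTR
#'
#' Combines [find_uorfs()], [detect_top()], and [fold_windows()] into the
#' per-isoform feature record used by the association and modelling stages.
#'
#' @param utr Mature 5'UTR sequence.
#' @param engine,window,step,cap_thresh,window_thresh Passed to
#'   [fold_windows()].
#' @param fold Set `FALSE` to skip secondary-structure features (columns
#'   are `NA`).
#' @return One-row tibble: `utr_length`, `n_uorf`, `n_uaug_in`,
#'   `n_uaug_out`, `has_top`, `cap_mfe`, `cap_efe`, `min_mfe`, `min_efe`,
#'   `cap_stable`, `downstream_stable`.
#' @export
utr_features <- function(utr, engine = "auto", window = 50, step = 10,
                         cap_thresh = -30, window_thresh = -35, fold = TRUE) {
  orf <- find_uorfs(utr)
  fw <- if (fold) {
    fold_windows(utr, engine = engine, window = window, step = step,
                 cap_thresh = cap_thresh, window_thresh = window_thresh)
  } else {
    tibble(cap_mfe = NA_real_, cap_efe = NA_real_, min_mfe = NA_real_,
           min_efe = NA_real_, cap_stable = NA, downstream_stable = NA)
  }
  bind_cols(tibble(utr_length = nchar(utr)), orf,
            tibble(has_top = detect_top(utr)), fw)
}
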