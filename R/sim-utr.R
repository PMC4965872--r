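# Synthetic 5'UTR sequences with planted cis-elements.
#
# Backgrounds are drawn from the {A, C, G} alphabet: with no T they can
# contain neither AUGs nor stop codons in any frame, so every planted
# uORF/uAUG is recoverable verbatim and planted uAUGs can never gain an
# accidental in-frame stop from the background.

T_FREE_BASES <- c("A", "C", "G")

#' AUG- and stop-free random background sequence
#'
#' @param n Length in nt.
#' @param first_base Base forced at position 1 (default "G", so a cap-site C
#'   and hence an accidental 5' TOP cannot arise by chance).
#' @return A character scalar.
#' @export
random_utr_background <- function(n, first_base = "G") {
  if (n < 1) abort("`n` must be positive")
  s <- sample(T_FREE_BASES, n, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  if (!is.null(first_base)) s[1] <- first_base
  paste(s, collapse = "")
}

# element builders ----------------------------------------------------------

elem_uorf <- function(n_codons = 2) {
  body <- replicate(n_codons, paste(sample(T_FREE_BASES, 3, TRUE), collapse = ""))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

elem_top <- function(n_pyr = 5) {
  pyr <- sample(c("T", "C"), n_pyr, replace = TRUE, prob = c(0.5, 0.5))
  paste0("C", paste(pyr, collapse = ""))
}

elem_hairpin <- function(stem = 20) {
  left <- paste(sample(c("G", "C"), stem, TRUE), collapse = "")
  paste0(left, "GAAA", revcomp(left))
}

#' Plant cis-element features into an AUG-free background sequence
#'
#' Overwrites stretches of `seq` (length is preserved) with the requested
#' elements: uORFs (AUG + AUG-free codons + UAA), upstream AUGs placed in or
#' out of frame relative to the main ORF, a 5' TOP tract at position 1, GC
#' hairpins, and literal hexamer motifs. uAUGs are placed in the rightmost
#' free slots so that no later element can supply them an in-frame stop.
#' After assembly the sequence is verified to contain exactly the planted
#' AUGs; an AUG formed across an element/background boundary is broken by
#' mutating the background base.
#'
#' @param seq Background sequence (character scalar) with no "ATG"
#'   occurrence; typically from [random_utr_background()].
#' @param features List with any of: `n_uorf`, `n_uaug_out`, `n_uaug_in`
#'   (counts), `top` (logical), `n_hairpin` (count), `hexamers` (character
#'   vector of AUG-free motifs, each planted once), `uorf_codons`
#'   (body codons per uORF, default 2), `top_pyr` (pyrimidines after the cap
#'   C, default 5), `hairpin_stem` (default 20).
#' @param dist_to_start Distance (nt) from the end of `seq` to the main
#'   start codon; 0 when `seq` is the full 5'UTR. Used for the in/out-of-
#'   frame placement of uAUGs.
#' @param seed Optional integer seed for reproducible placement.
#' @return The sequence with planted features; attribute `"planted"` holds a
#'   tibble (`type`, `start0`, `length`, `element`) of what was placed where
#'   (0-based starts).
#' @export
plant_utr_features <- function(seq, features = list(), dist_to_start = 0L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- as_dna(seq)
  if (grepl("ATG", seq)) abort("background sequence must be AUG-free")
  f <- utils::modifyList(
    list(n_uorf = 0L, n_uaug_out = 0L, n_uaug_in = 0L, top = FALSE,
         n_hairpin = 0L, hexamers = character(0), uorf_codons = 2L,
         top_pyr = 5L, hairpin_stem = 20L),
    features
  )
  if (length(f$hexamers) && any(grepl("ATG", toupper(f$hexamers)))) {
    abort("planted hexamers must be AUG-free")
  }
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  occupied <- integer(0)     # 1-based positions already claimed (with margin)
  planted <- list()
  failed <- character(0)

  claim <- function(start, len) {
    # margin of 2 background nt around each element
    occupied <<- c(occupied, max(1L, start - 2L):min(L, start + len + 1L))
  }
  free_at <- function(start, len) {
    start >= 1L && start + len - 1L <= L && !any(start:(start + len - 1L) %in% occupied)
  }
  place_random <- function(el, type, lo = 2L, hi = L) {
    len <- nchar(el)
    starts <- lo:max(lo, hi - len + 1L)
    # random tries first, then a deterministic sweep so that placement only
    # fails when no free slot exists at all
    cand <- unique(c(sample(starts, min(length(starts), 200L)), starts))
    for (s in cand) {
      if (free_at(s, len)) {
        chars[s:(s + len - 1L)] <<- strsplit(el, "")[[1]]
        claim(s, len)
        planted[[length(planted) + 1L]] <<-
          tibble(type = type, start0 = s - 1L, length = len, element = el)
        return(TRUE)
      }
    }
    failed <<- c(failed, type)
    FALSE
  }

  # 5' TOP occupies the cap site
  if (isTRUE(f$top)) {
    el <- elem_top(f$top_pyr)
    if (nchar(el) > L) {
      failed <- c(failed, "top")
    } else {
      chars[1:nchar(el)] <- strsplit(el, "")[[1]]
      claim(1L, nchar(el))
      planted[[length(planted) + 1L]] <-
        tibble(type = "top", start0 = 0L, length = nchar(el), element = el)
    }
  }

  # uAUGs first reserve the rightmost frame-compatible slots, then the bulky
  # elements fill the remainder; placement order 3' -> 5' guarantees no
  # planted element sits downstream of a uAUG.
  uaug_slots <- list()
  n_uaug <- f$n_uaug_out + f$n_uaug_in
  if (n_uaug > 0L) {
    wanted <- c(rep("uaug_in", f$n_uaug_in), rep("uaug_out", f$n_uaug_out))
    s <- L - 2L
    for (type in wanted) {
      placed <- FALSE
      while (s >= 2L) {
        dist <- (L - (s - 1L)) + dist_to_start  # nt from uAUG to main AUG
        frame_ok <- if (type == "uaug_in") dist %% 3L == 0L else dist %% 3L != 0L
        if (frame_ok && free_at(s, 3L)) {
          chars[s:(s + 2L)] <- c("A", "T", "G")
          claim(s, 3L)
          planted[[length(planted) + 1L]] <-
            tibble(type = type, start0 = s - 1L, length = 3L, element = "ATG")
          uaug_limit <- s  # subsequent elements stay 5' of this
          s <- s - 5L
          placed <- TRUE
          break
        }
        s <- s - 1L
      }
      if (!placed) failed <- c(failed, type)
    }
  }
  # bulky elements go 5' of the leftmost uAUG
  uaug_starts <- vapply(planted, function(p)
    if (p$type %in% c("uaug_in", "uaug_out")) p$start0 + 1L else NA_integer_,
    integer(1))
  hi_bulk <- if (all(is.na(uaug_starts))) L else min(uaug_starts, na.rm = TRUE) - 3L

  for (i in seq_len(f$n_uorf)) place_random(elem_uorf(f$uorf_codons), "uorf", hi = hi_bulk)
  for (i in seq_len(f$n_hairpin)) place_random(elem_hairpin(f$hairpin_stem), "hairpin", hi = hi_bulk)
  for (h in f$hexamers) place_random(toupper(h), "hexamer", hi = hi_bulk)

  if (length(failed)) {
    abort(paste0("sequence too short to host requested features: ",
                 paste(unique(failed), collapse = ", ")))
  }

  out <- paste(chars, collapse = "")
  planted_tbl <- if (length(planted)) list_rbind(planted) else
    tibble(type = character(), start0 = integer(), length = integer(),
           element = character())

  # verify AUG inventory; break boundary-formed AUGs on the background side
  expected <- sort(c(
    planted_tbl$start0[planted_tbl$type %in% c("uorf", "uaug_in", "uaug_out")]))
  hits <- str_locate_all(out, "ATG")[[1]][, 1] - 1L
  extra <- setdiff(hits, expected)
  if (length(extra)) {
    el_pos <- unlist(map2(planted_tbl$start0 + 1L,
                          planted_tbl$start0 + planted_tbl$length,
                          function(a, b) a:b))
    for (p in extra) {
      cand <- setdiff((p + 1L):(p + 3L), el_pos)
      if (!length(cand)) abort("internal: boundary AUG inside two elements")
      chars[cand[1]] <- "C"
    }
    out <- paste(chars, collapse = "")
    if (length(setdiff(str_locate_all(out, "ATG")[[1]][, 1] - 1L, expected))) {
      abort("internal: failed to remove boundary AUG")
    }
  }
  if (!setequal(str_locate_all(out, "ATG")[[1]][, 1] - 1L, expected)) {
    abort("internal: planted AUG inventory mismatch")
  }
  attr(out, "planted") <- planted_tbl
  out
}
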