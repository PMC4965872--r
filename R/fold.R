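# RNA secondary-structure energies for 5'UTR windows.
#
# Two engines: "vienna" shells out to the RNAfold binary (partition function
# on, 37 C) and returns true thermodynamic MFE and ensemble free energy;
# "builtin" is a self-contained stacking-weighted base-pair maximisation DP
# (GC -3, AU -2, GU -1 kcal/mol-ish weights, minimum hairpin loop 3,
# -1 stacking bonus) that preserves relative stability ordering and needs no
# external program, but whose absolute values should not be read against
# literature kcal/mol cutoffs. "auto" prefers vienna when RNAfold is on the
# PATH.

vienna_available <- function() nzchar(Sys.which("RNAfold"))

resolve_engine <- function(engine = c("auto", "vienna", "builtin")) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    if (vienna_available()) "vienna" else "builtin"
  } else if (engine == "vienna" && !vienna_available()) {
    abort("RNAfold binary not found on PATH; use engine = \"builtin\"")
  } else {
    engine
  }
}

# fold a character vector of sequences with RNAfold; returns tibble(mfe, efe)
fold_vienna <- function(seqs, temperature = 37) {
  fa <- as.vector(rbind(paste0(">s", seq_along(seqs)), toupper(seqs)))
  old <- setwd(tempdir()); on.exit(setwd(old), add = TRUE)
  out <- suppressWarnings(system2(
    "RNAfold", c("-p", "--noPS", "--noDP", "-T", format(temperature)),
    input = fa, stdout = TRUE, stderr = FALSE))
  mfe <- rep(NA_real_, length(seqs)); efe <- rep(NA_real_, length(seqs))
  idx <- 0L
  for (line in out) {
    if (startsWith(line, ">")) { idx <- idx + 1L; next }
    m <- regmatches(line, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", line))[[1]]
    if (length(m) == 2 && idx > 0) mfe[idx] <- as.numeric(m[2])
    e <- regmatches(line, regexec("\\[\\s*(-?[0-9.]+)\\]\\s*$", line))[[1]]
    if (length(e) == 2 && idx > 0) efe[idx] <- as.numeric(e[2])
  }
  tibble(mfe = mfe, efe = efe)
}

# stacking-weighted Nussinov-style minimum "energy"; O(n^3), fine for 50-mers
builtin_mfe_one <- function(seq) {
  s <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  if (n < 5L) return(0)
  pairw <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
    0
  }
  W <- matrix(0, n, n)
  for (len in 5:n) {
    for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      best <- W[i, j - 1]
      pw <- pairw(s[i], s[j])
      if (pw < 0) {
        inner <- if (j - 1 >= i + 1) W[i + 1, j - 1] else 0
        stack <- if (j - 2 >= i + 2 && pairw(s[i + 1], s[j - 1]) < 0) -1 else 0
        best <- min(best, inner + pw + stack)
      }
      if (len > 2) {
        k <- (i + 1):(j - 1)
        split_best <- min(W[i, k] + W[cbind(k + 1, j)])
        best <- min(best, split_best)
      }
      # pairing j with an interior k
      W[i, j] <- best
    }
  }
  W[1, n]
}

fold_builtin <- function(seqs) {
  tibble(mfe = vapply(seqs, builtin_mfe_one, numeric(1), USE.NAMES = FALSE),
         efe = NA_real_)
}

#' Fold 5'UTR windows and flag stable secondary structure
#'
#' The cap window is the first `window` nt (shorter UTRs are folded whole);
#' downstream windows of the same width slide at `step`-nt intervals over
#' the region beyond the cap window. Stability flags use strict-inequality
#' thresholds on the MFE in kcal/mol (meaningful with the vienna engine;
#' defaults -30 for the cap window and -35 for downstream windows). The
#' ensemble free energy is returned where the engine computes a partition
#' function (vienna) and is always <= the MFE.
#'
#' @param utr 5'UTR sequence (A/C/G/T/U).
#' @param engine `"auto"`, `"vienna"` or `"builtin"`.
#' @param window Window width in nt (default 50).
#' @param step Slide step for downstream windows (default 10 nt; 1 gives
#'   every offset).
#' @param cap_thresh,window_thresh Stability cutoffs (kcal/mol).
#' @param temperature Folding temperature in Celsius (vienna engine).
#' @return One-row tibble: `cap_mfe`, `cap_efe`, `min_mfe`, `min_efe`
#'   (minimum over downstream windows; `NA` when there are none),
#'   `cap_stable`, `downstream_stable`.
#' @export
fold_windows <- function(utr, engine = "auto", window = 50, step = 10,
                         cap_thresh = -30, window_thresh = -35,
                         temperature = 37) {
  eng <- resolve_engine(engine)
  s <- as_dna(utr)
  L <- nchar(s)
  cap <- substr(s, 1, min(window, L))
  starts <- if (L >= window + window) seq(window + 1, L - window + 1, by = step) else integer(0)
  wins <- vapply(starts, function(i) substr(s, i, i + window - 1), character(1))
  res <- if (eng == "vienna") fold_vienna(c(cap, wins), temperature) else
    fold_builtin(c(cap, wins))
  capr <- res[1, ]
  dw <- res[-1, , drop = FALSE]
  min_mfe <- if (nrow(dw)) suppressWarnings(min(dw$mfe, na.rm = TRUE)) else NA_real_
  if (!is.na(min_mfe) && !is.finite(min_mfe)) min_mfe <- NA_real_
  min_efe <- if (nrow(dw) && any(is.finite(dw$efe))) min(dw$efe, na.rm = TRUE) else NA_real_
  tibble(cap_mfe = capr$mfe, cap_efe = capr$efe,
         min_mfe = min_mfe, min_efe = min_efe,
         cap_stable = !is.na(capr$mfe) & capr$mfe < cap_thresh,
         downstream_stable = !is.na(min_mfe) & min_mfe < window_thresh)
}

#' Fold many sequences' cap windows in one engine call
#'
#' Batch counterpart of the cap-window part of [fold_windows()], used when
#' scoring hundreds of isoforms (one RNAfold process instead of one per
#' sequence).
#'
#' @param seqs Character vector of 5'UTR sequences (`NA`s allowed).
#' @inheritParams fold_windows
#' @return Tibble with `cap_mfe`, `cap_efe`, `cap_stable` per input.
#' @export
fold_cap_windows <- function(seqs, engine = "auto", window = 50,
                             cap_thresh = -30, temperature = 37) {
  eng <- resolve_engine(engine)
  ok <- !is.na(seqs) & nchar(seqs) >= 5
  caps <- substr(as.character(seqs[ok]), 1, window)
  res <- if (!any(ok)) tibble(mfe = numeric(0), efe = numeric(0))
  else if (eng == "vienna") fold_vienna(caps, temperature) else fold_builtin(caps)
  out <- tibble(cap_mfe = rep(NA_real_, length(seqs)),
                cap_efe = rep(NA_real_, length(seqs)))
  out$cap_mfe[ok] <- res$mfe; out$cap_efe[ok] <- res$efe
  out$cap_stable <- !is.na(out$cap_mfe) & out$cap_mfe < cap_thresh
  out
}
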