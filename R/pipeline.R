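# End-to-end study driver: from tag tables to feature-level models.

#' Quantify isoform counts from called clusters
#'
#' Assigns reproducible clusters to genes, keeps the gross-5'UTR classes
#' (annotated 5'UTR and 1 kb upstream), names isoforms within each gene by
#' decreasing 5'UTR length, and counts raw tags per cluster, replicate and
#' fraction.
#'
#' @param clusters Reproducible cluster tibble (e.g. from [idr_filter()]).
#' @param tags Raw tag tibble.
#' @param annotation Gene annotation tibble (see [assign_region()]).
#' @return List with `isoforms` (cluster-to-isoform map incl. `utr_length` =
#'   summit-to-start-codon genomic span) and `counts` (long count table).
#' @export
quantify_isoforms <- function(clusters, tags, annotation) {
  assigned <- assign_region(clusters, annotation) |>
    filter(.data$region %in% c("utr5", "up1kb"))
  if (nrow(assigned) == 0L) abort("no clusters in gross 5'UTR regions")
  iso <- assigned |>
    left_join(select(annotation, "gene", "start_codon", "orf_length"),
              by = "gene") |>
    mutate(utr_length = ifelse(.data$strand == "+",
                               .data$start_codon - .data$summit,
                               .data$summit - .data$start_codon)) |>
    filter(.data$utr_length > 0) |>
    group_by(.data$gene) |>
    arrange(dplyr::desc(.data$utr_length), .by_group = TRUE) |>
    mutate(isoform = sprintf("%s.c%d", .data$gene, dplyr::row_number())) |>
    ungroup()
  counts <- count_cluster_tags(iso, tags) |>
    left_join(select(iso, "cluster", "gene", "isoform", "utr_length"),
              by = "cluster")
  list(isoforms = iso, counts = counts)
}

#' Reconstruct 5'UTRs and extract features for quantified isoforms
#'
#' @param isoforms Isoform map from [quantify_isoforms()] (needs `summit`,
#'   `start_codon`, `chrom`, `strand`, `gene`, `isoform`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param junctions Junction tibble (`chrom`, `strand`, `donor0`,
#'   `acceptor0`, `status`, `reads_splicein`, `reads_spliceout`).
#' @param engine Folding engine for cap windows.
#' @return `isoforms` with `utr_status`, `utr_seq`, `mature_length`,
#'   `n_uorf`, `n_uaug_in`, `n_uaug_out`, `has_top`, `cap_mfe`, `cap_efe`,
#'   `cap_stable` columns.
#' @export
isoform_utr_features <- function(isoforms, genome, junctions, engine = "auto") {
  ev <- if (!is.null(junctions) && nrow(junctions)) compute_psi(junctions) else NULL
  rec <- purrr::pmap(
    list(isoforms$summit, isoforms$start_codon, isoforms$chrom, isoforms$strand),
    function(tss, sc, ch, st) {
      e <- if (!is.null(ev)) filter(ev, .data$chrom == ch, .data$strand == st) else NULL
      tryCatch(reconstruct_utr(tss, sc, genome, ch, strand = st, events = e),
               error = function(err) tibble(status = "error",
                                            utr_seq = NA_character_,
                                            utr_length = NA_integer_,
                                            segments = list(NULL)))
    }) |> list_rbind()
  out <- isoforms |>
    mutate(utr_status = rec$status, utr_seq = rec$utr_seq,
           mature_length = rec$utr_length)
  seq_feats <- map(out$utr_seq, function(s) {
    if (is.na(s)) tibble(n_uorf = NA_integer_, n_uaug_in = NA_integer_,
                         n_uaug_out = NA_integer_)
    else find_uorfs(s)
  }) |> list_rbind()
  caps <- fold_cap_windows(out$utr_seq, engine = engine)
  out |>
    bind_cols(seq_feats) |>
    mutate(has_top = map_lgl(.data$utr_seq,
                             ~ if (is.na(.x)) NA else detect_top(.x))) |>
    bind_cols(caps)
}

#' Assemble per-pair divergent-region features
#'
#' @param pairs Pair tibble from [te_divergence_test()].
#' @param features Isoform feature tibble from [isoform_utr_features()].
#' @param engine Folding engine for divergent-region windows.
#' @param window,step Sliding-window parameters over the divergent region.
#' @param window_thresh Stability cutoff for divergent-region windows.
#' @return Pair tibble with `log2fc` (replicate mean), `delta_length`,
#'   divergent-region feature columns and `divergent_seq`.
#' @export
pair_divergent_features <- function(pairs, features, engine = "auto",
                                    window = 50, step = 10,
                                    window_thresh = -35) {
  f <- features |> select("isoform", "utr_status", "utr_seq", "mature_length",
                          "has_top", "cap_stable", "cap_mfe")
  d <- pairs |>
    left_join(f, by = c("distal" = "isoform")) |>
    left_join(f, by = c("proximal" = "isoform"), suffix = c("_long", "_short")) |>
    filter(.data$utr_status_long == "resolved",
           .data$utr_status_short == "resolved")
  div <- purrr::map2(d$utr_seq_long, d$utr_seq_short, divergent_region) |>
    list_rbind()
  d <- bind_cols(d, div) |> filter(.data$ok)
  if (nrow(d) == 0L) abort("no pairs with a resolvable divergent region")
  dist <- nchar(d$utr_seq_short)
  divf <- purrr::map2(d$divergent_seq, dist,
                      function(s, ds) find_uorfs(s, dist_to_start = ds)) |>
    list_rbind()
  names(divf) <- paste0(names(divf), "_div")
  # sliding-window stability over the divergent region
  eng <- resolve_engine(engine)
  win_of <- function(s) {
    L <- nchar(s)
    if (L < 10) return(character(0))
    if (L <= window) return(s)
    starts <- unique(c(seq(1, L - window + 1, by = step), L - window + 1))
    vapply(starts, function(i) substr(s, i, i + window - 1), character(1))
  }
  wins <- map(d$divergent_seq, win_of)
  all_w <- unlist(wins)
  wmfe <- if (length(all_w)) {
    if (eng == "vienna") fold_vienna(all_w)$mfe else fold_builtin(all_w)$mfe
  } else numeric(0)
  idx <- rep(seq_along(wins), lengths(wins))
  min_mfe <- vapply(seq_len(nrow(d)), function(i) {
    v <- wmfe[idx == i]
    if (length(v)) min(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  reps <- as.integer(sub("^log2fc_rep", "",
                         grep("^log2fc_rep", names(d), value = TRUE)))
  fc <- rowMeans(as.matrix(d[paste0("log2fc_rep", reps)]))
  d |>
    mutate(log2fc = fc,
           delta_length = nchar(.data$utr_seq_long) - nchar(.data$utr_seq_short),
           div_min_mfe = min_mfe,
           div_struct = !is.na(min_mfe) & min_mfe < window_thresh,
           delta_top = as.integer(.data$has_top_long) -
             as.integer(.data$has_top_short),
           delta_cap_stable = as.integer(.data$cap_stable_long) -
             as.integer(.data$cap_stable_short)) |>
    bind_cols(divf) |>
    mutate(has_uorf_div = .data$n_uorf_div > 0)
}

#' Build the MARS design matrix from pair features
#'
#' @param pair_features Tibble from [pair_divergent_features()] (typically
#'   restricted to significant pairs).
#' @param sig_hexamers Character vector of hexamers to include as
#'   divergent-region presence indicators (e.g. the BH-significant scan
#'   hits).
#' @return List with `x` (data frame), `y` (response = replicate-mean log2
#'   TE fold change) and `groups` (for [variance_decomposition()]).
#' @export
build_design_matrix <- function(pair_features, sig_hexamers = character(0)) {
  x <- tibble(
    delta_length = pair_features$delta_length,
    n_uorf = pair_features$n_uorf_div,
    n_uaug_out = pair_features$n_uaug_out_div,
    n_uaug_in = pair_features$n_uaug_in_div,
    delta_top = pair_features$delta_top,
    cap_structure = pair_features$delta_cap_stable,
    div_structure = as.integer(pair_features$div_struct))
  groups <- setNames(as.list(names(x)), names(x))
  if (length(sig_hexamers)) {
    hm <- hexamer_matrix(pair_features$divergent_seq) > 0
    hx <- intersect(sig_hexamers, colnames(hm))
    if (length(hx)) {
      hxm <- as.data.frame(hm[, hx, drop = FALSE] * 1L)
      names(hxm) <- paste0("hex_", hx)
      x <- bind_cols(x, hxm)
      groups$hexamers <- names(hxm)
    }
  }
  keep <- complete.cases(x) & is.finite(pair_features$log2fc)
  list(x = as.data.frame(x[keep, ]), y = pair_features$log2fc[keep],
       groups = groups)
}

#' Run the full synthetic-study analysis
#'
#' Calls TSS clusters per replicate, filters for reproducibility, assigns
#' clusters to genes, normalizes by spike-ins, bootstrap-tests TE
#' divergence of every isoform pair, reconstructs 5'UTRs under the PSI
#' rules, extracts cis-element features, runs the association battery, and
#' fits the MARS variance decomposition on significant pairs.
#'
#' @param sim A [simulate_dataset()] result (or a list with the same
#'   elements read from files).
#' @param B Bootstrap replicates per pair (default 1000).
#' @param idr_mode `"idr"` or `"fallback"` cluster reproducibility filter.
#' @param engine Folding engine.
#' @param seed Integer seed for bootstrap/permutation/matching stages.
#' @param p_thresh,fc_thresh Significance thresholds.
#' @param run_hexamer_scan,run_model Stage toggles.
#' @return List with `clusters`, `isoforms`, `counts`, `size_factors`,
#'   `pairs`, `fdr`, `features`, `pair_features`, `assoc`, `design`,
#'   `model`, `decomposition`.
#' @export
run_te_study <- function(sim, B = 1000, idr_mode = c("idr", "fallback"),
                         engine = "auto", seed = 1L, p_thresh = 0.01,
                         fc_thresh = 1.5, run_hexamer_scan = TRUE,
                         run_model = TRUE) {
  idr_mode <- match.arg(idr_mode)
  reps <- sort(unique(sim$tags$replicate))
  cl_by_rep <- map(reps, function(r)
    call_tss_clusters(filter(sim$tags, .data$replicate == r),
                      coverage = sim$coverage))
  clusters <- if (length(reps) >= 2) {
    idr_filter(cl_by_rep[[1]], cl_by_rep[[2]], mode = idr_mode)
  } else {
    cl_by_rep[[1]]
  }
  quant <- quantify_isoforms(clusters, sim$tags, sim$annotation)
  sf <- spike_factors(sim$spikes)
  counts_norm <- normalize_counts(quant$counts, sf)
  orf <- select(sim$annotation, "gene", "orf_length")
  pairs <- te_divergence_test(quant$counts, orf, size_factors = sf, B = B,
                              p_thresh = p_thresh, fc_thresh = fc_thresh,
                              seed = seed)
  fdr <- permutation_fdr(pairs, fc_thresh = fc_thresh, p_thresh = p_thresh,
                         seed = seed)
  features <- isoform_utr_features(quant$isoforms, sim$genome, sim$junctions,
                                   engine = engine)
  pf <- pair_divergent_features(pairs, features, engine = engine)

  # association battery --------------------------------------------------
  assoc <- list()
  with_u <- filter(pf, .data$has_uorf_div)
  without_u <- filter(pf, !.data$has_uorf_div)
  if (nrow(with_u) >= 3 && nrow(without_u) >= 3) {
    m <- match_length_diff(with_u, without_u, seed = seed)
    assoc$uorf <- group_compare(m$a$log2fc, m$b$log2fc)
    assoc$uorf_dose <- tryCatch(uorf_dose_response(pf), error = function(e) NULL)
  }
  sig_pf <- filter(pf, .data$significant)
  if (nrow(sig_pf) >= 4 && dplyr::n_distinct(sig_pf$has_uorf_div) > 1 &&
      dplyr::n_distinct(sig_pf$direction) > 1) {
    assoc$uorf_fisher <- tryCatch(
      fisher_direction_enrichment(sig_pf, "has_uorf_div"),
      error = function(e) NULL)
  }
  with_s <- filter(pf, .data$div_struct | .data$delta_cap_stable > 0)
  without_s <- filter(pf, !(.data$div_struct | .data$delta_cap_stable > 0))
  if (nrow(with_s) >= 3 && nrow(without_s) >= 3) {
    m <- match_length_diff(with_s, without_s, seed = seed)
    assoc$structure <- group_compare(m$a$log2fc, m$b$log2fc)
  }
  iso_te_tbl <- te_quantify(counts_norm, orf) |>
    group_by(.data$gene, .data$isoform) |>
    summarise(te = mean(.data$te), total = mean(.data$total),
              .groups = "drop") |>
    left_join(select(features, "isoform", "has_top"), by = "isoform") |>
    filter(!is.na(.data$has_top))
  assoc$top <- tryCatch(top_comparison(iso_te_tbl, seed = seed),
                        error = function(e) NULL)
  hx <- if (run_hexamer_scan && nrow(pf) >= 20) {
    hexamer_scan(pf, seed = seed)
  } else NULL
  assoc$hexamers <- hx

  # quantitative model ---------------------------------------------------
  model <- NULL; decomp <- NULL; design <- NULL
  if (run_model) {
    sig_hex <- if (!is.null(hx) && nrow(hx)) hx$hexamer[hx$padj < 0.01] else character(0)
    base <- if (nrow(sig_pf) > 30) sig_pf else pf
    design <- build_design_matrix(base, sig_hexamers = sig_hex)
    if (length(design$y) > 10) {
      model <- mars_fit(design$x, design$y)
      decomp <- tryCatch(
        variance_decomposition(design$x, design$y, groups = design$groups),
        error = function(e) NULL)
    }
  }
  list(clusters = clusters, isoforms = quant$isoforms, counts = counts_norm,
       size_factors = sf, pairs = pairs, fdr = fdr, features = features,
       pair_features = pf, assoc = assoc, design = design, model = model,
       decomposition = decomp)
}
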