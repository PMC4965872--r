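# Full synthetic polysome 5'-end sequencing study with ground truth.

# sample per-isoform fraction counts for one replicate:
# copies are partitioned over fractions by the censored-Poisson load map.
sample_fraction_counts <- function(n_copies, lambda) {
  as.integer(rmultinom(1, n_copies, fraction_probs(lambda)[1, ]))
}

# scatter `count` tags geometrically downstream of a TSS; returns a list of
# offset/count vectors. scatter is the mean offset in nt.
scatter_offsets <- function(count, scatter, max_offset = 50L) {
  if (count == 0L) return(list(offset = integer(0), count = integer(0)))
  if (scatter <= 0) return(list(offset = 0L, count = as.integer(count)))
  off <- pmin(rgeom(count, 1 / (1 + scatter)), max_offset)
  tab <- tabulate(off + 1L, nbins = max_offset + 1L)
  keep <- which(tab > 0L)
  list(offset = keep - 1L, count = tab[keep])
}

#' Simulate a complete polysome-fractionated 5'-end sequencing study
#'
#' Generates, per gene on its own contig: a T-free 5'UTR block hosting 1-3
#' TSS isoforms with planted cis-elements (or one splice event), a CDS, and
#' flanking sequence; then, per replicate, per-fraction tag counts obtained
#' by partitioning each isoform's copies over the seven gradient fractions
#' according to its (feature-penalised) mean ribosome load, with geometric
#' positional scatter, uniform background tags, and per-fraction library
#' distortions that the spike-in table lets the pipeline undo. Ground truth
#' for every quantity is returned alongside.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `annotation`, `tags`, `spikes`,
#'   `coverage`, `junctions` (tibbles), `truth` (list of tibbles: `isoforms`,
#'   `genes`, `events`, `spike_factors`), and `config`. All genomic
#'   coordinates are 0-based, half-open.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  reps <- seq_len(cfg$n_replicates)

  genes <- list(); isoforms <- list(); events <- list()
  tags <- list(); coverage <- list(); seqs <- character(cfg$n_genes)
  contigs <- sprintf("ctg%04d", seq_len(cfg$n_genes))

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", g)
    chrom <- contigs[g]
    strand <- if (runif(1) < cfg$minus_strand_prob) "-" else "+"
    n_tss <- sample(1:3, 1, prob = cfg$tss_per_gene)

    # ascending 5'UTR lengths with >= 48 nt divergent segments
    lr <- cfg$utr_length_range
    u <- sort(round(runif(n_tss, lr[1], lr[2])))
    if (n_tss > 1) for (k in 2:n_tss) u[k] <- max(u[k], u[k - 1] + 48)
    if (u[n_tss] > lr[2]) u <- pmax(u - (u[n_tss] - lr[2]), c(40, 88, 136)[seq_len(n_tss)])
    Lmax <- u[n_tss]

    # one splice event (shared segment) XOR planted features (divergent segments)
    has_splice <- runif(1) < cfg$splice_prob && u[1] >= 120
    utr <- random_utr_background(Lmax)
    plant_truth <- vector("list", n_tss)

    if (!has_splice) {
      # iterate isoforms shortest (1) .. longest (n); divergent segment of
      # isoform k (k >= 2) is [Lmax-u[k], Lmax-u[k-1]) in 0-based UTR coords
      pp <- cfg$feature_plant_probs
      for (k in seq_len(n_tss)) {
        if (k == 1L) {
          # only a cap TOP can be planted in the shared segment
          if (runif(1) < pp["top"]) {
            lo <- Lmax - u[1]
            sub <- substr(utr, lo + 1, Lmax)
            sub2 <- plant_utr_features(sub, list(top = TRUE))
            utr <- paste0(substr(utr, 1, lo), sub2)
            plant_truth[[1]] <- attr(sub2, "planted") |> mutate(start0 = .data$start0 + lo)
          }
          next
        }
        lo <- Lmax - u[k]; hi <- Lmax - u[k - 1]
        feats <- list(
          n_uorf = if (runif(1) < pp["uorf"]) sample(1:3, 1, prob = c(.6, .3, .1)) else 0L,
          n_uaug_out = if (runif(1) < pp["uaug_out"]) 1L else 0L,
          n_uaug_in = if (runif(1) < pp["uaug_in"]) 1L else 0L,
          top = runif(1) < pp["top"],
          n_hairpin = if (runif(1) < pp["hairpin"]) 1L else 0L,
          hexamers = if (runif(1) < pp["hexamer"]) cfg$effect_hexamer else character(0)
        )
        feats <- prune_to_capacity(feats, hi - lo)
        sub <- substr(utr, lo + 1, hi)
        sub2 <- plant_utr_features(sub, feats, dist_to_start = u[k - 1])
        utr <- paste0(substr(utr, 1, lo), sub2, substr(utr, hi + 1, Lmax))
        plant_truth[[k]] <- attr(sub2, "planted") |> mutate(start0 = .data$start0 + lo)
      }
    }
    # neutralize cap sites that did not receive a TOP (background first base
    # is only forced at UTR position 1)
    planted_all <- list_rbind(purrr::compact(plant_truth))
    for (k in seq_len(n_tss)) {
      cap0 <- Lmax - u[k]
      has_cap_top <- nrow(planted_all) > 0 &&
        any(planted_all$type == "top" & planted_all$start0 == cap0)
      if (!has_cap_top && substr(utr, cap0 + 1, cap0 + 1) == "C") {
        substr(utr, cap0 + 1, cap0 + 1) <- "G"
      }
    }

    # splice event in the shared segment
    ev <- NULL
    if (has_splice) {
      ilen <- round(runif(1, 60, min(150, u[1] - 40)))
      istart <- round(runif(1, Lmax - u[1] + 15, Lmax - 15 - ilen))  # 0-based
      type <- sample(names(cfg$splice_type_probs), 1, prob = cfg$splice_type_probs)
      status <- switch(type, removed = "annotated-constitutive",
                       retained = "novel", ambiguous = "annotated-alternative")
      true_psi <- switch(type, removed = 0, retained = 1, ambiguous = 0.5)
      base <- 4 * cfg$rnaseq_depth
      reads_in <- switch(type, removed = 0L, retained = rpois(1, 2 * base),
                         ambiguous = rpois(1, base))
      reads_out <- switch(type, removed = rpois(1, 2 * base), retained = 0L,
                          ambiguous = rpois(1, base))
      ev <- list(type = type, status = status, true_psi = true_psi,
                 istart = istart, iend = istart + ilen,
                 reads_in = reads_in, reads_out = reads_out)
    }

    # CDS and contig assembly (transcript orientation first)
    n_codons <- round(runif(1, cfg$cds_length_range[1], cfg$cds_length_range[2]) / 3)
    sense <- setdiff(mkCodons(), c("TAA", "TAG", "TGA"))
    cds <- paste0("ATG", paste(sample(sense, n_codons, TRUE), collapse = ""), "TAA")
    orf_length <- nchar(cds)
    pad5 <- paste(sample(c("A", "C", "G", "T"), 1250, TRUE), collapse = "")
    pad3 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    tcontig <- paste0(pad5, utr, cds, pad3)
    Lc <- nchar(tcontig)
    P0 <- 1250L                      # t-coord of UTR block start
    S0 <- P0 + Lmax                  # t-coord of main ATG 'A'
    t2g_pos <- function(p) if (strand == "+") p else Lc - 1L - p
    t2g_iv <- function(s, e) if (strand == "+") c(s, e) else c(Lc - e, Lc - s)
    seqs[g] <- if (strand == "+") tcontig else revcomp(tcontig)

    # per-isoform truth and counts
    lam_g <- runif(1, cfg$lambda_range[1], cfg$lambda_range[2])
    iso_rows <- list()
    for (k in seq_len(n_tss)) {
      iso_id <- sprintf("%s.i%d", gene_id, k)
      cap0 <- Lmax - u[k]
      own <- if (nrow(planted_all) > 0) filter(planted_all, .data$start0 >= cap0) else planted_all
      nf <- c(
        uorf = sum(own$type == "uorf"),
        uaug_out = sum(own$type == "uaug_out"),
        uaug_in = sum(own$type == "uaug_in"),
        top = as.integer(any(own$type == "top" & own$start0 == cap0)),
        hairpin = sum(own$type == "hairpin"),
        hexamer = sum(own$type == "hexamer")
      )
      lam <- min(lam_g * prod(cfg$effect_sizes^nf), 12)
      abundance <- max(1L, round(rlnorm(1, cfg$abundance_meanlog, cfg$abundance_sdlog)))
      # mature UTR truth
      mat_seq <- substr(utr, cap0 + 1, Lmax)
      excluded <- FALSE
      if (!is.null(ev)) {
        if (ev$type == "removed") {
          rel_s <- ev$istart - cap0; rel_e <- ev$iend - cap0
          mat_seq <- paste0(substr(mat_seq, 1, rel_s), substr(mat_seq, rel_e + 1, nchar(mat_seq)))
        } else if (ev$type == "ambiguous") {
          excluded <- TRUE
        }
      }
      tss_g <- t2g_pos(P0 + cap0)
      iso_rows[[k]] <- tibble(
        gene = gene_id, isoform = iso_id, chrom = chrom, strand = strand,
        tss = tss_g, utr_length = u[k], mature_utr_length = nchar(mat_seq),
        abundance = abundance, lambda = lam,
        expected_load = expected_ribosome_load(lam),
        n_uorf = nf[["uorf"]], n_uaug_out = nf[["uaug_out"]],
        n_uaug_in = nf[["uaug_in"]], has_top = nf[["top"]] == 1L,
        n_hairpin = nf[["hairpin"]], n_hexamer = nf[["hexamer"]],
        utr_seq = if (excluded) NA_character_ else mat_seq,
        excluded = excluded
      )
      # tags per replicate / fraction (plain vectors; one tibble at the end)
      for (r in reps) {
        cts <- sample_fraction_counts(abundance, lam)
        emit <- as.integer(round(cts * cfg$spike_factors[, r]))
        for (j in which(emit > 0L)) {
          sc <- scatter_offsets(emit[j], cfg$tag_scatter)
          gpos <- if (strand == "+") t2g_pos(P0 + cap0) + sc$offset
                  else t2g_pos(P0 + cap0) - sc$offset
          n <- length(gpos)
          tags[[length(tags) + 1L]] <- list(
            chrom = rep(chrom, n), pos = gpos, strand = rep(strand, n),
            replicate = rep(r, n), fraction = rep(j, n), count = sc$count)
        }
      }
    }
    isoforms[[g]] <- list_rbind(iso_rows)

    # background tags on the gene strand
    if (cfg$background_rate > 0) {
      for (r in reps) for (j in FRACTION_IDS) {
        nbg <- rpois(1, cfg$background_rate * Lc)
        if (nbg > 0L) {
          pos <- sample.int(Lc, nbg, replace = TRUE) - 1L
          tb <- table(pos)
          n <- length(tb)
          tags[[length(tags) + 1L]] <- list(
            chrom = rep(chrom, n), pos = as.integer(names(tb)),
            strand = rep(strand, n), replicate = rep(r, n),
            fraction = rep(j, n), count = as.integer(tb))
        }
      }
    }

    # gene annotation (annotated TSS = shortest isoform; most-3' start codon)
    ann_tss_g <- t2g_pos(P0 + Lmax - u[1])
    start_codon_g <- t2g_pos(S0)
    cds_iv <- t2g_iv(S0, S0 + orf_length)
    gene_iv <- t2g_iv(P0 + Lmax - u[n_tss], S0 + orf_length)
    genes[[g]] <- tibble(
      gene = gene_id, chrom = chrom, strand = strand,
      ann_tss = ann_tss_g, start_codon = start_codon_g,
      orf_length = orf_length,
      cds_lo = cds_iv[1], cds_hi = cds_iv[2],
      gene_lo = gene_iv[1], gene_hi = gene_iv[2],
      contig_length = Lc
    )
    # RNA-seq coverage over the transcribed span
    cov_iv <- t2g_iv(P0 + Lmax - u[n_tss], S0 + orf_length)
    coverage[[g]] <- tibble(chrom = chrom, start = cov_iv[1], end = cov_iv[2],
                            depth = cfg$rnaseq_depth)
    if (!is.null(ev)) {
      iv <- t2g_iv(ev$istart + P0, ev$iend + P0)
      events[[length(events) + 1L]] <- tibble(
        gene = gene_id, chrom = chrom, strand = strand,
        donor0 = iv[1], acceptor0 = iv[2], status = ev$status,
        reads_splicein = ev$reads_in, reads_spliceout = ev$reads_out,
        true_psi = ev$true_psi, type = ev$type)
    }
  }

  # spike-in table
  spike <- expand_grid(cluster = sprintf("spk%03d", seq_len(cfg$n_spike_clusters)),
                       replicate = reps, fraction = FRACTION_IDS)
  base <- setNames(rlnorm(cfg$n_spike_clusters, cfg$spike_meanlog, cfg$spike_sdlog),
                   sprintf("spk%03d", seq_len(cfg$n_spike_clusters)))
  spike <- spike |>
    mutate(count = pmax(1L, as.integer(round(
      base[.data$cluster] * cfg$spike_factors[cbind(.data$fraction, .data$replicate)] *
        rlnorm(dplyr::n(), 0, cfg$spike_noise_sd)))))

  genome <- Biostrings::DNAStringSet(setNames(seqs, contigs))
  ev_tbl <- if (length(events)) list_rbind(events) else
    tibble(gene = character(), chrom = character(), strand = character(),
           donor0 = integer(), acceptor0 = integer(), status = character(),
           reads_splicein = integer(), reads_spliceout = integer(),
           true_psi = double(), type = character())

  tag_tbl <- tibble(
    chrom = unlist(lapply(tags, `[[`, "chrom")),
    pos = as.integer(unlist(lapply(tags, `[[`, "pos"))),
    strand = unlist(lapply(tags, `[[`, "strand")),
    replicate = as.integer(unlist(lapply(tags, `[[`, "replicate"))),
    fraction = as.integer(unlist(lapply(tags, `[[`, "fraction"))),
    count = as.integer(unlist(lapply(tags, `[[`, "count"))))

  structure(list(
    genome = genome,
    annotation = list_rbind(genes),
    tags = tag_tbl,
    spikes = spike,
    coverage = list_rbind(coverage),
    junctions = select(ev_tbl, "gene", "chrom", "strand", "donor0",
                       "acceptor0", "status", "reads_splicein", "reads_spliceout"),
    truth = list(
      isoforms = list_rbind(isoforms),
      genes = list_rbind(genes),
      events = ev_tbl,
      spike_factors = as_tibble(cfg$spike_factors) |>
        mutate(fraction = FRACTION_IDS) |>
        pivot_longer(-"fraction", names_to = "replicate", values_to = "factor") |>
        mutate(replicate = as.integer(sub("rep", "", .data$replicate)))
    ),
    config = cfg
  ), class = "sim_dataset")
}

# drop planted features that cannot fit a segment of `len` nt, cheapest
# features kept first; footprints include the 2-nt placement margins
prune_to_capacity <- function(feats, len) {
  budget <- len - 20L  # slack for placement margins and frame constraints
  cost <- function(f) {
    (if (isTRUE(f$top)) 12L else 0L) + f$n_uorf * 20L + f$n_hairpin * 52L +
      length(f$hexamers) * 10L + (f$n_uaug_out + f$n_uaug_in) * 10L
  }
  # drop in order of bulk until it fits
  while (cost(feats) > budget) {
    if (feats$n_hairpin > 0L) feats$n_hairpin <- feats$n_hairpin - 1L
    else if (feats$n_uorf > 1L) feats$n_uorf <- feats$n_uorf - 1L
    else if (length(feats$hexamers)) feats$hexamers <- feats$hexamers[-1]
    else if (feats$n_uaug_in > 0L) feats$n_uaug_in <- 0L
    else if (feats$n_uaug_out > 0L) feats$n_uaug_out <- 0L
    else if (feats$n_uorf > 0L) feats$n_uorf <- 0L
    else if (isTRUE(feats$top)) feats$top <- FALSE
    else break
  }
  feats
}

mkCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits genome FASTA, tag/spike/junction/annotation/truth TSVs and an
#' RNA-seq coverage bedGraph under `dir`. All coordinates 0-based half-open.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  readr::write_tsv(sim$tags, file.path(dir, "tags.tsv"))
  readr::write_tsv(sim$spikes, file.path(dir, "spikes.tsv"))
  readr::write_tsv(sim$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$truth$isoforms, file.path(dir, "truth_isoforms.tsv"))
  readr::write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"))
  readr::write_tsv(sim$coverage, file.path(dir, "coverage.bedGraph"),
                   col_names = FALSE)
  invisible(dir)
}

#' Simulate fraction-count vectors for isoform pairs
#'
#' A light-weight generator for pair-level studies of the bootstrap test:
#' each pair gets two 7-fraction count vectors drawn multinomially from the
#' censored-Poisson load map, with either equal loads (null pairs) or
#' independently drawn loads, and an ORF-length ratio that spreads the
#' plug-in log2 TE fold changes.
#'
#' @param n_pairs Number of isoform pairs.
#' @param depth Expected tags per isoform (copies).
#' @param null If `TRUE` both isoforms share the same load and ORF length
#'   (true log2 TE fold change 0).
#' @param lambda_range Range of mean ribosome loads.
#' @param log2_length_ratio_range When not null, the log2 ORF-length ratio is
#'   uniform over this range (lengths shift TE but not bootstrap noise).
#' @param n_replicates Replicates with independent multinomial noise.
#' @param seed Integer seed.
#' @return Tibble with one row per pair/replicate: `pair`, `replicate`,
#'   list-columns `counts_a`, `counts_b`, lengths `len_a`, `len_b`, and the
#'   truth columns `lambda_a`, `lambda_b`, `true_log2fc`.
#' @export
simulate_pair_counts <- function(n_pairs, depth = 2000, null = FALSE,
                                 lambda_range = c(0.5, 10),
                                 log2_length_ratio_range = c(-2, 2),
                                 n_replicates = 2, seed = 1L) {
  set.seed(seed)
  lam_a <- runif(n_pairs, lambda_range[1], lambda_range[2])
  lam_b <- if (null) lam_a else runif(n_pairs, lambda_range[1], lambda_range[2])
  llr <- if (null) rep(0, n_pairs) else
    runif(n_pairs, log2_length_ratio_range[1], log2_length_ratio_range[2])
  len_a <- rep(600L, n_pairs)
  len_b <- as.integer(round(600 * 2^llr))
  true_fc <- log2(expected_ribosome_load(lam_a) / len_a) -
    log2(expected_ribosome_load(lam_b) / len_b)
  rows <- list()
  for (i in seq_len(n_pairs)) for (r in seq_len(n_replicates)) {
    rows[[length(rows) + 1L]] <- tibble(
      pair = i, replicate = r,
      counts_a = list(sample_fraction_counts(depth, lam_a[i])),
      counts_b = list(sample_fraction_counts(depth, lam_b[i])),
      len_a = len_a[i], len_b = len_b[i],
      lambda_a = lam_a[i], lambda_b = lam_b[i], true_log2fc = true_fc[i])
  }
  list_rbind(rows)
}
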