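# Simulation configuration.

#' Configuration for the synthetic polysome 5'-end sequencing study
#'
#' Bundles and validates every parameter of the data generator. Defaults
#' describe a deep two-replicate study of a few hundred genes: log-normal
#' isoform abundances around ~1,500 copies, per-gene mean ribosome loads
#' spread over the dynamic range of the gradient, mild geometric positional
#' scatter of cap tags, a low uniform background tag rate, and fixed
#' per-fraction library distortions that the spike-in normalization has to
#' undo.
#'
#' @param n_genes Number of genes (each on its own contig).
#' @param tss_per_gene Probabilities for 1, 2 or 3 TSSs per gene.
#' @param utr_length_range Bounds (nt) for 5'UTR lengths.
#' @param abundance_meanlog,abundance_sdlog Log-normal law for isoform copy
#'   numbers.
#' @param lambda_range Range of per-gene mean ribosome load (Poisson mean,
#'   right-censored at 12 per mRNA).
#' @param tag_scatter Mean geometric downstream offset (nt) of tag positions
#'   from the true TSS; 0 disables scatter.
#' @param background_rate Background tags per nt per fraction per replicate.
#' @param n_replicates Number of replicates (independent sampling noise,
#'   shared truth).
#' @param spike_factors 7 x `n_replicates` matrix of per-fraction library
#'   distortion factors applied multiplicatively to emitted counts.
#' @param n_spike_clusters,spike_meanlog,spike_sdlog,spike_noise_sd Spike-in
#'   cluster count model: log-normal baselines scaled by the same distortion
#'   factors with small multiplicative log-normal noise.
#' @param splice_prob Probability that a gene carries one splice event in the
#'   shared portion of its 5'UTR.
#' @param splice_type_probs Probabilities for the event being constitutively
#'   removed, constitutively retained, or ambiguous (0.1 < PSI < 0.9, which
#'   excludes the gene's isoforms from sequence-feature analyses).
#' @param feature_plant_probs Per-divergent-segment planting probabilities
#'   for uORFs, out-of-frame uAUGs, in-frame uAUGs, a 5' TOP tract, a stable
#'   GC hairpin, and the effect hexamer.
#' @param effect_sizes Multiplicative penalties on the isoform's mean
#'   ribosome load per planted feature copy (1 = no effect; a null study
#'   sets all entries to 1 while still planting features).
#' @param effect_hexamer The hexamer motif planted as a candidate regulatory
#'   element (must not contain ATG).
#' @param cds_length_range Bounds (nt) for CDS length (rounded to codons).
#' @param rnaseq_depth Constant RNA-seq coverage over the gene body.
#' @param minus_strand_prob Fraction of genes placed on the minus strand.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       tss_per_gene = c(`1` = 0.2, `2` = 0.6, `3` = 0.2),
                       utr_length_range = c(80, 600),
                       abundance_meanlog = log(1500),
                       abundance_sdlog = 0.6,
                       lambda_range = c(0.5, 10),
                       tag_scatter = 2,
                       background_rate = 0.002,
                       n_replicates = 2,
                       spike_factors = cbind(
                         rep1 = c(1.00, 1.18, 0.87, 1.30, 0.95, 1.12, 0.78),
                         rep2 = c(0.92, 1.05, 1.22, 0.81, 1.10, 0.97, 1.25)
                       )[, seq_len(n_replicates), drop = FALSE],
                       n_spike_clusters = 50,
                       spike_meanlog = log(120),
                       spike_sdlog = 0.5,
                       spike_noise_sd = 0.05,
                       splice_prob = 0.15,
                       splice_type_probs = c(removed = 0.5, retained = 0.25,
                                             ambiguous = 0.25),
                       feature_plant_probs = c(uorf = 0.25, uaug_out = 0.15,
                                               uaug_in = 0.10, top = 0.10,
                                               hairpin = 0.12, hexamer = 0.20),
                       effect_sizes = c(uorf = 0.5, uaug_out = 0.75,
                                        uaug_in = 0.9, top = 0.5,
                                        hairpin = 0.6, hexamer = 0.35),
                       effect_hexamer = "AATCCC",
                       cds_length_range = c(300, 1500),
                       rnaseq_depth = 5,
                       minus_strand_prob = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), tss_per_gene = tss_per_gene,
    utr_length_range = utr_length_range,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    lambda_range = lambda_range, tag_scatter = tag_scatter,
    background_rate = background_rate,
    n_replicates = as.integer(n_replicates),
    spike_factors = as.matrix(spike_factors),
    n_spike_clusters = as.integer(n_spike_clusters),
    spike_meanlog = spike_meanlog, spike_sdlog = spike_sdlog,
    spike_noise_sd = spike_noise_sd,
    splice_prob = splice_prob, splice_type_probs = splice_type_probs,
    feature_plant_probs = feature_plant_probs, effect_sizes = effect_sizes,
    effect_hexamer = toupper(effect_hexamer),
    cds_length_range = cds_length_range, rnaseq_depth = rnaseq_depth,
    minus_strand_prob = minus_strand_prob, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) abort("`n_genes` must be at least 1")
  if (abs(sum(cfg$tss_per_gene) - 1) > 1e-8 || any(cfg$tss_per_gene < 0)) {
    abort("`tss_per_gene` must be non-negative probabilities summing to 1")
  }
  if (any(cfg$utr_length_range <= 0) || diff(cfg$utr_length_range) < 0) {
    abort("`utr_length_range` must be positive and non-decreasing")
  }
  if (any(cfg$lambda_range < 0) || diff(cfg$lambda_range) < 0) {
    abort("`lambda_range` must be non-negative and non-decreasing")
  }
  if (cfg$tag_scatter < 0 || cfg$background_rate < 0) {
    abort("rates must be non-negative")
  }
  colnames(cfg$spike_factors) <- paste0("rep", seq_len(ncol(cfg$spike_factors)))
  if (nrow(cfg$spike_factors) != 7L ||
      ncol(cfg$spike_factors) != cfg$n_replicates ||
      any(cfg$spike_factors <= 0)) {
    abort("`spike_factors` must be a positive 7 x n_replicates matrix")
  }
  probs <- c(cfg$feature_plant_probs, cfg$splice_prob, cfg$splice_type_probs,
             cfg$minus_strand_prob)
  if (any(probs < 0) || any(probs > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (any(cfg$effect_sizes <= 0)) abort("`effect_sizes` must be positive")
  if (grepl("ATG", cfg$effect_hexamer)) {
    abort("`effect_hexamer` must be AUG-free")
  }
  required <- c("uorf", "uaug_out", "uaug_in", "top", "hairpin", "hexamer")
  if (!all(required %in% names(cfg$feature_plant_probs)) ||
      !all(required %in% names(cfg$effect_sizes))) {
    abort("`feature_plant_probs` and `effect_sizes` need entries: uorf, uaug_out, uaug_in, top, hairpin, hexamer")
  }
  structure(cfg, class = "sim_config")
}

#' Fraction occupancy probabilities for a given mean ribosome load
#'
#' Per-mRNA ribosome counts K are Poisson(`lambda`) right-censored at 12 and
#' mapped to gradient fractions: K = 0 splits evenly between the free-RNP
#' and 40S/60S fractions, K = 1 sediments in the 80S monosome fraction, and
#' K in 2-3 / 4-5 / 6-9 / >= 10 in the four polysome fractions.
#'
#' @param lambda Mean ribosome load (scalar or vector).
#' @return A matrix with 7 columns (one row per `lambda`).
#' @export
fraction_probs <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (any(lambda < 0)) abort("`lambda` must be non-negative")
  p <- vapply(lambda, function(l) {
    pk <- dpois(0:9, l)
    tail_p <- 1 - sum(pk)  # K >= 10 (censoring at 12 only reshuffles within this bin)
    c(pk[1] / 2, pk[1] / 2, pk[2], pk[3] + pk[4], pk[5] + pk[6],
      sum(pk[7:10]), tail_p)
  }, numeric(7))
  t(p)
}

#' Expected estimated ribosome load under the fraction map
#'
#' The weighted mean `sum(r_j * q_j(lambda))` that the TE estimator recovers
#' in expectation for an isoform with mean load `lambda`; useful as a truth
#' value when checking estimator consistency.
#'
#' @inheritParams fraction_probs
#' @return Numeric vector.
#' @export
expected_ribosome_load <- function(lambda) {
  as.numeric(fraction_probs(lambda) %*% ribosome_weights())
}
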