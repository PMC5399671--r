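#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: the shape of the
#' ground-truth network, the stage activation schedule, the count-noise model,
#' the knockdown model and the per-assay read-out models. A fixed `seed` makes
#' every downstream simulated artifact byte-identical on re-run.
#'
#' The defaults describe the study design the generator emulates: a tiered
#' regulatory hierarchy (posterior PPR regulators feeding an otic-epibranchial
#' progenitor module feeding placode genes) active across four ordered somite
#' stages, negative-binomial count noise on a NanoString-sized panel, partial
#' morpholino knockdown of one regulator per experiment, Ct values log2-linked
#' to abundance against stable reference genes, and per-embryo Bernoulli in
#' situ hybridization outcomes.
#'
#' @param seed Integer master seed; every source of randomness derives from it.
#' @param n_genes Number of genes in the ground-truth network.
#' @param n_tiers Number of hierarchy tiers (default 3: posterior PPR, OEP,
#'   placode).
#' @param edges_per_gene Target mean in-degree of the network (edges per gene,
#'   counted over all genes).
#' @param repressor_fraction Probability that a non-input gene is a repressed
#'   target: an intrinsically expressed alternative-fate gene cleared by a
#'   single repressive input (see [generate_network()]).
#' @param stages Ordered character vector of stage labels.
#' @param baseline_mean Expected count of a transcriptionally inactive gene.
#'   The count scale is anchored so that inactive genes sit below the empirical
#'   expressed-count cut-off of 300.
#' @param amplitude Multiplicative expression gain of a fully active gene
#'   (mean = `baseline_mean * amplitude^activity`).
#' @param dispersion Negative-binomial dispersion alpha, so that
#'   `variance = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param knockdown_efficiency Fraction of a regulator's activity removed by
#'   its morpholino (partial knockdown by default).
#' @param n_replicates Biological replicates per condition for count assays.
#' @param ct_intercept Ct of a transcript at unit abundance
#'   (`Ct = ct_intercept - log2(mean)` plus noise).
#' @param ct_noise_sd Standard deviation of technical Ct noise, in cycles.
#' @param ish_embryos Embryos scored per in situ hybridization experiment.
#' @param ish_sensitivity Slope mapping |log2 effect size| to per-embryo
#'   detection probability.
#' @param size_factor_sd Log-scale s.d. of the per-sample size factors
#'   (log-normal around 1), making normalization non-trivial but benign.
#' @param or_gate_fraction Probability that a multi-input target integrates its
#'   activators as an OR (max) rather than an AND (product) gate. Defaults to
#'   0: the study's documented integration logic is AND-type, and OR-redundant
#'   inputs are invisible to single-knockdown screens by construction.
#' @param n_feedback Number of designated two-gene mutual-activation feedback
#'   pairs placed in the middle tier.
#' @param qpcr_bio_replicates Biological replicates per condition for qPCR.
#' @param qpcr_tech_replicates Technical replicates per biological replicate.
#'
#' @return An object of class `otog_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 12)
#' cfg$stages
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       n_tiers = 3L,
                       edges_per_gene = 2,
                       repressor_fraction = 0.1,
                       stages = c("0ss", "5-6ss", "8-9ss", "11-12ss"),
                       baseline_mean = 200,
                       amplitude = 4,
                       dispersion = 0.05,
                       knockdown_efficiency = 0.8,
                       n_replicates = 3L,
                       ct_intercept = 34,
                       ct_noise_sd = 0.25,
                       ish_embryos = 12L,
                       ish_sensitivity = 1.5,
                       size_factor_sd = 0.15,
                       or_gate_fraction = 0,
                       n_feedback = 1L,
                       qpcr_bio_replicates = 2L,
                       qpcr_tech_replicates = 3L) {
  cfg <- list(
    seed = seed, n_genes = n_genes, n_tiers = n_tiers,
    edges_per_gene = edges_per_gene, repressor_fraction = repressor_fraction,
    stages = stages, baseline_mean = baseline_mean, amplitude = amplitude,
    dispersion = dispersion, knockdown_efficiency = knockdown_efficiency,
    n_replicates = n_replicates, ct_intercept = ct_intercept,
    ct_noise_sd = ct_noise_sd, ish_embryos = ish_embryos,
    ish_sensitivity = ish_sensitivity, size_factor_sd = size_factor_sd,
    or_gate_fraction = or_gate_fraction, n_feedback = n_feedback,
    qpcr_bio_replicates = qpcr_bio_replicates,
    qpcr_tech_replicates = qpcr_tech_replicates
  )
  validate_config(cfg)
  structure(cfg, class = "otog_config")
}

validate_config <- function(cfg) {
  check_field(is_count(cfg$seed) || (is_scalar_num(cfg$seed) && cfg$seed == floor(cfg$seed)),
              "seed", "must be a single integer")
  check_field(is_count(cfg$n_genes), "n_genes", "must be a positive integer")
  check_field(is_count(cfg$n_tiers), "n_tiers", "must be a positive integer")
  check_field(cfg$n_genes >= cfg$n_tiers, "n_genes",
              "must be at least n_tiers (one gene per tier)")
  check_field(is_scalar_num(cfg$edges_per_gene) && cfg$edges_per_gene > 0,
              "edges_per_gene", "must be a positive number")
  check_field(is_prob(cfg$repressor_fraction), "repressor_fraction",
              "must be a probability in [0, 1]")
  check_field(is.character(cfg$stages) && length(cfg$stages) >= 2 &&
                !anyDuplicated(cfg$stages), "stages",
              "must be >= 2 unique ordered labels")
  check_field(is_scalar_num(cfg$baseline_mean) && cfg$baseline_mean > 0,
              "baseline_mean", "must be positive")
  check_field(is_scalar_num(cfg$amplitude) && cfg$amplitude > 1,
              "amplitude", "must be > 1")
  check_field(is_scalar_num(cfg$dispersion) && cfg$dispersion >= 0,
              "dispersion", "must be >= 0")
  check_field(is_scalar_num(cfg$knockdown_efficiency) &&
                cfg$knockdown_efficiency > 0 && cfg$knockdown_efficiency <= 1,
              "knockdown_efficiency", "must be in (0, 1]")
  check_field(is_count(cfg$n_replicates), "n_replicates",
              "must be a positive integer")
  check_field(is_scalar_num(cfg$ct_intercept), "ct_intercept", "must be numeric")
  check_field(is_scalar_num(cfg$ct_noise_sd) && cfg$ct_noise_sd >= 0,
              "ct_noise_sd", "must be >= 0")
  check_field(is_count(cfg$ish_embryos), "ish_embryos",
              "must be a positive integer")
  check_field(is_scalar_num(cfg$ish_sensitivity) && cfg$ish_sensitivity >= 0,
              "ish_sensitivity", "must be >= 0")
  check_field(is_scalar_num(cfg$size_factor_sd) && cfg$size_factor_sd >= 0,
              "size_factor_sd", "must be >= 0")
  check_field(is_prob(cfg$or_gate_fraction), "or_gate_fraction",
              "must be a probability in [0, 1]")
  check_field(is_scalar_num(cfg$n_feedback) && cfg$n_feedback >= 0 &&
                cfg$n_feedback == floor(cfg$n_feedback), "n_feedback",
              "must be a non-negative integer")
  check_field(is_count(cfg$qpcr_bio_replicates), "qpcr_bio_replicates",
              "must be a positive integer")
  check_field(is_count(cfg$qpcr_tech_replicates), "qpcr_tech_replicates",
              "must be a positive integer")
  invisible(cfg)
}

#' @export
print.otog_config <- function(x, ...) {
  cat("<otog_config>\n")
  cat(sprintf("  %d genes, %d tiers, mean in-degree %.2f, %d%% repressors\n",
              x$n_genes, x$n_tiers, x$edges_per_gene,
              round(100 * x$repressor_fraction)))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  counts: baseline %.0f, amplitude %.1f, dispersion %.3f\n",
              x$baseline_mean, x$amplitude, x$dispersion))
  cat(sprintf("  knockdown efficiency %.2f, %d replicates, seed %d\n",
              x$knockdown_efficiency, x$n_replicates, as.integer(x$seed)))
  invisible(x)
}
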