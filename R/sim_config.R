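#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators into one
#' validated object. A single integer \code{seed} pins all randomness:
#' running any generator twice with the same configuration reproduces its
#' output byte for byte.
#'
#' Defaults describe the study design the package is benchmarked against:
#' a paired tumor/normal cohort in which roughly a third of detectable
#' arm pairs move in the same direction and about 9\% move in opposite
#' directions; a four-library biotinylated pull-down with a few percent of
#' genes truly bound (enrichment ratio 3) and depleted about two-fold upon
#' miRNA overexpression; and small-RNA libraries dominated by canonical
#' mature reads with a minority of 3'-trimmed and 3'-tailed isoforms.
#'
#' @param seed integer master seed.
#' @param n_patients paired tumor/normal patients in the cohort.
#' @param n_arm_pairs number of 5p/3p precursor arm pairs simulated.
#' @param trend_fractions named proportions over the planted trend classes
#'   \code{same_up}, \code{same_down}, \code{opposite_5p_up},
#'   \code{opposite_3p_up}, \code{single}, \code{null}; must sum to 1.
#' @param lognormal_sd standard deviation, on the natural-log scale, of
#'   multiplicative expression noise in the cohort tables.
#' @param fold_effect multiplicative tumor/normal effect applied to
#'   dysregulated arms.
#' @param replicate_sd standard deviation (cycles) of qPCR replicate noise.
#' @param n_replicates qPCR replicates per well.
#' @param n_genes,n_enriched genes in the pull-down universe and how many
#'   are truly bound (spiked).
#' @param er_effect true enrichment ratio of spiked genes.
#' @param depletion_log2fc mean log2 fold change of true targets upon
#'   miRNA overexpression (negative = depleted).
#' @param library_sizes expected sequencing depth (reads) of each simulated
#'   library; gene-level counts are Poisson draws at this depth.
#' @param n_mirnas,mirna_len,flank_len reference set size, mature length,
#'   and precursor flank length for the sequence generators.
#' @param transcript_len background length of generated target transcripts.
#' @param isoform_mixture named proportions over read classes
#'   \code{canonical}, \code{trimmed}, \code{tailed_nt} (non-templated
#'   tail), \code{tailed_t} (templated tail); must sum to 1.
#' @param n_reads number of small-RNA reads to generate.
#' @param read_error_rate per-base substitution probability.
#' @param hazard_beta log hazard ratio per unit risk score.
#' @param baseline_hazard baseline exponential hazard (per day).
#' @param censor_rate proportion of subjects independently censored.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_patients = 10, n_arm_pairs = 20)
#' cohort <- gen_cohort(cfg)
#' head(cohort$expression)
sim_config <- function(seed = 1L,
                       n_patients = 50L,
                       n_arm_pairs = 800L,
                       trend_fractions = c(same_up = 0.18, same_down = 0.18,
                                           opposite_5p_up = 0.045,
                                           opposite_3p_up = 0.045,
                                           single = 0.10, null = 0.45),
                       lognormal_sd = 0.3,
                       fold_effect = 4,
                       replicate_sd = 0.2,
                       n_replicates = 3L,
                       n_genes = 5000L,
                       n_enriched = 200L,
                       er_effect = 3,
                       depletion_log2fc = -1,
                       library_sizes = rep(1e7, 6),
                       n_mirnas = 5L,
                       mirna_len = 22L,
                       flank_len = 25L,
                       transcript_len = 300L,
                       isoform_mixture = c(canonical = 0.70, trimmed = 0.20,
                                           tailed_nt = 0.05, tailed_t = 0.05),
                       n_reads = 10000L,
                       read_error_rate = 0,
                       hazard_beta = 1,
                       baseline_hazard = 0.002,
                       censor_rate = 0.2) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              n_arm_pairs = as.integer(n_arm_pairs),
              trend_fractions = trend_fractions,
              lognormal_sd = lognormal_sd, fold_effect = fold_effect,
              replicate_sd = replicate_sd,
              n_replicates = as.integer(n_replicates),
              n_genes = as.integer(n_genes),
              n_enriched = as.integer(n_enriched),
              er_effect = er_effect, depletion_log2fc = depletion_log2fc,
              library_sizes = library_sizes,
              n_mirnas = as.integer(n_mirnas),
              mirna_len = as.integer(mirna_len),
              flank_len = as.integer(flank_len),
              transcript_len = as.integer(transcript_len),
              isoform_mixture = isoform_mixture,
              n_reads = as.integer(n_reads),
              read_error_rate = read_error_rate,
              hazard_beta = hazard_beta, baseline_hazard = baseline_hazard,
              censor_rate = censor_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  trend_classes <- c("same_up", "same_down", "opposite_5p_up",
                     "opposite_3p_up", "single", "null")
  iso_classes <- c("canonical", "trimmed", "tailed_nt", "tailed_t")
  if (!identical(sort(names(cfg$trend_fractions)), sort(trend_classes)))
    stop_mirarm("trend_fractions must be named over: ",
                paste(trend_classes, collapse = ", "),
                class = "mirarmkit_config_error")
  if (!identical(sort(names(cfg$isoform_mixture)), sort(iso_classes)))
    stop_mirarm("isoform_mixture must be named over: ",
                paste(iso_classes, collapse = ", "),
                class = "mirarmkit_config_error")
  assert_proportions(cfg$trend_fractions, "trend_fractions")
  assert_proportions(cfg$isoform_mixture, "isoform_mixture")
  counts <- c(n_patients = cfg$n_patients, n_arm_pairs = cfg$n_arm_pairs,
              n_replicates = cfg$n_replicates, n_genes = cfg$n_genes,
              n_mirnas = cfg$n_mirnas, mirna_len = cfg$mirna_len,
              n_reads = cfg$n_reads)
  if (any(counts <= 0))
    stop_mirarm("all counts must be > 0",
                class = "mirarmkit_config_error")
  if (cfg$n_enriched >= cfg$n_genes)
    stop_mirarm("n_enriched must be smaller than n_genes",
                class = "mirarmkit_config_error")
  if (cfg$fold_effect <= 0 || cfg$er_effect <= 0)
    stop_mirarm("fold_effect and er_effect must be positive",
                class = "mirarmkit_config_error")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop_mirarm("censor_rate must lie in [0, 1]",
                class = "mirarmkit_config_error")
  if (!is.finite(cfg$hazard_beta))
    stop_mirarm("hazard_beta must be finite",
                class = "mirarmkit_config_error")
  if (cfg$read_error_rate < 0 || cfg$read_error_rate > 1)
    stop_mirarm("read_error_rate must lie in [0, 1]",
                class = "mirarmkit_config_error")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_patients, "patients,",
      x$n_arm_pairs, "arm pairs,", x$n_genes, "genes,",
      x$n_reads, "reads\n")
  invisible(x)
}
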