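#' Simulation configuration for the synthetic asMIP assay
#'
#' Collects the generative parameters of the additive log2 signal model
#' \eqn{\theta = p + t + \delta + \epsilon}: probe effects `p`, per-tissue
#' gene baselines `t`, splicing shifts `delta` on alternative junctions, and
#' noise `epsilon`, together with the platform rendering parameters (array
#' saturation and dilution series, sequencing depth, qPCR intercept and
#' dropout).  Defaults describe the assayed design: 17 genes, 10-20
#' junctions per gene, five tissues plus a pooled reference, 30% candidate
#' alternative junctions.
#'
#' @param n_genes number of genes.
#' @param junctions_per_gene integer range (length 2) of junctions per gene.
#' @param n_tissues number of tissues, excluding the pooled reference.
#' @param frac_alternative fraction of junctions per gene made alternative.
#' @param delta_magnitude absolute splicing shift |delta| in log2 units.
#' @param alt_tissue_range integer range of how many tissues an alternative
#'   junction shifts in (must stay a proper subset of the tissues); default
#'   1-2 of 5, matching tissue-specific splicing events.
#' @param probe_effect_sd SD of probe effects `p` (log2 units).
#' @param tissue_baseline_range total range of gene baselines `t` (log2
#'   units); baselines are uniform on +/- half this range.
#' @param noise_sd SD of noise `epsilon` (log2 units).
#' @param seq_depth_scale expected sequencing reads at theta = 0.
#' @param array_background_mean,array_background_sd fluorescence background.
#' @param array_saturation array intensity ceiling (fluorescence units).
#' @param array_gain fluorescence per linear signal unit at dilution 1, or
#'   `NULL` to auto-scale so the mid dilution places the median probe
#'   mid-range between background and saturation.
#' @param dilution_factors strictly increasing positive triple of relative
#'   sample volumes (default 0.01, 0.1, 1 mirroring 0.2/2.0/20 ul).
#' @param n_unused_features unused control features per array (>= 2).
#' @param qpcr_ct_intercept Ct at theta = 0.
#' @param qpcr_dropout_prob probability a primer set fails entirely.
#' @param nb_dispersion optional negative-binomial dispersion for sequencing
#'   counts (`NULL` = Poisson).
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return an object of class `asmip_sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 3, junctions_per_gene = c(4, 6), seed = 7)
#' truth <- simulate_truth(cfg)
#' @export
sim_config <- function(n_genes = 17L,
                       junctions_per_gene = c(10L, 20L),
                       n_tissues = 5L,
                       frac_alternative = 0.3,
                       delta_magnitude = 2.5,
                       alt_tissue_range = c(1L, 2L),
                       probe_effect_sd = 1.0,
                       tissue_baseline_range = 4.0,
                       noise_sd = 0.4,
                       seq_depth_scale = 100,
                       array_background_mean = 100,
                       array_background_sd = 15,
                       array_saturation = 3500,
                       array_gain = NULL,
                       dilution_factors = c(0.01, 0.1, 1.0),
                       n_unused_features = 20L,
                       qpcr_ct_intercept = 30,
                       qpcr_dropout_prob = 0.1,
                       nb_dispersion = NULL,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    junctions_per_gene = as.integer(junctions_per_gene),
    n_tissues = as.integer(n_tissues),
    frac_alternative = frac_alternative,
    delta_magnitude = delta_magnitude,
    alt_tissue_range = as.integer(alt_tissue_range),
    probe_effect_sd = probe_effect_sd,
    tissue_baseline_range = tissue_baseline_range,
    noise_sd = noise_sd,
    seq_depth_scale = seq_depth_scale,
    array_background_mean = array_background_mean,
    array_background_sd = array_background_sd,
    array_saturation = array_saturation,
    array_gain = array_gain,
    dilution_factors = dilution_factors,
    n_unused_features = as.integer(n_unused_features),
    qpcr_ct_intercept = qpcr_ct_intercept,
    qpcr_dropout_prob = qpcr_dropout_prob,
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "asmip_sim_config"
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "asmip_sim_config"))
  with(cfg, {
    if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
    if (length(junctions_per_gene) != 2L ||
        any(junctions_per_gene < 2L) ||
        junctions_per_gene[1] > junctions_per_gene[2])
      stop("junctions_per_gene must be an increasing integer range >= 2",
           call. = FALSE)
    if (n_tissues < 2L) stop("n_tissues must be >= 2", call. = FALSE)
    if (frac_alternative < 0 || frac_alternative > 1)
      stop("frac_alternative must lie in [0, 1]", call. = FALSE)
    if (any(c(probe_effect_sd, noise_sd, array_background_sd) < 0))
      stop("all SDs must be >= 0", call. = FALSE)
    if (length(dilution_factors) != 3L || any(dilution_factors <= 0) ||
        any(diff(dilution_factors) <= 0))
      stop("dilution_factors must be a strictly increasing positive triple",
           call. = FALSE)
    if (n_unused_features < 2L)
      stop("n_unused_features must be >= 2 (background SD needs n >= 2)",
           call. = FALSE)
    if (qpcr_dropout_prob < 0 || qpcr_dropout_prob > 1)
      stop("qpcr_dropout_prob must lie in [0, 1]", call. = FALSE)
    if (length(alt_tissue_range) != 2L || alt_tissue_range[1] < 1L ||
        alt_tissue_range[1] > alt_tissue_range[2] ||
        alt_tissue_range[2] > n_tissues - 1L)
      stop("alt_tissue_range must satisfy 1 <= lo <= hi <= n_tissues - 1 ",
           "(a proper subset of tissues)", call. = FALSE)
  })
  cfg
}

#' @export
print.asmip_sim_config <- function(x, ...) {
  cat("asMIP simulation config:",
      sprintf("%d genes, %d-%d junctions/gene, %d tissues + %s",
              x$n_genes, x$junctions_per_gene[1], x$junctions_per_gene[2],
              x$n_tissues, REF_TISSUE), "\n")
  cat(sprintf("  frac_alternative=%.2f  |delta|=%.2f  probe_sd=%.2f  noise_sd=%.2f  seed=%d\n",
              x$frac_alternative, x$delta_magnitude, x$probe_effect_sd,
              x$noise_sd, x$seed))
  invisible(x)
}

#' @noRd
tissue_ids <- function(n_tissues) {
  ## the five assayed human tissues when n = 5, generic ids otherwise
  if (n_tissues == 5L) c("PLA", "SKM", "STM", "CEB", "FRL")
  else sprintf("T%02d", seq_len(n_tissues))
}
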