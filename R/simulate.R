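## Synthetic asMIP data: ground truth under the additive log2 model
## theta = p + t + delta + epsilon, rendered on three platforms.

#' Draw the generative ground truth of a synthetic asMIP experiment
#'
#' Draws probe effects `p ~ Normal(0, probe_effect_sd)` independently per
#' (gene, junction, tag), gene baselines `t ~ Uniform(+/- range/2)` per
#' (gene, tissue) including the pooled reference, and assigns
#' `ceiling(frac_alternative * n_junctions)` junctions per gene as
#' alternative.  Each alternative junction receives `delta = +/-
#' delta_magnitude` (sign random) in a randomly chosen proper subset of the
#' non-reference tissues; `delta = 0` everywhere else, in particular in the
#' reference sample and for every constitutive junction.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `asmip_truth`: a list with data.tables
#'   `probe_effects` (gene_id, junction_id, tag, p), `baselines`
#'   (gene_id, tissue_id, t_base), `deltas` (gene_id, junction_id,
#'   tissue_id, delta), `junctions` (gene_id, junction_id, status), plus
#'   `tissues`, `noise_sd` and the `config`.
#' @export
simulate_truth <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, 0L))
  tis <- tissue_ids(config$n_tissues)
  all_tis <- c(REF_TISSUE, tis)
  genes <- sprintf("G%02d", seq_len(config$n_genes))

  ## sample() treats a length-1 vector as 1:n; always pass the full range
  sample_range <- function(lo, hi) if (lo == hi) lo else sample(seq(lo, hi), 1L)

  pe <- list(); bl <- list(); de <- list(); ju <- list()
  for (g in genes) {
    nj <- sample_range(config$junctions_per_gene[1],
                       config$junctions_per_gene[2])
    jid <- sprintf("%d-%d", seq_len(nj), seq_len(nj) + 1L)
    n_alt <- as.integer(ceiling(config$frac_alternative * nj))
    if (nj - n_alt < 1L) {
      stop("gene ", g, ": frac_alternative leaves no constitutive junction ",
           "(R-scores need a constitutive baseline)", call. = FALSE)
    }
    alt <- if (n_alt > 0L) sample(jid, n_alt) else character(0)

    pe[[g]] <- data.table(
      gene_id = g,
      junction_id = rep(jid, each = 2L),
      tag = rep(1:2, nj),
      p = rnorm(2L * nj, 0, config$probe_effect_sd))
    bl[[g]] <- data.table(
      gene_id = g, tissue_id = all_tis,
      t_base = runif(length(all_tis),
                     -config$tissue_baseline_range / 2,
                     config$tissue_baseline_range / 2))
    dg <- CJ(gene_id = g, junction_id = jid, tissue_id = all_tis)
    dg[, delta := 0]
    for (j in alt) {
      k <- sample_range(config$alt_tissue_range[1],
                        config$alt_tissue_range[2])
      shifted <- sample(tis, k)
      sgn <- sample(c(-1, 1), 1L)
      dg[junction_id == j & tissue_id %in% shifted,
         delta := sgn * config$delta_magnitude]
    }
    de[[g]] <- dg
    ju[[g]] <- data.table(
      gene_id = g, junction_id = jid,
      status = ifelse(jid %in% alt, "alternative", "constitutive"))
  }
  out <- list(probe_effects = rbindlist(pe), baselines = rbindlist(bl),
              deltas = rbindlist(de), junctions = rbindlist(ju),
              tissues = all_tis, noise_sd = config$noise_sd, config = config)
  class(out) <- "asmip_truth"
  out
}

#' @export
print.asmip_truth <- function(x, ...) {
  cat(sprintf("asMIP ground truth: %d genes, %d junctions (%d alternative), %d tissues + %s\n",
              length(unique(x$junctions$gene_id)), nrow(x$junctions),
              sum(x$junctions$status == "alternative"),
              length(x$tissues) - 1L, REF_TISSUE))
  invisible(x)
}

#' Noiseless theta grid for a ground truth
#'
#' Expands the truth to one row per (gene, junction, tag, tissue) with the
#' noiseless additive signal `theta = p + t + delta`.
#'
#' @param truth an `asmip_truth` object.
#' @return a data.table with columns gene_id, junction_id, tag, tissue_id,
#'   p, t_base, delta, theta.
#' @export
truth_theta <- function(truth) {
  stopifnot(inherits(truth, "asmip_truth"))
  g <- merge(truth$probe_effects,
             truth$deltas, by = c("gene_id", "junction_id"),
             allow.cartesian = TRUE)
  g <- merge(g, truth$baselines, by = c("gene_id", "tissue_id"))
  g[, theta := p + t_base + delta]
  setorder(g, gene_id, junction_id, tag, tissue_id)
  g[]
}

#' Render sequencing tag counts from a ground truth
#'
#' For every (gene, junction, tag, tissue) cell, draws
#' `theta = p + t + delta + epsilon` and a read count
#' `Poisson(seq_depth_scale * 2^theta)` (negative binomial with the
#' configured dispersion when `nb_dispersion` is set).
#'
#' @param truth an `asmip_truth` object.
#' @param config its [sim_config()]; defaults to the one stored in `truth`.
#' @return a SignalTable data.table (platform "seq"): gene_id, junction_id,
#'   tag, tissue_id, dilution (NA), value (count), is_unused_feature.
#' @export
render_sequencing <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "asmip_truth"))
  set.seed(derive_seed(config$seed, 1L))
  g <- truth_theta(truth)
  g[, theta := theta + rnorm(.N, 0, config$noise_sd)]
  g[, mu := config$seq_depth_scale * 2^theta]
  value <- if (is.null(config$nb_dispersion)) {
    rpois(nrow(g), g$mu)
  } else {
    rnbinom(nrow(g), mu = g$mu, size = 1 / config$nb_dispersion)
  }
  out <- g[, .(platform = "seq", gene_id, junction_id, tag, tissue_id,
               dilution = NA_character_, value = as.numeric(value),
               is_unused_feature = FALSE)]
  out[]
}

#' Render array fluorescence intensities from a ground truth
#'
#' One array per (tissue, dilution).  Probe intensity is
#' `min(saturation, background_draw + gain * v * 2^theta)` for dilution
#' volume `v`, with a fresh background draw per feature and fresh noise in
#' theta per array.  Each array additionally carries `n_unused_features`
#' background-only control features (no junction key).  When `array_gain`
#' is `NULL` it is fixed so the mid dilution places the median probe halfway
#' between mean background and saturation.
#'
#' @inheritParams render_sequencing
#' @return a SignalTable data.table (platform "array") with a `dilution`
#'   column in `c("low","mid","high")` and unused-feature rows flagged.
#' @export
render_array <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "asmip_truth"))
  set.seed(derive_seed(config$seed, 2L))
  base <- truth_theta(truth)
  gain <- config$array_gain
  if (is.null(gain)) {
    target <- (config$array_background_mean + config$array_saturation) / 2
    gain <- target / (config$dilution_factors[2] * 2^median(base$theta))
  }
  out <- vector("list", (length(truth$tissues)) * 3L * 2L)
  k <- 0L
  for (ti in truth$tissues) {
    th_t <- base[tissue_id == ti]
    for (dl in seq_along(DILUTION_LEVELS)) {
      v <- config$dilution_factors[dl]
      theta_arr <- th_t$theta + rnorm(nrow(th_t), 0, config$noise_sd)
      bg_draw <- rnorm(nrow(th_t), config$array_background_mean,
                       config$array_background_sd)
      intensity <- pmin(config$array_saturation,
                        pmax(0, bg_draw + gain * v * 2^theta_arr))
      k <- k + 1L
      out[[k]] <- data.table(
        platform = "array", gene_id = th_t$gene_id,
        junction_id = th_t$junction_id, tag = th_t$tag, tissue_id = ti,
        dilution = DILUTION_LEVELS[dl], value = intensity,
        is_unused_feature = FALSE)
      k <- k + 1L
      out[[k]] <- data.table(
        platform = "array", gene_id = NA_character_,
        junction_id = NA_character_, tag = NA_integer_, tissue_id = ti,
        dilution = DILUTION_LEVELS[dl],
        value = pmax(0, rnorm(config$n_unused_features,
                              config$array_background_mean,
                              config$array_background_sd)),
        is_unused_feature = TRUE)
    }
  }
  rbindlist(out)[]
}

#' Render qPCR cycle thresholds from a ground truth
#'
#' Two junction-spanning primer sets per junction play the role of the two
#' probe tags.  `Ct = ct_intercept - theta + Normal(0, noise_sd)` (slope -1:
#' one Ct cycle per log2 unit of template).  Each (junction, primer set)
#' independently fails outright (all samples missing) with probability
#' `qpcr_dropout_prob`.
#'
#' @inheritParams render_sequencing
#' @return a SignalTable data.table (platform "qpcr"); `tag` is the primer
#'   set index, `value` is the Ct.
#' @export
render_qpcr <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "asmip_truth"))
  set.seed(derive_seed(config$seed, 3L))
  g <- truth_theta(truth)
  g[, ct := config$qpcr_ct_intercept - (p + t_base + delta) +
        rnorm(.N, 0, config$noise_sd)]
  sets <- unique(g[, .(gene_id, junction_id, tag)])
  sets[, dropped := runif(.N) < config$qpcr_dropout_prob]
  g <- merge(g, sets, by = c("gene_id", "junction_id", "tag"))
  g <- g[dropped == FALSE]
  out <- g[, .(platform = "qpcr", gene_id, junction_id, tag, tissue_id,
               dilution = NA_character_, value = ct,
               is_unused_feature = FALSE)]
  setorder(out, gene_id, junction_id, tag, tissue_id)
  out[]
}

#' Simulate a complete multi-platform asMIP experiment
#'
#' @param config an [sim_config()] object.
#' @return a list with the `truth` and SignalTables `seq`, `array`, `qpcr`.
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_truth(config)
  list(truth = truth,
       seq = render_sequencing(truth, config),
       array = render_array(truth, config),
       qpcr = render_qpcr(truth, config))
}

utils::globalVariables(c("dropped"))
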