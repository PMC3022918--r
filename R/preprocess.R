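## Preprocessing: raw platform readouts -> log2 signal table theta.

#' Subtract array background estimated from unused control features
#'
#' Per array (one tissue at one dilution): the background is the mean
#' intensity of the unused control features and its SD their sample standard
#' deviation (n-1 denominator).  Every probe value is reduced by the
#' background; corrected values at or below `z` times the SD are marked
#' missing (reason `below_background`).  Unused rows are dropped from the
#' output.
#'
#' @param arrays an array SignalTable with `is_unused_feature` flags.
#' @param z exclusion multiplier on the background SD (default 1.96).
#' @return the probe rows with background-corrected `value`, plus `missing`,
#'   `missing_reason` and per-array `bg_threshold` (= z * SD) columns.
#' @export
subtract_background <- function(arrays, z = 1.96) {
  x <- as.data.table(arrays)
  assert_columns(x, c("platform", "gene_id", "junction_id", "tag",
                      "tissue_id", "dilution", "value", "is_unused_feature"),
                 "array SignalTable")
  if (!all(x$platform == "array")) stop("expected platform 'array'", call. = FALSE)

  bgs <- x[is_unused_feature == TRUE,
           .(bg = mean(value), bg_sd = sd(value), n_unused = .N),
           by = .(tissue_id, dilution)]
  probes <- x[is_unused_feature == FALSE]
  bad <- unique(probes[, .(tissue_id, dilution)])
  bad <- bad[!bgs[n_unused >= 2L], on = c("tissue_id", "dilution")]
  if (nrow(bad) > 0L || any(bgs$n_unused < 2L)) {
    stop("each array needs >= 2 unused features to estimate the background SD",
         call. = FALSE)
  }
  out <- merge(probes, bgs, by = c("tissue_id", "dilution"))
  out[, value := value - bg]
  out[, bg_threshold := z * bg_sd]
  out[, missing := value <= bg_threshold]
  out[, missing_reason := ifelse(missing, "below_background", NA_character_)]
  out[, c("bg", "bg_sd", "n_unused") := NULL]
  setcolorder(out, c("platform", "gene_id", "junction_id", "tag", "tissue_id",
                     "dilution", "value", "is_unused_feature"))
  setorder(out, gene_id, junction_id, tag, tissue_id, dilution)
  out[]
}

#' Select the dilution with the most in-dynamic-range points per gene/tissue
#'
#' For each (gene, tissue), counts background-corrected probe values lying
#' strictly between the background threshold and `upper` at each of the
#' three dilutions and keeps all probe rows of that gene/tissue from the
#' single winning dilution.  Ties break toward the lowest input volume
#' (least saturation risk).  Values at or above `upper` in the winning
#' dilution are marked missing (reason `out_of_range`).
#'
#' @param arrays output of [subtract_background()] (dilution key present).
#' @param upper upper bound of the array dynamic range (default 3500
#'   fluorescence units).
#' @return one dilution per (gene, tissue), saturated values marked missing.
#' @export
select_dilution <- function(arrays, upper = 3500) {
  x <- as.data.table(arrays)
  assert_columns(x, c("gene_id", "tissue_id", "dilution", "value", "missing"),
                 "background-subtracted array table")
  x[, dilution := factor(dilution, levels = DILUTION_LEVELS)]
  counts <- x[, .(n_in_range = sum(!missing & value < upper)),
              by = .(gene_id, tissue_id, dilution)]
  ## argmax with tie-break toward the lowest volume: order by -n then level
  setorder(counts, gene_id, tissue_id, -n_in_range, dilution)
  winners <- counts[, .SD[1L], by = .(gene_id, tissue_id)]
  none <- winners[n_in_range == 0L]
  if (nrow(none) > 0L) {
    warning(nrow(none), " gene/tissue group(s) have no in-range data at any ",
            "dilution; all their values are missing", call. = FALSE)
  }
  out <- merge(x, winners[, .(gene_id, tissue_id, dilution)],
               by = c("gene_id", "tissue_id", "dilution"))
  sat <- !out$missing & out$value >= upper
  out[sat, `:=`(missing = TRUE, missing_reason = "out_of_range")]
  out[, dilution := as.character(dilution)]
  setorder(out, gene_id, junction_id, tag, tissue_id)
  out[]
}

#' Assemble the log2 signal table theta
#'
#' Array and sequencing values become `theta = log2(value)`; zero sequencing
#' counts are marked missing (reason `zero_count`) unless a pseudocount is
#' supplied, and tags with fewer than `min_reads` reads are retained but
#' flagged `low_confidence` (the additive model was only verified at >= 4
#' reads per tag).  qPCR cycle thresholds are already on a log2 scale with
#' slope -1, so they pass through as `theta = -Ct`; the reference-based
#' difference `theta_i - theta_REF` then equals the Methods delta-Ct
#' `Ct_REF - Ct_tissue`.
#'
#' @param table a SignalTable (post background subtraction and dilution
#'   selection for arrays; raw counts for sequencing; Ct for qPCR).
#' @param min_reads low-confidence threshold for sequencing tags (default 4).
#' @param pseudocount added to sequencing counts before log2 (default 0 =
#'   off; zero counts stay missing).
#' @return a LogSignalTable data.table: platform, gene_id, junction_id, tag,
#'   tissue_id, theta, missing, missing_reason, low_confidence.
#' @export
log_transform <- function(table, min_reads = 4, pseudocount = 0) {
  x <- as.data.table(table)
  assert_columns(x, c("platform", "gene_id", "junction_id", "tag",
                      "tissue_id", "value"), "SignalTable")
  pf <- assert_single_platform(x)
  if (!"missing" %in% names(x)) x[, missing := FALSE]
  if (!"missing_reason" %in% names(x)) x[, missing_reason := NA_character_]
  x[, low_confidence := FALSE]

  if (pf == "qpcr") {
    x[, theta := -value]
  } else if (pf == "seq") {
    if (any(x$value < 0)) stop("negative read counts", call. = FALSE)
    v <- x$value + pseudocount
    zero <- !x$missing & v <= 0
    x[zero, `:=`(missing = TRUE, missing_reason = "zero_count")]
    x[, theta := ifelse(missing, NA_real_, log2(value + pseudocount))]
    x[!missing & value < min_reads, low_confidence := TRUE]
  } else if (pf == "array") {
    neg <- !x$missing & x$value <= 0
    ## post-threshold this cannot happen unless the background SD was 0
    x[neg, `:=`(missing = TRUE, missing_reason = "below_background")]
    x[, theta := ifelse(missing, NA_real_, log2(value))]
  } else {
    stop("unknown platform: ", pf, call. = FALSE)
  }
  out <- x[, .(platform, gene_id, junction_id, tag, tissue_id, theta,
               missing, missing_reason, low_confidence)]
  setorder(out, gene_id, junction_id, tag, tissue_id)
  out[]
}

#' Per-primer-set delta-Ct relative to the pooled reference
#'
#' For each primer set (tag) and tissue computes
#' `d = Ct_REF - Ct_tissue`, the qPCR analogue of the reference-based log2
#' ratio: one positive unit means 2-fold more template in the tissue than in
#' the reference.  A primer set missing either Ct contributes nothing; a
#' junction whose both primer sets fail is absent from the output ("only the
#' informative primer set" rule — surviving sets stand alone).
#'
#' @param ct a qPCR SignalTable (value = Ct) containing the reference tissue.
#' @param ref_tissue reference tissue id (default `"REF"`).
#' @return a data.table with columns gene_id, junction_id, tag, tissue_id,
#'   theta (= delta-Ct), missing, platform.
#' @export
qpcr_delta_ct <- function(ct, ref_tissue = REF_TISSUE) {
  x <- as.data.table(ct)
  assert_columns(x, c("platform", "gene_id", "junction_id", "tag",
                      "tissue_id", "value"), "qPCR SignalTable")
  if (!all(x$platform == "qpcr")) stop("expected platform 'qpcr'", call. = FALSE)
  ref <- x[tissue_id == ref_tissue,
           .(gene_id, junction_id, tag, ct_ref = value)]
  if (nrow(ref) == 0L) {
    stop("reference tissue '", ref_tissue, "' absent from qPCR table",
         call. = FALSE)
  }
  d <- merge(x[tissue_id != ref_tissue], ref,
             by = c("gene_id", "junction_id", "tag"))
  d[, theta := ct_ref - value]
  out <- d[, .(platform = "qpcr", gene_id, junction_id, tag, tissue_id,
               theta, missing = FALSE,
               missing_reason = NA_character_, low_confidence = FALSE)]
  setorder(out, gene_id, junction_id, tag, tissue_id)
  out[]
}

utils::globalVariables(c("n_unused", "bg_threshold", "ct_ref"))
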