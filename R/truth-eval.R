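## Ground-truth views used for recovery studies on synthetic data.

#' True splice calls of a simulated experiment
#'
#' @param truth an `asmip_truth` object.
#' @return call table (gene_id, junction_id, tissue_id, call = sign(delta))
#'   over the non-reference tissues.
#' @export
truth_calls <- function(truth) {
  stopifnot(inherits(truth, "asmip_truth"))
  d <- truth$deltas[tissue_id != REF_TISSUE]
  out <- d[, .(gene_id, junction_id, tissue_id,
               call = as.integer(sign(delta)))]
  setorder(out, gene_id, junction_id, tissue_id)
  out[]
}

#' Most informative tissue pair per gene, from truth
#'
#' Mirrors the control evaluation of the assay, where each gene was scored
#' on the pair of tissues known to show its splicing (e.g. skeletal muscle
#' versus stomach for tropomyosins): tissue A is the tissue with the most
#' alternative junctions shifted (delta != 0), tissue B the one with the
#' fewest; ties break on tissue order.
#'
#' @param truth an `asmip_truth` object.
#' @return data.table gene_id, tissue_a, tissue_b.
#' @export
truth_pair_map <- function(truth) {
  stopifnot(inherits(truth, "asmip_truth"))
  d <- truth$deltas[tissue_id != REF_TISSUE]
  cnt <- d[, .(n_alt = sum(delta != 0)), by = .(gene_id, tissue_id)]
  cnt[, tissue_id := factor(tissue_id, levels = setdiff(truth$tissues, REF_TISSUE))]
  setorder(cnt, gene_id, -n_alt, tissue_id)
  pairs <- cnt[, .(tissue_a = as.character(tissue_id[1L]),
                   tissue_b = as.character(tissue_id[.N])),
               by = gene_id]
  pairs[]
}

#' Control labels for tissue-pair evaluation, from truth
#'
#' Positive controls are junctions whose delta differs between the two
#' tissues of the gene's pair (the pair can expose them); negative controls
#' are globally constitutive junctions.  Alternative junctions quiescent in
#' the chosen pair are excluded — they are not controls for that pair.
#'
#' @param truth an `asmip_truth` object.
#' @param pairs a pair map as from [truth_pair_map()] (default).
#' @return data.table gene_id, junction_id, label (1 positive / 0 negative).
#' @export
truth_pair_labels <- function(truth, pairs = truth_pair_map(truth)) {
  stopifnot(inherits(truth, "asmip_truth"))
  d <- merge(truth$deltas, pairs, by = "gene_id")
  da <- d[tissue_id == tissue_a, .(gene_id, junction_id, delta_a = delta)]
  db <- d[tissue_id == tissue_b, .(gene_id, junction_id, delta_b = delta)]
  m <- merge(da, db, by = c("gene_id", "junction_id"))
  m <- merge(m, truth$junctions, by = c("gene_id", "junction_id"))
  m[, label := NA_integer_]
  m[status == "constitutive", label := 0L]
  m[status == "alternative" & delta_a != delta_b, label := 1L]
  out <- m[!is.na(label), .(gene_id, junction_id, label)]
  setorder(out, gene_id, junction_id)
  out[]
}

utils::globalVariables(c("delta_a", "delta_b"))
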