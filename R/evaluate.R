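## Evaluation: concordance-index AUC, sensitivity/specificity, correlations.

#' Concordance-index AUC
#'
#' Probability that a randomly chosen positive item outranks a randomly
#' chosen negative one, with ties credited 0.5 — the concordance index `c`,
#' equal to the trapezoidal area under the full ROC curve.  Computed via
#' midranks (Mann-Whitney U), so it is exact and invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive, 0 = negative), same length.
#' @return the AUC in `[0, 1]`.
#' @export
concordance_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one item of each label", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties get 0.5 credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @param scores,labels as in [concordance_auc()].
#' @return data.table (threshold, fpr, tpr), one row per distinct score
#'   plus the (0,0) endpoint; items with `score >= threshold` are predicted
#'   positive.
#' @export
roc_points <- function(scores, labels) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  n1 <- sum(l == 1L)
  n0 <- sum(l == 0L)
  tp <- cumsum(l == 1L)
  fp <- cumsum(l == 0L)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct score
  out <- data.table(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1))
  out[]
}

#' Sensitivity and specificity of paired binary calls
#'
#' Operates on the output of [binarize_calls()]: sensitivity is the
#' fraction of truth positives called concordantly (non-zero AND same
#' sign), specificity the fraction of truth negatives called zero.
#' Discordant (opposite-sign) pairs count as errors on both axes.
#'
#' @param pairs a [binarize_calls()] table.
#' @return list with `sensitivity`, `specificity` (NA when the truth class
#'   is empty), and counts `n_positive`, `n_negative`, `n_discordant`.
#' @export
sens_spec <- function(pairs) {
  p <- as.data.table(pairs)
  assert_columns(p, c("agreement", "truth_bin"), "binarized pairs")
  n_pos <- sum(p$truth_bin == 1L)
  n_neg <- sum(p$truth_bin == 0L)
  list(
    sensitivity = if (n_pos > 0L)
      sum(p$agreement == "concordant_positive") / n_pos else NA_real_,
    specificity = if (n_neg > 0L)
      sum(p$agreement == "concordant_negative") / n_neg else NA_real_,
    n_positive = n_pos, n_negative = n_neg,
    n_discordant = sum(p$agreement == "discordant"))
}

#' Correlate two score tables on their shared keys
#'
#' Pearson and Spearman coefficients over the intersection of non-missing
#' (gene, junction, tissue) keys.  Both are always reported.
#'
#' @param scores_a,scores_b ScoreTables.
#' @return list with `pearson_r`, `spearman_rho`, `n`.
#' @export
correlate_scores <- function(scores_a, scores_b) {
  keys <- c("gene_id", "junction_id", "tissue_id")
  a <- as.data.table(scores_a)
  b <- as.data.table(scores_b)
  assert_columns(a, c(keys, "value"), "scores_a")
  assert_columns(b, c(keys, "value"), "scores_b")
  m <- merge(a[is.finite(value), c(keys, "value"), with = FALSE],
             b[is.finite(value), .(gene_id, junction_id, tissue_id,
                                   value_b = value)],
             by = keys)
  if (nrow(m) < 3L) {
    stop("need >= 3 shared keys to correlate (got ", nrow(m), ")",
         call. = FALSE)
  }
  list(pearson_r = cor(m$value, m$value_b, method = "pearson"),
       spearman_rho = cor(m$value, m$value_b, method = "spearman"),
       n = nrow(m))
}

#' Assemble an evaluation report
#'
#' @param auc concordance AUC (or NA).
#' @param ss a [sens_spec()] list (or NULL).
#' @param corr a [correlate_scores()] list (or NULL).
#' @return a plain list suitable for JSON serialization.
#' @export
eval_report <- function(auc = NA_real_, ss = NULL, corr = NULL) {
  list(auc = auc,
       sensitivity = ss$sensitivity %||% NA_real_,
       specificity = ss$specificity %||% NA_real_,
       pearson_r = corr$pearson_r %||% NA_real_,
       spearman_rho = corr$spearman_rho %||% NA_real_,
       n_positive = ss$n_positive %||% NA_integer_,
       n_negative = ss$n_negative %||% NA_integer_,
       n_discordant = ss$n_discordant %||% NA_integer_)
}
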