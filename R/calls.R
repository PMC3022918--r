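## Score cutoffs and ternary splice calls.

#' Derive a symmetric score cutoff from baseline scores
#'
#' `cutoff = |mean(baseline)| + 3 * SD(baseline)`, applied symmetrically as
#' +/-cutoff (symmetry in the score is assumed for positive and negative
#' splicing changes).  The baseline is the constitutive-junction scores by
#' default — the cutoff marks the boundary of the constitutive score
#' distribution — or all scores with `baseline = "all"`.
#'
#' @param scores a ScoreTable, or a bare numeric vector of baseline scores.
#' @param baseline `"constitutive_only"` (default; requires `annot`) or
#'   `"all"`.  Ignored when `scores` is a numeric vector.
#' @param annot junction annotation (gene_id, junction_id, status), needed
#'   for `baseline = "constitutive_only"`.
#' @return an object of class `asmip_cutoff`: list with `cutoff`,
#'   `provenance = "derived_mean3sd"`, `mean_used`, `three_sd_used`,
#'   `n_baseline`, and the score_type/platform when derivable.
#' @export
derive_cutoff <- function(scores,
                          baseline = c("constitutive_only", "all"),
                          annot = NULL) {
  baseline <- match.arg(baseline)
  score_type <- NA_character_
  platform <- NA_character_
  if (is.numeric(scores)) {
    v <- scores[is.finite(scores)]
  } else {
    sc <- as.data.table(scores)
    assert_columns(sc, c("gene_id", "junction_id", "value"), "ScoreTable")
    if ("score_type" %in% names(sc) && uniqueN(sc$score_type) == 1L)
      score_type <- sc$score_type[1L]
    if ("platform" %in% names(sc) && uniqueN(sc$platform) == 1L)
      platform <- sc$platform[1L]
    if (baseline == "constitutive_only") {
      if (is.null(annot)) {
        stop("baseline = 'constitutive_only' needs a junction annotation",
             call. = FALSE)
      }
      an <- as.data.table(annot)
      sc <- merge(sc, an[, .(gene_id, junction_id, status)],
                  by = c("gene_id", "junction_id"))
      sc <- sc[status == "constitutive"]
    }
    v <- sc$value[is.finite(sc$value)]
  }
  if (length(v) < 10L) {
    stop("need >= 10 baseline scores to derive a cutoff (got ", length(v),
         ")", call. = FALSE)
  }
  m <- mean(v)
  s3 <- 3 * sd(v)
  structure(list(score_type = score_type, platform = platform,
                 cutoff = abs(m) + s3, provenance = "derived_mean3sd",
                 mean_used = m, three_sd_used = s3, n_baseline = length(v)),
            class = "asmip_cutoff")
}

#' Fixed score cutoff
#'
#' @param cutoff non-negative symmetric cutoff (the multiplexed-probe assay
#'   used 1.3 on both array and sequencing readouts).
#' @param score_type,platform optional labels.
#' @return an `asmip_cutoff` object with `provenance = "fixed"`.
#' @export
fixed_cutoff <- function(cutoff = 1.3, score_type = NA_character_,
                         platform = NA_character_) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  structure(list(score_type = score_type, platform = platform,
                 cutoff = cutoff, provenance = "fixed",
                 mean_used = NA_real_, three_sd_used = NA_real_,
                 n_baseline = NA_integer_),
            class = "asmip_cutoff")
}

#' @export
print.asmip_cutoff <- function(x, ...) {
  cat(sprintf("splice-call cutoff +/-%.4g (%s", x$cutoff, x$provenance))
  if (x$provenance == "derived_mean3sd")
    cat(sprintf(": |mean| %.4g + 3SD %.4g, n = %d",
                abs(x$mean_used), x$three_sd_used, x$n_baseline))
  cat(")\n")
  invisible(x)
}

#' Ternary splice calls from scores
#'
#' `call = +1` when `score > +cutoff`, `-1` when `score < -cutoff`, else 0.
#' Inequalities are strict: a score exactly at the cutoff is called 0.
#'
#' @param scores a ScoreTable.
#' @param cutoff an `asmip_cutoff` object or a non-negative number.
#' @return data.table gene_id, junction_id, tissue_id, call (-1/0/+1),
#'   score, cutoff.
#' @export
make_calls <- function(scores, cutoff) {
  if (is.numeric(cutoff)) cutoff <- fixed_cutoff(cutoff)
  stopifnot(inherits(cutoff, "asmip_cutoff"))
  sc <- as.data.table(scores)
  assert_columns(sc, c("gene_id", "junction_id", "tissue_id", "value"),
                 "ScoreTable")
  co <- cutoff$cutoff
  out <- sc[, .(gene_id, junction_id, tissue_id,
                call = fifelse(value > co, 1L, fifelse(value < -co, -1L, 0L)),
                score = value, cutoff = co)]
  setorder(out, gene_id, junction_id, tissue_id)
  out[]
}

#' Pair two call sets into binary labels with sign agreement
#'
#' Converts ternary calls on both sides to binary (non-zero versus zero) and
#' classifies each (junction, tissue) pair: a pair is a true (concordant)
#' positive only when both calls are non-zero AND share the same sign;
#' opposite-sign pairs are discordant — they count as errors on both ROC
#' axes, which is why such curves cannot reach (1, 1).
#'
#' @param calls,truth_calls call tables from [make_calls()] (or any table
#'   with gene_id, junction_id, tissue_id, call) on matching keys.
#' @return data.table with the keys, `call`, `truth_call`, binary `bin` and
#'   `truth_bin`, and `agreement` in `c("concordant_positive",
#'   "concordant_negative", "discordant", "false_positive",
#'   "false_negative")`.
#' @export
binarize_calls <- function(calls, truth_calls) {
  a <- as.data.table(calls)
  b <- as.data.table(truth_calls)
  keys <- c("gene_id", "junction_id", "tissue_id")
  assert_columns(a, c(keys, "call"), "calls")
  assert_columns(b, c(keys, "call"), "truth_calls")
  m <- merge(a[, c(keys, "call"), with = FALSE],
             b[, .(gene_id, junction_id, tissue_id, truth_call = call)],
             by = keys, all = TRUE)
  bad <- m[is.na(call) | is.na(truth_call)]
  if (nrow(bad) > 0L) {
    stop("key mismatch between call sets; unmatched keys: ",
         paste(utils::head(bad[, paste(gene_id, junction_id, tissue_id,
                                       sep = ":")], 10L), collapse = ", "),
         if (nrow(bad) > 10L) " ..." else "", call. = FALSE)
  }
  m[, `:=`(bin = as.integer(call != 0L), truth_bin = as.integer(truth_call != 0L))]
  m[, agreement := fcase(
    call != 0L & truth_call != 0L & sign(call) == sign(truth_call),
      "concordant_positive",
    call != 0L & truth_call != 0L, "discordant",
    call == 0L & truth_call == 0L, "concordant_negative",
    call != 0L & truth_call == 0L, "false_positive",
    default = "false_negative")]
  setorder(m, gene_id, junction_id, tissue_id)
  m[]
}

utils::globalVariables(c("bin", "truth_bin"))
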