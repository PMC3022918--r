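## Probe-effect-corrected splice scores.
##
## R-score (reference-based):  d = theta_i - theta_REF per (junction, tag,
## tissue); f = d - mean(d over the gene's constitutive junctions, same tag
## and tissue); f-bar = tag average; R = f-bar / s_g with s_g a robust scale
## of the constitutive f-bar pooled over tissues.
##
## M-score (model-based):  median polish of the (junction,tag) x tissue
## log2 matrix per gene; f* = residuals; M = tag-averaged f* / s*_g with
## s*_g the MAD (x 1.4826) of f* over all junctions and tissues of the gene.

#' Robust scale estimate with MAD-to-SD fallback
#'
#' Default is `mad(x)` (median absolute deviation scaled by 1.4826 so it
#' estimates a normal SD); when the MAD degenerates to zero the ordinary SD
#' is used.  `method = "huber"` uses the iterated Huber proposal-2 scale
#' ([MASS::hubers()]), falling back to the MAD rule on failure.
#'
#' @param x numeric vector.
#' @param method `"mad"` (default) or `"huber"`.
#' @return a scale estimate (>= 0), or `NA` when fewer than 2 finite values.
#' @export
robust_scale <- function(x, method = c("mad", "huber")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  if (method == "huber") {
    s <- tryCatch(MASS::hubers(x)$s, error = function(e) NA_real_)
    if (is.finite(s) && s > 0) return(s)
  }
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  s
}

#' Reference-based splice scores (R-scores)
#'
#' @param theta a LogSignalTable (single platform) including the reference
#'   tissue.
#' @param annot junction annotation: data.table with gene_id, junction_id,
#'   status in `c("constitutive", "alternative")`.
#' @param ref_tissue reference tissue id (default `"REF"`).
#' @param scale robust scale method for `s_g`, see [robust_scale()].
#' @return a ScoreTable data.table (gene_id, junction_id, tissue_id,
#'   score_type = "R", value, n_tags_used, platform) with attributes
#'   `intermediates` (list: d, f, fbar, s_g tables) for diagnostics.
#'   Genes with fewer than 2 constitutive junctions with data, or with a
#'   degenerate scale, are skipped with a warning (scores are never +/-Inf).
#' @export
r_score <- function(theta, annot, ref_tissue = REF_TISSUE,
                    scale = c("mad", "huber")) {
  scale <- match.arg(scale)
  th <- as.data.table(theta)
  assert_columns(th, c("platform", "gene_id", "junction_id", "tag",
                       "tissue_id", "theta"), "LogSignalTable")
  pf <- assert_single_platform(th)
  an <- as.data.table(annot)
  assert_columns(an, c("gene_id", "junction_id", "status"), "annotation")

  th <- th[not_missing(th) & is.finite(theta)]
  ref <- th[tissue_id == ref_tissue,
            .(gene_id, junction_id, tag, theta_ref = theta)]
  if (nrow(ref) == 0L) {
    stop("reference tissue '", ref_tissue, "' absent; R-scores need it",
         call. = FALSE)
  }
  d <- merge(th[tissue_id != ref_tissue], ref,
             by = c("gene_id", "junction_id", "tag"))
  d[, d := theta - theta_ref]
  d <- merge(d, an[, .(gene_id, junction_id, status)],
             by = c("gene_id", "junction_id"))

  ok <- d[status == "constitutive", .(ncj = uniqueN(junction_id)),
          by = gene_id][ncj >= 2L, gene_id]
  skipped <- setdiff(unique(d$gene_id), ok)
  if (length(skipped)) {
    warning("skipping gene(s) without >= 2 constitutive junctions with data: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  d <- d[gene_id %in% ok]
  if (nrow(d) == 0L) stop("no scorable genes", call. = FALSE)

  dbar <- d[status == "constitutive",
            .(dbar_c = mean(d)), by = .(gene_id, tag, tissue_id)]
  f <- merge(d, dbar, by = c("gene_id", "tag", "tissue_id"))
  f[, f := d - dbar_c]
  fbar <- f[, .(fbar = mean(f), n_tags_used = .N),
            by = .(gene_id, junction_id, tissue_id, status)]
  sg <- fbar[status == "constitutive",
             .(s_g = robust_scale(fbar, scale)), by = gene_id]
  bad <- sg[!is.finite(s_g) | s_g <= 0, gene_id]
  if (length(bad)) {
    warning("R-scores undefined (zero/degenerate scale) for gene(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  scores <- merge(fbar, sg[is.finite(s_g) & s_g > 0], by = "gene_id")
  scores[, value := fbar / s_g]
  out <- scores[, .(gene_id, junction_id, tissue_id, score_type = "R",
                    value, n_tags_used, platform = pf)]
  setorder(out, gene_id, junction_id, tissue_id)
  setattr(out, "intermediates",
          list(d = f[, .(gene_id, junction_id, tag, tissue_id, d, dbar_c, f)],
               fbar = fbar, s_g = sg))
  out[]
}

#' Model-based splice scores (M-scores)
#'
#' Per gene, fits the additive model
#' `theta[j,k; i] = p[j,k] + t[i] + eps` by [median_polish()] on the
#' (junction, tag) x tissue matrix — all tissues, the reference included as
#' an ordinary column, no constitutive annotation needed.  The residuals
#' `f*` are tag-averaged and divided by `s*_g`, the MAD (x 1.4826) of `f*`
#' over all junctions and tissues of the gene.
#'
#' @param theta a LogSignalTable (single platform).
#' @param tol,max_iter median polish stopping parameters, see
#'   [median_polish()].
#' @return a ScoreTable data.table (score_type = "M") with attributes
#'   `intermediates` (f* residual table, per-gene s*_g) and `fits` (the
#'   per-gene `asmip_medpolish` objects).  Genes with fewer than 2 junctions
#'   or 2 tissues with data, or a zero residual scale, are skipped with a
#'   warning (scores are never NaN-from-division).
#' @export
m_score <- function(theta, tol = 0.01, max_iter = 10L) {
  th <- as.data.table(theta)
  assert_columns(th, c("platform", "gene_id", "junction_id", "tag",
                       "tissue_id", "theta"), "LogSignalTable")
  pf <- assert_single_platform(th)
  th <- th[not_missing(th) & is.finite(theta)]

  fits <- list()
  res_list <- list()
  skipped <- character(0)
  for (g in unique(th$gene_id)) {
    tg <- th[gene_id == g]
    if (uniqueN(tg$junction_id) < 2L || uniqueN(tg$tissue_id) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    tg[, row_id := paste(junction_id, tag, sep = "|")]
    wide <- dcast(tg, row_id ~ tissue_id, value.var = "theta")
    m <- as.matrix(wide, rownames = "row_id")
    ## rows/columns with no observed cell cannot constrain the fit
    m <- m[rowSums(!is.na(m)) > 0L, colSums(!is.na(m)) > 0L, drop = FALSE]
    fit <- median_polish(m, tol = tol, max_iter = max_iter)
    fits[[g]] <- fit
    r <- as.data.table(as.table(fit$residuals))
    setnames(r, c("row_id", "tissue_id", "fstar"))
    r <- r[!is.na(fstar)]
    r[, gene_id := g]
    r[, junction_id := sub("\\|[0-9]+$", "", row_id)]
    r[, tag := as.integer(sub("^.*\\|", "", row_id))]
    res_list[[g]] <- r[, .(gene_id, junction_id, tag, tissue_id, fstar)]
  }
  if (length(skipped)) {
    warning("skipping gene(s) without >= 2 junctions and >= 2 tissues: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(res_list)) stop("no scorable genes", call. = FALSE)
  fstar <- rbindlist(res_list)

  sstar <- fstar[, .(s_star = stats::mad(fstar)), by = gene_id]
  bad <- sstar[!is.finite(s_star) | s_star <= 0, gene_id]
  if (length(bad)) {
    warning("M-scores undefined (zero residual scale) for gene(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  favg <- fstar[, .(fstar_avg = mean(fstar), n_tags_used = .N),
                by = .(gene_id, junction_id, tissue_id)]
  scores <- merge(favg, sstar[is.finite(s_star) & s_star > 0], by = "gene_id")
  scores[, value := fstar_avg / s_star]
  out <- scores[, .(gene_id, junction_id, tissue_id, score_type = "M",
                    value, n_tags_used, platform = pf)]
  setorder(out, gene_id, junction_id, tissue_id)
  setattr(out, "intermediates", list(fstar = fstar, s_star = sstar))
  setattr(out, "fits", fits)
  out[]
}

#' Tissue-pair splice scores
#'
#' For each gene with an assigned tissue pair, returns the absolute
#' difference of its junction scores between the two tissues.  The
#' difference of two splice scores is itself a splice score with the
#' baseline shifted to one tissue of the pair, which is how control-based
#' ROC evaluation restricts to the tissue pairs known to show splicing.
#'
#' @param scores a ScoreTable (output of [r_score()] or [m_score()]).
#' @param pairs data.table with gene_id, tissue_a, tissue_b.
#' @return data.table gene_id, junction_id, score_type, platform, tissue_a,
#'   tissue_b, value (= |score_A - score_B|).  Genes missing either tissue
#'   are skipped with a warning.
#' @export
tissue_pair_scores <- function(scores, pairs) {
  sc <- as.data.table(scores)
  assert_columns(sc, c("gene_id", "junction_id", "tissue_id", "score_type",
                       "value"), "ScoreTable")
  pr <- as.data.table(pairs)
  assert_columns(pr, c("gene_id", "tissue_a", "tissue_b"), "pair map")
  if (!"platform" %in% names(sc)) sc[, platform := NA_character_]

  a <- merge(sc, pr[, .(gene_id, tissue_id = tissue_a)],
             by = c("gene_id", "tissue_id"))
  b <- merge(sc, pr[, .(gene_id, tissue_id = tissue_b)],
             by = c("gene_id", "tissue_id"))
  m <- merge(a[, .(gene_id, junction_id, score_type,
                   platform, value_a = value)],
             b[, .(gene_id, junction_id, score_type, value_b = value)],
             by = c("gene_id", "junction_id", "score_type"))
  done <- unique(m$gene_id)
  skipped <- setdiff(pr$gene_id, done)
  if (length(skipped)) {
    warning("tissue pair incomplete for gene(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  m <- merge(m, pr, by = "gene_id")
  out <- m[, .(gene_id, junction_id, score_type, platform,
               tissue_a, tissue_b, value = abs(value_a - value_b))]
  setorder(out, gene_id, junction_id)
  out[]
}
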