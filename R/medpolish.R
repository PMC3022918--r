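## Tukey median polish with missing cells and a proportional-reduction
## stopping rule — the estimator behind the M-score's additive model
## theta[j,k; i] = p[j,k] + t[i] + eps.

#' Fit an additive two-way model by median polish
#'
#' Alternately removes row (junction-tag) and column (tissue) medians from
#' the observed cells, rows first, until the proportional reduction of the
#' sum of absolute residuals (SAR) falls below `tol` or `max_iter` full
#' sweeps have run.  Missing cells stay missing and never enter a median.
#' The decomposition is exact at every observed cell:
#' `x = overall + row_effects + col_effects + residuals`.
#'
#' @param x a numeric matrix (rows = junction-tag measurements, columns =
#'   tissues), `NA` for missing cells.  Every row and column must contain at
#'   least one observed cell.
#' @param tol stop when `(SAR_prev - SAR_new) / SAR_prev < tol`
#'   (default 0.01).
#' @param max_iter maximum number of full row+column sweeps (default 10).
#' @return an object of class `asmip_medpolish`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals` (same shape as `x`),
#'   `sar`, `n_iterations`, `converged`.
#' @examples
#' m <- outer(c(1, 4, 7), c(0, 1, 2), `+`)
#' fit <- median_polish(m)
#' max(abs(fit$residuals))  # 0: exactly additive data
#' @export
median_polish <- function(x, tol = 0.01, max_iter = 10L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix", call. = FALSE)
  if (length(x) == 0L || all(is.na(x))) stop("empty matrix", call. = FALSE)
  if (any(rowSums(!is.na(x)) == 0L)) stop("row with no observed cells", call. = FALSE)
  if (any(colSums(!is.na(x)) == 0L)) stop("column with no observed cells", call. = FALSE)
  stopifnot(tol >= 0, max_iter >= 1L)

  z <- x
  overall <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  sar_prev <- sum(abs(z), na.rm = TRUE)
  converged <- sar_prev == 0
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    ## rows first
    rdelta <- apply(z, 1L, median, na.rm = TRUE)
    z <- z - rdelta
    re <- re + rdelta
    shift <- median(ce)
    ce <- ce - shift
    overall <- overall + shift
    ## then columns
    cdelta <- apply(z, 2L, median, na.rm = TRUE)
    z <- sweep(z, 2L, cdelta)
    ce <- ce + cdelta
    shift <- median(re)
    re <- re - shift
    overall <- overall + shift
    sar <- sum(abs(z), na.rm = TRUE)
    if (sar == 0 || (sar_prev - sar) < tol * sar_prev) converged <- TRUE
    sar_prev <- sar
  }
  structure(list(overall = overall,
                 row_effects = setNames(re, rownames(x)),
                 col_effects = setNames(ce, colnames(x)),
                 residuals = z, sar = sar_prev,
                 n_iterations = iter, converged = converged),
            class = "asmip_medpolish")
}

#' @export
print.asmip_medpolish <- function(x, ...) {
  cat(sprintf("median polish fit: %d x %d, %d sweep(s), %s (SAR = %.4g)\n",
              length(x$row_effects), length(x$col_effects), x$n_iterations,
              if (x$converged) "converged" else "not converged", x$sar))
  invisible(x)
}

#' Fitted values of a median polish decomposition
#'
#' @param object an `asmip_medpolish` fit.
#' @param ... unused.
#' @return matrix of `overall + row + col` (NA pattern of the residuals).
#' @export
fitted.asmip_medpolish <- function(object, ...) {
  f <- object$overall + outer(object$row_effects, object$col_effects, `+`)
  f[is.na(object$residuals)] <- NA_real_
  f
}
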