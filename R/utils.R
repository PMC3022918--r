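## Internal helpers: seeding, constants, TSV round-trip, validation.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Reference sample identifier used across the package.  The reference is a
## pooled multi-tissue RNA mixture that approximates baseline splicing; it is
## required by R-scores and treated as an ordinary column by M-scores.
REF_TISSUE <- "REF"

## Dilution levels, ordered by input volume (lowest first).
DILUTION_LEVELS <- c("low", "mid", "high")

#' Derive a stage-specific RNG seed from a top-level seed
#'
#' All randomness in the package flows from one top-level integer seed;
#' each pipeline stage perturbs it deterministically so that stages are
#' reproducible independently of call order.  Kept strictly below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stage integer stage offset (0 = truth, 1 = seq, 2 = array, 3 = qpcr).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + 104729 * as.numeric(stage)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Write a table to tab-separated text
#'
#' One-line header, no quoting, `NA` for missing cells; the output of
#' [read_asmip_tsv()] on the file equals the input table.
#'
#' @param x a data.frame or data.table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_asmip_tsv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path, sep = "\t", quote = FALSE,
                     na = "NA", logical01 = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_asmip_tsv()]
#'
#' @param path file path.
#' @return a data.table.
#' @export
read_asmip_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- data.table::fread(path, sep = "\t", na.strings = "NA",
                         logical01 = FALSE)
  ## all-NA columns come back logical; restore the schema's types
  chr_cols <- intersect(c("platform", "gene_id", "junction_id", "tissue_id",
                          "dilution", "missing_reason"), names(x))
  for (cc in chr_cols) {
    if (is.logical(x[[cc]])) set(x, j = cc, value = as.character(x[[cc]]))
  }
  int_cols <- intersect(c("tag", "call", "truth_call", "n_tags_used"),
                        names(x))
  for (cc in int_cols) {
    if (is.logical(x[[cc]])) set(x, j = cc, value = as.integer(x[[cc]]))
  }
  x
}

#' @noRd
assert_columns <- function(x, cols, what = "table") {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(what, " lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
assert_single_platform <- function(x) {
  pf <- unique(x$platform)
  if (length(pf) != 1L) {
    stop("expected a single platform per call, got: ",
         paste(pf, collapse = ", "), call. = FALSE)
  }
  pf
}

#' @noRd
not_missing <- function(x) !(x$missing %in% TRUE)
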