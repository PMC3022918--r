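# Independent oracles. These deliberately share no code with the package:
# plain loops, no effect bookkeeping, quantities recomputed from scratch.

# Brute-force median polish residuals: alternate row-then-column median
# sweeps on the observed cells, recomputing the sum of absolute residuals
# after every full sweep and stopping when its proportional reduction drops
# below `tol` (or at `max_sweeps`).
oracle_medpolish_residuals <- function(x, tol = 1e-9, max_sweeps = 1000L) {
  z <- x
  sar_prev <- sum(abs(z), na.rm = TRUE)
  if (sar_prev == 0) return(z)
  for (s in seq_len(max_sweeps)) {
    z <- z - apply(z, 1L, stats::median, na.rm = TRUE)
    z <- sweep(z, 2L, apply(z, 2L, stats::median, na.rm = TRUE))
    sar <- sum(abs(z), na.rm = TRUE)
    if (sar == 0 || (sar_prev - sar) < tol * sar_prev) break
    sar_prev <- sar
  }
  z
}

# Exhaustive pairwise concordance index with 0.5 tie credit.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Build a LogSignalTable from explicit theta values.
theta_table <- function(df, platform = "seq") {
  dt <- data.table::as.data.table(df)
  dt[, platform := platform]
  if (!"tag" %in% names(dt)) dt[, tag := 1L]
  dt[, missing := FALSE]
  dt[, missing_reason := NA_character_]
  dt[, low_confidence := FALSE]
  dt[]
}

# Model-form gene: theta = p + t + delta exactly (no noise), with n_alt
# junctions shifted in 1-2 of the non-reference tissues (varied magnitudes
# and signs).  Sparse deltas keep every row/column median pinned to
# model-exact cells, so the polish residuals depend only on the delta
# pattern -- the domain where column-shift invariance is exact.  The
# residual MAD is 0 on such data (most residuals are exactly zero), so the
# scaled M-score is undefined by design; tests compare the residuals f*.
model_gene_theta <- function(gene = "G01", n_con = 8L, n_alt = 4L,
                             seed = 1L) {
  set.seed(seed)
  tissues <- c("REF", "A", "B", "C", "D", "E")
  nj <- n_con + n_alt
  jid <- sprintf("%d-%d", seq_len(nj), seq_len(nj) + 1L)
  alt <- jid[seq_len(n_alt)]
  rows <- data.table::CJ(gene_id = gene, junction_id = jid, tag = 1:2,
                         tissue_id = tissues)
  p <- stats::rnorm(2L * nj, 0, 1)
  names(p) <- paste(rep(jid, each = 2L), rep(1:2, nj))
  tt <- stats::runif(length(tissues), -2, 2)
  names(tt) <- tissues
  rows[, theta := p[paste(junction_id, tag)] + tt[tissue_id]]
  deltas <- list()
  for (j in alt) {
    shifted <- sample(setdiff(tissues, "REF"), sample(1:2, 1L))
    d <- sample(c(-1, 1), 1L) * stats::runif(1, 1.5, 3.5)
    rows[junction_id == j & tissue_id %in% shifted, theta := theta + d]
    deltas[[j]] <- data.table::data.table(junction_id = j,
                                          tissue_id = shifted, delta = d)
  }
  out <- theta_table(rows)
  data.table::setattr(out, "delta_cells", data.table::rbindlist(deltas))
  out
}

# Aligned polish residuals f* from an m_score run (all genes, including
# ones whose scaled score is undefined).
mscore_residuals <- function(theta, ...) {
  ms <- suppressWarnings(m_score(theta, ...))
  f <- attr(ms, "intermediates")$fstar
  data.table::setorder(f, gene_id, junction_id, tag, tissue_id)
  f
}

# Tiny array SignalTable for preprocessing tests: one array per
# (tissue, dilution) with the given unused-feature values.
array_table <- function(probes, unused_values) {
  pr <- data.table::as.data.table(probes)
  pr[, `:=`(platform = "array", is_unused_feature = FALSE)]
  if (!"tag" %in% names(pr)) pr[, tag := 1L]
  arrays <- unique(pr[, .(tissue_id, dilution)])
  un <- arrays[, .(platform = "array", gene_id = NA_character_,
                   junction_id = NA_character_, tag = NA_integer_,
                   value = unused_values, is_unused_feature = TRUE),
               by = .(tissue_id, dilution)]
  data.table::rbindlist(list(pr, un), use.names = TRUE, fill = TRUE)
}

# End-to-end single-seed M-score recovery run on sequencing data under the
# generator's default (stated) conditions; used by property and acceptance
# tests.
mscore_recovery_run <- function(seed, cutoff = 1.3) {
  cfg <- sim_config(seed = seed)
  truth <- simulate_truth(cfg)
  th <- log_transform(render_sequencing(truth, cfg))
  ms <- suppressWarnings(m_score(th))
  calls <- make_calls(ms, cutoff)
  alt <- truth$deltas[tissue_id != "REF" & delta != 0]
  rec <- merge(alt, calls, by = c("gene_id", "junction_id", "tissue_id"))
  recovery <- mean(rec$call == sign(rec$delta))
  pairs <- truth_pair_map(truth)
  ps <- tissue_pair_scores(ms, pairs)
  labels <- truth_pair_labels(truth, pairs)
  m <- merge(ps, labels, by = c("gene_id", "junction_id"))
  list(recovery = recovery,
       auc = concordance_auc(m$value, m$label),
       n_alt_cells = nrow(rec))
}
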