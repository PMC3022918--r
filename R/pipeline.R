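## End-to-end orchestration: simulate -> preprocess -> score -> call ->
## evaluate, with every intermediate written as diff-able TSV.

#' Pipeline configuration
#'
#' All stage parameters in one validated list; defaults are the assay's
#' published settings where it states them (background multiplier 1.96,
#' dynamic-range ceiling 3500 units, low-confidence threshold 4 reads,
#' fixed splice-call cutoff 1.3).
#'
#' @param seed top-level integer seed; all stage randomness derives from it.
#' @param sim an [sim_config()] for the synthetic inputs (its seed is
#'   overridden by `seed`).
#' @param z background exclusion multiplier.
#' @param upper array dynamic-range ceiling (fluorescence units).
#' @param min_reads sequencing low-confidence threshold.
#' @param pseudocount sequencing pseudocount (0 = off).
#' @param tol,max_iter median polish stopping parameters.
#' @param scale robust scale method for R-scores.
#' @param cutoff `"fixed:<x>"`, `"derive:constitutive"` or `"derive:all"`.
#' @param platforms platforms to process.
#' @param score_methods any of `"R"`, `"M"`.
#' @return an object of class `asmip_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            z = 1.96, upper = 3500,
                            min_reads = 4L, pseudocount = 0,
                            tol = 0.01, max_iter = 10L,
                            scale = "mad",
                            cutoff = "fixed:1.3",
                            platforms = c("seq", "array", "qpcr"),
                            score_methods = c("R", "M")) {
  sim$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), sim = sim, z = z, upper = upper,
              min_reads = as.integer(min_reads), pseudocount = pseudocount,
              tol = tol, max_iter = as.integer(max_iter), scale = scale,
              cutoff = cutoff, platforms = platforms,
              score_methods = score_methods)
  class(cfg) <- "asmip_pipeline_config"
  validate_pipeline_config(cfg)
}

#' @noRd
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "asmip_pipeline_config"))
  validate_sim_config(cfg$sim)
  if (!grepl("^(fixed:[0-9.]+|derive:(constitutive|all))$", cfg$cutoff))
    stop("cutoff must be 'fixed:<x>', 'derive:constitutive' or 'derive:all'",
         call. = FALSE)
  if (!all(cfg$platforms %in% c("seq", "array", "qpcr")))
    stop("unknown platform in config", call. = FALSE)
  if (!all(cfg$score_methods %in% c("R", "M")))
    stop("score_methods must be 'R' and/or 'M'", call. = FALSE)
  stopifnot(cfg$z >= 0, cfg$upper > 0, cfg$min_reads >= 0,
            cfg$pseudocount >= 0, cfg$tol >= 0, cfg$max_iter >= 1L)
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x`.
#'
#' @param config an `asmip_pipeline_config`.
#' @param path JSON file path.
#' @return the path (write) or the config object (read).
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sim_args <- x$sim
  sim_args$nb_dispersion <- sim_args$nb_dispersion %||% NULL
  sim_args$array_gain <- sim_args$array_gain %||% NULL
  sim <- do.call(sim_config, sim_args)
  pipeline_config(seed = x$seed, sim = sim, z = x$z, upper = x$upper,
                  min_reads = x$min_reads, pseudocount = x$pseudocount,
                  tol = x$tol, max_iter = x$max_iter, scale = x$scale,
                  cutoff = x$cutoff, platforms = x$platforms,
                  score_methods = x$score_methods)
}

#' @noRd
parse_cutoff_spec <- function(spec, scores = NULL, annot = NULL) {
  if (startsWith(spec, "fixed:")) {
    fixed_cutoff(as.numeric(sub("^fixed:", "", spec)))
  } else {
    mode <- sub("^derive:", "", spec)
    derive_cutoff(scores,
                  baseline = if (mode == "all") "all" else "constitutive_only",
                  annot = annot)
  }
}

#' Run the full pipeline into a directory
#'
#' Executes simulate -> preprocess -> score -> call -> evaluate, writing
#' every intermediate table as TSV, the resolved config as JSON, an
#' evaluation report per (platform, method), and a log with seed and
#' per-stage row counts.  Identical config + seed gives byte-identical
#' outputs.  A stage failure leaves partial outputs plus a `FAILED` marker
#' file and aborts with a stage-named error.
#'
#' @param config an `asmip_pipeline_config` (or path to its JSON).
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the truth, score tables, call tables and
#'   evaluation reports.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(log_lines, paste("FAILED at stage:", stage),
                 conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  res <- tryCatch({
    say("asmipr run: seed %d, platforms [%s], methods [%s]",
        config$seed, paste(config$platforms, collapse = ","),
        paste(config$score_methods, collapse = ","))
    write_pipeline_config(config, file.path(out_dir, "config_resolved.json"))

    stage <- "simulate"
    truth <- simulate_truth(config$sim)
    write_asmip_tsv(truth$probe_effects, file.path(out_dir, "truth_probe_effects.tsv"))
    write_asmip_tsv(truth$baselines, file.path(out_dir, "truth_baselines.tsv"))
    write_asmip_tsv(truth$deltas, file.path(out_dir, "truth_deltas.tsv"))
    write_asmip_tsv(truth$junctions, file.path(out_dir, "junction_annotation.tsv"))
    raw <- list()
    for (pf in config$platforms) {
      raw[[pf]] <- switch(pf,
        seq = render_sequencing(truth, config$sim),
        array = render_array(truth, config$sim),
        qpcr = render_qpcr(truth, config$sim))
      write_asmip_tsv(raw[[pf]], file.path(out_dir, paste0("signals_", pf, ".tsv")))
      say("simulate: %s rows = %d", pf, nrow(raw[[pf]]))
    }

    stage <- "preprocess"
    theta <- list()
    for (pf in config$platforms) {
      theta[[pf]] <- switch(pf,
        seq = log_transform(raw$seq, min_reads = config$min_reads,
                            pseudocount = config$pseudocount),
        array = log_transform(select_dilution(
          subtract_background(raw$array, z = config$z),
          upper = config$upper)),
        qpcr = log_transform(raw$qpcr))
      write_asmip_tsv(theta[[pf]], file.path(out_dir, paste0("theta_", pf, ".tsv")))
      say("preprocess: %s theta rows = %d (missing %d)", pf,
          nrow(theta[[pf]]), sum(theta[[pf]]$missing))
    }

    stage <- "score"
    scores <- list()
    for (pf in config$platforms) {
      for (meth in config$score_methods) {
        key <- paste(meth, pf, sep = "_")
        scores[[key]] <- withCallingHandlers(
          if (meth == "R") {
            r_score(theta[[pf]], truth$junctions, scale = config$scale)
          } else {
            m_score(theta[[pf]], tol = config$tol, max_iter = config$max_iter)
          },
          warning = function(w) {
            say("score %s: %s", key, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        write_asmip_tsv(scores[[key]],
                        file.path(out_dir, paste0("scores_", key, ".tsv")))
        say("score: %s rows = %d", key, nrow(scores[[key]]))
      }
    }

    stage <- "call"
    tcalls <- truth_calls(truth)
    write_asmip_tsv(tcalls, file.path(out_dir, "truth_calls.tsv"))
    calls <- list()
    cutoffs <- list()
    for (key in names(scores)) {
      co <- parse_cutoff_spec(config$cutoff, scores[[key]], truth$junctions)
      cutoffs[[key]] <- co
      calls[[key]] <- make_calls(scores[[key]], co)
      write_asmip_tsv(calls[[key]],
                      file.path(out_dir, paste0("calls_", key, ".tsv")))
      say("call: %s cutoff +/-%.4g, nonzero = %d", key, co$cutoff,
          sum(calls[[key]]$call != 0L))
    }
    jsonlite::write_json(lapply(cutoffs, unclass),
                         file.path(out_dir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "evaluate"
    reports <- list()
    for (key in names(calls)) {
      keys3 <- c("gene_id", "junction_id", "tissue_id")
      ## evaluate on the intersection of keys (the reference column has no
      ## truth call; M-score tables carry it as an ordinary tissue)
      common <- merge(unique(calls[[key]][, keys3, with = FALSE]),
                      unique(tcalls[, keys3, with = FALSE]), by = keys3)
      bp <- binarize_calls(merge(calls[[key]], common, by = keys3),
                           merge(tcalls, common, by = keys3))
      ss <- sens_spec(bp)
      sc <- merge(scores[[key]],
                  tcalls[, .(gene_id, junction_id, tissue_id,
                             label = as.integer(call != 0L))],
                  by = keys3)
      auc <- if (uniqueN(sc$label) == 2L)
        concordance_auc(abs(sc$value), sc$label) else NA_real_
      reports[[key]] <- eval_report(auc = auc, ss = ss)
      if (uniqueN(sc$label) == 2L) {
        write_asmip_tsv(roc_points(abs(sc$value), sc$label),
                        file.path(out_dir, paste0("roc_", key, ".tsv")))
      }
      say("evaluate: %s auc = %.3f sens = %.3f spec = %.3f", key,
          reports[[key]]$auc, ss$sensitivity, ss$specificity)
    }
    jsonlite::write_json(reports, file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "finish"
    writeLines(log_lines, log_path)
    list(truth = truth, theta = theta, scores = scores, calls = calls,
         cutoffs = cutoffs, reports = reports, out_dir = out_dir)
  }, error = on_fail)
  invisible(res)
}
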