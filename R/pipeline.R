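#' Run the simulate-and-analyze pipeline end to end
#'
#' Simulates a paired experiment from `config`, writes the simulated
#' inputs, runs the junction filters, ratio table and retention
#' classification, and writes `summary.tsv`, `retention.tsv`,
#' `dotplot.tsv`, `truth_vs_detected.tsv` (the confusion table of
#' implanted vs called misspliced introns) and a `run.log` echoing every
#' parameter, the input checksums and the per-rule filter removal
#' counts. Identical config and seed give byte-identical tables.
#'
#' @param config a [simConfig()] (the seed lives here).
#' @param filter a [filterConfig()].
#' @param outdir run directory, created if needed.
#' @param denominator passed to [summarizeSplicing()].
#' @return invisibly, a list with elements `summary`
#'   ([SplicingSummary-class]), `retention`, `ratios`, `confusion`
#'   (named TP/FP/FN/TN), `detectedFraction`, `sensitivity`, `fpr`, and
#'   `paths`.
#' @seealso [runAnalysis()] for precomputed inputs, [exportDotplot()]
#' @export
runFull <- function(config, filter = filterConfig(), outdir,
                    denominator = "all") {
  stopifnot(is(config, "SimConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateExperiment(config)
  in_dir <- file.path(outdir, "inputs")
  in_paths <- tryCatch(
    writeSimulation(sim, in_dir),
    error = function(e) stop("stage 'simulate' failed: ",
                             conditionMessage(e), call. = FALSE))

  res <- tryCatch(
    .analyze(sim@junctions, sim@introns, sim@intronCounts, filter,
             denominator),
    error = function(e) stop("stage 'analyze' failed: ",
                             conditionMessage(e), call. = FALSE))

  truth <- simTruth(sim)
  conf <- confusionTable(truth, res$retention)
  out_paths <- c(
    summary = file.path(outdir, "summary.tsv"),
    retention = file.path(outdir, "retention.tsv"),
    dotplot = file.path(outdir, "dotplot.tsv"),
    confusion = file.path(outdir, "truth_vs_detected.tsv"),
    log = file.path(outdir, "run.log"))
  writeSummary(res$summary, out_paths[["summary"]])
  .write_tsv(as.data.frame(res$retention), out_paths[["retention"]])
  writeDotplotTable(res$summary, out_paths[["dotplot"]])
  .write_tsv(data.frame(class = names(conf), n = as.integer(conf)),
             out_paths[["confusion"]])

  log_lines <- c(
    "# spliceRetention run log",
    paste0("mode: simulate+analyze"),
    .config_yaml(config),
    sprintf("min_cpm: %g", filter@minCPM),
    sprintf("cpm_filter_mode: %s", filter@cpmFilterMode),
    sprintf("fold_threshold: %g", filter@foldThreshold),
    sprintf("pseudocount: %g", filter@pseudocount),
    sprintf("denominator: %s", denominator),
    paste0("input_md5: ", names(in_paths), " ",
           unname(tools::md5sum(in_paths))),
    sprintf("junctions_input: %d", res$summary@nJunctionsInput),
    sprintf("removed_zero_in_any: %d",
            res$summary@nJunctionsInput - res$summary@nAfterZeroFilter),
    sprintf("removed_low_cpm: %d",
            res$summary@nAfterZeroFilter - res$summary@nAfterCpmFilter),
    sprintf("retained: %d", res$summary@nAfterCpmFilter),
    sprintf("misspliced: %d / %d (%.4f)", res$summary@nMisspliced,
            res$summary@nIntronsTotal, res$summary@fractionMisspliced),
    sprintf("confusion: TP=%d FP=%d FN=%d TN=%d",
            conf[["TP"]], conf[["FP"]], conf[["FN"]], conf[["TN"]]))
  writeLines(log_lines, out_paths[["log"]])

  invisible(list(
    summary = res$summary, retention = res$retention,
    ratios = res$ratios, confusion = conf,
    detectedFraction = res$summary@fractionMisspliced,
    sensitivity = if (conf[["TP"]] + conf[["FN"]] > 0)
      conf[["TP"]] / (conf[["TP"]] + conf[["FN"]]) else NA_real_,
    fpr = if (conf[["FP"]] + conf[["TN"]] > 0)
      conf[["FP"]] / (conf[["FP"]] + conf[["TN"]]) else NA_real_,
    paths = c(in_paths, out_paths), sim = sim))
}

.analyze <- function(je, intronRanges, intronCounts, filter, denominator) {
  filtered <- filterJunctions(je, filter)
  ratios <- junctionRatios(filtered)
  retention <- retentionFoldChanges(
    intronRanges, intronCounts, totalMapped(je), filter)
  summary <- summarizeSplicing(filtered, retention, ratios, denominator)
  list(filtered = filtered, ratios = ratios, retention = retention,
       summary = summary)
}

#' Analyze precomputed junction and intron counts
#'
#' The analyze-only entry point: reads an annotation GTF, per-sample
#' TopHat-style junction BED files, an intron-body count table and the
#' library sizes, then runs the same filter/ratio/retention cascade as
#' [runFull()] and writes `summary.tsv`, `retention.tsv` and
#' `dotplot.tsv`.
#'
#' @param annotationFile GTF path.
#' @param junctionFiles named character vector of per-sample
#'   `junctions.bed` paths (first name is the wild-type reference).
#' @param intronCountsFile intron-body count TSV
#'   (id/chrom/start/end/samples).
#' @param samplesFile `samples.tsv` with sample and total_mapped.
#' @param outdir output directory.
#' @param filter a [filterConfig()].
#' @param denominator passed to [summarizeSplicing()].
#' @return invisibly, the list from the analysis stage plus `paths`.
#' @export
runAnalysis <- function(annotationFile, junctionFiles, intronCountsFile,
                        samplesFile, outdir, filter = filterConfig(),
                        denominator = "all") {
  for (p in c(annotationFile, junctionFiles, intronCountsFile, samplesFile))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- readAnnotation(annotationFile)
  stats_tm <- readSampleStats(samplesFile)
  jbs <- lapply(names(junctionFiles), function(s)
    readJunctionBed(junctionFiles[[s]], s))
  names(jbs) <- names(junctionFiles)
  je <- makeJunctionExperiment(jbs, stats_tm)
  ic <- readIntronCounts(intronCountsFile)
  ir <- introns(ann)
  # align the count table to the annotation's introns by id
  m <- match(ir$intron_id, rownames(ic$counts))
  if (anyNA(m))
    stop("intron_counts table is missing annotated intron(s): ",
         paste(utils::head(ir$intron_id[is.na(m)], 5L), collapse = ", "))
  res <- .analyze(je, ir, ic$counts[m, , drop = FALSE], filter, denominator)
  paths <- c(summary = file.path(outdir, "summary.tsv"),
             retention = file.path(outdir, "retention.tsv"),
             dotplot = file.path(outdir, "dotplot.tsv"))
  writeSummary(res$summary, paths[["summary"]])
  .write_tsv(as.data.frame(res$retention), paths[["retention"]])
  writeDotplotTable(res$summary, paths[["dotplot"]])
  invisible(c(res, list(paths = paths)))
}

#' Confusion table of implanted vs detected misspliced introns
#'
#' Joins a simulation truth table with a retention classification by
#' `intron_id` and counts TP/FP/FN/TN; the four cells always sum to the
#' total intron count.
#'
#' @param truth a `DataFrame`/data.frame with `intron_id` and
#'   `misspliced` (the implanted flag).
#' @param retention a table from [retentionFoldChanges()].
#' @return named integer vector with elements TP, FP, FN, TN.
#' @export
confusionTable <- function(truth, retention) {
  m <- match(truth$intron_id, retention$intron_id)
  if (anyNA(m)) stop("retention table is missing introns present in truth")
  called <- retention$misspliced[m]
  implanted <- truth$misspliced
  c(TP = sum(implanted & called), FP = sum(!implanted & called),
    FN = sum(implanted & !called), TN = sum(!implanted & !called))
}

#' Export the junction-ratio dot plot
#'
#' One point per retained junction, mutant/wild-type CPM ratio on a
#' log10 axis against the junction's ratio rank, with a reference line
#' at ratio 1 (no difference); the sub-1 tail is where misspliced
#' junctions fall.
#'
#' @param ratios a [junctionRatios()] table (or
#'   `dotplotTable(summary)`).
#' @param file output figure path (`.pdf` or `.png`).
#' @return the ggplot object, invisibly; the file is written.
#' @export
exportDotplot <- function(ratios, file) {
  ratios <- as.data.frame(ratios)
  if (nrow(ratios) == 0L) stop("empty dotplot table")
  ratios$rank <- rank(ratios$ratio, ties.method = "first")
  p <- ggplot2::ggplot(ratios, ggplot2::aes(x = rank, y = ratio)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "junctions (ranked by ratio)",
                  y = "junction count ratio, mutant / wild type") +
    ggplot2::theme_classic()
  ggplot2::ggsave(file, p, width = 5, height = 4)
  invisible(p)
}
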