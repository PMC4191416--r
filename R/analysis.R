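#' Counts-per-million normalization
#'
#' `cpm = count * 1e6 / totalMapped`, the per-million unit used by the
#' junction filters (e.g. the 0.5-per-million-reads cutoff).
#'
#' @param count non-negative read count(s).
#' @param totalMapped total mapped reads in the library (> 0).
#' @return numeric vector of counts per million.
#' @examples
#' perMillion(10, 20208005)
#' @export
perMillion <- function(count, totalMapped) {
  if (any(totalMapped <= 0)) stop("totalMapped must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e6 / totalMapped
}

#' @describeIn perMillion fills the `"cpm"` assay of a
#'   [JunctionExperiment-class] from its `"counts"` assay and library
#'   sizes; `cpm == 0` exactly where `count == 0`.
#' @param x a `JunctionExperiment`.
#' @export
normalizeJunctions <- function(x) {
  stopifnot(is(x, "JunctionExperiment"))
  cnt <- junctionCounts(x)
  SummarizedExperiment::assay(x, "cpm") <-
    sweep(cnt, 2L, 1e6 / totalMapped(x), `*`)
  x
}

#' Apply the two junction filters
#'
#' Reproduces the dot-plot filter cascade: first remove junctions whose
#' raw count is zero in any sample (possible mapping noise), then remove
#' junctions below `minCPM` counts per million. Under the default
#' `cpmFilterMode = "both"` a junction is removed only when it falls
#' below the cutoff in *every* sample, so a junction that collapses in
#' the mutant but is solid in wild type survives to the ratio stage; the
#' either-sample reading is available as `"either"`. Removal counts per
#' rule are stored in `metadata(result)$filterStats`.
#'
#' @param x a [JunctionExperiment-class] with counts for every sample
#'   (an `NA` count is an error naming the junction).
#' @param config a [filterConfig()].
#' @return the retained `JunctionExperiment`, with a `cpm` assay and
#'   `metadata(x)$filterStats` = list(nInput, removedZero, removedLowCPM,
#'   nRetained).
#' @seealso [junctionRatios()]
#' @export
filterJunctions <- function(x, config = filterConfig()) {
  stopifnot(is(x, "JunctionExperiment"), is(config, "FilterConfig"))
  cnt <- junctionCounts(x)
  if (anyNA(cnt)) {
    bad <- rownames(cnt)[which(rowSums(is.na(cnt)) > 0L)]
    stop("junction(s) missing a sample's count: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x <- normalizeJunctions(x)
  n_input <- nrow(x)

  keep_zero <- if (config@dropZeroInAny) rowSums(cnt == 0L) == 0L
               else rep(TRUE, nrow(cnt))
  removed_zero <- sum(!keep_zero)
  x <- x[keep_zero, ]

  cpm <- SummarizedExperiment::assay(x, "cpm")
  below <- cpm < config@minCPM
  keep_cpm <- if (config@cpmFilterMode == "both") rowSums(below) < ncol(cpm)
              else rowSums(below) == 0L
  removed_cpm <- sum(!keep_cpm)
  x <- x[keep_cpm, ]

  S4Vectors::metadata(x)$filterStats <- list(
    nInput = n_input, removedZero = removed_zero,
    removedLowCPM = removed_cpm, nRetained = nrow(x))
  x
}

#' Mutant / wild-type junction ratios
#'
#' Per-junction ratio of mutant to wild-type counts per million, the
#' quantity plotted in the dot plot: a ratio of 1 means no difference
#' and the sub-1 tail flags missplicing. Must be called on
#' filter-retained junctions, where both CPMs are positive; a zero
#' wild-type CPM at this stage is an internal error (the filter contract
#' was violated).
#'
#' @param x a filtered [JunctionExperiment-class].
#' @param mutant,wt column (sample) names; default the second and first
#'   sample.
#' @return a `DataFrame` of `junction_id` and `ratio`, sorted by ratio
#'   (ascending) for dot-plot export.
#' @export
junctionRatios <- function(x, mutant = colnames(x)[2L],
                           wt = colnames(x)[1L]) {
  stopifnot(is(x, "JunctionExperiment"))
  cpm <- junctionCPM(x)
  if (any(cpm[, wt] == 0))
    stop("internal error: zero wild-type CPM reached the ratio stage; ",
         "junctions must pass filterJunctions() first")
  ratio <- unname(cpm[, mutant] / cpm[, wt])
  out <- S4Vectors::DataFrame(junction_id = rownames(x), ratio = ratio)
  # id as tie-break so the export is deterministic under input order
  out[order(out$ratio, out$junction_id), , drop = FALSE]
}

#' Intron-retention index
#'
#' Intron-body reads per kilobase of intron per million mapped reads:
#' `ri = (count * 1e6 / totalMapped) / (length / 1000)`. Length- and
#' library-size-corrected, so doubling both the count and the library
#' leaves it unchanged.
#'
#' @param count intron-body read count(s).
#' @param length intron length(s) in bases (> 0).
#' @param totalMapped library size (> 0).
#' @return numeric retention index.
#' @examples
#' retentionIndex(100, 1000, 1e7)
#' @export
retentionIndex <- function(count, length, totalMapped) {
  if (any(length <= 0)) stop("intron length must be positive")
  perMillion(count, totalMapped) / (length / 1000)
}

#' Per-intron retention fold changes and missplicing calls
#'
#' For every annotated intron, computes the retention index in each
#' sample, the mutant/wild-type fold change after adding `pseudocount`
#' raw reads to both counts (keeping the fold finite), and the
#' missplicing call: strictly greater than `foldThreshold` (a fold of
#' exactly 2 at the default threshold is *not* misspliced — "more than
#' 2-fold"). Introns whose fold drops below `1/foldThreshold` are
#' flagged `decreased` for reporting but deliberately not classified as
#' a splicing phenotype, since such signals are often mapping artifacts
#' of abundant non-coding RNAs.
#'
#' When `junctionCPM` per intron is supplied, a junction-normalized
#' variant of the index (`ri / junction cpm`, retention relative to the
#' spliced product) is reported alongside in `ri_rel_*` columns; the
#' fold change and the call always use the library-normalized index.
#'
#' @param intronRanges a `GRanges` of introns with an `intron_id` column
#'   (lengths taken from the ranges), or a named numeric vector of
#'   intron lengths.
#' @param counts integer matrix of intron-body counts, introns x
#'   samples.
#' @param totalMapped named numeric vector of library sizes.
#' @param config a [filterConfig()] (uses `pseudocount` and
#'   `foldThreshold`).
#' @param mutant,wt sample names; default second and first column.
#' @param junctionCPM optional named numeric vectors per sample (a
#'   matrix introns x samples of junction CPMs) for the relative
#'   variant.
#' @return a `DataFrame` with one row per intron: `intron_id`, `length`,
#'   `ri_wt`, `ri_mut`, `fold`, `misspliced`, `decreased` (and
#'   `ri_rel_wt`, `ri_rel_mut` when junction CPMs are given).
#' @export
retentionFoldChanges <- function(intronRanges, counts, totalMapped,
                                 config = filterConfig(),
                                 mutant = colnames(counts)[2L],
                                 wt = colnames(counts)[1L],
                                 junctionCPM = NULL) {
  if (is(intronRanges, "GRanges")) {
    len <- width(intronRanges)
    ids <- intronRanges$intron_id
  } else {
    len <- as.numeric(intronRanges)
    ids <- names(intronRanges)
  }
  counts <- as.matrix(counts)
  if (is.null(ids)) ids <- rownames(counts)
  if (nrow(counts) != length(len))
    stop("counts rows must match introns")
  if (anyNA(counts[, c(wt, mutant)]))
    stop("counts for both samples are required for every intron")
  ps <- config@pseudocount
  ri_wt <- retentionIndex(counts[, wt], len, totalMapped[[wt]])
  ri_mut <- retentionIndex(counts[, mutant], len, totalMapped[[mutant]])
  fold <- retentionIndex(counts[, mutant] + ps, len, totalMapped[[mutant]]) /
    retentionIndex(counts[, wt] + ps, len, totalMapped[[wt]])
  out <- S4Vectors::DataFrame(
    intron_id = ids, length = as.integer(len),
    ri_wt = unname(ri_wt), ri_mut = unname(ri_mut), fold = unname(fold),
    misspliced = unname(fold > config@foldThreshold),
    decreased = unname(fold < 1 / config@foldThreshold))
  if (!is.null(junctionCPM)) {
    out$ri_rel_wt <- ifelse(junctionCPM[, wt] > 0,
                            out$ri_wt / junctionCPM[, wt], NA_real_)
    out$ri_rel_mut <- ifelse(junctionCPM[, mutant] > 0,
                             out$ri_mut / junctionCPM[, mutant], NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Summarize a splicing comparison
#'
#' Combines the filter cascade statistics, the junction-ratio table and
#' the retention classification into one [SplicingSummary-class]. The
#' denominator of the misspliced fraction is every annotated intron with
#' counts present (`denominator = "all"`, the default — the headline
#' fraction is quoted against the genome's introns), or only introns
#' whose junction survived the filters (`"filtered"`).
#'
#' @param filtered a [JunctionExperiment-class] returned by
#'   [filterJunctions()].
#' @param retention a `DataFrame` from [retentionFoldChanges()].
#' @param ratios optional precomputed [junctionRatios()] table (computed
#'   from `filtered` when omitted).
#' @param denominator `"all"` or `"filtered"`; see above. For
#'   `"filtered"` the retention table's `intron_id`s must be mappable to
#'   retained junctions via `rowRanges(filtered)$intron_id`.
#' @return a [SplicingSummary-class].
#' @export
summarizeSplicing <- function(filtered, retention, ratios = NULL,
                              denominator = c("all", "filtered")) {
  denominator <- match.arg(denominator)
  fs <- S4Vectors::metadata(filtered)$filterStats
  if (is.null(fs))
    stop("'filtered' must come from filterJunctions()")
  if (nrow(retention) == 0L) stop("no introns in annotation")
  if (is.null(ratios)) ratios <- junctionRatios(filtered)
  tab <- retention
  if (denominator == "filtered") {
    keep_ids <- SummarizedExperiment::rowRanges(filtered)$intron_id
    if (is.null(keep_ids))
      stop("denominator='filtered' needs intron_id on the retained junctions")
    tab <- tab[tab$intron_id %in% keep_ids, , drop = FALSE]
    if (nrow(tab) == 0L) stop("no introns in annotation")
  }
  new("SplicingSummary",
      nIntronsTotal = nrow(tab),
      nMisspliced = sum(tab$misspliced),
      fractionMisspliced = sum(tab$misspliced) / nrow(tab),
      nJunctionsInput = as.integer(fs$nInput),
      nAfterZeroFilter = as.integer(fs$nInput - fs$removedZero),
      nAfterCpmFilter = as.integer(fs$nRetained),
      dotplot = ratios)
}

#' @rdname SplicingSummary-class
#' @param path output TSV path.
#' @export
writeSummary <- function(x, path) {
  stopifnot(is(x, "SplicingSummary"))
  df <- data.frame(
    metric = c("n_junctions_input", "n_after_zero_filter",
               "n_after_cpm_filter", "n_introns_total", "n_misspliced",
               "fraction_misspliced"),
    value = c(x@nJunctionsInput, x@nAfterZeroFilter, x@nAfterCpmFilter,
              x@nIntronsTotal, x@nMisspliced, x@fractionMisspliced))
  .write_tsv(df, path)
}

#' @rdname SplicingSummary-class
#' @export
writeDotplotTable <- function(x, path) {
  stopifnot(is(x, "SplicingSummary"))
  .write_tsv(as.data.frame(x@dotplot), path)
}

#' @rdname SplicingSummary-class
#' @export
dotplotTable <- function(x) x@dotplot
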