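#' Gene models as ordered exon chains
#'
#' `SpliceAnnotation` holds one transcript model per gene: an ordered,
#' non-overlapping chain of exons on a single chromosome and strand.
#' Introns and exon-exon junctions are derived from consecutive exon
#' pairs, so a gene with \eqn{k} exons contributes \eqn{k - 1} introns.
#' Coordinates follow the Bioconductor convention (1-based, closed);
#' conversion to and from the 0-based conventions of GTF/BED happens only
#' in the readers and writers.
#'
#' @slot exons a `GRangesList`, one element per gene (names are gene
#'   identifiers), each sorted by start with pairwise-disjoint exons on a
#'   single seqname and strand.
#'
#' @param x a `SpliceAnnotation` object.
#' @seealso [readAnnotation()], [introns()], [simulateAnnotation()]
#' @examples
#' exons <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 201), c(100, 300)), strand = "+"))
#' ann <- SpliceAnnotation(exons)
#' introns(ann)
#' @aliases SpliceAnnotation
#' @export
setClass("SpliceAnnotation", slots = c(exons = "GRangesList"))

setValidity("SpliceAnnotation", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return("annotation contains no genes")
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("gene names must be present and unique")
  if (any(lengths(ex) == 0L)) return("every gene needs at least one exon")
  # vectorized over the unlisted exons: per-element extraction from a
  # large GRangesList is far too slow for genome-scale annotations
  u <- unlist(ex, use.names = FALSE)
  if (any(width(u) < 1L)) return("exon intervals must satisfy start <= end")
  grp <- rep.int(seq_along(ex), lengths(ex))
  first <- cumsum(c(1L, lengths(ex)[-length(ex)]))
  chr <- as.integer(seqnames(u))
  str <- as.integer(strand(u))
  if (any(chr != chr[first][grp]) || any(str != str[first][grp]))
    return("each gene must lie on a single chromosome and strand")
  within <- grp[-1L] == grp[-length(grp)]
  if (length(u) > 1L) {
    s <- start(u); e <- end(u)
    if (any(within & s[-1L] <= s[-length(s)]))
      return("exons must be sorted by start within each gene")
    bad <- within & s[-1L] <= e[-length(e)]
    if (any(bad)) {
      genes <- unique(names(ex)[grp[-1L][bad]])
      return(paste0("overlapping exons in gene(s): ",
                    paste(utils::head(genes, 5L), collapse = ", ")))
    }
  }
  TRUE
})

#' @rdname SpliceAnnotation-class
#' @param exons a named `GRangesList` of exons, one element per gene.
#' @return `SpliceAnnotation()` returns a validated object.
#' @export
SpliceAnnotation <- function(exons) {
  if (is(exons, "GRanges")) {
    if (is.null(exons$gene_id)) stop("GRanges input needs a gene_id column")
    exons <- GenomicRanges::sort(
      S4Vectors::split(exons, exons$gene_id))
  }
  new("SpliceAnnotation", exons = exons)
}

setMethod("show", "SpliceAnnotation", function(object) {
  n <- length(object@exons)
  multi <- sum(lengths(object@exons) > 1L)
  cat("SpliceAnnotation with", n, "genes (",
      multi, "multi-exon,", sprintf("%.1f%%", 100 * multi / n), ")\n")
  cat("  introns:", sum(pmax(lengths(object@exons) - 1L, 0L)), "\n")
})

#' @rdname SpliceAnnotation-class
#' @export
setMethod("geneIds", "SpliceAnnotation", function(x) names(x@exons))

#' @rdname SpliceAnnotation-class
#' @export
setMethod("exonsByGene", "SpliceAnnotation", function(x) x@exons)

#' @rdname SpliceAnnotation-class
#' @export
setMethod("length", "SpliceAnnotation", function(x) length(x@exons))

#' Junction counts for a paired two-sample experiment
#'
#' `JunctionExperiment` extends `RangedSummarizedExperiment`: rows are
#' exon-exon junctions (the range spans the excised intron), columns are
#' samples, and the `"counts"` assay holds supporting read counts. Library
#' sizes live in `colData(x)$total_mapped` and feed the per-million
#' normalization ([normalizeJunctions()]) that fills the `"cpm"` assay.
#'
#' `donor(x)` and `acceptor(x)` report the junction coordinates in the
#' 0-based convention used by TopHat-style `junctions.bed` files: the
#' donor equals the intron start and the acceptor the intron end of the
#' 0-based half-open intron interval.
#'
#' @param x a `JunctionExperiment`.
#' @seealso [makeJunctionExperiment()], [filterJunctions()],
#'   [junctionRatios()]
#' @aliases JunctionExperiment
#' @export
setClass("JunctionExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("JunctionExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.na(cnt) & (cnt < 0 | cnt != round(cnt))))
    return("counts must be non-negative integers")
  if (!"total_mapped" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData needs a total_mapped column")
  tm <- object$total_mapped
  if (any(is.na(tm)) || any(tm <= 0))
    return("total_mapped must be positive for every sample")
  if (is.null(rownames(object)))
    return("junction identifiers (rownames) are required")
  TRUE
})

#' @rdname JunctionExperiment-class
#' @param junctions a `GRanges` spanning each excised intron, with a
#'   `junction_id` metadata column (used as rownames).
#' @param counts an integer matrix, junctions x samples.
#' @param totalMapped a named numeric vector of mapped-read totals, names
#'   matching `colnames(counts)`.
#' @return a `JunctionExperiment`.
#' @export
JunctionExperiment <- function(junctions, counts, totalMapped) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- names(totalMapped)
  totalMapped <- totalMapped[colnames(counts)]
  if (anyNA(totalMapped))
    stop("totalMapped must name every sample in counts")
  ids <- junctions$junction_id
  if (is.null(ids))
    ids <- paste0(seqnames(junctions), ":", start(junctions) - 1L,
                  "-", end(junctions))
  rownames(counts) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = stats::setNames(junctions, ids),
    colData = S4Vectors::DataFrame(
      sample = colnames(counts),
      total_mapped = as.numeric(totalMapped),
      row.names = colnames(counts)))
  new("JunctionExperiment", se)
}

#' @rdname JunctionExperiment-class
#' @export
setMethod("totalMapped", "JunctionExperiment", function(x) {
  stats::setNames(x$total_mapped, colnames(x))
})

#' @rdname JunctionExperiment-class
#' @export
setMethod("junctionCounts", "JunctionExperiment", function(x) {
  SummarizedExperiment::assay(x, "counts")
})

#' @rdname JunctionExperiment-class
#' @export
setMethod("junctionCPM", "JunctionExperiment", function(x) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(x))
    x <- normalizeJunctions(x)
  SummarizedExperiment::assay(x, "cpm")
})

#' Donor and acceptor coordinates of junctions
#'
#' 0-based coordinates flanking the excised intron: `donor` is the intron
#' start and `acceptor` the intron end of the half-open interval, matching
#' the TopHat `junctions.bed` dialect.
#'
#' @param x a `JunctionExperiment` or a junction `GRanges`.
#' @return an integer vector.
#' @name junctionAccessors
NULL

#' @rdname junctionAccessors
#' @export
setMethod("donor", "GRanges", function(x) start(x) - 1L)

#' @rdname junctionAccessors
#' @export
setMethod("acceptor", "GRanges", function(x) end(x))

#' @rdname junctionAccessors
#' @export
setMethod("donor", "JunctionExperiment", function(x)
  donor(SummarizedExperiment::rowRanges(x)))

#' @rdname junctionAccessors
#' @export
setMethod("acceptor", "JunctionExperiment", function(x)
  acceptor(SummarizedExperiment::rowRanges(x)))

#' Filtering and classification thresholds
#'
#' Bundles the junction filters and the missplicing classification rule:
#' junctions with a zero raw count in any sample are dropped as possible
#' mapping noise, junctions below `minCPM` counts-per-million are dropped
#' (in both samples under the default `cpmFilterMode = "both"`; the
#' stricter either-sample reading is available as `"either"`), and an
#' intron is called misspliced when its retention fold change is strictly
#' greater than `foldThreshold`. The `pseudocount` (raw reads) is added to
#' intron-body counts before fold changes so they stay finite.
#'
#' @param minCPM junction retention threshold in counts per million mapped
#'   reads (default 0.5).
#' @param dropZeroInAny drop junctions with a zero raw count in any sample
#'   (default `TRUE`).
#' @param cpmFilterMode `"both"` removes a junction only when it is below
#'   `minCPM` in every sample; `"either"` removes it when any sample is
#'   below.
#' @param foldThreshold strict fold-change threshold for the misspliced
#'   call (default 2: "more than 2-fold").
#' @param pseudocount raw reads added to intron-body counts before fold
#'   changes (default 0.5).
#' @return a `FilterConfig` object.
#' @examples
#' filterConfig(minCPM = 1)
#' @aliases FilterConfig
#' @export
filterConfig <- function(minCPM = 0.5, dropZeroInAny = TRUE,
                         cpmFilterMode = c("both", "either"),
                         foldThreshold = 2.0, pseudocount = 0.5) {
  new("FilterConfig", minCPM = minCPM, dropZeroInAny = dropZeroInAny,
      cpmFilterMode = match.arg(cpmFilterMode),
      foldThreshold = foldThreshold, pseudocount = pseudocount)
}

#' @rdname filterConfig
#' @export
setClass("FilterConfig", slots = c(
  minCPM = "numeric", dropZeroInAny = "logical", cpmFilterMode = "character",
  foldThreshold = "numeric", pseudocount = "numeric"))

setValidity("FilterConfig", function(object) {
  if (length(object@minCPM) != 1L || is.na(object@minCPM) ||
      object@minCPM < 0) return("minCPM must be a single value >= 0")
  if (object@foldThreshold <= 0) return("foldThreshold must be > 0")
  if (object@pseudocount < 0) return("pseudocount must be >= 0")
  if (!object@cpmFilterMode %in% c("both", "either"))
    return("cpmFilterMode must be 'both' or 'either'")
  TRUE
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: drop zero-in-any =", object@dropZeroInAny,
      "| min CPM =", object@minCPM, paste0("(", object@cpmFilterMode, ")"),
      "| fold >", object@foldThreshold,
      "| pseudocount =", object@pseudocount, "\n")
})

#' Configuration of the synthetic paired experiment
#'
#' All knobs of the synthetic wild-type/mutant experiment. The defaults
#' describe the emulated study conditions: 43\% of genes contain introns,
#' 1-3 introns per intron-containing gene, short introns (40-200 bp),
#' heavy-tailed log-normal expression, a background retention rate of 0.01
#' in both samples, 7.3\% of introns with a 4-fold retention increase
#' implanted in the mutant only, and unequal library sizes (wild type
#' 2,020,800 and mutant 3,178,960 mapped reads, a 1:10 scale-down of the
#' study's sequencing depth). The seed is mandatory: a reproducible run is
#' part of the contract, not an option.
#'
#' @param nGenes number of genes to simulate.
#' @param seed integer seed governing every random draw (required).
#' @param intronGeneFraction fraction of genes that contain introns; the
#'   realized count is exactly `round(nGenes * intronGeneFraction)`.
#' @param intronsPerGeneProbs probabilities of 1, 2 or 3 introns for an
#'   intron-containing gene.
#' @param exonLenRange,intronLenRange inclusive integer ranges that exon
#'   and intron lengths are drawn from uniformly.
#' @param meanlog,sdlog log-normal expression parameters (expression
#'   units per gene).
#' @param baseRetention background intron retention rate \eqn{\rho_0} in
#'   `[0, 1)`.
#' @param missplicedFraction fraction of introns given elevated retention
#'   in the mutant.
#' @param effectFold true mutant/wild-type retention ratio for affected
#'   introns (> 1).
#' @param librarySizes named vector of total mapped reads; names define
#'   the sample names, the first sample is the wild-type reference.
#' @param depthFactor expected reads per expression unit per million
#'   mapped reads.
#' @return a `SimConfig` object.
#' @examples
#' simConfig(nGenes = 100, seed = 7)
#' @aliases SimConfig
#' @export
simConfig <- function(nGenes, seed,
                      intronGeneFraction = 0.43,
                      intronsPerGeneProbs = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                      exonLenRange = c(100L, 500L),
                      intronLenRange = c(40L, 200L),
                      meanlog = log(1000), sdlog = 1,
                      baseRetention = 0.01,
                      missplicedFraction = 0.073,
                      effectFold = 4,
                      librarySizes = c(wt = 2020800, mut = 3178960),
                      depthFactor = 50) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required; refusing to default silently")
  new("SimConfig", nGenes = as.integer(nGenes), seed = as.integer(seed),
      intronGeneFraction = intronGeneFraction,
      intronsPerGeneProbs = intronsPerGeneProbs,
      exonLenRange = as.integer(exonLenRange),
      intronLenRange = as.integer(intronLenRange),
      meanlog = meanlog, sdlog = sdlog, baseRetention = baseRetention,
      missplicedFraction = missplicedFraction, effectFold = effectFold,
      librarySizes = librarySizes, depthFactor = depthFactor)
}

#' @rdname simConfig
#' @export
setClass("SimConfig", slots = c(
  nGenes = "integer", seed = "integer", intronGeneFraction = "numeric",
  intronsPerGeneProbs = "numeric", exonLenRange = "integer",
  intronLenRange = "integer", meanlog = "numeric", sdlog = "numeric",
  baseRetention = "numeric", missplicedFraction = "numeric",
  effectFold = "numeric", librarySizes = "numeric", depthFactor = "numeric"))

setValidity("SimConfig", function(object) {
  frac_ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (object@nGenes < 1L) return("nGenes must be positive")
  if (!frac_ok(object@intronGeneFraction))
    return("intronGeneFraction must lie in [0, 1]")
  if (!frac_ok(object@missplicedFraction))
    return("missplicedFraction must lie in [0, 1]")
  if (object@baseRetention < 0 || object@baseRetention >= 1)
    return("baseRetention must lie in [0, 1)")
  if (object@effectFold <= 1) return("effectFold must exceed 1")
  if (object@baseRetention * object@effectFold >= 1)
    return("baseRetention * effectFold must stay below 1")
  if (length(object@librarySizes) != 2L || any(object@librarySizes <= 0) ||
      is.null(names(object@librarySizes)))
    return("librarySizes must be two named positive totals")
  if (abs(sum(object@intronsPerGeneProbs) - 1) > 1e-8 ||
      any(object@intronsPerGeneProbs < 0) ||
      length(object@intronsPerGeneProbs) != 3L)
    return("intronsPerGeneProbs must be 3 non-negative values summing to 1")
  if (any(diff(object@exonLenRange) < 0) || object@exonLenRange[1] < 1L)
    return("exonLenRange must be an increasing positive range")
  if (any(diff(object@intronLenRange) < 0) || object@intronLenRange[1] < 1L)
    return("intronLenRange must be an increasing positive range")
  if (object@depthFactor <= 0) return("depthFactor must be positive")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes, seed", object@seed, "\n")
  cat(sprintf("  intron genes %.0f%%, rho0 %.3g, misspliced %.1f%% at %gx\n",
              100 * object@intronGeneFraction, object@baseRetention,
              100 * object@missplicedFraction, object@effectFold))
  cat("  libraries:", paste(names(object@librarySizes),
                            format(object@librarySizes, big.mark = ","),
                            collapse = " | "), "\n")
})

#' A fitted qPCR standard curve
#'
#' Least-squares line of Ct on log10(relative template amount), fitted to
#' a serial-dilution series. The amplification efficiency is
#' \eqn{10^{-1/slope} - 1} (1 for perfect doubling per cycle, i.e. a slope
#' of about -3.32 per 10-fold dilution).
#'
#' @slot primerPair primer-pair label.
#' @slot slope,intercept coefficients of the fitted line (Ct per log10
#'   amount).
#' @slot efficiency amplification efficiency.
#' @slot r2 coefficient of determination of the fit.
#' @slot positiveSlope flag raised when the fitted slope is positive
#'   (invalid amplification).
#' @param x a `StandardCurve`.
#' @seealso [fitStandardCurve()], [quantifyRelative()]
#' @name StandardCurve-class
#' @aliases StandardCurve
#' @export
setClass("StandardCurve", slots = c(
  primerPair = "character", slope = "numeric", intercept = "numeric",
  efficiency = "numeric", r2 = "numeric", positiveSlope = "logical"))

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve [%s]: Ct = %.4f * log10(amount) + %.4f\n",
    object@primerPair, object@slope, object@intercept))
  cat(sprintf("  efficiency %.4f, r2 %.6f%s\n", object@efficiency,
              object@r2,
              if (object@positiveSlope) "  ** positive slope **" else ""))
})

#' @rdname qpcr
#' @export
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)

#' A simulated paired experiment with its ground truth
#'
#' Returned by [simulateExperiment()]. Bundles the synthetic annotation,
#' the junction-count experiment, the intron-body count matrix, and the
#' truth table recording which introns were implanted as misspliced and
#' their true retention rates in each sample.
#'
#' @slot annotation the [SpliceAnnotation-class] the counts were drawn
#'   from.
#' @slot junctions a [JunctionExperiment-class] of junction counts.
#' @slot introns a `GRanges` of introns with `intron_id`, `gene_id`,
#'   `ordinal` columns.
#' @slot intronCounts integer matrix of intron-body counts, introns x
#'   samples.
#' @slot truth a `DataFrame` with `intron_id`, `misspliced`, `rho_wt`,
#'   `rho_mut`.
#' @slot expression named numeric vector of the drawn per-gene
#'   expression levels (expression units).
#' @slot config the [SimConfig-class] used.
#' @param x a `SpliceSimulation`.
#' @name SpliceSimulation-class
#' @aliases SpliceSimulation
#' @export
setClass("SpliceSimulation", slots = c(
  annotation = "SpliceAnnotation", junctions = "JunctionExperiment",
  introns = "GRanges", intronCounts = "matrix", truth = "DataFrame",
  expression = "numeric", config = "SimConfig"))

setValidity("SpliceSimulation", function(object) {
  if (nrow(object@intronCounts) != length(object@introns))
    return("intronCounts rows must match introns")
  if (!identical(rownames(object@intronCounts), object@introns$intron_id))
    return("intronCounts rownames must be the intron ids")
  if (nrow(object@truth) != length(object@introns))
    return("truth must cover every intron exactly once")
  bad <- object@truth$misspliced !=
    (object@truth$rho_mut > object@truth$rho_wt)
  if (any(bad))
    return("truth flag must equal an elevated mutant retention rate")
  TRUE
})

setMethod("show", "SpliceSimulation", function(object) {
  cat("SpliceSimulation:", length(object@annotation), "genes,",
      length(object@introns), "introns,",
      sum(object@truth$misspliced), "implanted misspliced\n")
  cat("  samples:", paste(colnames(object@junctions), collapse = ", "), "\n")
})

#' @rdname SpliceSimulation-class
#' @export
setMethod("introns", "SpliceSimulation", function(x, ...) x@introns)

#' @rdname SpliceSimulation-class
#' @param object a `SpliceSimulation`.
#' @export
simTruth <- function(object) object@truth

#' @rdname SpliceSimulation-class
#' @export
simJunctions <- function(object) object@junctions

#' @rdname SpliceSimulation-class
#' @export
simIntronCounts <- function(object) object@intronCounts

#' @rdname SpliceSimulation-class
#' @export
simAnnotation <- function(object) object@annotation

#' @rdname SpliceSimulation-class
#' @export
simExpression <- function(object) object@expression

#' Summary of a splicing comparison
#'
#' Counts of junctions surviving each filter, the misspliced-intron
#' classification totals, and the per-junction ratio table backing the
#' dot plot.
#'
#' @slot nIntronsTotal,nMisspliced,fractionMisspliced classification
#'   totals; the fraction is misspliced / total annotated introns.
#' @slot nJunctionsInput,nAfterZeroFilter,nAfterCpmFilter junction counts
#'   through the filter cascade (non-increasing).
#' @slot dotplot a `DataFrame` of `junction_id` and mutant/wild-type
#'   `ratio`, sorted by ratio.
#' @param x a `SplicingSummary`.
#' @name SplicingSummary-class
#' @aliases SplicingSummary
#' @export
setClass("SplicingSummary", slots = c(
  nIntronsTotal = "integer", nMisspliced = "integer",
  fractionMisspliced = "numeric", nJunctionsInput = "integer",
  nAfterZeroFilter = "integer", nAfterCpmFilter = "integer",
  dotplot = "DataFrame"))

setValidity("SplicingSummary", function(object) {
  if (object@nIntronsTotal < 1L) return("no introns in annotation")
  if (object@nJunctionsInput < object@nAfterZeroFilter ||
      object@nAfterZeroFilter < object@nAfterCpmFilter)
    return("filter counts must be non-increasing")
  expectFrac <- object@nMisspliced / object@nIntronsTotal
  if (abs(object@fractionMisspliced - expectFrac) > 1e-12)
    return("fractionMisspliced must equal nMisspliced / nIntronsTotal")
  TRUE
})

setMethod("show", "SplicingSummary", function(object) {
  cat("SplicingSummary\n")
  cat(sprintf("  junctions: %d input -> %d after zero filter -> %d after CPM filter\n",
              object@nJunctionsInput, object@nAfterZeroFilter,
              object@nAfterCpmFilter))
  cat(sprintf("  misspliced introns: %d / %d (%.1f%%)\n",
              object@nMisspliced, object@nIntronsTotal,
              100 * object@fractionMisspliced))
})
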