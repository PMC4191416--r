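#' Read splice junctions from a TopHat-style junctions.bed
#'
#' Parses a BED12 file in the TopHat `junctions.bed` dialect: two blocks
#' per line flanking the excised intron, with the supporting read count
#' in the score column. The junction's 0-based donor is
#' `chromStart + blockSizes[1]` and its acceptor
#' `chromStart + blockStarts[2]`. Lines with a block count other than two
#' are rejected with a warning that reports how many were dropped; a
#' negative score is an error.
#'
#' @param path path to a BED12 file.
#' @param sample sample name attached to the counts.
#' @return a `GRanges` spanning each excised intron, with `junction_id`,
#'   `count` and `sample` columns, keyed by (chrom, donor, acceptor).
#' @seealso [writeJunctionBed()], [makeJunctionExperiment()]
#' @export
readJunctionBed <- function(path, sample) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out) <- S4Vectors::DataFrame(
      junction_id = character(0), count = integer(0), sample = character(0))
    return(out)
  }
  nb <- lengths(gr$blocks)
  if (any(nb != 2L)) {
    warning(sum(nb != 2L), " line(s) with block count != 2 rejected in ",
            path)
    gr <- gr[nb == 2L]
  }
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out) <- S4Vectors::DataFrame(
      junction_id = character(0), count = integer(0), sample = character(0))
    return(out)
  }
  if (any(gr$score < 0)) stop("negative junction score in ", path)
  u <- unlist(rtracklayer::blocks(gr), use.names = FALSE)  # absolute coords
  donor0 <- end(u)[c(TRUE, FALSE)]
  acceptor0 <- start(u)[c(FALSE, TRUE)] - 1L
  if (any(acceptor0 <= donor0))
    stop("malformed junction blocks (acceptor <= donor) in ", path)
  out <- GRanges(seqnames(gr), IRanges(donor0 + 1L, acceptor0))
  mcols(out) <- S4Vectors::DataFrame(
    junction_id = as.character(gr$name),
    count = as.integer(gr$score),
    sample = sample)
  out
}

#' Write splice junctions as a TopHat-style junctions.bed
#'
#' Inverse of [readJunctionBed()]: each junction becomes a BED12 line
#' with two `anchor`-bp blocks flanking the intron and the read count in
#' the score column. The (chrom, donor, acceptor, count) quadruple
#' round-trips exactly.
#'
#' @param junctions a `GRanges` spanning each excised intron with
#'   `junction_id` and `count` columns (as from [readJunctionBed()]).
#' @param path output path.
#' @param anchor flanking block size in bp (clipped when the donor sits
#'   close to the chromosome start).
#' @return `path`, invisibly.
#' @export
writeJunctionBed <- function(junctions, path, anchor = 50L) {
  stopifnot(!is.null(junctions$count))
  if (length(junctions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  donor0 <- start(junctions) - 1L
  acceptor0 <- end(junctions)
  if (any(donor0 < 1L))
    stop("cannot write a junction whose donor touches the chromosome start")
  left <- pmin(anchor, donor0)
  chromStart <- donor0 - left
  rel2 <- acceptor0 - chromStart + 1L  # 1-based relative start of block 2
  bed <- GRanges(
    seqnames(junctions),
    IRanges(chromStart + 1L, acceptor0 + anchor),
    name = if (is.null(junctions$junction_id))
      paste0("JUNC", seq_along(junctions)) else junctions$junction_id,
    score = as.numeric(junctions$count),
    blocks = IRangesList(mapply(function(l, s2, a) {
      IRanges(start = c(1L, s2), width = c(l, a))
    }, left, rel2, anchor, SIMPLIFY = FALSE)))
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Tabular junction and intron count I/O
#'
#' TSV tables with a header of `id`, `chrom`, `start`, `end` followed by
#' one column per sample; coordinates are 0-based half-open (start =
#' donor, end = acceptor for junctions). `readIntronCounts` additionally
#' derives intron lengths from the interval.
#'
#' @param path TSV path.
#' @return `readJunctionCounts`: a list with a junction `GRanges`
#'   (`junction_id` column) and a `counts` matrix. `readIntronCounts`:
#'   the same with `intron_id`.
#' @name countTables
#' @export
readJunctionCounts <- function(path) {
  df <- .read_tsv(path, c("id", "chrom", "start", "end"))
  samples <- setdiff(colnames(df), c("id", "chrom", "start", "end"))
  if (length(samples) == 0L) stop("no sample columns in ", path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- S4Vectors::DataFrame(junction_id = as.character(df$id))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$id
  list(junctions = gr, counts = counts)
}

#' @rdname countTables
#' @export
readIntronCounts <- function(path) {
  df <- .read_tsv(path, c("id", "chrom", "start", "end"))
  samples <- setdiff(colnames(df), c("id", "chrom", "start", "end"))
  if (length(samples) == 0L) stop("no sample columns in ", path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- S4Vectors::DataFrame(intron_id = as.character(df$id))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$id
  list(introns = gr, counts = counts)
}

#' @rdname countTables
#' @param ranges a `GRanges` with an id column (`junction_id` or
#'   `intron_id`).
#' @param counts matrix of counts, rows parallel to `ranges`.
#' @export
writeCountTable <- function(ranges, counts, path) {
  id <- if (!is.null(ranges$junction_id)) ranges$junction_id
        else ranges$intron_id
  df <- data.frame(id = id, chrom = as.character(seqnames(ranges)),
                   start = start(ranges) - 1L, end = end(ranges),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  .write_tsv(df, path)
}

#' Sample library-size tables
#'
#' `samples.tsv` has columns `sample` and `total_mapped` (positive
#' integers, the mapped-read total used for per-million normalization).
#'
#' @param path TSV path.
#' @return a named numeric vector of totals.
#' @name sampleStats
#' @export
readSampleStats <- function(path) {
  df <- .read_tsv(path, c("sample", "total_mapped"))
  if (any(df$total_mapped <= 0)) stop("total_mapped must be positive")
  stats::setNames(as.numeric(df$total_mapped), df$sample)
}

#' @rdname sampleStats
#' @param totalMapped named numeric vector of totals.
#' @export
writeSampleStats <- function(totalMapped, path) {
  .write_tsv(data.frame(sample = names(totalMapped),
                        total_mapped = as.numeric(totalMapped)), path)
}

#' Assemble a JunctionExperiment from per-sample junction calls
#'
#' Takes one junction `GRanges` per sample (e.g. from
#' [readJunctionBed()]) and merges them over the union of (chrom, donor,
#' acceptor) keys. A junction absent from a sample's file gets the fill
#' count for that sample (0 by default, the convention of aligners that
#' only report observed junctions).
#'
#' @param junctionsBySample named list of junction `GRanges` with `count`
#'   columns.
#' @param totalMapped named numeric vector of library sizes covering
#'   every sample.
#' @param fill count assigned to junctions missing from a sample
#'   (default `0L`; use `NA` to have [filterJunctions()] flag them).
#' @return a [JunctionExperiment-class].
#' @export
makeJunctionExperiment <- function(junctionsBySample, totalMapped,
                                   fill = 0L) {
  stopifnot(is.list(junctionsBySample), !is.null(names(junctionsBySample)))
  samples <- names(junctionsBySample)
  if (!all(samples %in% names(totalMapped)))
    stop("totalMapped must cover every sample")
  keys <- lapply(junctionsBySample, function(g)
    paste0(seqnames(g), ":", start(g) - 1L, "-", end(g)))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  counts <- matrix(as.integer(fill), nrow = length(all_keys),
                   ncol = length(samples),
                   dimnames = list(all_keys, samples))
  for (s in samples)
    counts[keys[[s]], s] <- junctionsBySample[[s]]$count
  first <- !duplicated(unlist(keys, use.names = FALSE))
  gr_all <- unlist(GRangesList(lapply(junctionsBySample, function(g) {
    mcols(g) <- NULL
    g
  })), use.names = FALSE)[first]
  names(gr_all) <- NULL
  mcols(gr_all) <- S4Vectors::DataFrame(junction_id = all_keys)
  o <- GenomicRanges::order(gr_all)
  JunctionExperiment(gr_all[o], counts[o, , drop = FALSE],
                     totalMapped[samples])
}
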