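#' Read gene models from a GTF file
#'
#' Imports `exon` features, groups them by `gene_id`, sorts each gene's
#' exons by start and validates the resulting models (non-overlapping
#' exon chains on one chromosome and strand). GTF's 1-based closed
#' coordinates map directly onto the internal `GRanges` representation.
#'
#' @param path path to a GTF file whose exon features carry `gene_id`
#'   attributes.
#' @return a [SpliceAnnotation-class].
#' @seealso [writeAnnotation()], [introns()]
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon features must carry gene_id attributes")
  gid <- gr$gene_id
  mcols(gr) <- NULL
  ex <- GenomicRanges::sort(S4Vectors::split(gr, gid))
  SpliceAnnotation(ex)
}

#' Write gene models to a GTF file
#'
#' One `exon` feature per exon, with `gene_id` and a single synthetic
#' `transcript_id` per gene (`<gene_id>.1`; one transcript per gene is
#' the package's model). Output order is deterministic (genes in
#' annotation order, exons by start), so identical annotations produce
#' identical files.
#'
#' @param annotation a [SpliceAnnotation-class].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "SpliceAnnotation"))
  ex <- exonsByGene(annotation)
  gr <- unlist(ex, use.names = FALSE)
  gid <- rep(names(ex), lengths(ex))
  mcols(gr) <- S4Vectors::DataFrame(
    source = "spliceRetention", type = "exon",
    gene_id = gid, transcript_id = paste0(gid, ".1"))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @describeIn introns Introns of every multi-exon gene: each consecutive
#'   exon pair contributes the closed interval strictly between the two
#'   exons. Ordinals follow transcription order (reverse genomic order on
#'   the minus strand) and intron identifiers are `<gene_id>.I<ordinal>`.
#'   The returned `GRanges` carries `gene_id`, `intron_id` and `ordinal`
#'   columns.
#' @export
setMethod("introns", "SpliceAnnotation", function(x, ...) {
  ex <- exonsByGene(x)
  multi <- ex[lengths(ex) > 1L]
  if (length(multi) == 0L) {
    out <- GRanges()
    mcols(out) <- S4Vectors::DataFrame(
      gene_id = character(0), intron_id = character(0), ordinal = integer(0))
    return(out)
  }
  gaps <- IRanges::psetdiff(unlist(range(multi), use.names = FALSE), multi)
  gr <- unlist(gaps, use.names = FALSE)
  gid <- rep(names(multi), lengths(gaps))
  neg <- as.character(strand(gr)) == "-"
  ord <- unlist(lapply(lengths(gaps), seq_len), use.names = FALSE)
  n_per <- rep(lengths(gaps), lengths(gaps))
  ord[neg] <- n_per[neg] - ord[neg] + 1L
  mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gid, intron_id = paste0(gid, ".I", ord), ordinal = ord)
  gr
})

#' Junction universe implied by an annotation
#'
#' One exon-exon junction per intron; the junction range spans the
#' excised intron, `donor(x)`/`acceptor(x)` give the 0-based flanking
#' coordinates. Carries the matching `intron_id` so junction-level and
#' intron-level results can be joined.
#'
#' @param annotation a [SpliceAnnotation-class].
#' @return a `GRanges` with `junction_id`, `intron_id`, `gene_id`.
#' @export
junctionsFromAnnotation <- function(annotation) {
  ir <- introns(annotation)
  jid <- paste0(seqnames(ir), ":", start(ir) - 1L, "-", end(ir))
  mcols(ir) <- S4Vectors::DataFrame(
    junction_id = jid, intron_id = ir$intron_id, gene_id = ir$gene_id)
  ir
}
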