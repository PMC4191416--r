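#' Simulate a gene annotation with a fixed intron-containing fraction
#'
#' Builds a synthetic chromosome of non-overlapping genes. Exactly
#' `round(nGenes * intronGeneFraction)` genes are multi-exon (1-3
#' introns each, drawn from `intronsPerGeneProbs`); exon and intron
#' lengths are uniform over their configured ranges, strands are random,
#' and genes are laid head-to-tail with a fixed spacer so placements
#' never overlap. The whole construction is a deterministic function of
#' the seed: the same config yields a byte-identical GTF.
#'
#' @param config a [simConfig()].
#' @return a [SpliceAnnotation-class].
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  n <- config@nGenes
  k <- round(n * config@intronGeneFraction)
  which_multi <- sort(sample.int(n, k))
  n_introns <- integer(n)
  n_introns[which_multi] <- sample(1:3, k, replace = TRUE,
                                   prob = config@intronsPerGeneProbs)
  n_exons <- n_introns + 1L
  total_ex <- sum(n_exons)
  # sample() treats a length-1 vector as 1:n; guard degenerate ranges
  runif_len <- function(range, n) {
    v <- range[1]:range[2]
    if (length(v) == 1L) rep.int(v, n) else sample(v, n, replace = TRUE)
  }
  ex_len <- runif_len(config@exonLenRange, total_ex)
  in_len <- runif_len(config@intronLenRange, sum(n_introns))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  gene_of_exon <- rep.int(seq_len(n), n_exons)
  # within each gene: exon1, (intron1, exon2), ... — cumulative offsets
  ex_idx_end <- cumsum(n_exons)
  ex_idx_start <- ex_idx_end - n_exons + 1L
  in_idx_end <- cumsum(n_introns)
  in_idx_start <- in_idx_end - n_introns + 1L

  spacer <- 500L
  starts <- integer(total_ex)
  ends <- integer(total_ex)
  cursor <- 1000L
  for (g in seq_len(n)) {
    e_ix <- ex_idx_start[g]:ex_idx_end[g]
    lens_e <- ex_len[e_ix]
    lens_i <- if (n_introns[g] > 0L)
      in_len[in_idx_start[g]:in_idx_end[g]] else integer(0)
    pos <- cursor
    for (j in seq_along(e_ix)) {
      starts[e_ix[j]] <- pos
      ends[e_ix[j]] <- pos + lens_e[j] - 1L
      pos <- ends[e_ix[j]] + 1L
      if (j <= length(lens_i)) pos <- pos + lens_i[j]
    }
    cursor <- pos + spacer
  }
  gid <- sprintf("SRG%05d", seq_len(n))
  gr <- GRanges("simI", IRanges(starts, ends),
                strand = strands[gene_of_exon])
  ex <- S4Vectors::split(gr, gid[gene_of_exon])
  ex <- ex[gid]  # annotation order, not alphabetical surprises
  SpliceAnnotation(ex)
}

#' Simulate a paired wild-type/mutant count experiment
#'
#' Generates the full two-sample experiment the analysis consumes, plus
#' its ground truth. Per gene g, an expression level
#' \eqn{e_g \sim LogNormal(meanlog, sdlog)} is drawn. For an intron with
#' retention rate \eqn{\rho} (the background rate in wild type;
#' `baseRetention * effectFold` for implanted misspliced introns in the
#' mutant, the background rate otherwise), counts are Poisson:
#' \deqn{junction \sim Pois(S \cdot e_g \cdot (1-\rho)), \quad
#'       intron \sim Pois(S \cdot e_g \cdot \rho \cdot length/1000)}
#' with \eqn{S = depthFactor \cdot totalMapped / 10^6} per sample. The
#' intron-body rate scales with intron length in kb (body coverage grows
#' with length); the junction is a point feature and does not.
#' Misspliced introns are drawn uniformly at random,
#' `round(missplicedFraction * nIntrons)` of them, and implanted in the
#' mutant only. Everything is reproducible from the config seed.
#'
#' @param config a [simConfig()].
#' @return a [SpliceSimulation-class].
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 50, seed = 1))
#' sim
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  ann <- simulateAnnotation(config)  # seeds the RNG stream
  ir <- introns(ann)
  jx <- junctionsFromAnnotation(ann)
  samples <- names(config@librarySizes)
  wt <- samples[1L]; mut <- samples[2L]

  expr <- stats::setNames(
    stats::rlnorm(length(ann), config@meanlog, config@sdlog), geneIds(ann))

  n_intr <- length(ir)
  n_set <- round(config@missplicedFraction * n_intr)
  if (config@missplicedFraction > 0 && n_set < 1L) {
    warning("misspliced_fraction too small for ", n_intr,
            " introns; zero implanted")
    n_set <- 0L
  }
  implanted <- if (n_set > 0L) sort(sample.int(n_intr, n_set)) else integer(0)
  is_miss <- seq_len(n_intr) %in% implanted

  rho0 <- config@baseRetention
  rho_wt <- rep(rho0, n_intr)
  rho_mut <- ifelse(is_miss, rho0 * config@effectFold, rho0)

  e_i <- expr[ir$gene_id]
  len_kb <- width(ir) / 1000
  S <- config@depthFactor * config@librarySizes / 1e6

  jx_counts <- cbind(
    stats::rpois(n_intr, S[[wt]] * e_i * (1 - rho_wt)),
    stats::rpois(n_intr, S[[mut]] * e_i * (1 - rho_mut)))
  in_counts <- cbind(
    stats::rpois(n_intr, S[[wt]] * e_i * rho_wt * len_kb),
    stats::rpois(n_intr, S[[mut]] * e_i * rho_mut * len_kb))
  colnames(jx_counts) <- colnames(in_counts) <- samples
  rownames(in_counts) <- ir$intron_id

  je <- JunctionExperiment(jx, jx_counts, config@librarySizes)
  truth <- S4Vectors::DataFrame(
    intron_id = ir$intron_id,
    misspliced = is_miss & rho_mut > rho_wt,  # vacuous when rho0 == 0
    rho_wt = rho_wt, rho_mut = rho_mut)
  new("SpliceSimulation", annotation = ann, junctions = je,
      introns = ir, intronCounts = in_counts, truth = truth,
      expression = expr, config = config)
}

#' Write a simulated experiment to disk
#'
#' Emits the file set a real analysis would start from: the GTF
#' annotation, one TopHat-style `junctions_<sample>.bed` per sample,
#' `intron_counts.tsv`, `samples.tsv`, the `truth.tsv` ground-truth
#' table, and the full configuration as `config.yaml`.
#'
#' @param sim a [SpliceSimulation-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "SpliceSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    intron_counts = file.path(dir, "intron_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  writeAnnotation(sim@annotation, paths[["annotation"]])
  je <- sim@junctions
  rr <- SummarizedExperiment::rowRanges(je)
  for (s in colnames(je)) {
    p <- file.path(dir, paste0("junctions_", s, ".bed"))
    g <- rr
    mcols(g) <- S4Vectors::DataFrame(
      junction_id = rr$junction_id, count = junctionCounts(je)[, s])
    writeJunctionBed(g, p)
    paths[[paste0("junctions_", s)]] <- p
  }
  writeCountTable(sim@introns, sim@intronCounts, paths[["intron_counts"]])
  writeSampleStats(totalMapped(je), paths[["samples"]])
  .write_tsv(as.data.frame(simTruth(sim)), paths[["truth"]])
  writeLines(.config_yaml(sim@config), paths[["config"]])
  invisible(paths)
}

# flat key: value serialization of a SimConfig (readable by yaml parsers)
.config_yaml <- function(config) {
  num <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = ", ")
  c(paste0("n_genes: ", config@nGenes),
    paste0("seed: ", config@seed),
    paste0("intron_gene_fraction: ", num(config@intronGeneFraction)),
    paste0("introns_per_gene_probs: [", num(config@intronsPerGeneProbs), "]"),
    paste0("exon_len_range: [", num(config@exonLenRange), "]"),
    paste0("intron_len_range: [", num(config@intronLenRange), "]"),
    paste0("meanlog: ", num(config@meanlog)),
    paste0("sdlog: ", num(config@sdlog)),
    paste0("base_retention: ", num(config@baseRetention)),
    paste0("misspliced_fraction: ", num(config@missplicedFraction)),
    paste0("effect_fold: ", num(config@effectFold)),
    paste0("library_sizes: {",
           paste(names(config@librarySizes),
                 format(config@librarySizes, scientific = FALSE, trim = TRUE),
                 sep = ": ", collapse = ", "), "}"),
    paste0("depth_factor: ", num(config@depthFactor)))
}
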