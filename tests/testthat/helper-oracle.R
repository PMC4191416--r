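# Independent straight-line oracles, deliberately written with plain
# loops and no calls into the package's analysis path.

# Filter + ratio oracle over a plain data.frame with columns wt, mut.
oracle_filter_ratios <- function(df, tot_wt, tot_mut, min_cpm = 0.5,
                                 mode = "both") {
  removed_zero <- 0L
  removed_cpm <- 0L
  keep <- logical(nrow(df))
  ratio <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    w <- df$wt[i]; m <- df$mut[i]
    if (w == 0L || m == 0L) {
      removed_zero <- removed_zero + 1L
      next
    }
    cw <- w * 1e6 / tot_wt
    cm <- m * 1e6 / tot_mut
    low <- if (mode == "both") (cw < min_cpm) && (cm < min_cpm)
           else (cw < min_cpm) || (cm < min_cpm)
    if (low) {
      removed_cpm <- removed_cpm + 1L
      next
    }
    keep[i] <- TRUE
    ratio[i] <- cm / cw
  }
  list(keep = keep, removed_zero = removed_zero, removed_cpm = removed_cpm,
       ratio = ratio[keep], ids = df$id[keep])
}

# Brute-force intron recount straight from exon chains.
oracle_intron_count <- function(annotation) {
  total <- 0L
  for (g in as.list(exonsByGene(annotation)))
    total <- total + max(length(g) - 1L, 0L)
  total
}

# Brute-force inter-exon gap intervals of one gene (1-based closed).
oracle_gene_gaps <- function(exons) {
  s <- GenomicRanges::start(exons); e <- GenomicRanges::end(exons)
  if (length(s) < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = e[-length(e)] + 1L, end = s[-1L] - 1L)
}

# A random two-sample junction count fixture as a JunctionExperiment,
# with zeros and low counts well represented.
random_junction_fixture <- function(n, tot = c(wt = 1e7, mut = 1e7)) {
  counts <- cbind(
    wt = as.integer(rbinom(n, 1, 0.85) * rpois(n, lambda = 8)),
    mut = as.integer(rbinom(n, 1, 0.85) * rpois(n, lambda = 12)))
  gr <- GenomicRanges::GRanges(
    "chrF", IRanges::IRanges(seq_len(n) * 1000L, width = 200L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    junction_id = sprintf("J%05d", seq_len(n)))
  JunctionExperiment(gr, counts, tot)
}

# Tiny JunctionExperiment from explicit counts.
je_from_counts <- function(wt, mut, tot_wt = 1e7, tot_mut = 1e7) {
  n <- length(wt)
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(seq_len(n) * 500L, width = 100L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    junction_id = paste0("J", seq_len(n)))
  JunctionExperiment(gr, cbind(wt = as.integer(wt), mut = as.integer(mut)),
                     c(wt = tot_wt, mut = tot_mut))
}
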