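test_that("per-million normalization is exact", {
  expect_equal(perMillion(0, 1e6), 0)
  expect_equal(perMillion(1, 1e6), 1)
  # 10 reads in the wild-type library of 20,208,005 mapped reads
  expect_equal(perMillion(10, 20208005), 10 * 1e6 / 20208005)
  expect_equal(perMillion(10, 20208005), 0.494853, tolerance = 1e-6)
  expect_error(perMillion(1, 0), "positive")
  je <- normalizeJunctions(je_from_counts(c(0L, 5L), c(3L, 0L)))
  cpm <- SummarizedExperiment::assay(je, "cpm")
  expect_true(all((cpm == 0) == (junctionCounts(je) == 0)))
})

test_that("the two junction filters apply in order with per-rule counts", {
  # rows: zero-in-one; low cpm in both; low in wt only; solid in both
  je <- je_from_counts(wt = c(0L, 4L, 4L, 60L),
                       mut = c(5L, 4L, 50L, 80L))
  f <- filterJunctions(je)   # min_cpm 0.5 against 1e7 libraries
  fs <- S4Vectors::metadata(f)$filterStats
  expect_equal(fs$nInput, 4L)
  expect_equal(fs$removedZero, 1L)     # (0, 5): zero in any sample
  expect_equal(fs$removedLowCPM, 1L)   # (4, 4): cpm 0.4 in both
  expect_equal(fs$nRetained, 2L)
  expect_setequal(rownames(f), c("J3", "J4"))  # (4,50) kept: both-mode

  # either-mode also drops the junction that is weak in one sample only
  fe <- filterJunctions(je, filterConfig(cpmFilterMode = "either"))
  expect_setequal(rownames(fe), "J4")

  # disabling the zero rule keeps zero junctions until the cpm rule
  fz <- filterJunctions(je, filterConfig(dropZeroInAny = FALSE))
  expect_equal(S4Vectors::metadata(fz)$filterStats$removedZero, 0L)
})

test_that("junction ratios are mutant/wt CPM, sorted, and exact on identity", {
  je <- je_from_counts(wt = c(20L, 40L), mut = c(10L, 40L))
  f <- filterJunctions(je)
  r <- junctionRatios(f)
  expect_equal(r$ratio, c(0.5, 1.0))       # sorted ascending
  expect_equal(r$junction_id, c("J1", "J2"))
  # a sample against itself is exactly 1 everywhere
  jeq <- je_from_counts(wt = c(7L, 130L, 22L), mut = c(7L, 130L, 22L))
  expect_true(all(junctionRatios(filterJunctions(jeq))$ratio == 1))
  # unfiltered zero wt cpm is an internal-error condition
  jz <- normalizeJunctions(je_from_counts(c(0L, 5L), c(3L, 4L)))
  expect_error(junctionRatios(jz), "filter")
})

test_that("unaffected junctions keep their median ratio near 1 at depth", {
  cfg <- simConfig(nGenes = 300, seed = 21, missplicedFraction = 0)
  sim <- simulateExperiment(cfg)
  r <- junctionRatios(filterJunctions(simJunctions(sim)))
  expect_gt(nrow(r), 200L)
  expect_gt(median(r$ratio), 0.95)
  expect_lt(median(r$ratio), 1.05)
})

test_that("the retention index is reads per kb per million mapped", {
  expect_equal(retentionIndex(0, 500, 1e7), 0)
  expect_equal(retentionIndex(100, 1000, 1e7), 10)
  expect_equal(retentionIndex(100, 1000, 1e7),
               retentionIndex(200, 1000, 2e7))  # scale invariance
  expect_error(retentionIndex(1, 0, 1e7), "length")
})

test_that("fold changes and the strict more-than-threshold call", {
  len <- c(a = 100, b = 100, c = 100, d = 100)
  tm <- c(wt = 1e7, mut = 1e7)
  # equal counts, equal libraries -> fold exactly 1, never misspliced
  eq <- retentionFoldChanges(len, cbind(wt = rep(5L, 4), mut = rep(5L, 4)),
                             tm)
  expect_true(all(eq$fold == 1))
  expect_false(any(eq$misspliced))
  # folds 4, 2, 1, 0.5 with pseudocount 0: exactly one strict call
  cnt <- cbind(wt = c(2L, 2L, 2L, 2L), mut = c(8L, 4L, 2L, 1L))
  r <- retentionFoldChanges(len, cnt, tm, filterConfig(pseudocount = 0))
  expect_equal(r$fold, c(4, 2, 1, 0.5))
  expect_equal(r$misspliced, c(TRUE, FALSE, FALSE, FALSE))  # 2.0 is NOT >2
  expect_equal(sum(r$misspliced) / nrow(r), 0.25)
  expect_equal(r$decreased, c(FALSE, FALSE, FALSE, FALSE) | r$fold < 0.5)
  # pseudocount keeps folds finite and positive at zero counts
  z <- retentionFoldChanges(len, cbind(wt = rep(0L, 4), mut = rep(0L, 4)),
                            c(wt = 1e7, mut = 2e7))
  expect_true(all(is.finite(z$fold) & z$fold > 0))
  expect_equal(unique(z$fold), 0.5)  # library-size correction alone
})

test_that("summaries count filters and misspliced fractions coherently", {
  sim <- simulateExperiment(simConfig(nGenes = 200, seed = 13))
  f <- filterJunctions(simJunctions(sim))
  ret <- retentionFoldChanges(introns(sim), simIntronCounts(sim),
                              totalMapped(simJunctions(sim)))
  s <- summarizeSplicing(f, ret)
  expect_s4_class(s, "SplicingSummary")
  expect_equal(s@fractionMisspliced, s@nMisspliced / s@nIntronsTotal)
  expect_true(s@nJunctionsInput >= s@nAfterZeroFilter)
  expect_true(s@nAfterZeroFilter >= s@nAfterCpmFilter)
  expect_equal(nrow(dotplotTable(s)), s@nAfterCpmFilter)
  # no-missplicing simulation summarizes to a (near-)zero fraction
  clean <- simulateExperiment(
    simConfig(nGenes = 100, seed = 13, missplicedFraction = 0))
  cf <- filterJunctions(simJunctions(clean))
  cret <- retentionFoldChanges(introns(clean), simIntronCounts(clean),
                               totalMapped(simJunctions(clean)))
  expect_equal(sum(simTruth(clean)$misspliced), 0L)
  expect_error(summarizeSplicing(cf, cret[0, ]), "no introns")
})

test_that("raising the CPM cutoff can only shrink the retained set", {
  set.seed(404)
  for (i in 1:20) {
    je <- random_junction_fixture(80)
    lo <- rownames(filterJunctions(je, filterConfig(minCPM = 0.5)))
    hi <- rownames(filterJunctions(je, filterConfig(minCPM = 1.0)))
    expect_true(all(hi %in% lo))
  }
})

test_that("the analysis is invariant under junction order", {
  set.seed(99)
  je <- random_junction_fixture(120)
  perm <- sample(nrow(je))
  a <- filterJunctions(je)
  b <- filterJunctions(je[perm, ])
  expect_setequal(rownames(a), rownames(b))
  ra <- junctionRatios(a); rb <- junctionRatios(b)
  expect_equal(as.data.frame(ra), as.data.frame(rb))
})

test_that("filter and ratio results match the brute-force oracle", {
  set.seed(7)
  je <- random_junction_fixture(500, tot = c(wt = 2020800, mut = 3178960))
  df <- data.frame(id = rownames(je),
                   wt = junctionCounts(je)[, "wt"],
                   mut = junctionCounts(je)[, "mut"])
  want <- oracle_filter_ratios(df, 2020800, 3178960)
  got <- filterJunctions(je)
  fs <- S4Vectors::metadata(got)$filterStats
  expect_setequal(rownames(got), want$ids)
  expect_equal(fs$removedZero, want$removed_zero)
  expect_equal(fs$removedLowCPM, want$removed_cpm)
  r <- junctionRatios(got)
  expect_equal(r$ratio, sort(want$ratio), tolerance = 1e-14)
})
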