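test_that("standard curves recover slope, efficiency and r2", {
  # perfect 2x amplification: Ct rises 3.321928 per 10-fold dilution
  sc <- fitStandardCurve(c(1, 0.1, 0.01), c(20.0, 23.321928, 26.643856))
  expect_equal(sc@slope, -3.321928, tolerance = 1e-6)
  expect_equal(efficiency(sc), 1.0, tolerance = 1e-6)
  expect_equal(sc@r2, 1.0)
  expect_equal(sc@intercept, 20.0, tolerance = 1e-9)
  # duplicated points leave a least-squares fit unchanged
  dup <- fitStandardCurve(c(1, 0.1, 0.01, 1, 0.1, 0.01),
                          c(20.0, 23.321928, 26.643856,
                            20.0, 23.321928, 26.643856))
  expect_equal(dup@slope, sc@slope)
  expect_equal(dup@intercept, sc@intercept)
  # degenerate and invalid designs
  expect_error(fitStandardCurve(c(1, 1, 1), c(20, 21, 22)), "degenerate")
  expect_error(fitStandardCurve(c(1, 0.1), c(20, 23)), "3 points")
  expect_warning(fitStandardCurve(c(1, 0.1, 0.01), c(20, 18, 16)),
                 "positive")
})

test_that("quantification inverts the fitted line", {
  sc <- fitStandardCurve(c(1, 0.1, 0.01), c(20.0, 23.321928, 26.643856))
  expect_equal(quantifyRelative(20.0, sc), 1.0)          # ct == intercept
  expect_equal(quantifyRelative(21.0, sc), 10^(-1 / 3.321928),
               tolerance = 1e-6)
  expect_equal(quantifyRelative(21.0, sc), 0.5, tolerance = 1e-6)
  # fit -> invert is the identity on collinear data
  amounts <- c(1, 0.2, 0.04, 0.008)
  cts <- 19 - 3.1 * log10(amounts)
  sc2 <- fitStandardCurve(amounts, cts)
  expect_equal(quantifyRelative(cts, sc2), amounts, tolerance = 1e-9)
})

test_that("relative expression is act1-normalized with the reference at 1", {
  target <- c(wt = 1.0, mut = 3.0)
  act1 <- c(wt = 1.0, mut = 1.5)
  rel <- relativeExpression(target, act1, "wt")
  expect_identical(unname(rel[["wt"]]), 1)
  expect_equal(rel[["mut"]], 2.0)             # (3/1.5)/(1/1)
  # rescaling every act1 amount cancels
  rel10 <- relativeExpression(target, act1 * 10, "wt")
  expect_equal(rel10, rel)
  # the reference is exactly 1 whatever the inputs
  set.seed(1)
  for (i in 1:10) {
    t2 <- setNames(runif(3, 0.1, 5), c("wt", "m1", "m2"))
    a2 <- setNames(runif(3, 0.1, 5), c("wt", "m1", "m2"))
    expect_identical(unname(relativeExpression(t2, a2, "wt")[["wt"]]), 1)
  }
  expect_error(relativeExpression(target, act1, "nope"), "reference")
})

test_that("ChIP enrichment is the stated double ratio with its invariances", {
  expect_equal(chipEnrichment(1, 1, 1, 1), 1.0)
  expect_equal(chipEnrichment(2, 1, 1, 1), 2.0)
  expect_equal(chipEnrichment(5, 2, 3, 4), (5 / 2) / (3 / 4))
  expect_equal(chipEnrichment(5, 2, 3, 4), 10 / 3, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    x <- runif(4, 0.1, 10); k <- runif(1, 0.1, 100)
    base <- chipEnrichment(x[1], x[2], x[3], x[4])
    expect_equal(chipEnrichment(k * x[1], x[2], k * x[3], x[4]), base)
    expect_equal(chipEnrichment(x[1], k * x[2], x[3], k * x[4]), base)
  }
  expect_error(chipEnrichment(-1, 1, 1, 1), "positive")
  expect_error(chipEnrichment(1, 0, 1, 1), "positive")
})

test_that("replicate summaries give mean and standard deviation", {
  s <- summarizeReplicates(c(2.0, 2.4, 2.2))
  expect_equal(s$mean, 2.2)
  expect_equal(s$sd, sd(c(2.0, 2.4, 2.2)))
  expect_equal(s$n, 3L)
})

test_that("dilution-series tables fit one curve per primer pair", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(
    data.frame(primer_pair = "rap1_intron", relative_amount = c(1, 0.1, 0.01),
               ct = c(22.0, 25.321928, 28.643856)),
    data.frame(primer_pair = "act1", relative_amount = c(1, 0.1, 0.01),
               ct = c(18.0, 21.4, 24.8)))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- readDilutionSeries(f)
  expect_named(curves, c("act1", "rap1_intron"))
  expect_equal(efficiency(curves$rap1_intron), 1.0, tolerance = 1e-6)
  expect_equal(curves$act1@slope, -3.4, tolerance = 1e-9)
})
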