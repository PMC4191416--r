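test_that("annotation composition hits the intron-gene fraction exactly", {
  ann <- simulateAnnotation(simConfig(nGenes = 100, seed = 2))
  expect_equal(sum(lengths(exonsByGene(ann)) > 1L), 43L)  # round(100*0.43)

  none <- simulateAnnotation(
    simConfig(nGenes = 50, seed = 2, intronGeneFraction = 0))
  expect_true(all(lengths(exonsByGene(none)) == 1L))
  expect_length(introns(none), 0L)
})

test_that("the generator is a deterministic function of the seed", {
  cfg <- simConfig(nGenes = 60, seed = 123)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeAnnotation(simulateAnnotation(cfg), f1)
  writeAnnotation(simulateAnnotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(junctionCounts(simJunctions(s1)),
                   junctionCounts(simJunctions(s2)))
  expect_identical(simIntronCounts(s1), simIntronCounts(s2))
  expect_identical(as.data.frame(simTruth(s1)), as.data.frame(simTruth(s2)))

  s3 <- simulateExperiment(simConfig(nGenes = 60, seed = 124))
  expect_false(identical(junctionCounts(simJunctions(s1)),
                         junctionCounts(simJunctions(s3))))
})

test_that("zero background retention gives all-zero intron bodies", {
  cfg <- simConfig(nGenes = 80, seed = 5, baseRetention = 0,
                   missplicedFraction = 0)
  sim <- simulateExperiment(cfg)
  expect_true(all(simIntronCounts(sim) == 0L))
  expect_true(all(junctionCounts(simJunctions(sim)) >= 0L))
})

test_that("a seed is mandatory, not silently defaulted", {
  expect_error(simConfig(nGenes = 10), "seed")
  expect_error(simConfig(nGenes = 10, seed = NA), "seed")
})

test_that("mutant intron-body counts match the Poisson rate law", {
  # degenerate length/expression distributions so the rate is known in
  # closed form: S_mut * e * effectFold * rho0 * len/1000
  base <- list(nGenes = 4, intronGeneFraction = 1,
               intronsPerGeneProbs = c(`1` = 1, `2` = 0, `3` = 0),
               exonLenRange = c(200L, 200L), intronLenRange = c(100L, 100L),
               meanlog = log(400), sdlog = 0, baseRetention = 0.01,
               missplicedFraction = 1, effectFold = 4)
  draws <- vapply(1:400, function(s) {
    sim <- do.call(simConfig, c(base, seed = s))
    mean(simIntronCounts(simulateExperiment(sim))[, "mut"])
  }, numeric(1))
  S_mut <- 50 * 3178960 / 1e6
  rate <- S_mut * 400 * 4 * 0.01 * 100 / 1000   # = 254.3168
  n_eff <- 400 * 4                              # 4 iid introns per replicate
  se <- sqrt(rate / n_eff)
  expect_lt(abs(mean(draws) - rate), 3 * se)
})

test_that("expected counts conserve transcript flux between junction and body", {
  # E[junction]/(1-rho) and E[intron]/(rho*len/1000) both estimate S*e
  base <- list(nGenes = 600, intronGeneFraction = 1,
               intronsPerGeneProbs = c(`1` = 1, `2` = 0, `3` = 0),
               exonLenRange = c(200L, 200L), intronLenRange = c(150L, 150L),
               meanlog = log(800), sdlog = 0, baseRetention = 0.05,
               missplicedFraction = 0, effectFold = 2)
  sim <- simulateExperiment(do.call(simConfig, c(base, seed = 31)))
  rho <- 0.05
  flux_j <- mean(junctionCounts(simJunctions(sim))[, "wt"]) / (1 - rho)
  flux_i <- mean(simIntronCounts(sim)[, "wt"]) / (rho * 150 / 1000)
  S_wt <- 50 * 2020800 / 1e6
  expect_equal(flux_j / (S_wt * 800), 1, tolerance = 0.02)
  expect_equal(flux_i / (S_wt * 800), 1, tolerance = 0.02)
})

test_that("count noise is Poisson: moments and dispersion at a fixed rate", {
  # 10,000 iid draws per seed at one fixed rate, pooled over five seeds
  # (50,000 draws) so a single unlucky replicate cannot dominate
  base <- list(nGenes = 10000, intronGeneFraction = 1,
               intronsPerGeneProbs = c(`1` = 1, `2` = 0, `3` = 0),
               exonLenRange = c(150L, 150L), intronLenRange = c(100L, 100L),
               meanlog = log(300), sdlog = 0, baseRetention = 0.02,
               missplicedFraction = 0)
  x <- unlist(lapply(77:81, function(s) {
    sim <- simulateExperiment(do.call(simConfig, c(base, seed = s)))
    simIntronCounts(sim)[, "wt"]
  }), use.names = FALSE)
  rate <- (50 * 2020800 / 1e6) * 300 * 0.02 * 0.1
  n <- length(x)
  expect_equal(n, 50000L)
  expect_lt(abs(mean(x) - rate), 3 * sqrt(rate / n))
  # Poisson variance == mean; SE of the sample variance ~ sqrt(2/(n-1))*rate
  expect_lt(abs(var(x) - rate), 3 * sqrt(2 / (n - 1)) * rate * 1.1)
  # chi-square goodness of fit against Poisson(rate), alpha = 0.01
  br <- c(-Inf, qpois(seq(0.1, 0.9, 0.1), rate), Inf)
  obs <- table(cut(x, br))
  pr <- diff(ppois(br, rate))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("implanted misspliced sets are sized and recorded correctly", {
  cfg <- simConfig(nGenes = 300, seed = 8)
  sim <- simulateExperiment(cfg)
  tr <- simTruth(sim)
  n_intr <- length(introns(sim))
  expect_equal(sum(tr$misspliced), round(0.073 * n_intr))
  expect_true(all(tr$rho_mut[tr$misspliced] == 4 * tr$rho_wt[tr$misspliced]))
  expect_true(all(tr$rho_mut[!tr$misspliced] == tr$rho_wt[!tr$misspliced]))
  # too few introns for the fraction -> warning and zero implanted
  tiny <- simConfig(nGenes = 10, seed = 8, missplicedFraction = 0.001)
  expect_warning(sim0 <- simulateExperiment(tiny), "zero implanted")
  expect_equal(sum(simTruth(sim0)$misspliced), 0L)
})
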