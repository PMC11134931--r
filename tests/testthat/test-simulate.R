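test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- smallSimConfig(seed = 7L)
  d1 <- simulateGenome(cfg)
  d2 <- simulateGenome(cfg)
  expect_identical(start(cpgSites(d1)), start(cpgSites(d2)))
  expect_identical(as.data.frame(geneModels(d1)), as.data.frame(geneModels(d2)))
  s1 <- simulateMethylationCounts(d1, cfg)
  s2 <- simulateMethylationCounts(d2, cfg)
  expect_identical(methCounts(s1$bulk), methCounts(s2$bulk))
  expect_identical(methCounts(s1$hybridAlleles), methCounts(s2$hybridAlleles))
  # a different seed changes the counts
  cfg3 <- smallSimConfig(seed = 8L)
  s3 <- simulateMethylationCounts(simulateGenome(cfg3), cfg3)
  expect_false(identical(methCounts(s1$bulk), methCounts(s3$bulk)))
})

test_that("island geometry is exact by construction", {
  cfg <- smallSimConfig(seed = 9L, islandRate = 20 / 300000,
                        islandLength = 500L, cgiPromoterFraction = 0)
  ds <- simulateGenome(cfg)
  expect_length(truthCGIs(ds), 20)
  expect_equal(sum(width(truthCGIs(ds))), 10000)
  # no islands at all in the degenerate config
  cfg0 <- smallSimConfig(seed = 9L, islandRate = 0, cgiPromoterFraction = 0)
  ds0 <- simulateGenome(cfg0)
  expect_length(truthCGIs(ds0), 0)
  # background spacing is then geometric with the configured rate
  gaps <- diff(start(cpgSites(ds0)))
  gaps <- gaps[gaps > 0]
  inMarker <- overlapsAny(cpgSites(ds0), markerLoci(ds0))
  bgGaps <- diff(start(cpgSites(ds0)[!inMarker]))
  expect_lt(abs(mean(bgGaps) - 1 / cfg0@cpgBackgroundRate),
            4 * sd(bgGaps) / sqrt(length(bgGaps)))
})

test_that("intervals live inside chromosomes and markers sit away from the ends", {
  cfg <- smallSimConfig(seed = 10L)
  ds <- simulateGenome(cfg)
  sz <- chromSizes(ds)
  for (gr in list(cpgSites(ds), geneModels(ds), promoterSet(ds),
                  truthCGIs(ds), markerLoci(ds))) {
    if (!length(gr)) next
    expect_true(all(start(gr) >= 1))
    expect_true(all(end(gr) <= sz[as.character(seqnames(gr))]))
  }
  mk <- markerLoci(ds)
  expect_true(all(width(mk) == 200))
  expect_true(all(start(mk) >= 101))
  # truth labels cover the configured mixes
  expect_equal(sort(unique(mcols(mk)$architecture)),
               sort(architectureClasses()))
  expect_equal(sum(mcols(geneModels(ds))$de),
               round(cfg@deFraction * cfg@nGenes))
})

test_that("null effects reproduce the configured genome-wide mean level", {
  cfg <- smallSimConfig(seed = 11L, islandRate = 0, cgiPromoterFraction = 0,
                        tissueEffects = c(brain = 0, heart = 0, kidney = 0,
                                          liver = 0, testis = 0),
                        speciesEffect = 0, baseLevel = 0.8,
                        inheritanceMix = c(conserved = 1, additive = 0,
                                           collared_dominant = 0,
                                           pied_dominant = 0,
                                           overdominant = 0,
                                           underdominant = 0),
                        architectureMix = c(conserved = 1, cis = 0, trans = 0,
                                            `cis+trans` = 0, cisxtrans = 0,
                                            compensatory = 0))
  ds <- simulateGenome(cfg)
  sim <- simulateMethylationCounts(ds, cfg)
  lev <- siteLevels(sim$bulk)
  # exclude promoters (gene-specific conserved levels), gene bodies (per-gene
  # shifts) and marker windows (architecture base 0.5): the remaining
  # background carries the configured base level
  bg <- !overlapsAny(rowRanges(sim$bulk),
                     c(granges(geneModels(ds)), granges(promoterSet(ds)),
                       granges(markerLoci(ds))))
  gm <- mean(lev[bg, ], na.rm = TRUE)
  expect_lt(abs(gm - 0.8), 0.015)
})

test_that("beta-binomial counts match the analytic variance at fixed coverage", {
  set.seed(12)
  n <- 10000; nn <- 30; mu <- 0.3; phi <- 20
  m <- hymeth:::.betaBinom(rep(nn, n), rep(mu, n), phi)
  want <- nn * mu * (1 - mu) * (nn + phi) / (1 + phi)
  batch <- matrix(m, 100)
  bv <- apply(batch, 2, var)
  se <- sd(bv) / sqrt(length(bv))
  expect_lt(abs(var(m) - want), 3 * se)
  # phi -> infinity approaches the binomial variance
  m2 <- hymeth:::.betaBinom(rep(nn, n), rep(mu, n), 1e7)
  expect_lt(abs(var(m2) - nn * mu * (1 - mu)), 0.35)
})

test_that("the marker generator honours the architecture contracts", {
  set.seed(13)
  sim <- simulateMarkerLevels(nPerClass = 150,
                              classes = c("cis", "trans", "compensatory"),
                              randomSign = FALSE)
  byClass <- function(cl, m) rowMeans(m[sim$truth == cl, ])
  # cis: parental delta ~ 0.3 reproduced between hybrid alleles
  dP <- byClass("cis", sim$colP) - byClass("cis", sim$pieP)
  dH <- byClass("cis", sim$colH) - byClass("cis", sim$pieH)
  expect_lt(abs(mean(dP) - 0.3), 0.03)
  expect_lt(abs(mean(dH) - 0.3), 0.03)
  # trans: hybrid alleles converge to the midparent
  dHt <- byClass("trans", sim$colH) - byClass("trans", sim$pieH)
  expect_lt(abs(mean(dHt)), 0.03)
  # compensatory: parents equal, hybrid alleles split
  dPc <- byClass("compensatory", sim$colP) - byClass("compensatory", sim$pieP)
  dHc <- byClass("compensatory", sim$colH) - byClass("compensatory", sim$pieH)
  expect_lt(abs(mean(dPc)), 0.03)
  expect_lt(abs(mean(dHc) - 0.3), 0.03)
})

test_that("expression coupling contracts hold at both extremes", {
  cfg <- smallSimConfig(seed = 14L, expressionCoupling = 0)
  ds <- simulateGenome(cfg)
  sim <- simulateMethylationCounts(ds, cfg)
  ex0 <- simulateExpression(ds, sim$bulk, cfg)
  expect_equal(sum(ex0$de), round(cfg@deFraction * cfg@nGenes))
  # decoupled: promoter methylation uninformative about expression
  s <- colnames(sim$bulk)[1]
  rho0 <- cor(ex0$promoterLevels[, s], log1p(ex0$counts[, s]),
              method = "spearman", use = "complete.obs")
  expect_lt(abs(rho0), 0.25)
  cfgN <- smallSimConfig(seed = 14L, expressionCoupling = -6)
  exN <- simulateExpression(ds, sim$bulk, cfgN)
  rhoN <- cor(exN$promoterLevels[, s], log1p(exN$counts[, s]),
              method = "spearman", use = "complete.obs")
  expect_lt(rhoN, -0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(architectureMix = c(conserved = 0.9, cis = 0.2,
                                             trans = 0, `cis+trans` = 0,
                                             cisxtrans = 0, compensatory = 0)),
               "sum to 1")
  expect_error(SimConfig(nGenes = 0L), "positive")
  cfg <- SimConfig(nChroms = 1L, chromLength = 50000L, nGenes = 40L,
                   nFixedDifferences = 5L)
  expect_error(simulateGenome(cfg), "too short")
})

test_that("the written study directory round-trips through the file readers", {
  cfg <- smallSimConfig(seed = 15L)
  ds <- simulateGenome(cfg)
  sim <- simulateMethylationCounts(ds, cfg)
  dir <- file.path(tempdir(), "studyrt")
  writeSimulatedStudy(ds, sim, expr = NULL, dir)
  sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
  expect_equal(sizes, chromSizes(ds))
  mk <- readBED(file.path(dir, "markers.bed"))
  expect_equal(length(mk), length(markerLoci(ds)))
  expect_equal(start(mk), start(markerLoci(ds)))
  samples <- read.table(file.path(dir, "samples.tsv"), sep = "\t",
                        header = TRUE, row.names = 1)
  one <- rownames(samples)[1]
  cov <- readBismarkCov(file.path(dir, "cov", paste0(one, ".cov")))
  keep <- totalCounts(sim$bulk)[, one] > 0
  expect_equal(mcols(cov)$meth, methCounts(sim$bulk)[keep, one])
})
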