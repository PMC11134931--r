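test_that("coverage capping rescales proportionally with half-to-even rounding", {
  got <- capCoverage(80, 20, capValue = 50)
  expect_equal(got$meth, 40); expect_equal(got$unmeth, 10)
  # below the cap: untouched
  m <- c(3, 10); u <- c(4, 12)
  got2 <- capCoverage(m, u, capValue = 100)
  expect_equal(got2$meth, m); expect_equal(got2$unmeth, u)
  # cap quantile 1.0 never rescales
  got3 <- capCoverage(m, u, q = 1)
  expect_equal(got3$meth, m)
  # linear-interpolated quantile cap
  tot <- c(10, 20, 30, 40)
  expect_equal(capCoverage(tot, rep(0, 4), q = 0.5)$cap,
               unname(quantile(tot, 0.5)))
  # half-to-even: 15 meth of 30 capped to 15 -> 7.5 rounds to 8
  got4 <- capCoverage(15, 15, capValue = 15)
  expect_equal(got4$meth, 8); expect_equal(got4$unmeth, 7)
})

test_that("parental downsampling is a deterministic-under-seed uniform subset", {
  ids <- paste0("COL", 1:6)
  set.seed(9); a <- downsampleParents(ids, 3)
  set.seed(9); b <- downsampleParents(ids, 3)
  expect_identical(a, b)
  expect_length(a, 3)
  expect_true(all(a %in% ids))
  expect_identical(downsampleParents(ids[1:3], 3), ids[1:3])
  expect_error(downsampleParents(ids[1:2], 3), "fewer than")
})

test_that("beta regression returns null results for identical groups", {
  res <- betaRegTest(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_true(res$converged)
  expect_lt(abs(res$beta1), 1e-4)
  expect_gt(res$p, 0.95)
})

test_that("beta regression separates well-separated groups with the right sign", {
  res <- betaRegTest(c(0.9, 0.85, 0.95), c(0.1, 0.15, 0.05))
  expect_lt(res$p, 0.01)
  expect_equal(res$sign, 1)
  res2 <- betaRegTest(c(0.1, 0.15, 0.05), c(0.9, 0.85, 0.95))
  expect_equal(res2$sign, -1)
  # too few observations: flagged, not crashed
  expect_false(betaRegTest(0.5, c(0.4, 0.6))$converged)
})

test_that("the Wald statistic agrees with an independent numerical-ML oracle", {
  skip_if_not_installed("pracma")
  set.seed(41)
  for (i in 1:50) {
    mu <- runif(1, 0.15, 0.85)
    d <- runif(1, -0.2, 0.2)
    a <- rbeta(3, (mu + d / 2) * 25, (1 - mu - d / 2) * 25)
    b <- rbeta(3, (mu - d / 2) * 25, (1 - mu + d / 2) * 25)
    fit <- betaRegTest(a, b)
    z <- fit$beta1 / fit$se
    zo <- betaWaldOracle(a, b)
    expect_lt(abs(z - zo), 1e-4)
  }
})

test_that("locus classification follows the seven-category rule table", {
  S <- 0.05; N <- 0.5   # significant / not at fdr = 0.1
  cl <- function(qp, qh, qtc, qtp, dP = 0.3, dH = 0.3, ...)
    classifyLocus(qp, qh, qtc, qtp, dP, dH, ...)
  expect_equal(cl(N, N, N, N), "conserved")
  expect_equal(cl(N, N, S, S), "conserved")       # trans alone cannot unseat it
  expect_equal(cl(S, S, N, N), "cis")
  expect_equal(cl(S, S, N, N, dP = 0.3, dH = -0.3), "unclassified") # sign clash
  expect_equal(cl(S, N, S, N), "trans")
  expect_equal(cl(S, N, N, S), "trans")           # either-allele trans rule
  expect_equal(cl(S, N, N, N), "unclassified")
  expect_equal(cl(N, S, S, N), "compensatory")
  expect_equal(cl(N, S, N, N), "unclassified")
  expect_equal(cl(S, S, S, N, dP = 0.6, dH = 0.3), "cis+trans")   # dT, dH agree
  expect_equal(cl(S, S, S, N, dP = 0.1, dH = 0.3), "cisxtrans")   # dT opposes
  expect_equal(cl(S, S, S, N, dP = 0.3, dH = 0.3), "unclassified") # dT = 0
  expect_equal(cl(NA, S, S, S), "ambiguous")
  expect_equal(cl(S, S, S, S, ambiguous = TRUE), "ambiguous")
  # single-test trans rule uses only the PIE contrast
  expect_equal(cl(S, N, S, N, transRule = "pie"), "unclassified")
  expect_equal(cl(S, N, N, S, transRule = "pie"), "trans")
  # exhaustive: every pattern maps to exactly one known category
  for (qp in c(S, N)) for (qh in c(S, N)) for (qtc in c(S, N))
    for (qtp in c(S, N)) for (dH in c(0.3, -0.3)) {
      got <- cl(qp, qh, qtc, qtp, dP = 0.45, dH = dH)
      expect_true(got %in% divergenceCategories())
    }
})

test_that("architecture recovery meets the study-condition targets on a reduced run", {
  set.seed(51)
  sim <- simulateMarkerLevels(nPerClass = 120,
                              classes = c("conserved", "cis", "trans"))
  tests <- locusTests(sim$colP, sim$pieP, sim$colH, sim$pieH)
  calls <- classifyCisTrans(tests, fdr = 0.1)
  tab <- table(truth = sim$truth, call = calls$category)
  expect_gt(tab["cis", "cis"] / 120, 0.75)
  expect_gt(tab["trans", "trans"] / 120, 0.75)
  divergent <- c("cis", "trans", "cis+trans", "cisxtrans", "compensatory")
  falseDiv <- sum(tab["conserved", divergent]) / 120
  expect_lt(falseDiv, 0.2)
})

test_that("major axis regression matches closed form, symmetry and the eigen oracle", {
  ma <- majorAxisRegression(c(0, 1, 2), c(0, -1, -2))
  expect_equal(ma$slope, -1)
  expect_equal(ma$intercept, 0)
  set.seed(52)
  x <- rnorm(300); y <- 0.7 * x + rnorm(300, 0, 0.5)
  m1 <- majorAxisRegression(x, y)
  m2 <- majorAxisRegression(y, x)
  expect_equal(m1$slope, 1 / m2$slope, tolerance = 1e-10)
  ev <- eigen(cov(cbind(x, y)))$vectors[, 1]
  expect_equal(m1$slope, ev[2] / ev[1], tolerance = 1e-10)
  expect_equal(m1$p, cor.test(x, y)$p.value)
  # axis-aligned scatter: undefined slope
  expect_true(is.na(majorAxisRegression(c(1, 2, 3), c(5, 5, 5))$slope))
  expect_error(majorAxisRegression(1:2, 1:2), "3 complete")
})

test_that("allele-specific level extraction caps, downsamples and measures windows", {
  cfg <- smallSimConfig(seed = 8L)
  ds <- simulateGenome(cfg)
  sim <- simulateMethylationCounts(ds, cfg)
  cd <- colData(sim$bulk)
  par <- sim$bulk[, cd$tissue == "heart" & cd$species != "HYB"]
  hcd <- colData(sim$hybridAlleles)
  hyb <- sim$hybridAlleles[, hcd$tissue == "heart"]
  set.seed(1)
  lev <- alleleSpecificLevels(par, hyb, markerLoci(ds))
  expect_equal(dim(lev$colP), c(length(markerLoci(ds)), 3L))
  expect_equal(dim(lev$colH), c(length(markerLoci(ds)), 3L))
  ok <- !is.na(lev$colP)
  expect_true(all(lev$colP[ok] >= 0 & lev$colP[ok] <= 1))
  # cis loci: allele difference preserved across environments (generator contract)
  arch <- mcols(markerLoci(ds))$architecture
  cis <- which(arch == "cis")
  dP <- rowMeans(lev$colP[cis, ]) - rowMeans(lev$pieP[cis, ])
  dH <- rowMeans(lev$colH[cis, ]) - rowMeans(lev$pieH[cis, ])
  expect_gt(cor(dP, dH), 0.8)
  expect_lt(abs(mean(abs(dP)) - mean(abs(dH))), 0.08)
})
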