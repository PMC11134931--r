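test_that("a planted differential block is recovered as one DMR meeting the criteria", {
  fix <- makeTwoGroupMS(nSites = 800, blockIdx = 400:409, delta = 0.5,
                        chromLen = 4e5, seed = 3)
  dmrs <- callDMRs(fix$ms, fix$g1, fix$g2)
  blk <- GRanges("chr1", IRanges(fix$pos[fix$blockIdx[1]],
                                 fix$pos[max(fix$blockIdx)]))
  hit <- overlapsAny(dmrs, blk)
  expect_equal(sum(hit), 1)
  d <- dmrs[hit]
  expect_gte(mcols(d)$n_cpgs, 3)
  expect_gte(abs(mcols(d)$mean_diff), 0.1)
  expect_gt(mcols(d)$mean_diff, 0)   # signed group1 - group2
  # every returned DMR satisfies the invariants
  expect_true(all(mcols(dmrs)$n_cpgs >= 3))
  expect_true(all(abs(mcols(dmrs)$mean_diff) >= 0.1))
})

test_that("identical groups produce no DMRs", {
  fix <- makeTwoGroupMS(nSites = 400, seed = 4)
  m <- methCounts(fix$ms); u <- unmethCounts(fix$ms)
  m[, 4:6] <- m[, 1:3]; u[, 4:6] <- u[, 1:3]   # group2 := group1
  ms <- makeMS(m, u, fix$pos, species = rep(c("COL", "PIE"), each = 3))
  expect_length(callDMRs(ms, fix$g1, fix$g2), 0)
})

test_that("null genomes put about 2% of CpGs in the pre-filter candidate tails", {
  fix <- makeTwoGroupMS(nSites = 3000, chromLen = 1.2e6, seed = 5)
  cand <- callDMRs(fix$ms, fix$g1, fix$g2, candidates = TRUE)
  frac <- sum(mcols(cand)$n_cpgs) / 3000
  expect_gt(frac, 0.012)
  expect_lt(frac, 0.032)
})

test_that("runs shorter than the CpG floor are rejected", {
  # an isolated 2-CpG block with a huge difference, far from other CpGs
  set.seed(6)
  pos <- c(seq(1000, 200000, by = 700), 500000, 500010)
  n <- length(pos)
  mu1 <- rep(0.5, n); mu2 <- rep(0.5, n)
  mu1[(n - 1):n] <- 0.95; mu2[(n - 1):n] <- 0.05
  meth <- unmeth <- matrix(0L, n, 6)
  for (j in 1:3) {
    cov <- rnbinom(n, mu = 30, size = 5)
    m <- rbinom(n, cov, rbeta(n, mu1 * 60, (1 - mu1) * 60))
    meth[, j] <- m; unmeth[, j] <- cov - m
    cov <- rnbinom(n, mu = 30, size = 5)
    m <- rbinom(n, cov, rbeta(n, mu2 * 60, (1 - mu2) * 60))
    meth[, j + 3] <- m; unmeth[, j + 3] <- cov - m
  }
  colnames(meth) <- colnames(unmeth) <- c(paste0("A", 1:3), paste0("B", 1:3))
  ms <- makeMS(meth, unmeth, pos, species = rep(c("COL", "PIE"), each = 3))
  dmrs <- callDMRs(ms, paste0("A", 1:3), paste0("B", 1:3))
  blk <- GRanges("chr1", IRanges(500000, 500011))
  expect_false(any(overlapsAny(dmrs, blk)))          # filtered by minCpgs
  cand <- callDMRs(ms, paste0("A", 1:3), paste0("B", 1:3), candidates = TRUE)
  expect_true(any(overlapsAny(cand, blk)))           # but present pre-filter
})

test_that("the coverage rule excludes CpGs without 2 samples at >= 2x per group", {
  meth <- cbind(A1 = c(5L, 5L), A2 = c(5L, 0L), B1 = c(1L, 1L), B2 = c(1L, 0L))
  unmeth <- cbind(A1 = c(5L, 5L), A2 = c(5L, 1L), B1 = c(9L, 9L), B2 = c(9L, 0L))
  ms <- makeMS(meth, unmeth, c(100, 2000),
               species = c("COL", "COL", "PIE", "PIE"))
  # site 2: group B has one sample with coverage 0 -> fails the rule
  gd <- hymeth:::.groupMeanDiff(ms, c("A1", "A2"), c("B1", "B2"))
  expect_true(gd$pass[1])
  expect_false(gd$pass[2])
  # nothing passing warns and returns empty
  ms0 <- makeMS(cbind(A1 = 1L, A2 = 0L, B1 = 0L, B2 = 1L),
                cbind(A1 = 0L, A2 = 0L, B1 = 1L, B2 = 0L), 100,
                species = c("COL", "COL", "PIE", "PIE"))
  expect_warning(res <- callDMRs(ms0, c("A1", "A2"), c("B1", "B2")),
                 "coverage rule")
  expect_length(res, 0)
})

test_that("direction test matches the exact binomial oracle", {
  dt <- directionTest(c(rep(0.3, 70), rep(-0.2, 30)))
  expect_equal(dt$freq_hyper, 0.7)
  expect_equal(dt$p, binom.test(70, 100, 0.5)$p.value)
  expect_lt(abs(dt$p - 7.85e-5), 1e-5)
  expect_equal(directionTest(c(rep(1, 50), rep(-1, 50)))$p, 1)
  expect_equal(directionTest(rep(0.4, 10))$p, 2 * 0.5^10)
  expect_true(is.na(directionTest(numeric(0))$p))
})

test_that("tissue-specific classification applies support and uniqueness set logic", {
  tissues <- c("brain", "heart", "kidney", "liver", "testis")
  pairs <- t(combn(tissues, 2))
  empty <- GRanges()
  mkSets <- function(fill) {
    s <- setNames(rep(list(empty), nrow(pairs)),
                  apply(pairs, 1, paste, collapse = "."))
    for (nm in names(fill)) s[[nm]] <- fill[[nm]]
    s
  }
  region <- GRanges("chr1", IRanges(1000, 2000))
  focalKeys <- c("brain.heart", "brain.kidney", "brain.liver", "brain.testis")
  # supported in all four focal comparisons, absent elsewhere -> tsDMR
  sets <- mkSets(setNames(rep(list(region), 4), focalKeys))
  got <- classifyTissueSpecific(sets, tissues, "brain")
  expect_length(got, 1)
  expect_equal(mcols(got)$focal_tissue, "brain")
  # present in only 3 of 4 -> rejected
  sets3 <- mkSets(setNames(rep(list(region), 3), focalKeys[1:3]))
  expect_length(classifyTissueSpecific(sets3, tissues, "brain"), 0)
  # present in all 4 but also in a non-focal comparison -> rejected
  sets5 <- mkSets(c(setNames(rep(list(region), 4), focalKeys),
                    list(`heart.liver` = region)))
  expect_length(classifyTissueSpecific(sets5, tissues, "brain"), 0)
  # a sub-reciprocal partner in the non-focal comparison does not veto
  small <- GRanges("chr1", IRanges(1950, 2000))
  sets6 <- mkSets(c(setNames(rep(list(region), 4), focalKeys),
                    list(`heart.liver` = small)))
  expect_length(classifyTissueSpecific(sets6, tissues, "brain"), 1)
  # missing comparison set is a configuration error
  expect_error(classifyTissueSpecific(sets[-1], tissues, "brain"), "missing")
})

test_that("the kernel smoother is a local weighted average", {
  pos <- c(0, 100, 200, 10000)
  d <- c(0, 1, 0, 5)
  sm <- smoothDiff(pos, d, bandwidth = 500)
  w <- 1 - abs(pos[1:3] - 100) / 500
  expect_equal(sm[2], sum(w * d[1:3]) / sum(w))
  expect_equal(sm[4], 5)   # isolated site keeps its own value
  expect_true(all(is.na(smoothDiff(pos, rep(NA_real_, 4)))))
})
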