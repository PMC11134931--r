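test_that("a dense CpG run on a sparse chromosome becomes one island", {
  # 30 CpGs spaced 2 bp inside a chromosome whose other CpGs are >= 500 apart
  dense <- seq(5001, by = 2, length.out = 30)
  sparse <- seq(1, 10000, by = 500)
  sparse <- sparse[sparse < 4800 | sparse > 5200]
  cpgs <- GRanges("chr1", IRanges(sort(c(dense, sparse)), width = 1))
  cgi <- detectCGIs(cpgs)
  expect_length(cgi, 1)
  expect_true(start(cgi) <= min(dense) && end(cgi) >= max(dense))
  expect_equal(mcols(cgi)$n_cpgs, 30L)
})

test_that("uniform spacing yields no significant cluster", {
  cpgs <- GRanges("chr1", IRanges(seq(1, 50000, by = 100), width = 1))
  expect_length(detectCGIs(cpgs), 0)
})

test_that("dense runs spanning under the minimum length are rejected", {
  dense <- seq(5001, by = 2, length.out = 20)   # span 38 + 1 < 50 bp
  sparse <- seq(10001, 60000, by = 500)
  cpgs <- GRanges("chr1", IRanges(sort(c(dense, sparse)), width = 1))
  cgi <- detectCGIs(cpgs, minLength = 50)
  expect_length(cgi, 0)
  # and accepted when the length floor allows it
  cgi2 <- detectCGIs(cpgs, minLength = 30)
  expect_length(cgi2, 1)
})

test_that("island calls are sorted and disjoint; tiny chromosomes give none", {
  set.seed(5)
  pos <- sort(sample.int(2e5, 800))
  pos <- unique(c(pos, unlist(lapply(c(3e4, 9e4, 15e4),
                                     function(s) seq(s, by = 3, length.out = 40)))))
  cpgs <- GRanges("chr1", IRanges(sort(pos), width = 1))
  cgi <- detectCGIs(cpgs)
  expect_true(length(cgi) >= 1)
  expect_false(is.unsorted(start(cgi)))
  expect_true(all(start(cgi)[-1] > end(cgi)[-length(cgi)]))
  expect_length(detectCGIs(GRanges("chr2", IRanges(5, width = 1))), 0)
})

test_that("promoters are the 2-kb strand-aware upstream region, trimmed at edges", {
  genes <- GRanges(c("chr1", "chr1", "chr1"),
                   IRanges(c(10001, 30001, 1001), c(12000, 32000, 3000)),
                   strand = c("+", "-", "+"))
  seqlengths(genes) <- c(chr1 = 50000)
  pr <- promoterRegions(genes)
  expect_equal(start(pr)[1], 8001); expect_equal(end(pr)[1], 10000)
  # minus strand: upstream lies above the TSS (= end)
  expect_equal(start(pr)[2], 32001); expect_equal(end(pr)[2], 34000)
  # truncated, not discarded, at the chromosome start
  expect_equal(start(pr)[3], 1); expect_equal(end(pr)[3], 1000)
})

test_that("promoter typing uses any 1-bp overlap and is idempotent", {
  prom <- GRanges("chr1", IRanges(1001, 3000))
  expect_equal(as.character(typePromoters(prom, GRanges("chr1", IRanges(3000, 3100)))),
               "CGI")   # single shared bp
  expect_equal(as.character(typePromoters(prom, GRanges("chr1", IRanges(3001, 3100)))),
               "Other") # adjacent, no overlap
  expect_equal(as.character(typePromoters(prom, GRanges("chr1", IRanges(1500, 1600)))),
               "CGI")   # island strictly inside
  expect_equal(as.character(typePromoters(prom, GRanges())), "Other")
  t1 <- typePromoters(prom, GRanges("chr1", IRanges(1500, 1600)))
  expect_identical(typePromoters(prom, GRanges("chr1", IRanges(1500, 1600))), t1)
})

test_that("reciprocal overlap fractions match brute-force bp counting", {
  a <- GRanges("chr1", IRanges(1, 100))
  expect_equal(unname(reciprocalOverlap(a, GRanges("chr1", IRanges(51, 150)))[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(reciprocalOverlap(GRanges("chr1", IRanges(1, 1000)),
                                        GRanges("chr1", IRanges(901, 1000)))[1, ]),
               c(0.1, 1.0))
  expect_equal(unname(reciprocalOverlap(a, GRanges("chr1", IRanges(500, 600)))[1, ]),
               c(0, 0))
  expect_equal(unname(reciprocalOverlap(a, GRanges("chr2", IRanges(1, 100)))[1, ]),
               c(0, 0))
  set.seed(8)
  for (i in 1:20) {
    s1 <- sample.int(500, 1); e1 <- s1 + sample.int(300, 1)
    s2 <- sample.int(500, 1); e2 <- s2 + sample.int(300, 1)
    x <- GRanges("chr1", IRanges(s1, e1)); y <- GRanges("chr1", IRanges(s2, e2))
    bp <- sum(seq(s1, e1) %in% seq(s2, e2))   # bitmap oracle
    expect_equal(unname(reciprocalOverlap(x, y)[1, ]),
                 c(bp / (e1 - s1 + 1), bp / (e2 - s2 + 1)))
  }
})

test_that("reciprocal-partner matching honours the 25% rule", {
  q <- GRanges("chr1", IRanges(1001, 2000))
  expect_true(hasReciprocalPartner(q, GRanges("chr1", IRanges(1200, 2200))))
  # partner overlaps 10% of the query: fails reciprocity
  expect_false(hasReciprocalPartner(q, GRanges("chr1", IRanges(1901, 2000))))
  expect_false(hasReciprocalPartner(q, GRanges("chr2", IRanges(1001, 2000))))
})

test_that("BED6 files round-trip through the 0-based disk convention", {
  gr <- GRanges("chr1", IRanges(c(1, 501), c(100, 900)),
                strand = c("+", "-"))
  mcols(gr)$name <- c("a", "b")
  f <- tempfile(fileext = ".bed")
  writeBED(gr, f)
  raw <- read.table(f, sep = "\t")
  expect_equal(raw$V2, c(0, 500))   # 0-based starts on disk
  back <- readBED(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(strand(back)), c("+", "-"))
})
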