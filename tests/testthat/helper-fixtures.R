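# shared fixture builders (all data generated in code)

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# MethylationSet with explicit counts; sites on one chromosome
makeMS <- function(meth, unmeth, pos, species = NULL, tissue = "brain",
                   chrom = "chr1") {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (is.null(colnames(meth)))
    colnames(meth) <- colnames(unmeth) <- paste0("s", seq_len(ncol(meth)))
  if (is.null(species)) species <- rep("COL", ncol(meth))
  MethylationSet(meth, unmeth,
                 GRanges(chrom, IRanges(pos, width = 1)),
                 data.frame(species = species,
                            tissue = rep(tissue, length.out = ncol(meth)),
                            row.names = colnames(meth)))
}

# two-group beta-binomial counts with a planted differential block
makeTwoGroupMS <- function(nSites = 800, nPerGroup = 3, blockIdx = integer(0),
                           mu0 = 0.5, delta = 0.5, phi = 60, covMean = 30,
                           chromLen = 1e6, seed = 1) {
  set.seed(seed)
  nBlock <- length(blockIdx)
  nBg <- nSites - nBlock
  if (nBlock) {
    # the planted block is a dense contiguous run (150-bp spacing) in a
    # reserved region, so a fortuitous CpG desert cannot split it
    blockStart <- round(chromLen / 2)
    blockPos <- blockStart + seq(0, by = 150, length.out = nBlock)
    bg <- sample.int(chromLen, nBg)
    bg <- bg[bg < blockStart - 150 | bg > max(blockPos) + 150]
    pos <- sort(unique(c(bg, blockPos)))
    blockIdx <- match(blockPos, pos)
    nSites <- length(pos)
  } else {
    pos <- sort(unique(sample.int(chromLen, nSites)))
    nSites <- length(pos)
  }
  mu1 <- rep(mu0, nSites); mu2 <- rep(mu0, nSites)
  mu1[blockIdx] <- mu0 + delta / 2
  mu2[blockIdx] <- mu0 - delta / 2
  draw <- function(mu) {
    cov <- rnbinom(nSites, mu = covMean, size = 5)
    p <- rbeta(nSites, mu * phi, (1 - mu) * phi)
    m <- rbinom(nSites, cov, p)
    list(m = m, u = cov - m)
  }
  meth <- unmeth <- matrix(0L, nSites, 2 * nPerGroup)
  for (j in seq_len(nPerGroup)) {
    d <- draw(mu1); meth[, j] <- d$m; unmeth[, j] <- d$u
    d <- draw(mu2); meth[, nPerGroup + j] <- d$m
    unmeth[, nPerGroup + j] <- d$u
  }
  colnames(meth) <- colnames(unmeth) <-
    c(paste0("A", seq_len(nPerGroup)), paste0("B", seq_len(nPerGroup)))
  list(ms = makeMS(meth, unmeth, pos,
                   species = rep(c("COL", "PIE"), each = nPerGroup)),
       pos = pos, blockIdx = blockIdx,
       g1 = paste0("A", seq_len(nPerGroup)),
       g2 = paste0("B", seq_len(nPerGroup)))
}

# independent numerical-ML oracle for the beta regression Wald statistic:
# same likelihood, generic optimiser, numerical Hessian
betaWaldOracle <- function(levelsA, levelsB) {
  y <- c(levelsA, levelsB)
  g <- c(rep(1, length(levelsA)), rep(0, length(levelsB)))
  N <- length(y)
  y <- (y * (N - 1) + 0.5) / N
  nll <- function(th) {
    mu <- plogis(th[1] + th[2] * g)
    phi <- exp(th[3])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  th0 <- c(qlogis(mean(y[g == 0])),
           qlogis(mean(y[g == 1])) - qlogis(mean(y[g == 0])), log(10))
  fit <- nlminb(th0, nll, control = list(rel.tol = 1e-12, eval.max = 500,
                                         iter.max = 300))
  H <- pracma::hessian(nll, fit$par)
  se <- sqrt(solve(H)[2, 2])
  fit$par[2] / se
}

smallSimConfig <- function(seed = 1L, ...) {
  SimConfig(nChroms = 1L, chromLength = 300000L, nGenes = 12L,
            nFixedDifferences = 30L, seed = seed, ...)
}
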