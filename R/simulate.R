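#' Group mean methylation levels implied by a cis/trans architecture
#'
#' For an effect size e on the proportion scale around a base level, returns
#' the mean methylation of the COL and PIE alleles in their parental
#' environment (PC, PP) and in the hybrid environment (HC, HP):
#' \itemize{
#' \item conserved: all equal to the base.
#' \item cis: allele difference e preserved in both environments (alleles are
#'   insensitive to the cellular environment).
#' \item trans: parental difference e, but hybrid alleles converge to the
#'   midparent (the additive-inheritance signature of trans divergence).
#' \item cis+trans: cis difference e in hybrids plus a reinforcing trans
#'   shift (parental difference 2e).
#' \item cisxtrans: cis difference e in hybrids opposed by trans (parental
#'   difference e/2).
#' \item compensatory: cis and trans cancel exactly between species (parents
#'   equal, hybrid alleles differ by e).
#' }
#'
#' @param class architecture class name.
#' @param effect effect size e on the proportion scale.
#' @param base base methylation proportion.
#' @param sgn +1/-1 orientation of the effect.
#' @return Named numeric: PC, PP, HC, HP.
#' @export
architectureMeans <- function(class, effect = 0.3, base = 0.5, sgn = 1) {
  e <- sgn * effect
  m <- switch(class,
    conserved = c(base, base, base, base),
    cis = c(base + e / 2, base - e / 2, base + e / 2, base - e / 2),
    trans = c(base + e / 2, base - e / 2, base, base),
    `cis+trans` = c(base + e, base - e, base + e / 2, base - e / 2),
    cisxtrans = c(base + e / 4, base - e / 4, base + e / 2, base - e / 2),
    compensatory = c(base, base, base + e / 2, base - e / 2),
    stop("unknown architecture class: ", class))
  setNames(pmin(0.98, pmax(0.02, m)), c("PC", "PP", "HC", "HP"))
}

#' Hybrid promoter mean implied by an inheritance mode
#'
#' Parental promoter means are \code{base +/- effect/2} (COL higher); the
#' hybrid mean is the midparent for additive, a parental value for the
#' dominant modes, and outside the parental range by \code{effect} for the
#' mismethylation modes (clamped to [0.02, 0.98]). Conserved promoters have
#' no parental difference.
#'
#' @param mode inheritance mode name.
#' @param effect parental difference on the proportion scale.
#' @param base midparent level.
#' @return Named numeric: COL, PIE, HYB.
#' @export
inheritanceMeans <- function(mode, effect = 0.3, base = 0.5) {
  cl <- base + effect / 2
  pl <- base - effect / 2
  hyb <- switch(mode,
    conserved = base,
    additive = base,
    collared_dominant = cl,
    pied_dominant = pl,
    overdominant = cl + effect,
    underdominant = pl - effect,
    stop("unknown inheritance mode: ", mode))
  if (mode == "conserved") cl <- pl <- base
  setNames(pmin(0.98, pmax(0.02, c(cl, pl, hyb))), c("COL", "PIE", "HYB"))
}

.countsByMix <- function(n, mix) {
  k <- floor(n * mix)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(n * mix - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  k
}

.cpgRun <- function(from, to, rate) {
  # geometric spacings with mean 1/rate starting at `from`
  n <- ceiling((to - from + 1) * rate * 1.6) + 20
  pos <- from + cumsum(rgeom(n, rate) + 1L)
  while (length(pos) && max(pos) < to) {
    pos <- c(pos, max(pos) + cumsum(rgeom(n, rate) + 1L))
  }
  pos[pos <= to]
}

#' Simulate a genome with annotations and truth labels
#'
#' Draws chromosome-length genomes with CpG positions as a background
#' geometric (rate \code{cpgBackgroundRate}) spacing process plus dense runs
#' at CpG islands; places non-overlapping genes with strand, derives 2-kb
#' promoters, seeds islands into a configurable fraction of promoters plus
#' \code{round(islandRate * genomeLength)} background islands; places
#' fixed-difference marker loci (200-bp windows at least 100 bp from
#' chromosome ends, each seeded with a dense CpG run) labelled with a true
#' architecture class; assigns per-gene inheritance modes and DE status; and
#' generates a per-gene-bin Fst track whose CpG context is coupled to the
#' per-gene methylation divergence. Deterministic under the config seed.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A \linkS4class{SyntheticDataset}.
#' @export
simulateGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nChr <- config@nChroms
  L <- config@chromLength
  sizes <- setNames(rep(L, nChr), paste0("chr", seq_len(nChr)))
  si <- Seqinfo(names(sizes), unname(sizes))

  # --- genes: sequential placement with random gaps -------------------------
  nGenes <- config@nGenes
  perChr <- .countsByMix(nGenes, rep(1 / nChr, nChr))
  geneList <- vector("list", nChr)
  markerSpace <- vector("list", nChr)
  for (c_ in seq_len(nChr)) {
    ng <- perChr[c_]
    if (ng == 0) { geneList[[c_]] <- GRanges(); next }
    glen <- round(runif(ng, 2000, 8000))
    gap <- round(runif(ng, 4000, 9000))
    starts <- 3000 + cumsum(gap) + c(0, cumsum(glen[-ng]))
    ends <- starts + glen - 1
    if (max(ends) > L - 6000)
      stop("chromosome too short for requested genes; reduce nGenes or ",
           "increase chromLength")
    geneList[[c_]] <- GRanges(names(sizes)[c_], IRanges(starts, ends),
                              strand = sample(c("+", "-"), ng, TRUE))
  }
  genes <- do.call(c, geneList)
  seqlevels(genes) <- names(sizes)
  seqlengths(genes) <- unname(sizes)
  mcols(genes)$gene_id <- sprintf("g%04d", seq_along(genes))
  names(genes) <- mcols(genes)$gene_id
  inh <- rep(inheritanceModes(), .countsByMix(length(genes),
                                              config@inheritanceMix))
  mcols(genes)$inheritance <- sample(inh)
  nde <- round(config@deFraction * length(genes))
  de <- rep(FALSE, length(genes)); de[sample(length(genes), nde)] <- TRUE
  mcols(genes)$de <- de
  mcols(genes)$species_shift <- rnorm(length(genes), 0, 0.6)
  promoters <- promoterRegions(genes)
  mcols(genes)$promoter_cgi <-
    runif(length(genes)) < config@cgiPromoterFraction

  # --- marker loci in intergenic space --------------------------------------
  occupied <- reduce(c(granges(genes), granges(promoters)),
                     ignore.strand = TRUE)
  nMk <- config@nFixedDifferences
  mkPos <- integer(0); mkChr <- character(0)
  guard <- 0
  while (length(mkPos) < nMk && guard < 60) {
    guard <- guard + 1
    need <- nMk - length(mkPos)
    cand <- GRanges(sample(names(sizes), 2 * need + 20, TRUE),
                    IRanges(round(runif(2 * need + 20, 201, L - 200)),
                            width = 1))
    ok <- !overlapsAny(resize(cand, 401, fix = "center"), occupied,
                       ignore.strand = TRUE)
    cand <- cand[ok]
    if (length(cand)) {
      take <- head(cand, need)
      mkPos <- c(mkPos, start(take))
      mkChr <- c(mkChr, as.character(seqnames(take)))
      occupied <- reduce(c(occupied,
                           resize(granges(take), 401, fix = "center")))
    }
  }
  if (length(mkPos) < nMk)
    stop("chromosome too short to place requested marker loci")
  markers <- GRanges(mkChr, IRanges(mkPos - 100L, mkPos + 99L))
  seqlevels(markers) <- names(sizes)
  seqlengths(markers) <- unname(sizes)
  arch <- rep(architectureClasses(), .countsByMix(nMk,
                                                  config@architectureMix))
  mcols(markers)$architecture <- sample(arch)
  mcols(markers)$effect_sign <- sample(c(-1, 1), nMk, TRUE)
  mcols(markers)$locus_id <- sprintf("m%05d", seq_len(nMk))
  names(markers) <- mcols(markers)$locus_id

  # --- islands: a fraction of promoters + background ------------------------
  cgiList <- list()
  if (any(mcols(genes)$promoter_cgi)) {
    ip <- promoters[mcols(genes)$promoter_cgi]
    iw <- pmin(config@islandLength, width(ip))
    # island abuts the TSS end of the promoter
    plus <- as.character(strand(ip)) == "+"
    st <- ifelse(plus, end(ip) - iw + 1L, start(ip))
    cgiList$promoter <- GRanges(seqnames(ip), IRanges(st, width = iw))
  }
  nBg <- round(config@islandRate * sum(sizes))
  if (nBg > 0) {
    placed <- GRanges(); blocked <- occupied
    guard <- 0
    while (length(placed) < nBg && guard < 100) {
      guard <- guard + 1
      need <- nBg - length(placed)
      bg <- GRanges(sample(names(sizes), 2 * need + 10, TRUE),
                    IRanges(round(runif(2 * need + 10, 1000,
                                        L - config@islandLength - 1000)),
                            width = config@islandLength))
      bg <- bg[!overlapsAny(bg, blocked, ignore.strand = TRUE)]
      bg <- head(bg[countOverlaps(bg, bg) == 1], need)  # drop batch collisions
      if (length(bg)) {
        placed <- c(placed, bg)
        blocked <- reduce(c(blocked, granges(bg)))
      }
    }
    if (length(placed) < nBg)
      stop("chromosome too short to place requested islands")
    cgiList$background <- placed
  }
  cgis <- if (length(cgiList)) sort(do.call(c, unname(cgiList)))
          else GRanges()
  if (length(cgis)) {
    seqlevels(cgis) <- names(sizes); seqlengths(cgis) <- unname(sizes)
    cgis <- reduce(cgis, ignore.strand = TRUE)
  }

  # --- CpG positions --------------------------------------------------------
  cpgList <- vector("list", nChr)
  for (c_ in seq_len(nChr)) {
    chr <- names(sizes)[c_]
    pos <- .cpgRun(0L, L - 1L, config@cpgBackgroundRate)
    dense <- suppressWarnings(c(cgis[seqnames(cgis) == chr],
               granges(markers[seqnames(markers) == chr])))
    for (i in seq_along(dense))
      pos <- c(pos, .cpgRun(start(dense)[i], end(dense)[i] - 1L,
                            1 / config@islandSpacing))
    pos <- sort(unique(pos))
    pos <- pos[pos >= 1 & pos <= L - 1]
    cpgList[[c_]] <- GRanges(chr, IRanges(pos, width = 1))
  }
  cpgs <- do.call(c, cpgList)
  seqlevels(cpgs) <- names(sizes)
  seqlengths(cpgs) <- unname(sizes)

  # --- TE / CNEE annotation sets --------------------------------------------
  nTe <- round(sum(sizes) / 2e4)
  tes <- GRanges(sample(names(sizes), nTe, TRUE),
                 IRanges(round(runif(nTe, 1, L - 600)), width = 500))
  tes <- sort(tes[!overlapsAny(tes, occupied, ignore.strand = TRUE)])
  nCn <- round(sum(sizes) / 2e4)
  cnees <- GRanges(sample(names(sizes), nCn, TRUE),
                   IRanges(round(runif(nCn, 1, L - 300)), width = 200))
  cnees <- sort(cnees[!overlapsAny(cnees, tes, ignore.strand = TRUE)])
  seqlevels(tes) <- seqlevels(cnees) <- names(sizes)
  seqlengths(tes) <- seqlengths(cnees) <- unname(sizes)

  # --- Fst track coupled to per-gene methylation divergence ------------------
  nBins <- 199L
  shift <- abs(mcols(genes)$species_shift)
  fst <- data.frame(
    gene_id = rep(mcols(genes)$gene_id, each = nBins),
    bin = rep(seq_len(nBins), length(genes)),
    fst_cpg = plogis(-2 + config@fstCoupling * rep(shift, each = nBins) +
                       rnorm(nBins * length(genes), 0, 0.3)),
    fst_noncpg = plogis(-2 + 0.3 * config@fstCoupling *
                          rep(shift, each = nBins) +
                          rnorm(nBins * length(genes), 0, 0.3)))

  new("SyntheticDataset", chromSizes = sizes, cpgSites = cpgs,
      genes = genes, promoters = promoters, cgis = cgis, tes = tes,
      cnees = cnees, markers = markers, fst = fst, config = config)
}

.siteEtas <- function(dataset, config) {
  # per-site logit-scale baselines for COL, PIE, hybrid COL/PIE alleles
  # (tissue effects are added later as scalars)
  cpgs <- dataset@cpgSites
  n <- length(cpgs)
  inIsland <- overlapsAny(cpgs, dataset@cgis, ignore.strand = TRUE)
  # per-site heterogeneity: beta-distributed site means preserve the
  # configured genome-wide mean exactly when all effects are zero
  kappa <- 8
  drawBase <- function(k, lvl)
    qlogis(pmin(0.995, pmax(0.005, rbeta(k, lvl * kappa, (1 - lvl) * kappa))))
  base <- drawBase(n, config@baseLevel)
  base[inIsland] <- drawBase(sum(inIsland), config@islandLevel)
  etaC <- base + config@speciesEffect / 2
  etaP <- base - config@speciesEffect / 2
  # gene bodies: per-gene species shift
  hitG <- findOverlaps(cpgs, dataset@genes, ignore.strand = TRUE)
  if (length(hitG)) {
    sh <- mcols(dataset@genes)$species_shift[subjectHits(hitG)]
    q <- queryHits(hitG)
    etaC[q] <- base[q] + sh / 2
    etaP[q] <- base[q] - sh / 2
  }
  etaHC <- etaC
  etaHP <- etaP
  # promoters: inheritance-mode group levels
  hitP <- findOverlaps(cpgs, dataset@promoters, ignore.strand = TRUE)
  if (length(hitP)) {
    q <- queryHits(hitP); gi <- subjectHits(hitP)
    modes <- mcols(dataset@genes)$inheritance[gi]
    cgi <- mcols(dataset@genes)$promoter_cgi[gi]
    siteNoise <- rnorm(length(q), 0, 0.15)
    lv <- t(vapply(modes, inheritanceMeans, numeric(3),
                   effect = config@inheritanceEffect))
    # conserved promoters keep a gene-specific base level so expression
    # coupling has variance to act on
    consBase <- ifelse(cgi, 0.12, 0.72)
    isCons <- modes == "conserved"
    gb <- stats::setNames(
      pmin(0.95, pmax(0.05, consBase +
                        rnorm(length(dataset@genes), 0, 0.12)[gi])), NULL)
    for (col in 1:3) lv[isCons, col] <- gb[isCons]
    etaC[q] <- qlogis(lv[, "COL"]) + siteNoise
    etaP[q] <- qlogis(lv[, "PIE"]) + siteNoise
    etaHC[q] <- qlogis(lv[, "HYB"]) + siteNoise
    etaHP[q] <- qlogis(lv[, "HYB"]) + siteNoise
  }
  # marker windows: architecture group levels
  hitM <- findOverlaps(cpgs, dataset@markers, ignore.strand = TRUE)
  if (length(hitM)) {
    q <- queryHits(hitM); mi <- subjectHits(hitM)
    siteNoise <- rnorm(length(q), 0, 0.1)
    mk <- dataset@markers
    am <- t(mapply(architectureMeans,
                   class = mcols(mk)$architecture[mi],
                   sgn = mcols(mk)$effect_sign[mi],
                   MoreArgs = list(effect = config@markerEffect)))
    etaC[q] <- qlogis(am[, "PC"]) + siteNoise
    etaP[q] <- qlogis(am[, "PP"]) + siteNoise
    etaHC[q] <- qlogis(am[, "HC"]) + siteNoise
    etaHP[q] <- qlogis(am[, "HP"]) + siteNoise
  }
  list(COL = etaC, PIE = etaP, HC = etaHC, HP = etaHP)
}

.betaBinom <- function(cov, mu, phi) {
  p <- rbeta(length(mu), mu * phi, (1 - mu) * phi)
  rbinom(length(cov), cov, p)
}

#' Simulate per-sample methylation counts
#'
#' Coverage per site and sample is negative binomial
#' (\code{coverageMean}, \code{coverageDispersion}); the methylated count is
#' beta-binomial with mean \code{plogis(baseline + tissue effect)} and
#' precision \code{betaPrecision}. Parental samples draw from their species'
#' allele baseline; hybrid bulk samples draw from the 50:50 allele mixture;
#' hybrid allele-resolved counts at marker-window CpGs are emitted separately
#' with roughly half the bulk coverage per allele. RNG streams are derived
#' per sample from the master seed so the output is reproducible and
#' insensitive to column evaluation order.
#'
#' @param dataset A \linkS4class{SyntheticDataset}.
#' @param config the generating \linkS4class{SimConfig}.
#' @return List with \code{bulk} (a \linkS4class{MethylationSet}, all
#'   individuals x tissues) and \code{hybridAlleles} (a
#'   \linkS4class{MethylationSet} over marker-window CpGs, one column per
#'   hybrid x tissue x allele, colData columns \code{sample_id},
#'   \code{tissue}, \code{allele}).
#' @export
simulateMethylationCounts <- function(dataset, config) {
  set.seed(config@seed + 1L)
  etas <- .siteEtas(dataset, config)
  cpgs <- dataset@cpgSites
  n <- length(cpgs)
  tissues <- config@tissues
  inds <- c(sprintf("COL%02d", seq_len(config@nCol)),
            sprintf("PIE%02d", seq_len(config@nPie)),
            sprintf("HYB%02d", seq_len(config@nHyb)))
  spp <- c(rep("COL", config@nCol), rep("PIE", config@nPie),
           rep("HYB", config@nHyb))
  samples <- as.vector(outer(inds, tissues, paste, sep = "_"))
  sampSpecies <- rep(spp, length(tissues))
  sampTissue <- rep(tissues, each = length(inds))
  sampInd <- rep(inds, length(tissues))
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(samples) + config@nHyb * length(tissues) * 2L)
  meth <- matrix(0L, n, length(samples))
  unmeth <- matrix(0L, n, length(samples))
  colnames(meth) <- colnames(unmeth) <- samples
  muHyb <- (plogis(etas$HC) + plogis(etas$HP)) / 2
  etaHybMix <- qlogis(pmin(0.999, pmax(0.001, muHyb)))
  for (j in seq_along(samples)) {
    set.seed(seeds[j])
    te <- config@tissueEffects[sampTissue[j]]
    eta <- switch(sampSpecies[j], COL = etas$COL, PIE = etas$PIE,
                  HYB = etaHybMix)
    mu <- plogis(eta + te)
    cov <- rnbinom(n, mu = config@coverageMean,
                   size = config@coverageDispersion)
    m <- .betaBinom(cov, mu, config@betaPrecision)
    meth[, j] <- m
    unmeth[, j] <- cov - m
  }
  bulk <- MethylationSet(meth, unmeth, cpgs,
                         data.frame(sample_id = sampInd,
                                    species = sampSpecies,
                                    tissue = sampTissue,
                                    row.names = samples))
  # hybrid allele-resolved counts at marker-window CpGs
  inWin <- overlapsAny(cpgs, dataset@markers, ignore.strand = TRUE)
  mkSites <- cpgs[inWin]
  hybInds <- inds[spp == "HYB"]
  cols <- expand.grid(ind = hybInds, tissue = tissues,
                      allele = c("COL", "PIE"),
                      stringsAsFactors = FALSE)
  am <- matrix(0L, sum(inWin), nrow(cols))
  au <- matrix(0L, sum(inWin), nrow(cols))
  colnames(am) <- colnames(au) <-
    paste(cols$ind, cols$tissue, cols$allele, sep = "_")
  for (j in seq_len(nrow(cols))) {
    set.seed(seeds[length(samples) + j])
    te <- config@tissueEffects[cols$tissue[j]]
    eta <- if (cols$allele[j] == "COL") etas$HC[inWin] else etas$HP[inWin]
    mu <- plogis(eta + te)
    cov <- rnbinom(sum(inWin), mu = config@coverageMean / 2,
                   size = config@coverageDispersion)
    m <- .betaBinom(cov, mu, config@betaPrecision)
    am[, j] <- m
    au[, j] <- cov - m
  }
  hybridAlleles <- MethylationSet(
    am, au, mkSites,
    data.frame(sample_id = cols$ind, tissue = cols$tissue,
               allele = cols$allele, species = "HYB",
               row.names = colnames(am)))
  list(bulk = bulk, hybridAlleles = hybridAlleles)
}

#' Simulate expression with promoter-methylation coupling
#'
#' Per-gene negative-binomial counts whose log2 mean is a gene baseline plus
#' \code{expressionCoupling} times the sample's centred promoter methylation
#' level, plus a species shift of \code{deEffect} log2 units for truth-DE
#' genes (hybrids at the midparent). A coupling of 0 decouples expression
#' from methylation entirely.
#'
#' @param dataset A \linkS4class{SyntheticDataset}.
#' @param bulk the bulk \linkS4class{MethylationSet} from
#'   \code{\link{simulateMethylationCounts}}.
#' @param config the generating \linkS4class{SimConfig}.
#' @return List with \code{counts} (genes x samples), \code{promoterLevels}
#'   (genes x samples), and \code{de} (named logical truth labels).
#' @export
simulateExpression <- function(dataset, bulk, config) {
  set.seed(config@seed + 2L)
  genes <- dataset@genes
  prom <- dataset@promoters
  promLev <- regionLevelMatrix(bulk, prom, minCov = 1, maxCov = Inf)
  rownames(promLev) <- mcols(genes)$gene_id
  base <- rnorm(length(genes), 7, 1.5)
  de <- mcols(genes)$de
  sp <- colData(bulk)$species
  shift <- ifelse(sp == "COL", 1, ifelse(sp == "PIE", -1, 0)) *
    config@deEffect / 2
  counts <- matrix(0L, length(genes), ncol(bulk),
                   dimnames = list(mcols(genes)$gene_id, colnames(bulk)))
  pl <- promLev
  pl[is.na(pl)] <- mean(promLev, na.rm = TRUE)
  for (j in seq_len(ncol(bulk))) {
    l2 <- base + config@expressionCoupling * (pl[, j] - 0.5) + de * shift[j]
    counts[, j] <- rnbinom(length(genes), mu = 2^l2, size = 10)
  }
  list(counts = counts, promoterLevels = promLev,
       de = setNames(de, mcols(genes)$gene_id))
}

#' Simulate marker-locus methylation levels directly
#'
#' Focused generator for calibration work on the cis/trans machinery: for
#' \code{nPerClass} loci per architecture class it draws, per locus, per-site
#' beta-binomial counts for the four sample groups (parental COL/PIE, hybrid
#' COL/PIE alleles; \code{nRep} replicates, \code{nCpgs} CpGs per 200-bp
#' window) and returns the per-replicate region levels.
#'
#' @param nPerClass loci per architecture class.
#' @param classes architecture classes to include.
#' @param effect effect size on the proportion scale.
#' @param nRep replicates per group.
#' @param coverage mean coverage (negative binomial, size =
#'   \code{dispersion}).
#' @param dispersion negative-binomial size.
#' @param phi beta-binomial precision.
#' @param nCpgs CpGs per locus window.
#' @param base base methylation level.
#' @param randomSign random effect orientation per locus.
#' @return List of loci x replicate matrices \code{colP}, \code{pieP},
#'   \code{colH}, \code{pieH} plus \code{truth} (class labels) and
#'   \code{sign}.
#' @export
simulateMarkerLevels <- function(nPerClass = 500,
                                 classes = architectureClasses(),
                                 effect = 0.3, nRep = 3, coverage = 30,
                                 dispersion = 5, phi = 30, nCpgs = 8,
                                 base = 0.5, randomSign = TRUE) {
  nl <- nPerClass * length(classes)
  truth <- rep(classes, each = nPerClass)
  sgn <- if (randomSign) sample(c(-1, 1), nl, TRUE) else rep(1, nl)
  groups <- c("PC", "PP", "HC", "HP")
  out <- lapply(groups, function(g) matrix(NA_real_, nl, nRep))
  names(out) <- groups
  mus <- t(mapply(architectureMeans, class = truth, sgn = sgn,
                  MoreArgs = list(effect = effect, base = base)))
  for (g in groups) {
    mu <- mus[, g]
    for (r in seq_len(nRep)) {
      cov <- matrix(rnbinom(nl * nCpgs, mu = coverage, size = dispersion),
                    nl, nCpgs)
      p <- matrix(rbeta(nl * nCpgs, rep(mu, nCpgs) * phi,
                        rep(1 - mu, nCpgs) * phi), nl, nCpgs)
      m <- matrix(rbinom(nl * nCpgs, cov, p), nl, nCpgs)
      lev <- m / cov
      lev[cov == 0] <- NA
      out[[g]][, r] <- rowMeans(lev, na.rm = TRUE)
    }
  }
  list(colP = out$PC, pieP = out$PP, colH = out$HC, pieH = out$HP,
       truth = truth, sign = sgn)
}

#' Write a simulated study to disk
#'
#' Emits the on-disk interface consumed by the command-line pipeline: one
#' Bismark coverage file per bulk sample (and per hybrid allele at marker
#' windows), BED6 files for truth CGIs, TEs, CNEEs, promoters (type in the
#' name field) and marker windows (architecture in the name field), a BED6
#' gene file with inheritance mode in the name field, chrom.sizes, a sample
#' sheet, the Fst track and the expression matrix with DE truth labels.
#'
#' @param dataset A \linkS4class{SyntheticDataset}.
#' @param sim output of \code{\link{simulateMethylationCounts}}.
#' @param expr output of \code{\link{simulateExpression}} (optional).
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeSimulatedStudy <- function(dataset, sim, expr = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeBismarkCovSet(sim$bulk, file.path(dir, "cov"))
  writeBismarkCovSet(sim$hybridAlleles, file.path(dir, "allele_cov"))
  writeChromSizes(dataset@chromSizes, file.path(dir, "chrom.sizes"))
  g <- granges(dataset@genes)
  mcols(g)$name <- paste(mcols(dataset@genes)$gene_id,
                         mcols(dataset@genes)$inheritance, sep = "|")
  writeBED(g, file.path(dir, "genes.bed"))
  p <- granges(dataset@promoters)
  mcols(p)$name <- paste(mcols(dataset@genes)$gene_id,
                         ifelse(mcols(dataset@genes)$promoter_cgi,
                                "CGI", "Other"), sep = "|")
  writeBED(p, file.path(dir, "promoters.bed"))
  writeBED(dataset@cgis, file.path(dir, "cgis.bed"))
  writeBED(dataset@tes, file.path(dir, "tes.bed"))
  writeBED(dataset@cnees, file.path(dir, "cnees.bed"))
  m <- granges(dataset@markers)
  mcols(m)$name <- paste(mcols(dataset@markers)$locus_id,
                         mcols(dataset@markers)$architecture, sep = "|")
  writeBED(m, file.path(dir, "markers.bed"))
  cp <- granges(dataset@cpgSites)
  writeBED(cp, file.path(dir, "cpgs.bed"))
  write.table(as.data.frame(colData(sim$bulk)),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE)
  write.table(as.data.frame(colData(sim$hybridAlleles)),
              file.path(dir, "allele_samples.tsv"), sep = "\t",
              quote = FALSE)
  write.table(dataset@fst, file.path(dir, "fst.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(expr)) {
    write.table(expr$counts, file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE)
    write.table(data.frame(gene_id = names(expr$de), de = expr$de),
                file.path(dir, "de_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
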