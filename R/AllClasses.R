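#' MethylationSet: per-CpG bisulfite counts across samples
#'
#' A \linkS4class{RangedSummarizedExperiment} with two integer assays,
#' \code{meth} and \code{unmeth}, holding strand-collapsed methylated and
#' unmethylated read counts per CpG site (rows) and sample (columns).
#' \code{rowRanges} are width-1 \link[GenomicRanges]{GRanges} keyed to the C of
#' the plus-strand CpG; \code{colData} carries at least \code{species}
#' (COL/PIE/HYB) and \code{tissue}.
#'
#' @slot .Data inherited RangedSummarizedExperiment structure.
#' @aliases MethylationSet-class
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "RangedSummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!all(c("meth", "unmeth") %in% an))
    msg <- c(msg, "assays 'meth' and 'unmeth' are required")
  else {
    m <- assay(object, "meth"); u <- assay(object, "unmeth")
    if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationSet
#'
#' @param meth,unmeth integer matrices (sites x samples) of methylated and
#'   unmethylated read counts, strand-collapsed.
#' @param sites \link[GenomicRanges]{GRanges} of CpG positions (width 1),
#'   one per row of the count matrices.
#' @param sampleData data.frame or DataFrame of per-sample metadata with
#'   columns \code{species} and \code{tissue}; rownames become sample names.
#' @return A \linkS4class{MethylationSet}.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1))
#' ms <- MethylationSet(meth = cbind(s1 = c(3L, 5L)),
#'                      unmeth = cbind(s1 = c(7L, 5L)),
#'                      sites = sites,
#'                      sampleData = data.frame(species = "COL", tissue = "brain",
#'                                              row.names = "s1"))
#' siteLevels(ms)
#' @export
MethylationSet <- function(meth, unmeth, sites, sampleData = NULL) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  stopifnot(identical(dim(meth), dim(unmeth)),
            length(sites) == nrow(meth))
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(meth))
  se <- SummarizedExperiment(
    assays = list(meth = meth, unmeth = unmeth),
    rowRanges = sites,
    colData = as(sampleData, "DataFrame"))
  new("MethylationSet", se)
}

#' Accessors for MethylationSet assays
#'
#' \code{methCounts} and \code{unmethCounts} return the raw count matrices,
#' \code{totalCounts} their sum (per-site coverage), and \code{siteLevels} the
#' per-site methylation proportion \eqn{x_m / (x_m + x_u)}, \code{NA} where
#' coverage is zero (an undefined level is missing, never 0).
#'
#' @param object A \linkS4class{MethylationSet}.
#' @return A numeric matrix, sites x samples.
#' @rdname methylationset-accessors
#' @export
methCounts <- function(object) assay(object, "meth")

#' @rdname methylationset-accessors
#' @export
unmethCounts <- function(object) assay(object, "unmeth")

#' @rdname methylationset-accessors
#' @export
totalCounts <- function(object) assay(object, "meth") + assay(object, "unmeth")

#' @rdname methylationset-accessors
#' @export
siteLevels <- function(object) {
  m <- assay(object, "meth")
  tot <- m + assay(object, "unmeth")
  lev <- m / tot
  lev[tot == 0] <- NA_real_
  lev
}

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet with", nrow(object), "CpG sites and",
      ncol(object), "samples\n")
  cd <- colData(object)
  if ("species" %in% colnames(cd))
    cat("  species:", paste(sprintf("%s=%d", names(table(cd$species)),
                                    table(cd$species)), collapse = " "), "\n")
  if ("tissue" %in% colnames(cd))
    cat("  tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
  cov <- totalCounts(object)
  cat("  median coverage:", stats::median(cov[cov > 0]), "\n")
})

#' SimConfig: parameters of the synthetic two-species + hybrid design
#'
#' Holds every tunable of the generator: genome geometry (chromosomes, CpG
#' background rate, CpG-island rate and length), gene and marker counts, the
#' sampling design (6 COL + 5 PIE + 3 HYB individuals across five tissues by
#' default, mirroring the study system), the count-noise model
#' (negative-binomial coverage, beta-binomial methylation with precision
#' \code{betaPrecision}), logit-scale tissue/species effects, the
#' architecture mix over the six cis/trans classes at marker loci, and the
#' inheritance mix over the six promoter inheritance modes.
#'
#' @slot nChroms,chromLength integer; genome geometry (bp).
#' @slot cpgBackgroundRate numeric; background CpGs per bp.
#' @slot islandRate numeric; expected CpG islands per bp.
#' @slot islandLength,islandSpacing integer; island span (bp) and within-island
#'   CpG spacing mean (bp).
#' @slot nGenes,nFixedDifferences integer counts.
#' @slot nCol,nPie,nHyb integer; individuals per group.
#' @slot tissues character; tissue panel.
#' @slot coverageMean,coverageDispersion numeric; negative-binomial coverage.
#' @slot betaPrecision numeric; beta-binomial precision (larger = less
#'   overdispersion).
#' @slot baseLevel numeric; genome background methylation proportion.
#' @slot islandLevel numeric; CpG-island methylation proportion.
#' @slot tissueEffects named numeric; logit-scale tissue shifts.
#' @slot speciesEffect numeric; logit-scale COL-PIE shift at non-marker sites.
#' @slot markerEffect numeric; architecture effect size on the proportion scale.
#' @slot architectureMix,inheritanceMix named numeric; class proportions
#'   (sum to 1).
#' @slot inheritanceEffect numeric; parental promoter difference on the
#'   proportion scale.
#' @slot cgiPromoterFraction numeric; fraction of promoters seeded with an
#'   island.
#' @slot expressionCoupling numeric; slope of log expression on promoter
#'   methylation (negative = repression).
#' @slot deFraction,deEffect numeric; fraction of truth-DE genes and their
#'   log2 species shift.
#' @slot fstCoupling numeric; coupling of CpG-context Fst to the per-gene
#'   species methylation shift.
#' @slot seed integer; master seed.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nChroms = "integer", chromLength = "integer",
  cpgBackgroundRate = "numeric",
  islandRate = "numeric", islandLength = "integer", islandSpacing = "integer",
  nGenes = "integer", nFixedDifferences = "integer",
  nCol = "integer", nPie = "integer", nHyb = "integer",
  tissues = "character",
  coverageMean = "numeric", coverageDispersion = "numeric",
  betaPrecision = "numeric",
  baseLevel = "numeric", islandLevel = "numeric",
  tissueEffects = "numeric", speciesEffect = "numeric",
  markerEffect = "numeric",
  architectureMix = "numeric", inheritanceMix = "numeric",
  inheritanceEffect = "numeric",
  cgiPromoterFraction = "numeric",
  expressionCoupling = "numeric", deFraction = "numeric", deEffect = "numeric",
  fstCoupling = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (abs(sum(object@architectureMix) - 1) > 1e-9)
    msg <- c(msg, "architectureMix must sum to 1")
  if (abs(sum(object@inheritanceMix) - 1) > 1e-9)
    msg <- c(msg, "inheritanceMix must sum to 1")
  if (!all(names(object@architectureMix) == architectureClasses()))
    msg <- c(msg, "architectureMix names must be the six architecture classes")
  if (!all(names(object@inheritanceMix) == inheritanceModes()))
    msg <- c(msg, "inheritanceMix names must be the six inheritance modes")
  pos <- c(nChroms = object@nChroms, chromLength = object@chromLength,
           nGenes = object@nGenes, nFixedDifferences = object@nFixedDifferences,
           nCol = object@nCol, nPie = object@nPie, nHyb = object@nHyb)
  if (any(pos <= 0)) msg <- c(msg, "counts and lengths must be positive")
  if (object@cpgBackgroundRate <= 0 || object@cpgBackgroundRate >= 1)
    msg <- c(msg, "cpgBackgroundRate must be in (0,1)")
  if (any(object@architectureMix < 0) || any(object@inheritanceMix < 0))
    msg <- c(msg, "mix proportions must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a simulation configuration
#'
#' Defaults encode the emulated study design: 2 chromosomes of 1 Mb, five
#' tissues, 6 COL + 5 PIE + 3 HYB individuals, 30x mean coverage, effect size
#' 0.3 on the proportion scale at marker loci and promoters.
#'
#' @param nChroms,chromLength genome geometry.
#' @param cpgBackgroundRate background CpG density (CpGs per bp).
#' @param islandRate expected islands per bp (0 disables islands).
#' @param islandLength,islandSpacing island span and in-island spacing (bp).
#' @param nGenes,nFixedDifferences number of genes / marker loci (total).
#' @param nCol,nPie,nHyb individuals per group.
#' @param tissues tissue panel.
#' @param coverageMean,coverageDispersion negative-binomial coverage mean and
#'   size.
#' @param betaPrecision beta-binomial precision phi.
#' @param baseLevel,islandLevel background and island methylation proportions.
#' @param tissueEffects named logit-scale shifts, one per tissue.
#' @param speciesEffect logit-scale COL-vs-PIE shift at non-marker background.
#' @param markerEffect architecture effect size, proportion scale.
#' @param architectureMix,inheritanceMix named class proportions (sum 1).
#' @param inheritanceEffect parental promoter difference, proportion scale.
#' @param cgiPromoterFraction fraction of promoters seeded with a CpG island.
#' @param expressionCoupling slope of log-mean expression on promoter
#'   methylation.
#' @param deFraction,deEffect truth-DE gene fraction and log2 fold shift.
#' @param fstCoupling coupling of CpG Fst to per-gene methylation divergence.
#' @param seed master RNG seed.
#' @return A validated \linkS4class{SimConfig}.
#' @export
SimConfig <- function(nChroms = 2L, chromLength = 1000000L,
                      cpgBackgroundRate = 0.01,
                      islandRate = 2e-05, islandLength = 600L,
                      islandSpacing = 8L,
                      nGenes = 100L, nFixedDifferences = 240L,
                      nCol = 6L, nPie = 5L, nHyb = 3L,
                      tissues = hymethTissues(),
                      coverageMean = 30, coverageDispersion = 5,
                      betaPrecision = 30,
                      baseLevel = 0.8, islandLevel = 0.1,
                      tissueEffects = c(brain = 0.8, heart = 0,
                                        kidney = -0.3, liver = 0.3,
                                        testis = -0.8),
                      speciesEffect = 0.15,
                      markerEffect = 0.3,
                      architectureMix = c(conserved = 0.5, cis = 0.15,
                                          trans = 0.15, `cis+trans` = 0.08,
                                          cisxtrans = 0.07,
                                          compensatory = 0.05),
                      inheritanceMix = c(conserved = 0.5, additive = 0.2,
                                         collared_dominant = 0.1,
                                         pied_dominant = 0.1,
                                         overdominant = 0.05,
                                         underdominant = 0.05),
                      inheritanceEffect = 0.3,
                      cgiPromoterFraction = 0.6,
                      expressionCoupling = -3,
                      deFraction = 0.1, deEffect = 1,
                      fstCoupling = 1.5,
                      seed = 1L) {
  tissueEffects <- tissueEffects[tissues]
  names(tissueEffects) <- tissues
  tissueEffects[is.na(tissueEffects)] <- 0
  new("SimConfig",
      nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
      cpgBackgroundRate = cpgBackgroundRate,
      islandRate = islandRate, islandLength = as.integer(islandLength),
      islandSpacing = as.integer(islandSpacing),
      nGenes = as.integer(nGenes),
      nFixedDifferences = as.integer(nFixedDifferences),
      nCol = as.integer(nCol), nPie = as.integer(nPie), nHyb = as.integer(nHyb),
      tissues = tissues,
      coverageMean = coverageMean, coverageDispersion = coverageDispersion,
      betaPrecision = betaPrecision,
      baseLevel = baseLevel, islandLevel = islandLevel,
      tissueEffects = tissueEffects, speciesEffect = speciesEffect,
      markerEffect = markerEffect,
      architectureMix = architectureMix[architectureClasses()],
      inheritanceMix = inheritanceMix[inheritanceModes()],
      inheritanceEffect = inheritanceEffect,
      cgiPromoterFraction = cgiPromoterFraction,
      expressionCoupling = expressionCoupling,
      deFraction = deFraction, deEffect = deEffect,
      fstCoupling = fstCoupling,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChroms, "x", object@chromLength, "bp;",
      object@nGenes, "genes;", object@nFixedDifferences, "marker loci;",
      "samples COL/PIE/HYB =", object@nCol, object@nPie, object@nHyb,
      "x", length(object@tissues), "tissues; seed", object@seed, "\n")
})

#' SyntheticDataset: genome, annotations and truth labels
#'
#' Output of \code{\link{simulateGenome}}: chromosome sizes, CpG positions,
#' non-overlapping gene models with strand and derived promoters, truth CpG
#' islands, TE and CNEE interval sets, fixed-difference marker loci with their
#' true architecture class, per-gene true inheritance mode and DE status, and
#' a per-gene-bin Fst track.
#'
#' @slot chromSizes named integer vector of chromosome lengths.
#' @slot cpgSites width-1 GRanges of CpG positions.
#' @slot genes GRanges with mcols gene_id, strand, inheritance, promoter_cgi,
#'   de (logical), promoter_base, species_shift.
#' @slot promoters GRanges (2 kb upstream of TSS, strand aware, trimmed).
#' @slot cgis,tes,cnees GRanges truth annotation sets.
#' @slot markers GRanges (200 bp windows) with mcols architecture, effect.
#' @slot fst data.frame with columns gene_id, bin, fst_cpg, fst_noncpg.
#' @slot config the generating \linkS4class{SimConfig}.
#' @aliases SyntheticDataset-class
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
  chromSizes = "integer", cpgSites = "GRanges", genes = "GRanges",
  promoters = "GRanges", cgis = "GRanges", tes = "GRanges",
  cnees = "GRanges", markers = "GRanges", fst = "data.frame",
  config = "SimConfig"))

setValidity("SyntheticDataset", function(object) {
  msg <- NULL
  sz <- object@chromSizes
  inBounds <- function(gr) {
    length(gr) == 0 ||
      all(start(gr) >= 1 & end(gr) <= sz[as.character(seqnames(gr))])
  }
  for (nm in c("cpgSites", "genes", "promoters", "cgis", "tes", "cnees",
               "markers")) {
    if (!inBounds(slot(object, nm)))
      msg <- c(msg, paste0(nm, " extends beyond chromosome bounds"))
  }
  mk <- object@markers
  if (length(mk) &&
      any(start(mk) < 1 | end(mk) > sz[as.character(seqnames(mk))]))
    msg <- c(msg, "marker windows must lie >= 100 bp from chromosome ends")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@chromSizes), "chromosomes,",
      length(object@cpgSites), "CpGs,", length(object@genes), "genes,",
      length(object@cgis), "truth CGIs,", length(object@markers),
      "marker loci\n")
})

#' Accessors for SyntheticDataset slots
#'
#' @param object A \linkS4class{SyntheticDataset}.
#' @return The requested component (named integer vector, GRanges, data.frame
#'   or SimConfig).
#' @rdname syntheticdataset-accessors
#' @export
chromSizes <- function(object) object@chromSizes

#' @rdname syntheticdataset-accessors
#' @export
cpgSites <- function(object) object@cpgSites

#' @rdname syntheticdataset-accessors
#' @export
geneModels <- function(object) object@genes

#' @rdname syntheticdataset-accessors
#' @export
promoterSet <- function(object) object@promoters

#' @rdname syntheticdataset-accessors
#' @export
truthCGIs <- function(object) object@cgis

#' @rdname syntheticdataset-accessors
#' @export
markerLoci <- function(object) object@markers

#' @rdname syntheticdataset-accessors
#' @export
fstTrack <- function(object) object@fst

#' @rdname syntheticdataset-accessors
#' @export
simConfig <- function(object) object@config
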