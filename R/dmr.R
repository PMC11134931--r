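#' Kernel-smoothed per-CpG group mean difference
#'
#' Nadaraya-Watson smoother with a triangular kernel over genomic position,
#' applied per chromosome to the per-CpG difference of group mean methylation
#' levels. The smoother stands in for a local-likelihood fit: the DMR
#' definition downstream only consumes a smoothed methylation difference.
#'
#' @param pos integer positions (one chromosome, sorted).
#' @param diffs per-CpG raw differences (NA allowed; ignored as neighbours).
#' @param bandwidth half-width of the triangular kernel in bp.
#' @return Smoothed differences, NA where no neighbour has data.
#' @export
smoothDiff <- function(pos, diffs, bandwidth = 500) {
  n <- length(pos)
  out <- rep(NA_real_, n)
  ok <- which(!is.na(diffs))
  if (!length(ok)) return(out)
  p <- pos[ok]; d <- diffs[ok]
  lo <- findInterval(pos - bandwidth, p) + 1L   # first neighbour index
  hi <- findInterval(pos + bandwidth, p)        # last neighbour index
  for (i in seq_len(n)) {
    if (hi[i] < lo[i]) next
    j <- lo[i]:hi[i]
    w <- 1 - abs(p[j] - pos[i]) / bandwidth
    w[w < 0] <- 0
    if (sum(w) == 0) next
    out[i] <- sum(w * d[j]) / sum(w)
  }
  out
}

.groupMeanDiff <- function(ms, group1, group2, minCov = 2, minSamples = 2) {
  m <- methCounts(ms); tot <- totalCounts(ms)
  lev <- m / tot
  lev[tot == 0] <- NA
  g1 <- which(colnames(ms) %in% group1)
  g2 <- which(colnames(ms) %in% group2)
  if (length(g1) < minSamples || length(g2) < minSamples)
    stop("need at least ", minSamples, " samples per group")
  covOK1 <- rowSums(tot[, g1, drop = FALSE] >= minCov) >= minSamples
  covOK2 <- rowSums(tot[, g2, drop = FALSE] >= minCov) >= minSamples
  pass <- covOK1 & covOK2
  mean1 <- rowMeans(lev[, g1, drop = FALSE], na.rm = TRUE)
  mean2 <- rowMeans(lev[, g2, drop = FALSE], na.rm = TRUE)
  d <- mean1 - mean2
  d[!pass | is.nan(mean1) | is.nan(mean2)] <- NA
  list(diff = d, pass = pass)
}

#' Call differentially methylated regions between two sample groups
#'
#' Per-CpG group mean levels are computed after the coverage rule (a CpG is
#' used only where at least \code{minSamples} samples per group have coverage
#' >= \code{minCov}); their difference is kernel-smoothed along each
#' chromosome; candidate regions are maximal runs of consecutive CpGs (gaps
#' > \code{maxGap} bp break a run) whose smoothed difference lies beyond the
#' comparison-wide \code{quantiles} of the smoothed difference, one tail at a
#' time. Candidates are reported as DMRs when they span at least
#' \code{minCpgs} CpGs and their mean raw difference is at least
#' \code{minDiff} in absolute value. \code{mean_diff} is signed group1 -
#' group2 (positive = hypermethylated in group1).
#'
#' @param ms A \linkS4class{MethylationSet}.
#' @param group1,group2 character vectors of sample names.
#' @param quantiles lower/upper tail quantiles of the smoothed difference.
#' @param minCpgs minimum CpGs per DMR.
#' @param minDiff minimum absolute mean raw difference.
#' @param minCov,minSamples per-CpG coverage rule.
#' @param bandwidth smoother bandwidth (bp).
#' @param maxGap maximum intra-run CpG gap (bp).
#' @param candidates if TRUE, return pre-filter candidate runs (before the
#'   minCpgs/minDiff filters) instead of DMRs.
#' @return GRanges of DMRs with mcols \code{n_cpgs}, \code{mean_diff},
#'   \code{comparison}; empty (with a warning) if no CpG passes the coverage
#'   rule.
#' @export
callDMRs <- function(ms, group1, group2, quantiles = c(0.01, 0.99),
                     minCpgs = 3, minDiff = 0.1, minCov = 2, minSamples = 2,
                     bandwidth = 500, maxGap = 1000, candidates = FALSE) {
  gd <- .groupMeanDiff(ms, group1, group2, minCov, minSamples)
  if (!any(gd$pass)) {
    warning("no CpG passes the coverage rule")
    return(GRanges())
  }
  sites <- rowRanges(ms)
  ord <- order(seqnames(sites), start(sites))
  sites <- sites[ord]
  rawd <- gd$diff[ord]
  sm <- rep(NA_real_, length(sites))
  for (chr in as.character(unique(seqnames(sites)))) {
    ix <- which(as.character(seqnames(sites)) == chr)
    sm[ix] <- smoothDiff(start(sites)[ix], rawd[ix], bandwidth)
  }
  qs <- quantile(sm, quantiles, na.rm = TRUE, names = FALSE)
  out <- GRanges()
  for (tailSign in c(-1, 1)) {
    inTail <- if (tailSign < 0) !is.na(sm) & sm <= qs[1]
              else !is.na(sm) & sm >= qs[2]
    if (!any(inTail)) next
    idx <- which(inTail)
    chrv <- as.character(seqnames(sites))[idx]
    posv <- start(sites)[idx]
    newRun <- c(TRUE, chrv[-1] != chrv[-length(chrv)] |
                  diff(posv) > maxGap)
    runId <- cumsum(newRun)
    for (r in unique(runId)) {
      ix <- idx[runId == r]
      md <- mean(rawd[ix], na.rm = TRUE)
      gr <- GRanges(chrv[runId == r][1],
                    IRanges(min(posv[runId == r]),
                            max(posv[runId == r]) + 1L))
      mcols(gr)$n_cpgs <- length(ix)
      mcols(gr)$mean_diff <- md
      if (candidates || (length(ix) >= minCpgs && !is.na(md) &&
                         abs(md) >= minDiff))
        suppressWarnings(out <- c(out, gr))
    }
  }
  if (length(out))
    mcols(out)$comparison <- paste0(paste(group1, collapse = "+"), "-vs-",
                                    paste(group2, collapse = "+"))
  sort(out)
}

#' Classify tissue-specific DMRs
#'
#' Given the DMR sets of all pairwise tissue comparisons within one sample
#' group, a region of a focal tissue is a tissue-specific DMR (tsDMR) when it
#' has a partner with at least \code{minReciprocal} reciprocal overlap in all
#' comparisons of the focal tissue against each other tissue, and no such
#' partner in any comparison not involving the focal tissue.
#'
#' @param dmrSets named list of GRanges; names are "tissueA.tissueB" for each
#'   unordered tissue pair (all \code{choose(T,2)} pairs required).
#' @param tissues character vector of tissue names.
#' @param focal focal tissue.
#' @param minReciprocal minimum reciprocal overlap fraction.
#' @return GRanges of tsDMRs (regions drawn from the first focal comparison
#'   set) with mcol \code{focal_tissue}.
#' @export
classifyTissueSpecific <- function(dmrSets, tissues, focal,
                                   minReciprocal = 0.25) {
  pairKey <- function(a, b) {
    if (paste(a, b, sep = ".") %in% names(dmrSets)) paste(a, b, sep = ".")
    else paste(b, a, sep = ".")
  }
  others <- setdiff(tissues, focal)
  focalKeys <- vapply(others, function(o) pairKey(focal, o), "")
  allPairs <- t(utils::combn(tissues, 2))
  allKeys <- apply(allPairs, 1, function(p) pairKey(p[1], p[2]))
  if (!all(allKeys %in% names(dmrSets)))
    stop("missing comparison set(s): ",
         paste(setdiff(allKeys, names(dmrSets)), collapse = ", "))
  nonFocalKeys <- setdiff(allKeys, focalKeys)
  cand <- dmrSets[[focalKeys[1]]]
  if (length(cand) == 0) return(GRanges())
  ok <- rep(TRUE, length(cand))
  for (k in focalKeys[-1])
    ok <- ok & hasReciprocalPartner(cand, dmrSets[[k]], minReciprocal)
  for (k in nonFocalKeys)
    ok <- ok & !hasReciprocalPartner(cand, dmrSets[[k]], minReciprocal)
  res <- cand[ok]
  if (length(res)) mcols(res)$focal_tissue <- focal
  res
}

#' Directional bias of a DMR set
#'
#' Fraction of DMRs hypermethylated in group 1 (\code{mean_diff > 0}) and the
#' two-sided exact binomial p-value against the random expectation of 0.5.
#'
#' @param dmrs GRanges with mcol \code{mean_diff} (or a numeric vector of
#'   signed differences).
#' @return List with \code{freq_hyper}, \code{p}, \code{n}.
#' @examples
#' directionTest(c(rep(1, 70), rep(-1, 30)))  # freq 0.7, p ~ 7.9e-5
#' @export
directionTest <- function(dmrs) {
  d <- if (is(dmrs, "GRanges")) mcols(dmrs)$mean_diff else dmrs
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) return(list(freq_hyper = NA_real_, p = NA_real_, n = 0L))
  k <- sum(d > 0); n <- length(d)
  list(freq_hyper = k / n,
       p = binom.test(k, n, p = 0.5)$p.value,
       n = n)
}

#' Write DMRs as extended BED
#'
#' Columns: chrom, start (0-based), end, comparison, mean_diff, n_cpgs.
#'
#' @param dmrs GRanges from \code{\link{callDMRs}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeDMRs <- function(dmrs, path) {
  df <- data.frame(chrom = as.character(seqnames(dmrs)),
                   start = start(dmrs) - 1L, end = end(dmrs),
                   comparison = if (length(dmrs) &&
                                    !is.null(mcols(dmrs)$comparison))
                                  mcols(dmrs)$comparison else character(0),
                   mean_diff = mcols(dmrs)$mean_diff,
                   n_cpgs = mcols(dmrs)$n_cpgs)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
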