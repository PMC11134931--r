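#' Metagene profile bins
#'
#' Builds the 199-bin metagene coordinate system for a set of genes: 50
#' upstream bins of 100 bp covering the 5 kb upstream of the TSS (bin 1 is the
#' most distal), 99 gene-body rank bins, and 50 downstream bins of 100 bp
#' after the TTS. Gene bodies are split into 100-bp segments from the 5' end
#' (a shorter terminal segment is kept) and each segment is assigned the rank
#' \code{ceiling(99 * midpoint / geneLength)} of its midpoint, ties going to
#' the lower rank. All coordinates are strand-aware, so minus-strand upstream
#' bins lie at coordinates greater than the TSS. Genes shorter than 100 bp
#' are skipped with a warning.
#'
#' @param genes GRanges of gene bodies with strand and names or a
#'   \code{gene_id} mcol.
#' @param flank flanking span in bp (default 5000; 50 bins of 100 bp).
#' @param binWidth flank bin width in bp.
#' @param nRanks number of gene-body ranks.
#' @return GRanges of segments with mcols \code{gene_id}, \code{bin}
#'   (1..199) and \code{bin_class} (up/body/down). Flank bins extending
#'   beyond a chromosome are dropped.
#' @export
profileBins <- function(genes, flank = 5000, binWidth = 100, nRanks = 99) {
  ids <- if (!is.null(mcols(genes)$gene_id)) mcols(genes)$gene_id
         else if (!is.null(names(genes))) names(genes)
         else as.character(seq_along(genes))
  short <- width(genes) < binWidth
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", binWidth, " bp skipped")
    genes <- genes[!short]; ids <- ids[!short]
  }
  if (length(genes) == 0) return(GRanges())
  nF <- flank %/% binWidth
  pieces <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    chr <- as.character(seqnames(g))
    minus <- as.character(strand(g)) == "-"
    len <- width(g)
    # gene-body segments from the 5' end
    off <- seq(0L, len - 1L, by = binWidth)
    segW <- pmin(binWidth, len - off)
    midRel <- off + (segW + 1) / 2           # 1-based relative midpoint
    rank <- pmin(nRanks, pmax(1L, as.integer(ceiling(nRanks * midRel / len))))
    if (minus) {
      bodyStart <- end(g) - off - segW + 1L
    } else {
      bodyStart <- start(g) + off
    }
    body <- GRanges(chr, IRanges(bodyStart, width = segW),
                    gene_id = ids[i], bin = nF + rank, bin_class = "body")
    # flanks
    fOff <- seq_len(nF) * binWidth
    if (!minus) {
      upStart <- start(g) - rev(fOff)          # bin 1 most distal
      dnStart <- end(g) + 1L + (seq_len(nF) - 1L) * binWidth
    } else {
      upStart <- end(g) + rev(seq_len(nF) - 1L) * binWidth + 1L  # bin 1 distal
      dnStart <- start(g) - seq_len(nF) * binWidth
    }
    up <- GRanges(chr, IRanges(upStart, width = binWidth),
                  gene_id = ids[i], bin = seq_len(nF), bin_class = "up")
    dn <- GRanges(chr, IRanges(dnStart, width = binWidth),
                  gene_id = ids[i], bin = nF + nRanks + seq_len(nF),
                  bin_class = "down")
    pieces[[i]] <- c(up, body, dn)
  }
  out <- do.call(c, pieces)
  sl <- seqlengths(genes)
  if (!all(is.na(sl))) {
    lim <- sl[as.character(seqnames(out))]
    keep <- start(out) >= 1 & (is.na(lim) | end(out) <= lim)
    out <- out[keep]
  } else {
    out <- out[start(out) >= 1]
  }
  out
}

#' Metagene methylation profile
#'
#' Per-bin methylation level for every gene: the value of a bin is the
#' coverage-filtered region level (unweighted mean of per-site proportions)
#' over the CpGs falling in that bin's segments. Missing bins stay NA.
#'
#' @param ms A \linkS4class{MethylationSet}.
#' @param genes GRanges of gene bodies (strand-aware; see
#'   \code{\link{profileBins}}).
#' @param samples sample names/indices to average; per-site proportions are
#'   pooled across the chosen samples' passing sites.
#' @param minCov,maxCov per-sample coverage filter on sites.
#' @param flank,binWidth,nRanks see \code{\link{profileBins}}.
#' @return Numeric matrix genes x 199 (rows named by gene, columns
#'   \code{up1..up50, body1..body99, down1..down50}).
#' @export
buildProfile <- function(ms, genes, samples = colnames(ms),
                         minCov = 6, maxCov = 200,
                         flank = 5000, binWidth = 100, nRanks = 99) {
  bins <- profileBins(genes, flank, binWidth, nRanks)
  sub <- ms[, samples, drop = FALSE]
  lev <- regionLevelMatrix(sub, bins, minCov, maxCov)
  nmat <- .regionNMatrix(sub, bins, minCov, maxCov)
  # average level across samples per segment (unweighted over samples),
  # then pool segments within (gene, bin) weighting by CpGs used
  segLev <- rowMeans(lev, na.rm = TRUE)
  segN <- rowMeans(nmat, na.rm = TRUE)
  segLev[is.nan(segLev)] <- NA
  ids <- if (!is.null(mcols(genes)$gene_id)) mcols(genes)$gene_id
         else if (!is.null(names(genes))) names(genes)
         else as.character(seq_along(genes))
  nF <- flank %/% binWidth
  nBins <- 2L * nF + nRanks
  out <- matrix(NA_real_, length(ids), nBins,
                dimnames = list(ids, c(paste0("up", seq_len(nF)),
                                       paste0("body", seq_len(nRanks)),
                                       paste0("down", seq_len(nF)))))
  ok <- !is.na(segLev) & segN > 0
  if (any(ok)) {
    key <- paste(mcols(bins)$gene_id[ok], mcols(bins)$bin[ok], sep = "\r")
    wsum <- rowsum(segLev[ok] * segN[ok], key)
    wn <- rowsum(segN[ok], key)
    parts <- strsplit(rownames(wsum), "\r", fixed = TRUE)
    gi <- match(vapply(parts, `[`, "", 1L), ids)
    bi <- as.integer(vapply(parts, `[`, "", 2L))
    out[cbind(gi, bi)] <- wsum / wn
  }
  out
}

.regionNMatrix <- function(ms, regions, minCov, maxCov) {
  hits <- findOverlaps(regions, rowRanges(ms))
  tot <- totalCounts(ms)
  keep <- tot >= minCov & tot <= maxCov
  out <- matrix(0, nrow = length(regions), ncol = ncol(ms))
  if (!length(hits)) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  for (j in seq_len(ncol(ms))) {
    k <- keep[s, j]
    if (!any(k)) next
    ns <- rowsum(rep(1, sum(k)), q[k])
    out[as.integer(rownames(ns)), j] <- ns
  }
  out
}

#' Correlation profile between bin methylation and expression
#'
#' Per metagene bin, the Spearman rank correlation across genes between the
#' bin's methylation level and a per-gene expression value. Bins with fewer
#' than \code{minGenes} complete pairs, or with all-tied values, return NA.
#'
#' @param profile genes x bins matrix from \code{\link{buildProfile}}.
#' @param expr named numeric vector of per-gene expression (matched by
#'   rowname).
#' @param minGenes minimum genes per reported bin.
#' @return data.frame with columns \code{bin}, \code{rho}, \code{n}.
#' @export
correlationProfile <- function(profile, expr, minGenes = 3) {
  e <- expr[rownames(profile)]
  rho <- rep(NA_real_, ncol(profile))
  n <- integer(ncol(profile))
  for (b in seq_len(ncol(profile))) {
    v <- profile[, b]
    ok <- !is.na(v) & !is.na(e)
    n[b] <- sum(ok)
    if (n[b] >= minGenes && sd(v[ok]) > 0 && sd(e[ok]) > 0)
      rho[b] <- cor(v[ok], e[ok], method = "spearman")
  }
  data.frame(bin = colnames(profile), rho = rho, n = n,
             row.names = NULL)
}

#' Per-gene methylation-expression correlation across tissues
#'
#' For each gene, the Spearman correlation between its methylation level and
#' expression over the tissue panel (one pair per tissue). Genes with fewer
#' than \code{minTissues} complete pairs, or all-tied values, return NA.
#'
#' @param methByTissue,exprByTissue genes x tissues matrices with matching
#'   dimnames.
#' @param minTissues minimum complete tissue pairs.
#' @return Named numeric vector of per-gene rho.
#' @export
crossTissueCorrelation <- function(methByTissue, exprByTissue,
                                   minTissues = 3) {
  stopifnot(identical(dim(methByTissue), dim(exprByTissue)))
  n <- nrow(methByTissue)
  rho <- setNames(rep(NA_real_, n), rownames(methByTissue))
  for (i in seq_len(n)) {
    m <- methByTissue[i, ]; e <- exprByTissue[i, ]
    ok <- !is.na(m) & !is.na(e)
    if (sum(ok) >= minTissues && sd(m[ok]) > 0 && sd(e[ok]) > 0)
      rho[i] <- cor(m[ok], e[ok], method = "spearman")
  }
  rho
}

#' Split genes into low/medium/high expression classes
#'
#' Exact 20/60/20 partition by expression rank (ties broken by order), the
#' standard L/M/H categorisation for profile plots.
#'
#' @param expr named numeric vector of per-gene expression.
#' @param probs lower and upper quantile cut points.
#' @return Factor with levels L, M, H, named by gene.
#' @export
expressionClasses <- function(expr, probs = c(0.2, 0.8)) {
  n <- length(expr)
  r <- rank(expr, ties.method = "first")
  nL <- floor(probs[1] * n)
  nH <- n - floor(probs[2] * n)
  cls <- rep("M", n)
  cls[r <= nL] <- "L"
  cls[r > n - nH] <- "H"
  factor(setNames(cls, names(expr)), levels = c("L", "M", "H"))
}

#' Write a profile matrix as long-format TSV
#'
#' Columns \code{gene}, \code{bin_index}, \code{bin_class} (up/body/down) and
#' \code{value}; missing bins are omitted.
#'
#' @param profile genes x bins matrix.
#' @param path output file.
#' @param flankBins number of flank bins on each side.
#' @return Invisibly, the path.
#' @export
writeProfileTSV <- function(profile, path, flankBins = 50) {
  nb <- ncol(profile)
  cls <- c(rep("up", flankBins), rep("body", nb - 2 * flankBins),
           rep("down", flankBins))
  idx <- which(!is.na(profile), arr.ind = TRUE)
  df <- data.frame(gene = rownames(profile)[idx[, 1]],
                   bin_index = idx[, 2], bin_class = cls[idx[, 2]],
                   value = profile[idx])
  df <- df[order(df$gene, df$bin_index), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
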