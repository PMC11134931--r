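#' Per-site methylation level
#'
#' The methylation level of one CpG is the proportion of methylated reads
#' mapping to both strands of the dinucleotide,
#' \eqn{x_m / (x_m + x_u)}. Sites with zero coverage have an undefined level
#' and return \code{NA} (never 0: 0 is a valid, fully unmethylated level).
#'
#' @param meth,unmeth non-negative counts of methylated and unmethylated reads
#'   (vectorised).
#' @return Numeric vector of proportions in [0,1], \code{NA} where coverage
#'   is zero.
#' @examples
#' siteLevel(c(5, 0, 3), c(5, 7, 7))  # 0.5 0.0 0.3
#' @export
siteLevel <- function(meth, unmeth) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  tot <- meth + unmeth
  out <- meth / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Region methylation level with coverage filter
#'
#' The level of a region spanning n CpGs is the unweighted mean of the per-site
#' proportions, restricted to sites whose total (strand-collapsed) coverage
#' lies within \code{[minCov, maxCov]} (defaults 6 and 200; the lower bound
#' limits sampling noise, the upper bound guards against collapsed repeats).
#'
#' @param meth,unmeth per-site counts over the region's CpGs.
#' @param minCov,maxCov inclusive coverage bounds for a site to be used.
#' @return List with \code{level} (NA if no site passes the filter, a distinct
#'   undefined state) and \code{n} (number of sites used).
#' @examples
#' regionLevel(c(5, 2), c(5, 8))   # (0.5 + 0.2)/2 = 0.35, n = 2
#' regionLevel(5, 0)               # coverage 5 < 6: undefined
#' @export
regionLevel <- function(meth, unmeth, minCov = 6, maxCov = 200) {
  if (length(meth) != length(unmeth))
    stop("meth and unmeth must have equal length")
  tot <- meth + unmeth
  keep <- !is.na(tot) & tot >= minCov & tot <= maxCov
  if (!any(keep)) return(list(level = NA_real_, n = 0L))
  list(level = mean(meth[keep] / tot[keep]), n = sum(keep))
}

#' Region levels for every sample of a MethylationSet over a set of regions
#'
#' Applies \code{\link{regionLevel}} per (region, sample): per-site proportions
#' are averaged unweighted over the CpGs of each region that pass the coverage
#' filter in that sample.
#'
#' @param ms A \linkS4class{MethylationSet}.
#' @param regions GRanges of regions.
#' @param minCov,maxCov coverage filter bounds.
#' @return Numeric matrix regions x samples of levels (NA = undefined).
#' @export
regionLevelMatrix <- function(ms, regions, minCov = 6, maxCov = 200) {
  hits <- findOverlaps(regions, rowRanges(ms))
  m <- methCounts(ms); u <- unmethCounts(ms)
  tot <- m + u
  lev <- m / tot
  keep <- tot >= minCov & tot <= maxCov
  lev[!keep | tot == 0] <- NA_real_
  out <- matrix(NA_real_, nrow = length(regions), ncol = ncol(ms),
                dimnames = list(names(regions), colnames(ms)))
  if (length(hits) == 0) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  for (j in seq_len(ncol(ms))) {
    v <- lev[s, j]
    ok <- !is.na(v)
    if (!any(ok)) next
    sums <- rowsum(v[ok], q[ok])
    ns <- rowsum(rep(1, sum(ok)), q[ok])
    out[as.integer(rownames(sums)), j] <- sums / ns
  }
  out
}

#' Absolute methylation differentiation between species
#'
#' Mdiff is the absolute difference of group mean methylation levels,
#' \eqn{|mean(COL) - mean(PIE)|}, for a region or profile bin. Undefined
#' (NA) levels are dropped; if either group has no defined level the result is
#' undefined.
#'
#' @param colLevels,pieLevels per-sample levels for the two species.
#' @return Absolute mean difference in [0,1], or NA.
#' @examples
#' mDiff(c(0.1, 0.3), c(0.9, 0.7))  # |0.2 - 0.8| = 0.6
#' @export
mDiff <- function(colLevels, pieLevels) {
  a <- colLevels[!is.na(colLevels)]
  b <- pieLevels[!is.na(pieLevels)]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  abs(mean(a) - mean(b))
}

#' Read and write Bismark coverage files
#'
#' Bismark coverage format is a 6-column TSV:
#' \code{chrom start end pct_meth count_meth count_unmeth} with 1-based
#' inclusive positions (start == end for a CpG). Positions are stored
#' unchanged in the returned 1-based GRanges; the companion 0-based BED
#' convention is handled by the BED I/O helpers.
#'
#' @param path file path.
#' @return \code{readBismarkCov}: GRanges with mcols \code{meth},
#'   \code{unmeth}; \code{writeBismarkCov}: invisibly, the path.
#' @export
readBismarkCov <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "pct",
                                 "meth", "unmeth"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric", "integer", "integer"))
  bad <- which(df$meth < 0 | df$unmeth < 0 | df$start < 1 |
                 df$end < df$start)
  if (length(bad))
    stop("malformed Bismark coverage record at line ", bad[1])
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$meth <- df$meth
  mcols(gr)$unmeth <- df$unmeth
  gr
}

#' @param sites GRanges with mcols \code{meth} and \code{unmeth}.
#' @rdname readBismarkCov
#' @export
writeBismarkCov <- function(sites, path) {
  m <- mcols(sites)$meth; u <- mcols(sites)$unmeth
  tot <- m + u
  pct <- ifelse(tot > 0, 100 * m / tot, 0)
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites), end = end(sites),
                   pct = pct, meth = m, unmeth = u)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one Bismark coverage file per sample of a MethylationSet
#'
#' @param ms A \linkS4class{MethylationSet}.
#' @param dir output directory (created if missing). Files are named
#'   \code{<sample>.cov}; sites with zero coverage in a sample are omitted,
#'   as a bisulfite caller would.
#' @return Invisibly, the written file paths.
#' @export
writeBismarkCovSet <- function(ms, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- rowRanges(ms)
  m <- methCounts(ms); u <- unmethCounts(ms)
  paths <- character(ncol(ms))
  for (j in seq_len(ncol(ms))) {
    keep <- (m[, j] + u[, j]) > 0
    gr <- sites[keep]
    mcols(gr)$meth <- m[keep, j]
    mcols(gr)$unmeth <- u[keep, j]
    paths[j] <- file.path(dir, paste0(colnames(ms)[j], ".cov"))
    writeBismarkCov(gr, paths[j])
  }
  invisible(paths)
}

#' Assemble a MethylationSet from Bismark coverage files
#'
#' Sites are unioned across files; a sample missing a site gets zero counts
#' there (undefined level).
#'
#' @param paths character vector of coverage-file paths.
#' @param sampleData per-sample metadata, rows in the order of \code{paths}.
#' @return A \linkS4class{MethylationSet}.
#' @export
readBismarkCovSet <- function(paths, sampleData = NULL) {
  grs <- lapply(paths, readBismarkCov)
  all <- sort(unique(do.call(c, lapply(grs, granges))))
  n <- length(all)
  meth <- matrix(0L, n, length(paths))
  unmeth <- matrix(0L, n, length(paths))
  for (j in seq_along(grs)) {
    idx <- match(grs[[j]], all)
    meth[idx, j] <- mcols(grs[[j]])$meth
    unmeth[idx, j] <- mcols(grs[[j]])$unmeth
  }
  nm <- sub("\\.cov$", "", basename(paths))
  colnames(meth) <- colnames(unmeth) <- nm
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = nm)
  MethylationSet(meth, unmeth, all, sampleData)
}
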