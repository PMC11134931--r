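#' Detect CpG islands by distance-based clustering
#'
#' CpG islands are detected per chromosome as maximal runs of consecutive CpGs
#' whose neighbour distance is at most the chromosome's median inter-CpG
#' distance. Each cluster of k+1 CpGs (k distances) is scored against the
#' null that spacings are geometric with rate \eqn{\hat p = 1/\bar d}
#' (\eqn{\bar d} = chromosome mean distance): the sum of k geometric spacings
#' is k plus a negative binomial, so the lower-tail p-value is
#' \code{pnbinom(sum(d) - k, k, p)}. Clusters are kept when BH-significant at
#' \code{fdr} and spanning at least \code{minLength} bp.
#'
#' @param cpgs width-1 GRanges of CpG positions (plus-strand C).
#' @param minLength minimum island span in bp.
#' @param fdr Benjamini-Hochberg threshold on cluster p-values.
#' @return GRanges of islands, sorted and disjoint, with mcols \code{n_cpgs}
#'   and \code{p_value}. Chromosomes with fewer than 2 CpGs contribute none.
#' @export
detectCGIs <- function(cpgs, minLength = 50, fdr = 0.05) {
  out <- GRanges()
  for (chr in as.character(unique(seqnames(cpgs)))) {
    pos <- sort(start(cpgs[seqnames(cpgs) == chr]))
    if (length(pos) < 2) next
    d <- diff(pos)
    thr <- median(d)
    phat <- 1 / mean(d)
    close <- d <= thr
    # runs of consecutive close spacings
    r <- rle(close)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ki <- which(r$values)
    if (!length(ki)) next
    cl_start <- pos[starts[ki]]          # first CpG of run
    cl_end <- pos[ends[ki] + 1]          # last CpG of run
    k <- r$lengths[ki]
    s <- vapply(ki, function(i) sum(d[starts[i]:ends[i]]), numeric(1))
    p <- pnbinom(s - k, size = k, prob = phat)
    gr <- GRanges(chr, IRanges(cl_start, cl_end + 1))
    mcols(gr)$n_cpgs <- k + 1L
    mcols(gr)$p_value <- p
    suppressWarnings(out <- c(out, gr))
  }
  if (!length(out)) return(out)
  padj <- p.adjust(mcols(out)$p_value, method = "BH")
  keep <- padj <= fdr & width(out) >= minLength
  sort(out[keep])
}

#' Derive promoter regions from gene models
#'
#' The promoter is the 2-kb region immediately upstream of the TSS on the
#' gene's strand (so for minus-strand genes it lies at coordinates greater
#' than the TSS), truncated rather than discarded at chromosome edges.
#'
#' @param genes GRanges of gene bodies with strand; \code{seqlengths} must be
#'   set for edge truncation.
#' @param width promoter width in bp (default 2000).
#' @return GRanges of promoters, parallel to \code{genes}.
#' @export
promoterRegions <- function(genes, width = 2000) {
  # promoters() warns about ranges that stick out before we trim them
  pr <- suppressWarnings(promoters(genes, upstream = width, downstream = 0))
  trim(pr)
}

#' Classify promoters by CpG-island overlap
#'
#' A promoter overlapping at least one island by at least 1 bp is a CGI
#' promoter; all others are typed Other.
#'
#' @param promoters GRanges of promoter regions.
#' @param cgis GRanges of CpG islands.
#' @return Factor ("CGI"/"Other") parallel to \code{promoters}.
#' @export
typePromoters <- function(promoters, cgis) {
  hit <- overlapsAny(promoters, cgis, ignore.strand = TRUE)
  factor(ifelse(hit, "CGI", "Other"), levels = c("CGI", "Other"))
}

#' Reciprocal overlap between two intervals
#'
#' Returns the overlap in bp divided by each interval's length. Intervals on
#' different chromosomes overlap by 0.
#'
#' @param a,b GRanges of length 1 (or equal-length, compared pairwise).
#' @return Numeric matrix with columns \code{frac_a}, \code{frac_b}.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' reciprocalOverlap(a, b)  # 0.5 0.5
#' @export
reciprocalOverlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmax(0, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1)
  ov[!same] <- 0
  cbind(frac_a = ov / width(a), frac_b = ov / width(b))
}

#' Which query intervals have a reciprocal-overlap partner
#'
#' For every interval of \code{query}, tests whether any interval of
#' \code{subject} overlaps it such that the shared bp are at least
#' \code{minFrac} of both intervals' lengths (the "25\% reciprocal overlap"
#' rule used for tissue-specific DMR matching).
#'
#' @param query,subject GRanges.
#' @param minFrac minimum reciprocal overlap fraction.
#' @return Logical vector parallel to \code{query}.
#' @export
hasReciprocalPartner <- function(query, subject, minFrac = 0.25) {
  if (length(query) == 0) return(logical(0))
  if (length(subject) == 0) return(rep(FALSE, length(query)))
  hits <- suppressWarnings(findOverlaps(query, subject, ignore.strand = TRUE))
  if (!length(hits)) return(rep(FALSE, length(query)))
  q <- query[queryHits(hits)]
  s <- subject[subjectHits(hits)]
  ov <- pmin(end(q), end(s)) - pmax(start(q), start(s)) + 1
  ok <- ov >= minFrac * width(q) & ov >= minFrac * width(s)
  res <- rep(FALSE, length(query))
  res[unique(queryHits(hits)[ok])] <- TRUE
  res
}

#' Minimal BED6 writer/reader
#'
#' Writes GRanges as BED6 (0-based half-open on disk) and reads BED3/BED6 back
#' to 1-based GRanges. Score defaults to 0 and name to ".".
#'
#' @param gr GRanges to write; \code{name} mcol used if present.
#' @param path file path.
#' @return \code{writeBED}: invisibly the path; \code{readBED}: GRanges.
#' @export
writeBED <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else rep(".", length(gr))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc, strand = st)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBED
#' @export
readBED <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = list(V1 = "character"))
  gr <- GRanges(df$V1, IRanges(df$V2 + 1L, df$V3))
  if (ncol(df) >= 4) mcols(gr)$name <- as.character(df$V4)
  if (ncol(df) >= 5) mcols(gr)$score <- df$V5
  if (ncol(df) >= 6) {
    st <- as.character(df$V6); st[st == "."] <- "*"
    if (all(st %in% c("+", "-", "*"))) strand(gr) <- st
    else mcols(gr)$extra <- df$V6        # BED6+ numeric extension column
  }
  gr
}

#' Read/write chromosome sizes
#'
#' Two-column TSV \code{chrom\\tlength}, as used by interval shuffling.
#'
#' @param sizes named integer vector / @param path file path.
#' @return \code{readChromSizes}: named integer vector.
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeChromSizes
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer"))
  setNames(df$V2, df$V1)
}
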