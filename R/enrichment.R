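#' Shuffle intervals uniformly across the genome
#'
#' Each interval is placed independently and uniformly over all genomic start
#' positions that keep it within one chromosome: a chromosome is chosen with
#' probability proportional to its number of valid placements
#' (\code{size - width + 1}), then the start uniformly within it. Lengths are
#' preserved; overlaps among placed intervals are permitted and no regions are
#' excluded.
#'
#' @param gr GRanges to shuffle.
#' @param sizes named integer vector of chromosome lengths.
#' @return GRanges of shuffled intervals.
#' @export
shuffleIntervals <- function(gr, sizes) {
  w <- width(gr)
  if (any(w > max(sizes)))
    stop("interval longer than every chromosome")
  n <- length(gr)
  out <- .shuffleStarts(w, sizes)
  GRanges(out$chrom, IRanges(out$start, width = w))
}

.shuffleStarts <- function(w, sizes) {
  # vectorised placement for possibly many intervals; returns chrom + start
  nchr <- length(sizes)
  valid <- outer(unname(sizes), w, function(s, ww) pmax(0, s - ww + 1))
  totals <- colSums(valid)
  if (any(totals == 0)) stop("interval longer than every chromosome")
  u <- runif(length(w)) * totals
  cs <- matrix(apply(valid, 2, cumsum), nrow = nchr)  # nchr x n
  chromIdx <- colSums(sweep(cs, 2, u, "<")) + 1L      # first chrom with cs >= u
  chromIdx <- pmin(chromIdx, nchr)
  prev <- rbind(0, cs)[cbind(chromIdx, seq_along(w))]
  offset <- u - prev
  start <- as.integer(ceiling(offset))
  start[start < 1] <- 1L
  maxStart <- unname(sizes)[chromIdx] - w + 1L
  start <- pmin(start, maxStart)
  list(chrom = names(sizes)[chromIdx], start = start)
}

#' Total overlapping base pairs between two interval sets
#'
#' Both sets are merged per chromosome before intersection, so shared bp are
#' counted once.
#'
#' @param a,b GRanges.
#' @return Total intersected base pairs (numeric).
#' @export
overlapBp <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  suppressWarnings(
    sum(width(intersect(reduce(a, ignore.strand = TRUE),
                        reduce(b, ignore.strand = TRUE)))))
}

#' Enrichment odds ratio
#'
#' \deqn{OR = \frac{overlap / L_{query}}{L_{annotation} / L_{genome}}}
#' the observed per-bp overlap rate of the query relative to the annotation's
#' genomic density.
#'
#' @param overlap overlapping bp.
#' @param lenQuery,lenAnnotation,genome total bp of query set, annotation set
#'   and genome.
#' @return Odds ratio (>= 0).
#' @examples
#' oddsRatio(100, 1000, 10000, 1e6)  # 10
#' @export
oddsRatio <- function(overlap, lenQuery, lenAnnotation, genome) {
  if (genome <= 0 || lenQuery <= 0) stop("query and genome lengths must be > 0")
  (overlap / lenQuery) / (lenAnnotation / genome)
}

#' Empirical Monte Carlo p-value
#'
#' For the enrichment tail, r is the number of replicates with overlap greater
#' than or equal to the observed; for depletion, less than or equal. p = r/n
#' exactly (so p = 0 is attainable); \code{pseudo = TRUE} uses the smoothed
#' (r+1)/(n+1) instead.
#'
#' @param observed observed overlap.
#' @param replicates vector of replicate overlaps.
#' @param tail "enrichment" or "depletion".
#' @param pseudo use (r+1)/(n+1) smoothing.
#' @return List with \code{r}, \code{n}, \code{p}.
#' @export
empiricalTest <- function(observed, replicates,
                          tail = c("enrichment", "depletion"),
                          pseudo = FALSE) {
  tail <- match.arg(tail)
  n <- length(replicates)
  stopifnot(n >= 1)
  r <- if (tail == "enrichment") sum(replicates >= observed)
       else sum(replicates <= observed)
  p <- if (pseudo) (r + 1) / (n + 1) else r / n
  list(r = r, n = n, p = p)
}

#' Bonferroni control at a family-wise error rate
#'
#' Adjusted p is \code{min(1, m p)}; a test is significant when its raw p is
#' at most \code{fwer / m}.
#'
#' @param pvals raw p-values.
#' @param fwer family-wise error rate (default 0.1).
#' @return data.frame with \code{p}, \code{p_adj}, \code{significant}.
#' @export
bonferroniAdjust <- function(pvals, fwer = 0.1) {
  m <- length(pvals)
  data.frame(p = pvals,
             p_adj = p.adjust(pvals, method = "bonferroni"),
             significant = pvals <= fwer / m)
}

#' Monte Carlo interval enrichment test
#'
#' Shuffles the query set \code{n} times across the genome, recomputes the
#' total bp overlap with the annotation per replicate, and reports the
#' empirical p (both tails computed; the reported tail is enrichment when the
#' observed overlap exceeds the replicate mean, depletion otherwise) together
#' with the odds ratio.
#'
#' @param query,annotation GRanges.
#' @param sizes named chromosome lengths.
#' @param n number of shuffling replicates (default 1000).
#' @param pseudo passed to \code{\link{empiricalTest}}.
#' @return One-row data.frame: observed_overlap, odds_ratio, tail, r, n,
#'   p_emp, mean_null.
#' @export
enrichmentTest <- function(query, annotation, sizes, n = 1000,
                           pseudo = FALSE) {
  obs <- overlapBp(query, annotation)
  reps <- .nullOverlaps(query, annotation, sizes, n)
  tail <- if (obs >= mean(reps)) "enrichment" else "depletion"
  et <- empiricalTest(obs, reps, tail, pseudo)
  or <- oddsRatio(obs, sum(width(reduce(query, ignore.strand = TRUE))),
                  sum(width(reduce(annotation, ignore.strand = TRUE))),
                  sum(sizes))
  data.frame(observed_overlap = obs, odds_ratio = or, tail = tail,
             r = et$r, n = et$n, p_emp = et$p, mean_null = mean(reps))
}

.nullOverlaps <- function(query, annotation, sizes, n) {
  # all n replicates placed in one batch, overlap aggregated per replicate;
  # per-interval overlaps may double count bp shared between placed intervals
  # of one replicate, which uniform placement makes a measure-zero concern at
  # the sparse query densities used here
  w <- rep(width(query), n)
  repId <- rep(seq_len(n), each = length(query))
  pl <- .shuffleStarts(w, sizes)
  shuf <- GRanges(pl$chrom, IRanges(pl$start, width = w))
  ann <- reduce(annotation, ignore.strand = TRUE)
  hits <- findOverlaps(shuf, ann, ignore.strand = TRUE)
  reps <- numeric(n)
  if (length(hits)) {
    qh <- queryHits(hits)
    ov <- width(pintersect(shuf[qh], ann[subjectHits(hits)],
                           ignore.strand = TRUE))
    agg <- rowsum(ov, repId[qh])
    reps[as.integer(rownames(agg))] <- agg
  }
  reps
}
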