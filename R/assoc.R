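#' Per-bin correlation between Fst and methylation differentiation
#'
#' For each metagene bin, the Spearman correlation across genes between the
#' bin's genetic differentiation (Fst) and absolute methylation
#' differentiation (Mdiff). Run separately per promoter type and Fst class
#' (CpG / non-CpG) by subsetting the inputs.
#'
#' @param fst,mdiff genes x bins matrices with matching dimnames.
#' @param minGenes minimum complete pairs per bin.
#' @return data.frame with \code{bin}, \code{rho}, \code{n}.
#' @export
fstMdiffProfile <- function(fst, mdiff, minGenes = 3) {
  stopifnot(identical(dim(fst), dim(mdiff)))
  rho <- rep(NA_real_, ncol(fst))
  n <- integer(ncol(fst))
  for (b in seq_len(ncol(fst))) {
    f <- fst[, b]; m <- mdiff[, b]
    ok <- !is.na(f) & !is.na(m)
    n[b] <- sum(ok)
    if (n[b] >= minGenes && sd(f[ok]) > 0 && sd(m[ok]) > 0)
      rho[b] <- cor(f[ok], m[ok], method = "spearman")
  }
  data.frame(bin = colnames(fst), rho = rho, n = n, row.names = NULL)
}

.bcaR2 <- function(X, groups) {
  # X: samples x features, column-centred by caller
  gm <- rowsum(X, groups) / as.vector(table(groups)[levels(factor(groups))])
  ng <- table(groups)[rownames(gm)]
  between <- sum(as.vector(ng) * rowSums(gm^2))
  total <- sum(X^2)
  if (total == 0) return(NA_real_)
  between / total
}

#' Between-groups PCA R-squared with permutation test
#'
#' Quantifies how much of the total methylation variance a grouping explains:
#' the matrix (regions x samples) is transposed and column-centred; R-squared
#' is the between-group sum of squares of the samples (group means weighted by
#' group size) over the total sum of squares. Significance by permuting group
#' labels. When a \code{control} grouping is supplied, the matrix is first
#' centred within each control stratum (removing, e.g., tissue effects before
#' testing species) and labels are permuted within strata.
#'
#' @param mat regions x samples numeric matrix (rows with NA are dropped).
#' @param groups per-sample grouping to test.
#' @param nPerm number of permutations (default 999).
#' @param control optional per-sample stratification.
#' @return List with \code{R2}, \code{p_perm}, \code{n_perm}.
#' @export
bca <- function(mat, groups, nPerm = 999, control = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  mat <- mat[complete.cases(mat), , drop = FALSE]
  X <- t(mat)
  if (!is.null(control)) {
    control <- factor(control)
    for (s in levels(control)) {
      ix <- which(control == s)
      X[ix, ] <- sweep(X[ix, , drop = FALSE], 2,
                       colMeans(X[ix, , drop = FALSE]))
    }
  }
  X <- sweep(X, 2, colMeans(X))
  obs <- .bcaR2(X, groups)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    pg <- if (is.null(control)) sample(groups) else {
      pg <- groups
      for (s in levels(control)) {
        ix <- which(control == s)
        pg[ix] <- sample(groups[ix])
      }
      pg
    }
    if (.bcaR2(X, pg) >= obs) exceed <- exceed + 1L
  }
  list(R2 = obs, p_perm = (exceed + 1) / (nPerm + 1), n_perm = nPerm)
}

#' Preferential expression measure
#'
#' PEM of gene g in tissue t is \code{log10(x[g,t] / mean_t(x[g,]))}: 0 for
#' uniform expression, positive where a tissue over-expresses, -Inf where a
#' tissue is silent. With T tissues the maximum is log10(T) (log10(5) ~ 0.699
#' for a five-tissue panel). Genes with no expression in any tissue are
#' excluded.
#'
#' @param expr genes x tissues matrix of non-negative expression values.
#' @return genes x tissues matrix of PEM values (rows of excluded genes are
#'   dropped); -Inf marks zero expression in one tissue.
#' @export
pem <- function(expr) {
  stopifnot(ncol(expr) >= 2, all(expr >= 0, na.rm = TRUE))
  keep <- rowSums(expr, na.rm = TRUE) > 0
  expr <- expr[keep, , drop = FALSE]
  log10(expr / rowMeans(expr))
}

#' PEM rank test for tissue-specific DMR genes
#'
#' Contingency chi-square test of independence between gene set (focal-tissue
#' tsDMR promoter genes vs reference genes with no promoter tsDMR in any
#' tissue) and the rank of the focal tissue's PEM within each gene (1 = most
#' expressed). An association concentrates tsDMR genes at the extreme ranks.
#'
#' @param pemMat genes x tissues PEM matrix.
#' @param tsdmrGenes,referenceGenes rowname sets.
#' @param focal focal tissue (column name).
#' @return \code{htest} from \code{chisq.test}; a warning flags expected
#'   counts below 5.
#' @export
pemRankTest <- function(pemMat, tsdmrGenes, referenceGenes, focal) {
  rankOf <- function(genes) {
    g <- intersect(genes, rownames(pemMat))
    if (!length(g)) stop("empty gene set")
    apply(pemMat[g, , drop = FALSE], 1,
          function(v) rank(-v, ties.method = "first")[focal])
  }
  r1 <- rankOf(tsdmrGenes)
  r0 <- rankOf(referenceGenes)
  T_ <- ncol(pemMat)
  tab <- rbind(tsDMR = tabulate(r1, T_), reference = tabulate(r0, T_))
  suppressWarnings(ht <- chisq.test(tab))
  if (any(ht$expected < 5))
    warning("expected cell count below 5; chi-square approximation weak")
  ht
}

#' Wilcoxon PEM mean test, separately per expression side
#'
#' Rank-sum comparison of focal-tissue PEM between tsDMR genes and reference
#' genes, run separately for over-expressed (PEM > 0) and under-expressed
#' (PEM < 0) genes.
#'
#' @param pemMat genes x tissues PEM matrix.
#' @param tsdmrGenes,referenceGenes rowname sets.
#' @param focal focal tissue.
#' @param minGenes minimum genes per side per group.
#' @return List with \code{p_over}, \code{p_under} (NA where a side is too
#'   small).
#' @export
pemMeanTest <- function(pemMat, tsdmrGenes, referenceGenes, focal,
                        minGenes = 3) {
  v1 <- pemMat[intersect(tsdmrGenes, rownames(pemMat)), focal]
  v0 <- pemMat[intersect(referenceGenes, rownames(pemMat)), focal]
  sideP <- function(sel) {
    a <- v1[sel(v1)]; b <- v0[sel(v0)]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < minGenes || length(b) < minGenes) return(NA_real_)
    suppressWarnings(wilcox.test(a, b)$p.value)
  }
  list(p_over = sideP(function(v) !is.na(v) & v > 0),
       p_under = sideP(function(v) !is.na(v) & v < 0))
}

#' Paired DE vs non-DE profile comparison
#'
#' Paired t-test across profile bins of the difference between the DE-gene
#' mean profile and the non-DE-gene mean profile for a region (promoter bins
#' or gene-body bins); the sign of the mean difference is reported (negative
#' = average value lower in DE genes).
#'
#' @param profileDE,profileNonDE per-bin mean values over the region's bins
#'   (equal length >= 3 after NA removal).
#' @return List with \code{p}, \code{sign}, \code{mean_diff}, \code{n_bins}.
#' @export
deAssociation <- function(profileDE, profileNonDE) {
  ok <- !is.na(profileDE) & !is.na(profileNonDE)
  a <- profileDE[ok]; b <- profileNonDE[ok]
  if (length(a) < 3) stop("need >= 3 paired bins")
  d <- a - b
  if (sd(d) == 0 && mean(d) == 0)
    return(list(p = 1, sign = 0, mean_diff = 0, n_bins = length(a)))
  tt <- t.test(a, b, paired = TRUE)
  list(p = tt$p.value, sign = sign(mean(d)), mean_diff = mean(d),
       n_bins = length(a))
}
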