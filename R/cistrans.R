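#' Cap read coverage at a quantile
#'
#' The cap is the linearly interpolated \code{q} quantile of the total
#' coverage distribution. Sites above the cap are rescaled to a total of
#' \code{floor(cap)} reads preserving the methylated proportion, the
#' methylated count rounded half-to-even. Used to mimic the read depth of
#' allele-split hybrid data: hybrids are capped at the 0.9 quantile of their
#' own coverage, parents at the 0.45 quantile (half their reads carry each
#' allele in a hybrid).
#'
#' @param meth,unmeth per-site counts.
#' @param q cap quantile in (0, 1]; 1 leaves everything unchanged.
#' @param capValue optional explicit cap overriding the quantile.
#' @return List with rescaled \code{meth}, \code{unmeth} and the \code{cap}
#'   used.
#' @examples
#' capCoverage(80, 20, capValue = 50)  # (40, 10)
#' @export
capCoverage <- function(meth, unmeth, q = 0.9, capValue = NULL) {
  stopifnot(q > 0, q <= 1)
  tot <- meth + unmeth
  cap <- if (!is.null(capValue)) capValue
         else quantile(tot, q, names = FALSE, type = 7)
  over <- !is.na(tot) & tot > cap
  if (any(over)) {
    newTot <- floor(cap)
    prop <- meth[over] / tot[over]
    newMeth <- round(prop * newTot)   # round() is half-to-even
    meth[over] <- newMeth
    unmeth[over] <- newTot - newMeth
  }
  list(meth = meth, unmeth = unmeth, cap = cap)
}

#' Downsample parental samples to the hybrid sample size
#'
#' Uniform random subset of size k, to match the n = 3 hybrids.
#'
#' @param sampleIds character vector of candidate sample ids.
#' @param k subset size (default 3).
#' @return Character vector of k sampled ids.
#' @export
downsampleParents <- function(sampleIds, k = 3) {
  if (length(sampleIds) < k)
    stop("fewer than ", k, " samples available")
  if (length(sampleIds) == k) return(sampleIds)
  sample(sampleIds, k)
}

.betaNll <- function(theta, y, grp) {
  mu <- plogis(theta[1] + theta[2] * grp)
  phi <- exp(theta[3])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

.betaGrad <- function(theta, y, grp) {
  mu <- plogis(theta[1] + theta[2] * grp)
  phi <- exp(theta[3])
  a <- mu * phi; b <- (1 - mu) * phi
  dl_dmu <- phi * (digamma(b) - digamma(a) + log(y) - log1p(-y))
  dmu_deta <- mu * (1 - mu)
  dl_dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  -c(sum(dl_dmu * dmu_deta),
     sum(dl_dmu * dmu_deta * grp),
     sum(dl_dphi) * phi)
}

#' Beta-regression test of a methylation-level difference between two groups
#'
#' Maximum-likelihood fit of a beta distribution with logit-linked mean
#' \eqn{\mu = logit^{-1}(\beta_0 + \beta_1 g)} (g = 1 for group A) and common
#' precision \eqn{\phi}, Wald test on \eqn{\beta_1}. Boundary observations are
#' shrunk towards 0.5 before fitting via \eqn{y' = (y (N-1) + 0.5)/N} with N
#' the total number of observations, the standard transform for proportions
#' containing exact 0s or 1s. The Wald statistic is referred to a t
#' distribution on N - 3 degrees of freedom (the residual df after the three
#' likelihood parameters): with the tiny group sizes this design affords
#' (n = 3 per group), the usual normal reference is strongly anti-conservative
#' because the ML precision estimate is biased upward.
#'
#' @param levelsA,levelsB methylation levels in [0,1] per sample (NA dropped).
#' @param minObs minimum observations per group.
#' @return List with \code{p}, \code{sign} (of the A-B effect), \code{beta1}
#'   (logit effect), \code{se}, \code{phi}, \code{converged}. Non-convergence
#'   yields \code{p = NA} (caller treats the locus as ambiguous).
#' @export
betaRegTest <- function(levelsA, levelsB, minObs = 2) {
  a <- levelsA[!is.na(levelsA)]; b <- levelsB[!is.na(levelsB)]
  if (length(a) < minObs || length(b) < minObs)
    return(list(p = NA_real_, sign = NA_integer_, beta1 = NA_real_,
                se = NA_real_, phi = NA_real_, converged = FALSE))
  y <- c(a, b); g <- c(rep(1, length(a)), rep(0, length(b)))
  N <- length(y)
  y <- (y * (N - 1) + 0.5) / N
  ma <- mean(y[g == 1]); mb <- mean(y[g == 0])
  v <- var(y)
  mbar <- mean(y)
  phi0 <- max(1, mbar * (1 - mbar) / max(v, 1e-6) - 1)
  theta0 <- c(qlogis(mb), qlogis(ma) - qlogis(mb), log(min(phi0, 1e4)))
  fit <- tryCatch(
    optim(theta0, .betaNll, .betaGrad, y = y, grp = g, method = "L-BFGS-B",
          lower = c(-30, -60, -5), upper = c(30, 60, 14), hessian = TRUE,
          control = list(factr = 1e4, maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(p = NA_real_, sign = NA_integer_, beta1 = NA_real_,
                se = NA_real_, phi = NA_real_, converged = FALSE))
  H <- fit$hessian
  covb <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(covb) || !is.finite(covb[2, 2]) || covb[2, 2] <= 0)
    covb <- tryCatch(rbind(cbind(solve(H[1:2, 1:2]), 0), 0),
                     error = function(e) NULL)
  if (is.null(covb) || !is.finite(covb[2, 2]) || covb[2, 2] <= 0)
    return(list(p = NA_real_, sign = NA_integer_, beta1 = fit$par[2],
                se = NA_real_, phi = exp(fit$par[3]), converged = FALSE))
  se <- sqrt(covb[2, 2])
  z <- fit$par[2] / se
  df <- N - 3
  p <- if (df >= 1) 2 * stats::pt(-abs(z), df) else 2 * pnorm(-abs(z))
  list(p = p,
       sign = sign(ma - mb),
       beta1 = fit$par[2], se = se, phi = exp(fit$par[3]),
       converged = TRUE)
}

#' Per-locus test battery for cis/trans classification
#'
#' Runs the four beta-regression contrasts per marker locus: parental
#' (COL parents vs PIE parents), hybrid (COL allele vs PIE allele within
#' hybrids), and the two trans-effect tests (same allele across the parental
#' and hybrid environments). Also records the effect sizes
#' \code{dP = mean(COL_p) - mean(PIE_p)}, \code{dH = mean(COL_h) -
#' mean(PIE_h)} and the trans component \code{dT = dP - dH}.
#'
#' @param colP,pieP,colH,pieH loci x replicates matrices of methylation
#'   levels: parental COL/PIE samples and hybrid COL/PIE-origin alleles.
#' @return data.frame, one row per locus, with the four p-values, effect
#'   columns and per-group observation counts.
#' @export
locusTests <- function(colP, pieP, colH, pieH) {
  n <- nrow(colP)
  stopifnot(nrow(pieP) == n, nrow(colH) == n, nrow(pieH) == n)
  res <- data.frame(locus = seq_len(n),
                    p_parental = NA_real_, p_hybrid = NA_real_,
                    p_trans_col = NA_real_, p_trans_pie = NA_real_,
                    dP = NA_real_, dH = NA_real_, dT = NA_real_,
                    n_missing_groups = 0L)
  for (i in seq_len(n)) {
    grps <- list(colP[i, ], pieP[i, ], colH[i, ], pieH[i, ])
    nobs <- vapply(grps, function(v) sum(!is.na(v)), 1L)
    res$n_missing_groups[i] <- sum(nobs < 2)
    if (res$n_missing_groups[i] > 0) next
    tp <- betaRegTest(grps[[1]], grps[[2]])
    th <- betaRegTest(grps[[3]], grps[[4]])
    tc <- betaRegTest(grps[[1]], grps[[3]])
    tq <- betaRegTest(grps[[2]], grps[[4]])
    res$p_parental[i] <- tp$p; res$p_hybrid[i] <- th$p
    res$p_trans_col[i] <- tc$p; res$p_trans_pie[i] <- tq$p
    res$dP[i] <- mean(grps[[1]], na.rm = TRUE) - mean(grps[[2]], na.rm = TRUE)
    res$dH[i] <- mean(grps[[3]], na.rm = TRUE) - mean(grps[[4]], na.rm = TRUE)
    res$dT[i] <- res$dP[i] - res$dH[i]
  }
  res
}

#' Classify one locus into a cis/trans divergence category
#'
#' Pure function of the per-family q-values and effect signs. Rules:
#' \itemize{
#' \item ambiguous: any sample group without data (or a failed test).
#' \item conserved: neither the parental nor the hybrid contrast significant.
#' \item cis: parental and hybrid contrasts significant with the same sign
#'   and no significant trans effect.
#' \item trans: parental significant, hybrid not, trans significant.
#' \item cis+trans / cis x trans: parental, hybrid and trans all significant;
#'   same sign of the trans component and the hybrid (cis) contrast gives
#'   cis+trans, opposite gives cis x trans.
#' \item compensatory: parental not significant, hybrid significant, trans
#'   significant (cis and trans cancel between species).
#' \item unclassified: any remaining significance pattern.
#' }
#'
#' @param qParental,qHybrid,qTransCol,qTransPie per-family BH q-values.
#' @param dP,dH signed parental and hybrid effect sizes (dT = dP - dH).
#' @param fdr significance threshold on q (default 0.1).
#' @param transRule "either" calls a trans effect when either allele's
#'   environment contrast is significant; "pie" uses only the PIE contrast.
#' @param ambiguous force-ambiguous flag (missing data).
#' @return Character category (see \code{divergenceCategories}).
#' @export
classifyLocus <- function(qParental, qHybrid, qTransCol, qTransPie,
                          dP, dH, fdr = 0.1,
                          transRule = c("either", "pie"),
                          ambiguous = FALSE) {
  transRule <- match.arg(transRule)
  if (ambiguous || is.na(qParental) || is.na(qHybrid) ||
      is.na(qTransCol) || is.na(qTransPie))
    return("ambiguous")
  P <- qParental < fdr
  H <- qHybrid < fdr
  Tr <- if (transRule == "either") (qTransCol < fdr) || (qTransPie < fdr)
        else qTransPie < fdr
  dT <- dP - dH
  if (!P && !H) return("conserved")
  if (P && H && !Tr && sign(dP) == sign(dH) && sign(dP) != 0) return("cis")
  if (P && !H && Tr) return("trans")
  if (!P && H && Tr) return("compensatory")
  if (P && H && Tr) {
    if (sign(dT) == 0 || sign(dH) == 0) return("unclassified")
    return(if (sign(dT) == sign(dH)) "cis+trans" else "cisxtrans")
  }
  "unclassified"
}

#' Classify all loci of a test table
#'
#' Applies Benjamini-Hochberg correction across loci separately within each
#' of the four test families, then \code{\link{classifyLocus}} per locus.
#'
#' @param tests data.frame from \code{\link{locusTests}}.
#' @param fdr FDR threshold (default 0.1).
#' @param transRule see \code{\link{classifyLocus}}.
#' @return \code{tests} with added q-value columns and \code{category}.
#' @export
classifyCisTrans <- function(tests, fdr = 0.1,
                             transRule = c("either", "pie")) {
  transRule <- match.arg(transRule)
  for (fam in c("parental", "hybrid", "trans_col", "trans_pie"))
    tests[[paste0("q_", fam)]] <-
      p.adjust(tests[[paste0("p_", fam)]], method = "BH")
  tests$category <- vapply(seq_len(nrow(tests)), function(i) {
    classifyLocus(tests$q_parental[i], tests$q_hybrid[i],
                  tests$q_trans_col[i], tests$q_trans_pie[i],
                  tests$dP[i], tests$dH[i], fdr = fdr,
                  transRule = transRule,
                  ambiguous = tests$n_missing_groups[i] > 0)
  }, "")
  tests$category <- factor(tests$category, levels = divergenceCategories())
  tests
}

#' Major axis (model II) regression
#'
#' Slope of the major axis of the (x, y) scatter:
#' \deqn{b = \frac{s_{yy} - s_{xx} + \sqrt{(s_{yy} - s_{xx})^2 + 4 s_{xy}^2}}
#' {2 s_{xy}},}
#' intercept through the means; significance from the Pearson correlation
#' test of x and y. Used to summarise inheritance over marker loci with
#' COL:parental-hybrid as response and PIE:parental-hybrid as predictor.
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @return List with \code{slope}, \code{intercept}, \code{p}, \code{n}.
#'   \code{slope} is NA when \code{s_xy = 0} (axis-aligned scatter).
#' @export
majorAxisRegression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxy == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                p = NA_real_, n = length(x)))
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       p = cor.test(x, y)$p.value,
       n = length(x))
}

#' Allele-specific region levels at marker loci
#'
#' Applies the allele-specific estimation protocol to count matrices at
#' marker windows: hybrid allele coverage is capped at its 0.9 quantile,
#' parental samples are randomly downsampled to \code{k} individuals and
#' capped at the 0.45 quantile of their coverage, then per-locus region
#' levels are computed per sample/allele with no additional coverage floor
#' (the caps already bound the depth; sites with any remaining coverage
#' contribute).
#'
#' @param parental \linkS4class{MethylationSet} of parental samples (colData
#'   \code{species} in COL/PIE) restricted to one tissue.
#' @param hybridAlleles \linkS4class{MethylationSet} of hybrid allele-resolved
#'   counts (colData \code{allele} in COL/PIE, \code{sample_id} per hybrid).
#' @param markers GRanges of 200-bp marker windows.
#' @param k parental downsampling size.
#' @param capHyb,capPar cap quantiles for hybrid and parental coverage.
#' @param minCov minimum site coverage after capping (default 1).
#' @return List of loci x replicate level matrices \code{colP}, \code{pieP},
#'   \code{colH}, \code{pieH}.
#' @export
alleleSpecificLevels <- function(parental, hybridAlleles, markers, k = 3,
                                 capHyb = 0.9, capPar = 0.45, minCov = 1) {
  cd <- colData(parental)
  colIds <- rownames(cd)[cd$species == "COL"]
  pieIds <- rownames(cd)[cd$species == "PIE"]
  colIds <- downsampleParents(colIds, k)
  pieIds <- downsampleParents(pieIds, k)
  par <- parental[, c(colIds, pieIds)]
  capP <- capCoverage(methCounts(par), unmethCounts(par), capPar)
  parCap <- MethylationSet(capP$meth, capP$unmeth, rowRanges(par),
                           colData(par))
  capH <- capCoverage(methCounts(hybridAlleles),
                      unmethCounts(hybridAlleles), capHyb)
  hybCap <- MethylationSet(capH$meth, capH$unmeth,
                           rowRanges(hybridAlleles),
                           colData(hybridAlleles))
  levP <- regionLevelMatrix(parCap, markers, minCov = minCov, maxCov = Inf)
  levH <- regionLevelMatrix(hybCap, markers, minCov = minCov, maxCov = Inf)
  hcd <- colData(hybridAlleles)
  list(colP = levP[, colIds, drop = FALSE],
       pieP = levP[, pieIds, drop = FALSE],
       colH = levH[, hcd$allele == "COL", drop = FALSE],
       pieH = levH[, hcd$allele == "PIE", drop = FALSE])
}
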