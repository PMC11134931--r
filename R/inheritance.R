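#' Decorrelated inheritance coordinates per promoter
#'
#' For each promoter, x = M_H - M_COL and y = M_H - M_PIE place the hybrid
#' relative to both parents. Using the same hybrid value on both axes induces
#' cov(x, y) = var(M_H) under independence, inflating apparent over- and
#' underdominance. The correction draws two distinct hybrid replicates
#' without replacement, one per axis; parental terms use group means.
#' With a single hybrid sample the same sample is reused on both axes and a
#' warning records the bias.
#'
#' @param levels promoters x samples matrix of methylation levels.
#' @param species character vector (COL/PIE/HYB), one per column.
#' @return data.frame with \code{x}, \code{y}, \code{radius}, \code{angle}
#'   (atan2(y, x) in (-pi, pi]), one row per promoter (rownames kept).
#' @export
decorrelatedPoints <- function(levels, species) {
  stopifnot(length(species) == ncol(levels))
  hy <- which(species == "HYB")
  co <- which(species == "COL")
  pi_ <- which(species == "PIE")
  if (length(hy) < 1 || length(co) < 1 || length(pi_) < 1)
    stop("need at least one sample per group")
  n <- nrow(levels)
  if (length(hy) == 1) {
    warning("single hybrid sample: axes share the replicate (biased)")
    i <- rep(hy, n); j <- rep(hy, n)
  } else {
    picks <- replicate(n, sample(hy, 2))
    i <- picks[1, ]; j <- picks[2, ]
  }
  mCol <- rowMeans(levels[, co, drop = FALSE], na.rm = TRUE)
  mPie <- rowMeans(levels[, pi_, drop = FALSE], na.rm = TRUE)
  hx <- levels[cbind(seq_len(n), i)]
  hyv <- levels[cbind(seq_len(n), j)]
  x <- hx - mCol
  y <- hyv - mPie
  data.frame(x = x, y = y,
             radius = sqrt(x^2 + y^2),
             angle = atan2(y, x),
             row.names = rownames(levels))
}

#' Classify hybrid inheritance mode from a decorrelated point
#'
#' Points with radius below the circular \code{cutoff} are conserved. The
#' remaining plane is split into eight pi/4-wide sectors whose boundaries lie
#' at odd multiples of pi/8 (i.e. pi/8 on each side of the axes and
#' diagonals); boundaries are half-open with the counter-clockwise sector
#' inclusive. Sector centres map to categories by the geometry of
#' x = H - COL, y = H - PIE:
#' \itemize{
#' \item pi/4 (x = y > 0): overdominant; -3pi/4: underdominant.
#' \item 3pi/4 and -pi/4 (x = -y): additive (hybrid between parents).
#' \item pi/2 and -pi/2 (x ~ 0): collared_dominant (hybrid at the COL value).
#' \item 0 and pi (y ~ 0): pied_dominant (hybrid at the PIE value).
#' }
#'
#' @param x,y decorrelated coordinates (vectorised).
#' @param cutoff conserved radius (default 0.1).
#' @return Factor of inheritance modes.
#' @examples
#' classifyInheritance(c(0.3, 0.3, 0, 0.05), c(-0.3, 0.3, 0.3, 0.02))
#' # additive, overdominant, collared_dominant, conserved
#' @export
classifyInheritance <- function(x, y, cutoff = 0.1) {
  sectorMap <- c("pied_dominant",      # k = 0,  angle ~ 0
                 "overdominant",       # k = 1,  ~ pi/4
                 "collared_dominant",  # k = 2,  ~ pi/2
                 "additive",           # k = 3,  ~ 3pi/4
                 "pied_dominant",      # k = 4,  ~ pi
                 "underdominant",      # k = -3, ~ -3pi/4
                 "collared_dominant",  # k = -2, ~ -pi/2
                 "additive")           # k = -1, ~ -pi/4
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  k <- floor((theta + pi / 8) / (pi / 4))   # CCW-inclusive boundaries
  k <- ((k %% 8) + 8) %% 8                  # 0..7; 5,6,7 = -3,-2,-1
  cat_ <- sectorMap[k + 1]
  cat_[!is.na(r) & r < cutoff] <- "conserved"
  cat_[is.na(r)] <- NA
  factor(cat_, levels = inheritanceModes())
}

#' Inheritance classification for a promoter level matrix
#'
#' Convenience wrapper: decorrelated points then sector classification.
#'
#' @param levels promoters x samples matrix.
#' @param species per-column group labels (COL/PIE/HYB).
#' @param cutoff conserved radius.
#' @return data.frame with x, y, radius, angle and \code{category}.
#' @export
classifyPromoterInheritance <- function(levels, species, cutoff = 0.1) {
  pts <- decorrelatedPoints(levels, species)
  pts$category <- classifyInheritance(pts$x, pts$y, cutoff)
  pts
}
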