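#' @importFrom stats dhyper phyper quantile rbinom rpois
NULL

#' SNP-index of one pool at one site
#'
#' Fraction of the pool's reads carrying the designated allele. On a
#' polarized record the designated allele is "allele A", the fruiting
#' parent's allele, so the index is A / (A + non-A).
#'
#' @param ad length-2 numeric vector `(other, A)` of read counts, or a
#'   two-column matrix of such pairs.
#' @return numeric fraction(s) in [0, 1].
#' @examples
#' snpIndex(c(41, 27))   # 27/68
#' @export
snpIndex <- function(ad) {
  if (is.null(dim(ad))) ad <- matrix(ad, ncol = 2)
  tot <- rowSums(ad)
  if (any(tot < 1))
    stop("SNP-index undefined at zero total depth; filter such sites first")
  unname(ad[, 2] / tot)
}

#' Difference of SNP-index between the two bulks
#'
#' @param indexF,indexN SNP-index of the fruiting and non-fruiting pools.
#' @return value(s) in [-1, 1]; near +1 when the fruiting bulk is fixed
#'   for the fruiting-parent allele and the non-fruiting bulk lacks it.
#' @export
deltaSnpIndex <- function(indexF, indexN) indexF - indexN

# vectorized G over table cells (rows = pools, cols = alleles)
.gStatVec <- function(n11, n12, n21, n22) {
  n11 <- as.numeric(n11); n12 <- as.numeric(n12)
  n21 <- as.numeric(n21); n22 <- as.numeric(n22)
  N <- n11 + n12 + n21 + n22
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  term <- function(n, e) ifelse(n > 0, n * log(n / e), 0)
  2 * (term(n11, r1 * c1 / N) + term(n12, r1 * c2 / N) +
       term(n21, r2 * c1 / N) + term(n22, r2 * c2 / N))
}

#' Likelihood-ratio G statistic of a 2x2 pool-by-allele table
#'
#' `G = 2 * sum n log(n / e)` over cells with `n > 0`, where
#' `e = (row total x column total) / grand total`. No continuity
#' correction is applied; zero cells contribute zero. G is 0 exactly when
#' the table is independent.
#'
#' @param table 2x2 numeric matrix of read counts (pools x alleles).
#' @return the G statistic (>= 0).
#' @examples
#' gStatistic(matrix(c(50, 0, 0, 50), 2, byrow = TRUE))  # 200 log 2
#' @export
gStatistic <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a row or column sum is zero")
  .gStatVec(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

#' Euclidean distance between pool allele-frequency vectors
#'
#' Root-sum-square difference over alleles; for a biallelic site this is
#' `sqrt(2) * |freq difference|` and is often raised to the 4th power
#' before smoothing to sharpen peaks.
#'
#' @param freqF,freqN per-allele frequency vectors (each sums to 1).
#' @return the Euclidean distance, in [0, sqrt(2)] for biallelic sites.
#' @examples
#' euclideanDistance(c(1, 0), c(0, 1))  # sqrt(2)
#' @export
euclideanDistance <- function(freqF, freqN) {
  sqrt(sum((freqF - freqN)^2))
}

# Vectorized exact two-tailed Fisher p for tables (a, b / c, d):
# sums the hypergeometric outcomes with point probability <= the
# observed one (at fixed margins), with the customary 1 + 1e-7 relative
# slack against floating-point ties. The hypergeometric pmf is
# log-concave, hence unimodal in k, so the outcome set is a left tail
# [lo, kL] plus a right tail [kR, hi]; the two crossing points are
# located by binary search and the tails summed with phyper, keeping
# the computation exact at large depth.
.fisherPvec <- function(a, b, c, d, log = FALSE) {
  n <- length(a)
  out <- numeric(n)
  logRelErr <- log1p(1e-7)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 + m2 == 0) { out[i] <- NA_real_; next }
    lo <- max(0L, k - m2); hi <- min(k, m1)
    cut <- dhyper(a[i], m1, m2, k, log = TRUE) + logRelErr
    mode <- min(hi, max(lo, floor((k + 1) * (m1 + 1) / (m1 + m2 + 2))))
    # largest kL in [lo, mode] with log p(kL) <= cut (p increasing there)
    l <- lo; r <- mode; kL <- lo - 1L
    while (l <= r) {
      m <- (l + r) %/% 2L
      if (dhyper(m, m1, m2, k, log = TRUE) <= cut) { kL <- m; l <- m + 1L }
      else r <- m - 1L
    }
    # smallest kR in [mode, hi] with log p(kR) <= cut (p decreasing there)
    l <- mode; r <- hi; kR <- hi + 1L
    while (l <= r) {
      m <- (l + r) %/% 2L
      if (dhyper(m, m1, m2, k, log = TRUE) <= cut) { kR <- m; r <- m - 1L }
      else l <- m + 1L
    }
    if (log) {
      lt <- if (kL >= lo) phyper(kL, m1, m2, k, log.p = TRUE) else -Inf
      rt <- if (kR <= hi) phyper(kR - 1, m1, m2, k, lower.tail = FALSE,
                                 log.p = TRUE) else -Inf
      hiT <- max(lt, rt)
      out[i] <- min(0, hiT + log1p(exp(min(lt, rt) - hiT)))
    } else {
      p <- 0
      if (kL >= lo) p <- p + phyper(kL, m1, m2, k)
      if (kR <= hi) p <- p + phyper(kR - 1, m1, m2, k, lower.tail = FALSE)
      out[i] <- min(1, p)
    }
  }
  out
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact p-value obtained by summing, over the hypergeometric support at
#' fixed margins, all outcomes whose point probability does not exceed
#' that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-tailed p-value in (0, 1].
#' @examples
#' fisherTwoTailed(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))  # 2/choose(20,10)
#' @export
fisherTwoTailed <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  .fisherPvec(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

#' Per-site association statistics for a polarized variant set
#'
#' Computes, at every site, the SNP-index of both pools, their
#' difference, the Euclidean distance between pool allele-frequency
#' vectors (and its configured power), the likelihood-ratio G statistic
#' of the pool-by-allele read-count table, and the exact two-tailed
#' Fisher p-value.
#'
#' @param vs an oriented [BsaVariantSet-class] with positive depth in
#'   both pools at every site.
#' @param edPower exponent applied to ED (default 4).
#' @return a `GRanges` with metadata columns `snpIndexF`, `snpIndexN`,
#'   `deltaSnpIndex`, `ed`, `edPow`, `g`, `fisherP` (plus `ref`, `alt`,
#'   `aIsAlt` carried over).
#' @export
siteStatistics <- function(vs, edPower = 4) {
  stopifnot(is(vs, "BsaVariantSet"))
  if (!isTRUE(vs@oriented))
    stop("variant set must be polarized first (see polarizeVariants)")
  mc <- mcols(vs@variants)
  dF <- mc$adF1 + mc$adF2
  dN <- mc$adN1 + mc$adN2
  if (any(is.na(dF) | is.na(dN) | dF == 0 | dN == 0))
    stop("sites with missing or zero pool depth present; filter first")
  siF <- mc$adF2 / dF
  siN <- mc$adN2 / dN
  ed <- sqrt(2) * abs(siF - siN)
  g <- .gStatVec(mc$adF1, mc$adF2, mc$adN1, mc$adN2)
  fp <- .fisherPvec(mc$adF1, mc$adF2, mc$adN1, mc$adN2)
  gr <- granges(vs@variants)
  mcols(gr) <- DataFrame(ref = mc$ref, alt = mc$alt, aIsAlt = mc$aIsAlt,
                         snpIndexF = siF, snpIndexN = siN,
                         deltaSnpIndex = siF - siN,
                         ed = ed, edPow = ed^edPower, g = g, fisherP = fp)
  gr
}

#' Kernel-smooth a statistic along the genome
#'
#' Weighted average over sites within `bandwidth` bp on the same
#' scaffold, with tricube weights `(1 - (d/h)^3)^3` (or uniform weights).
#' Scaffolds are never mixed; an isolated site keeps its raw value.
#'
#' @param sites `GRanges` of sites, sorted by scaffold then position.
#' @param values numeric vector of raw statistic values, one per site,
#'   or a matrix with one column per statistic (smoothed in one pass
#'   with shared kernel weights).
#' @param bandwidth half-window in bp (> 0).
#' @param kernel `"tricube"` (default) or `"uniform"`.
#' @return smoothed values in the shape of `values`.
#' @export
smoothTrack <- function(sites, values, bandwidth = 1e6,
                        kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  vec <- is.null(dim(values))
  V <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  stopifnot(length(sites) == nrow(V), bandwidth > 0)
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  runs <- rle(chrom)$values
  if (anyDuplicated(runs) ||
      any(vapply(split(pos, factor(chrom, levels = runs)),
                 is.unsorted, logical(1))))
    stop("sites must be sorted by scaffold then position")
  out <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  for (s in runs) {
    idx <- which(chrom == s)
    p <- pos[idx]; n <- length(idx)
    block <- 1024L
    for (from in seq(1L, n, by = block)) {
      rows <- from:min(from + block - 1L, n)
      D <- abs(outer(p[rows], p, "-"))
      W <- if (kernel == "tricube") (1 - pmin(D / bandwidth, 1)^3)^3
           else (D <= bandwidth) * 1
      out[idx[rows], ] <- (W %*% V[idx, , drop = FALSE]) / rowSums(W)
    }
  }
  if (vec) as.numeric(out) else out
}

#' Null-simulation significance thresholds for a haploid cross
#'
#' Simulates unlinked null sites under the haploid pool model: for each
#' pool independently the fruiting-allele carrier count is
#' Binomial(`poolSize`, 1/2) (a monokaryotic F1 segregates 1:1), depth is
#' Poisson(`meanDepth`) (floored at one read so the site statistics stay
#' defined) and allele reads are Binomial(depth, carrier frequency). The
#' requested upper quantile of |Delta SNP-index|, ED^power, G and
#' -log10(Fisher p) over the simulated sites is returned.
#'
#' @param poolSize strains per bulk.
#' @param meanDepth mean pooled depth per site.
#' @param nNullSites number of null sites to simulate (>= 10,000
#'   recommended).
#' @param quantile upper quantile in (0, 1) (default 0.99).
#' @param edPower exponent applied to ED (default 4).
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return a [BsaNullThresholds-class].
#' @export
nullThresholds <- function(poolSize, meanDepth, nNullSites = 100000L,
                           quantile = 0.99, edPower = 4, seed = NULL) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nNullSites)
  pF <- rbinom(n, poolSize, 0.5) / poolSize
  pN <- rbinom(n, poolSize, 0.5) / poolSize
  dF <- pmax(1L, rpois(n, meanDepth))
  dN <- pmax(1L, rpois(n, meanDepth))
  aF <- rbinom(n, dF, pF)
  aN <- rbinom(n, dN, pN)
  siF <- aF / dF; siN <- aN / dN
  delta <- abs(siF - siN)
  ed <- (sqrt(2) * delta)^edPower
  g <- .gStatVec(dF - aF, aF, dN - aN, aN)
  fl <- -.fisherPvec(dF - aF, aF, dN - aN, aN, log = TRUE) / log(10)
  th <- c(delta = unname(stats::quantile(delta, quantile)),
          ed = unname(stats::quantile(ed, quantile)),
          g = unname(stats::quantile(g, quantile)),
          fisher = unname(stats::quantile(fl, quantile)))
  new("BsaNullThresholds", thresholds = th, quantile = quantile,
      nNullSites = n, poolSize = as.integer(poolSize),
      meanDepth = meanDepth, edPower = edPower,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
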