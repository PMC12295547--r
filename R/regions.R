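#' @importFrom GenomicRanges reduce coverage findOverlaps
#' @importFrom IRanges slice
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths<-
NULL

#' Call significant regions from a statistic track
#'
#' Identifies maximal runs of consecutive sites at or above the
#' threshold (a site exactly equal to the cutoff counts as significant)
#' on one scaffold, then merges runs whose bp gap is at most `maxGap`.
#' Region boundaries are the outermost significant marker positions.
#'
#' @param sites `GRanges` of sites, sorted by scaffold then position.
#' @param values numeric statistic per site, on the scale of the
#'   threshold (e.g. |Delta SNP-index|, ED^power, G, -log10 Fisher p).
#' @param threshold significance cutoff from [nullThresholds()].
#' @param maxGap merge runs separated by at most this many bp; defaults
#'   to the smoothing bandwidth in the pipeline.
#' @param method label stored on the regions.
#' @return `GRanges` of regions with metadata `method`, `peakPos`,
#'   `peakValue`, `nSites`; empty when no site is significant.
#' @export
callRegions <- function(sites, values, threshold, maxGap = 1e6,
                        method = "stat") {
  stopifnot(length(sites) == length(values))
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  runs <- rle(chrom)$values
  if (anyDuplicated(runs) ||
      any(vapply(split(pos, factor(chrom, levels = runs)),
                 is.unsorted, logical(1))))
    stop("sites must be sorted by scaffold then position")
  sig <- !is.na(values) & values >= threshold
  if (!any(sig))
    return(GRanges(method = character(0), peakPos = integer(0),
                   peakValue = numeric(0), nSites = integer(0)))
  acc <- list()
  for (s in runs) {
    idx <- which(chrom == s)
    sigIdx <- idx[sig[idx]]
    if (!length(sigIdx)) next
    # runs of consecutive significant markers
    runId <- cumsum(c(1L, diff(match(sigIdx, idx)) > 1L))
    runStart <- tapply(pos[sigIdx], runId, min)
    runEnd <- tapply(pos[sigIdx], runId, max)
    # merge runs separated by <= maxGap bp
    grp <- cumsum(c(1, runStart[-1] - runEnd[-length(runEnd)] > maxGap))
    for (m in split(seq_along(runId), grp[runId])) {
      ii <- sigIdx[m]
      peak <- ii[which.max(values[ii])]
      acc[[length(acc) + 1L]] <- data.frame(
        chrom = s, start = min(pos[ii]), end = max(pos[ii]),
        peakPos = pos[peak], peakValue = values[peak],
        nSites = length(ii))
    }
  }
  acc <- do.call(rbind, acc)
  GRanges(acc$chrom, IRanges(acc$start, acc$end), method = method,
          peakPos = acc$peakPos, peakValue = acc$peakValue,
          nSites = as.integer(acc$nSites))
}

#' Intersect per-method regions into consensus QTL intervals
#'
#' Returns the maximal genomic intervals covered by significant regions
#' from at least `consensusLevel` of the supplied methods. With the
#' default full-consensus level this is the intersection of all methods'
#' regions: the overlapping interval of the four methods is the final
#' QTL interval, and any method without an overlapping region empties
#' the consensus.
#'
#' @param regionsByMethod named list of `GRanges` from [callRegions()],
#'   one element per method.
#' @param consensusLevel minimum number of supporting methods, in
#'   `[1, length(regionsByMethod)]`.
#' @return `GRanges` of consensus intervals with a `supportingMethods`
#'   character-list column.
#' @export
consensusIntervals <- function(regionsByMethod,
                               consensusLevel = length(regionsByMethod)) {
  nMethods <- length(regionsByMethod)
  if (consensusLevel < 1 || consensusLevel > nMethods)
    stop(sprintf("consensusLevel must lie in [1, %d]", nMethods))
  if (is.null(names(regionsByMethod)))
    names(regionsByMethod) <- paste0("m", seq_len(nMethods))
  red <- lapply(regionsByMethod, function(g) reduce(granges(g)))
  chroms <- unique(unlist(lapply(red, function(g)
    as.character(seqnames(g)))))
  if (!length(chroms)) return(GRanges(supportingMethods = list()))
  maxEnd <- vapply(chroms, function(ch) {
    max(unlist(lapply(red, function(g)
      c(0, end(g)[as.character(seqnames(g)) == ch]))))
  }, numeric(1))
  cov <- NULL
  for (g in red) {
    seqlevels(g) <- chroms
    seqlengths(g) <- as.integer(maxEnd)
    cv <- coverage(g)
    cov <- if (is.null(cov)) cv else cov + cv
  }
  hits <- slice(cov, lower = consensusLevel, rangesOnly = TRUE)
  n <- vapply(hits, length, integer(1))
  if (sum(n) == 0) return(GRanges(supportingMethods = list()))
  out <- GRanges(rep(names(hits), n), unlist(hits, use.names = FALSE))
  support <- lapply(seq_along(out), function(i) {
    names(red)[vapply(red, function(g)
      length(findOverlaps(out[i], g)) > 0, logical(1))]
  })
  mcols(out)$supportingMethods <- S4Vectors::SimpleList(support)
  sort(out)
}
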