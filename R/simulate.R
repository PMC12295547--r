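#' @importFrom stats rpois runif rbinom
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo
NULL

.phenoLevels <- c("fruiting", "non_fruiting")

#' Generate the marker table of a fully informative haploid cross
#'
#' Places `nMarkers` biallelic SNP markers uniformly at random over the
#' configured genome (scaffolds drawn with probability proportional to
#' length, positions uniform, no duplicates) and forces one marker onto
#' the causal position. The two parents are opposite constant haplotypes:
#' the fruiting parent carries the ALT allele at every marker and the
#' non-fruiting parent the REF allele, so every marker is fully
#' informative. Uses the current RNG state; seed it (or call via
#' [simulateCross()]) for reproducibility.
#'
#' @param config a [BsaSimConfig-class].
#' @return a list with `markers` (a `GRanges` with `ref`/`alt` metadata
#'   columns, sorted by scaffold and position) and `causalMarker` (index
#'   of the marker at the causal position, `NA` for an empty table).
#' @export
generateParents <- function(config) {
  stopifnot(is(config, "BsaSimConfig"))
  validObject(config)
  sn <- scaffoldNames(config)
  si <- Seqinfo(seqnames = sn, seqlengths = as.integer(config@scaffoldLengths))
  n <- config@nMarkers
  if (n == 0L) {
    gr <- GRanges(seqinfo = si)
    mcols(gr)$ref <- character(0)
    mcols(gr)$alt <- character(0)
    return(list(markers = gr, causalMarker = NA_integer_))
  }
  scafIdx <- sample.int(config@nScaffolds, n, replace = TRUE,
                        prob = config@scaffoldLengths)
  pos <- floor(runif(n, min = 1, max = config@scaffoldLengths[scafIdx] + 1))
  # resample duplicate (scaffold, position) pairs until distinct
  repeat {
    dup <- duplicated(paste(scafIdx, pos))
    if (!any(dup)) break
    pos[dup] <- floor(runif(sum(dup), min = 1,
                            max = config@scaffoldLengths[scafIdx[dup]] + 1))
  }
  # force one marker onto the causal position
  ci <- match(config@causalScaffold, sn)
  atCausal <- scafIdx == ci & pos == config@causalPos
  if (!any(atCausal)) {
    onScaf <- which(scafIdx == ci)
    repl <- if (length(onScaf)) onScaf[which.min(abs(pos[onScaf] - config@causalPos))]
            else sample.int(n, 1L)
    scafIdx[repl] <- ci
    pos[repl] <- config@causalPos
  }
  o <- order(scafIdx, pos)
  scafIdx <- scafIdx[o]; pos <- pos[o]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)
  gr <- GRanges(sn[scafIdx], IRanges(pos, width = 1L), seqinfo = si)
  mcols(gr)$ref <- ref
  mcols(gr)$alt <- alt
  list(markers = gr,
       causalMarker = which(scafIdx == ci & pos == config@causalPos))
}

#' Simulate one meiosis of the haploid cross
#'
#' Draws a recombinant haploid progeny over the marker positions. Per
#' scaffold the crossover count is Poisson(`recombRate` x length in Mb),
#' crossover positions are uniform and the haplotype alternates parental
#' origin at each crossover; the starting parent is chosen with
#' probability 1/2 (no interference, Haldane-consistent). `crossovers`
#' and `startFrom` override the random draws for constructed cases.
#'
#' @param markers marker `GRanges` from [generateParents()].
#' @param config a [BsaSimConfig-class].
#' @param crossovers optional named list (by scaffold) of fixed crossover
#'   positions in bp.
#' @param startFrom optional named character vector (by scaffold) of
#'   `"F"` or `"N"`: parent contributing the leftmost segment.
#' @return logical vector over markers; `TRUE` where the allele derives
#'   from the fruiting parent.
#' @export
simulateMeiosis <- function(markers, config, crossovers = NULL,
                            startFrom = NULL) {
  sn <- scaffoldNames(config)
  originF <- logical(length(markers))
  chrom <- as.character(seqnames(markers))
  pos <- start(markers)
  for (i in seq_along(sn)) {
    s <- sn[i]
    len <- config@scaffoldLengths[i]
    idx <- which(chrom == s)
    br <- if (!is.null(crossovers) && s %in% names(crossovers)) {
      sort(as.numeric(crossovers[[s]]))
    } else {
      k <- rpois(1L, config@recombRate * len / 1e6)
      sort(runif(k, 0, len))
    }
    firstF <- if (!is.null(startFrom) && s %in% names(startFrom)) {
      startFrom[[s]] == "F"
    } else {
      runif(1) < 0.5
    }
    if (length(idx)) {
      seg <- findInterval(pos[idx], br)
      originF[idx] <- xor(firstF, seg %% 2L == 1L)
    }
  }
  originF
}

#' Assign fruiting phenotypes from the causal-locus allele
#'
#' Carriers of the fruiting-parent allele at the causal marker fruit with
#' probability `penetrance`; every assigned label is then flipped with
#' probability `misclassRate` (phenotyping error). Non-carriers never
#' fruit except through misclassification.
#'
#' @param originF logical matrix (progeny x markers) of fruiting-parent
#'   origin, or a logical vector for a single progeny.
#' @param config a [BsaSimConfig-class].
#' @param causalMarker column index of the causal marker.
#' @return character vector of `"fruiting"` / `"non_fruiting"`.
#' @export
assignPhenotypes <- function(originF, config, causalMarker) {
  if (is.null(dim(originF))) originF <- matrix(originF, nrow = 1L)
  if (is.na(causalMarker) || causalMarker < 1L || causalMarker > ncol(originF))
    stop("causal locus does not resolve to a marker on any scaffold")
  carrier <- originF[, causalMarker]
  n <- length(carrier)
  fruits <- carrier & (runif(n) < config@penetrance)
  flip <- runif(n) < config@misclassRate
  fruits <- xor(fruits, flip)
  ifelse(fruits, "fruiting", "non_fruiting")
}

#' Sample the two phenotype bulks
#'
#' Draws `poolSize` strains without replacement from each phenotype class.
#'
#' @param phenotypes character vector of `"fruiting"`/`"non_fruiting"`.
#' @param poolSize strains per bulk (> 0).
#' @return list with integer index vectors `F` (fruiting bulk) and `N`.
#' @export
buildPools <- function(phenotypes, poolSize) {
  poolSize <- as.integer(poolSize)
  if (poolSize <= 0L) stop("poolSize must be a positive count")
  idxF <- which(phenotypes == "fruiting")
  idxN <- which(phenotypes == "non_fruiting")
  for (cls in list(c("fruiting", length(idxF)), c("non_fruiting", length(idxN)))) {
    if (as.integer(cls[2]) < poolSize)
      stop(sprintf("cannot bulk %d strains of class '%s': only %s available",
                   poolSize, cls[1], cls[2]))
  }
  list(F = sort(sample(idxF, poolSize)),
       N = sort(sample(idxN, poolSize)))
}

#' Simulate pooled short-read allele depths
#'
#' For each marker the true pool alt-allele frequency is the fraction of
#' bulk members carrying the alt allele; sequencing depth is Poisson with
#' mean `meanDepth`, and each read reports the alt allele with
#' probability `p (1 - e) + (1 - p) e` where `e` is the per-read flip
#' probability.
#'
#' @param altCarriers integer vector: alt-allele carriers in the bulk per
#'   marker.
#' @param poolSize bulk size.
#' @param meanDepth Poisson mean depth per site.
#' @param seqError per-read allele flip probability.
#' @return integer matrix with columns `ref` and `alt` (one row per marker).
#' @export
simulatePoolReads <- function(altCarriers, poolSize, meanDepth, seqError = 0) {
  if (poolSize <= 0L) stop("bulk must be non-empty")
  p <- altCarriers / poolSize
  d <- rpois(length(p), meanDepth)
  altReads <- rbinom(length(p), d, p * (1 - seqError) + (1 - p) * seqError)
  cbind(ref = d - altReads, alt = altReads)
}

#' Run the full synthetic haploid cross
#'
#' Seeds the RNG from the configuration and runs marker generation,
#' per-progeny meiosis, phenotype assignment, bulk construction and
#' pooled read simulation.
#'
#' @param config a [BsaSimConfig-class].
#' @return a [BsaSimulation-class].
#' @examples
#' sim <- simulateCross(bsaSimConfig(nScaffolds = 2L,
#'   scaffoldLengths = c(5e5, 5e5), nMarkers = 50L, nProgeny = 60L,
#'   poolSize = 10L, causalScaffold = "scaffold01", causalPos = 250000,
#'   seed = 7L))
#' sim
#' @export
simulateCross <- function(config) {
  validObject(config)
  set.seed(config@seed)
  par <- generateParents(config)
  m <- length(par$markers)
  originF <- matrix(FALSE, nrow = config@nProgeny, ncol = m)
  for (i in seq_len(config@nProgeny))
    originF[i, ] <- simulateMeiosis(par$markers, config)
  phen <- assignPhenotypes(originF, config, par$causalMarker)
  pools <- buildPools(phen, config@poolSize)
  # fruiting parent carries ALT everywhere, so alt carriers = F-origin count
  altF <- colSums(originF[pools$F, , drop = FALSE])
  altN <- colSums(originF[pools$N, , drop = FALSE])
  rf <- simulatePoolReads(altF, config@poolSize, config@meanDepth,
                          config@seqError)
  rn <- simulatePoolReads(altN, config@poolSize, config@meanDepth,
                          config@seqError)
  counts <- cbind(refF = rf[, "ref"], altF = rf[, "alt"],
                  refN = rn[, "ref"], altN = rn[, "alt"])
  new("BsaSimulation", config = config, markers = par$markers,
      originF = originF, phenotypes = phen, pools = pools,
      poolCounts = counts, causalMarker = as.integer(par$causalMarker))
}
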