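#' @importFrom VariantAnnotation readVcf geno ref alt
#' @importFrom GenomicRanges granges
NULL

.GT_CLASSES <- c("hom_ref", "hom_alt", "het", "missing")

.gtClass <- function(gt) {
  gt <- sub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0", "0")] <- "hom_ref"
  out[gt %in% c("1/1", "1")] <- "hom_alt"
  out[grepl("^([0-9]+)/([0-9]+)$", gt) &
        !(gt %in% c("0/0", "1/1"))] <- "het"
  out
}

#' Build a variant set in code
#'
#' Constructor used by the reader and convenient for fixtures: one record
#' per site with parental genotype classes and pool allele depth pairs.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param ref,alt allele strings (`alt` comma-joined when multiallelic).
#' @param gtF,gtN parental genotype classes (`"hom_ref"`, `"hom_alt"`,
#'   `"het"`, `"missing"`).
#' @param adF,adN two-column matrices of (ref, alt) read counts; `NA`
#'   rows denote missing depth.
#' @param samples named character vector of VCF sample names.
#' @return an unoriented [BsaVariantSet-class].
#' @export
bsaVariantSet <- function(chrom, pos, ref, alt, gtF, gtN, adF, adN,
                          samples = c(parentF = "ParentF", parentN = "ParentN",
                                      poolF = "PoolF", poolN = "PoolN")) {
  adF <- matrix(as.integer(adF), ncol = 2)
  adN <- matrix(as.integer(adN), ncol = 2)
  stopifnot(all(gtF %in% .GT_CLASSES), all(gtN %in% .GT_CLASSES))
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  oneBase <- function(x) nchar(x) == 1L & x %in% c("A", "C", "G", "T")
  mcols(gr) <- DataFrame(
    ref = ref, alt = alt, gtF = gtF, gtN = gtN,
    adF1 = adF[, 1], adF2 = adF[, 2], adN1 = adN[, 1], adN2 = adN[, 2],
    isSnp = oneBase(ref) & oneBase(alt),
    multiallelic = grepl(",", alt))
  new("BsaVariantSet", variants = gr, oriented = FALSE, samples = samples)
}

# extract (sites x 2) ref/alt depth matrix for one sample from geno(vcf)$AD
.adMatrix <- function(ad, sample) {
  col <- ad[, sample]
  if (is.array(ad) && length(dim(ad)) == 3L) {
    m <- matrix(as.integer(ad[, sample, 1:2]), ncol = 2)
  } else {
    m <- t(vapply(col, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) < 2L || anyNA(x[1:2])) c(NA_integer_, NA_integer_)
      else x[1:2]
    }, integer(2)))
  }
  m
}

#' Read pool-sequenced variants from a VCF
#'
#' Reads a VCF 4.2 with two parent samples (GT) and two pool samples
#' (AD, DP) into a [BsaVariantSet-class]. One record is produced per VCF
#' data line; multiallelic sites are retained but flagged; missing AD is
#' recorded as `NA`, never zero.
#'
#' @param vcfPath path to the VCF file.
#' @param parentF,parentN,poolF,poolN sample names of the fruiting /
#'   non-fruiting parents and bulks.
#' @return an unoriented [BsaVariantSet-class].
#' @export
readPoolVariants <- function(vcfPath, parentF = "ParentF",
                             parentN = "ParentN", poolF = "PoolF",
                             poolN = "PoolN") {
  vcf <- suppressWarnings(readVcf(vcfPath, genome = "unknown"))
  want <- c(parentF, parentN, poolF, poolN)
  missing <- setdiff(want, colnames(vcf))
  if (length(missing))
    stop("VCF is missing sample(s): ", paste(missing, collapse = ", "))
  gr <- granges(vcf)
  names(gr) <- NULL
  chrom <- as.character(seqnames(gr))
  if (length(gr) > 1L) {
    runs <- rle(chrom)$values
    if (anyDuplicated(runs))
      stop("VCF is not sorted: scaffold blocks are interleaved")
    byChrom <- split(start(gr), factor(chrom, levels = runs))
    if (any(vapply(byChrom, is.unsorted, logical(1))))
      stop("VCF is not sorted by position within scaffold")
  }
  if (length(gr) == 0L) {
    empty <- matrix(integer(0), ncol = 2)
    return(bsaVariantSet(character(0), integer(0), character(0),
                         character(0), character(0), character(0),
                         empty, empty,
                         samples = c(parentF = parentF, parentN = parentN,
                                     poolF = poolF, poolN = poolN)))
  }
  refStr <- as.character(ref(vcf))
  altStr <- vapply(as(alt(vcf), "CharacterList"), paste,
                   character(1), collapse = ",")
  gt <- geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks the GT FORMAT field")
  ad <- geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD FORMAT field for the pools")
  bsaVariantSet(chrom, start(gr), refStr, altStr,
                .gtClass(gt[, parentF]), .gtClass(gt[, parentN]),
                .adMatrix(ad, poolF), .adMatrix(ad, poolN),
                samples = c(parentF = parentF, parentN = parentN,
                            poolF = poolF, poolN = poolN))
}

#' Filtering thresholds for informative markers
#'
#' @param minPoolDepth,maxPoolDepth allowed per-pool depth range (both
#'   pools must fall inside). The pipeline default caps depth at three
#'   times the expected mean to guard against collapsed repeats.
#' @param requireSnp keep only biallelic single-base substitutions.
#' @param requireInformativeParents keep only sites where the parents are
#'   homozygous for opposite alleles.
#' @return a `BsaFilterCriteria` object.
#' @export
filterCriteria <- function(minPoolDepth = 10L, maxPoolDepth = Inf,
                           requireSnp = TRUE,
                           requireInformativeParents = TRUE) {
  if (minPoolDepth < 0 || minPoolDepth > maxPoolDepth)
    stop("need 0 <= minPoolDepth <= maxPoolDepth")
  structure(list(minPoolDepth = minPoolDepth, maxPoolDepth = maxPoolDepth,
                 requireSnp = requireSnp,
                 requireInformativeParents = requireInformativeParents),
            class = "BsaFilterCriteria")
}

#' @export
print.BsaFilterCriteria <- function(x, ...) {
  cat(sprintf("BsaFilterCriteria: depth [%s, %s], SNPs only: %s, informative parents: %s\n",
              x$minPoolDepth, x$maxPoolDepth, x$requireSnp,
              x$requireInformativeParents))
  invisible(x)
}

#' Apply informative-marker filters
#'
#' Keeps records that are biallelic SNPs, have opposite-homozygous
#' parents, and have both pool depths inside the configured range; sites
#' with missing or zero depth in either pool are dropped (the SNP-index
#' is undefined there). Each rejected record is tallied under the first
#' failing rule, in the fixed order `not_snp`, `uninformative_parents`,
#' `missing_or_zero_depth`, `depth_range`, so that
#' `length(kept) + sum(tally)` equals the input count. Filters never
#' throw on data content.
#'
#' @param vs a [BsaVariantSet-class].
#' @param criteria a [filterCriteria()] object.
#' @return list with `kept` (filtered `BsaVariantSet`) and `tally`
#'   (named integer rejection counts).
#' @export
filterVariants <- function(vs, criteria = filterCriteria()) {
  stopifnot(is(vs, "BsaVariantSet"))
  mc <- mcols(vs@variants)
  n <- length(vs)
  dF <- mc$adF1 + mc$adF2
  dN <- mc$adN1 + mc$adN2
  informative <- (mc$gtF == "hom_ref" & mc$gtN == "hom_alt") |
                 (mc$gtF == "hom_alt" & mc$gtN == "hom_ref")
  failSnp <- criteria$requireSnp & !mc$isSnp
  failInf <- criteria$requireInformativeParents & !informative
  failZero <- is.na(dF) | is.na(dN) | dF == 0L | dN == 0L
  failDepth <- !failZero &
    (dF < criteria$minPoolDepth | dF > criteria$maxPoolDepth |
     dN < criteria$minPoolDepth | dN > criteria$maxPoolDepth)
  firstFail <- rep(NA_character_, n)
  firstFail[failDepth] <- "depth_range"
  firstFail[failZero] <- "missing_or_zero_depth"
  firstFail[failInf] <- "uninformative_parents"
  firstFail[failSnp] <- "not_snp"
  keep <- is.na(firstFail)
  tally <- vapply(c("not_snp", "uninformative_parents",
                    "missing_or_zero_depth", "depth_range"),
                  function(r) sum(firstFail == r, na.rm = TRUE), integer(1))
  list(kept = vs[keep], tally = tally)
}

#' Polarize alleles to the fruiting parent
#'
#' Reorients every site so that "allele A" denotes the fruiting parent's
#' allele: where the fruiting parent is homozygous reference, the pool
#' depth pairs are swapped; where it is homozygous alternate they are
#' kept. After polarization the depth pair is (non-A, A) and the `aIsAlt`
#' column records which VCF allele is allele A. Applying the function to
#' an already-oriented set is a no-op.
#'
#' @param vs a [BsaVariantSet-class] that passed the informative-parents
#'   filter.
#' @return the oriented `BsaVariantSet`.
#' @export
polarizeVariants <- function(vs) {
  stopifnot(is(vs, "BsaVariantSet"))
  if (isTRUE(vs@oriented)) return(vs)
  mc <- mcols(vs@variants)
  bad <- !((mc$gtF == "hom_ref" & mc$gtN == "hom_alt") |
           (mc$gtF == "hom_alt" & mc$gtN == "hom_ref"))
  if (any(bad))
    stop(sprintf("cannot polarize %d site(s) with non-opposite-homozygous parents (filter first); first offender: %s:%d",
                 sum(bad),
                 as.character(seqnames(vs@variants))[which(bad)[1]],
                 start(vs@variants)[which(bad)[1]]))
  aIsAlt <- mc$gtF == "hom_alt"
  swap <- !aIsAlt
  newF1 <- ifelse(swap, mc$adF2, mc$adF1)
  newF2 <- ifelse(swap, mc$adF1, mc$adF2)
  newN1 <- ifelse(swap, mc$adN2, mc$adN1)
  newN2 <- ifelse(swap, mc$adN1, mc$adN2)
  mc$adF1 <- newF1; mc$adF2 <- newF2
  mc$adN1 <- newN1; mc$adN2 <- newN2
  mc$aIsAlt <- aIsAlt
  mcols(vs@variants) <- mc
  vs@oriented <- TRUE
  validObject(vs)
  vs
}
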