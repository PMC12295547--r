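#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Configuration of a synthetic haploid cross
#'
#' Parameterizes the synthetic segregating population: a haploid
#' (monokaryotic) F1 population derived from two fully homozygous parents,
#' a single causal locus controlling a binary fruiting trait, two
#' phenotype bulks, and a pooled short-read sequencing model.
#'
#' @slot nScaffolds number of scaffolds in the synthetic genome.
#' @slot scaffoldLengths integer vector of scaffold lengths (bp).
#' @slot nMarkers total number of biallelic SNP markers, placed uniformly
#'   at random genome-wide (one marker is forced onto the causal position).
#' @slot nProgeny number of haploid progeny strains.
#' @slot poolSize number of strains bulked per phenotype pool.
#' @slot meanDepth expected sequencing depth per site per pool (Poisson mean).
#' @slot seqError per-read allele flip probability, in [0, 0.5).
#' @slot recombRate expected crossovers per Mb per meiosis (Haldane, no
#'   interference).
#' @slot causalScaffold,causalPos location of the causal locus.
#' @slot penetrance probability that a carrier of the fruiting allele fruits.
#' @slot misclassRate probability a strain is phenotyped into the wrong bulk.
#' @slot seed integer seed driving all randomness of the simulation.
#'
#' @seealso [bsaSimConfig()] for the user constructor with the study
#'   defaults (156 progeny, pools of 24, 7021 markers, 68.8x depth).
#' @export
setClass("BsaSimConfig",
  representation(
    nScaffolds      = "integer",
    scaffoldLengths = "numeric",
    nMarkers        = "integer",
    nProgeny        = "integer",
    poolSize        = "integer",
    meanDepth       = "numeric",
    seqError        = "numeric",
    recombRate      = "numeric",
    causalScaffold  = "character",
    causalPos       = "numeric",
    penetrance      = "numeric",
    misclassRate    = "numeric",
    seed            = "integer"
  )
)

setValidity("BsaSimConfig", function(object) {
  msg <- character()
  if (object@nScaffolds < 1L)
    msg <- c(msg, "nScaffolds must be >= 1")
  if (length(object@scaffoldLengths) != object@nScaffolds)
    msg <- c(msg, "scaffoldLengths must have one entry per scaffold")
  if (any(object@scaffoldLengths < 1))
    msg <- c(msg, "scaffoldLengths must be positive")
  if (object@nMarkers < 0L)
    msg <- c(msg, "nMarkers must be >= 0")
  if (2L * object@poolSize > object@nProgeny)
    msg <- c(msg, "2 * poolSize must not exceed nProgeny")
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be positive")
  if (object@seqError < 0 || object@seqError >= 0.5)
    msg <- c(msg, "seqError must lie in [0, 0.5)")
  if (object@recombRate < 0)
    msg <- c(msg, "recombRate must be >= 0")
  for (p in c("penetrance", "misclassRate")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  sn <- scaffoldNames(object)
  if (!(object@causalScaffold %in% sn)) {
    msg <- c(msg, "causal locus must lie on an existing scaffold")
  } else {
    len <- object@scaffoldLengths[match(object@causalScaffold, sn)]
    if (object@causalPos < 1 || object@causalPos > len)
      msg <- c(msg, "causal position exceeds its scaffold length")
  }
  if (object@nMarkers > sum(object@scaffoldLengths))
    msg <- c(msg, "more markers requested than representable positions")
  if (length(msg)) msg else TRUE
})

#' A set of polarizable pool-sequenced variants
#'
#' One record per biallelic (or flagged multiallelic) site, carrying the
#' two parental genotype calls and the two pools' allele depths. Sites are
#' held as a [GenomicRanges::GRanges] with metadata columns `ref`, `alt`,
#' `gtF`, `gtN` (parental genotype classes), `adF1`, `adF2`, `adN1`,
#' `adN2` (pool allele depths), `isSnp` and `multiallelic`. Before
#' polarization the depth pair (`*1`, `*2`) is (ref, alt); after
#' [polarizeVariants()] it is (non-A, A) where "allele A" is the fruiting
#' parent's allele at every site, and `aIsAlt` records which VCF allele
#' that is.
#'
#' @slot variants a `GRanges` of width-1 (or indel-width) sites.
#' @slot oriented logical; `TRUE` once alleles have been polarized.
#' @slot samples named character vector of the four VCF sample names
#'   (`parentF`, `parentN`, `poolF`, `poolN`).
#' @export
setClass("BsaVariantSet",
  representation(
    variants = "GRanges",
    oriented = "logical",
    samples  = "character"
  )
)

setValidity("BsaVariantSet", function(object) {
  msg <- character()
  need <- c("ref", "alt", "gtF", "gtN", "adF1", "adF2", "adN1", "adN2",
            "isSnp", "multiallelic")
  have <- colnames(mcols(object@variants))
  if (!all(need %in% have))
    msg <- c(msg, paste("missing metadata columns:",
                        paste(setdiff(need, have), collapse = ", ")))
  else {
    ad <- as.matrix(mcols(object@variants)[, c("adF1", "adF2", "adN1", "adN2")])
    if (any(ad < 0, na.rm = TRUE))
      msg <- c(msg, "allele depths must be >= 0")
  }
  if (length(object@oriented) != 1L)
    msg <- c(msg, "oriented must be a single logical")
  if (isTRUE(object@oriented) && !("aIsAlt" %in% have))
    msg <- c(msg, "oriented variant sets need the aIsAlt column")
  if (length(msg)) msg else TRUE
})

#' Null-simulation significance thresholds
#'
#' Upper-quantile cutoffs for |Delta SNP-index|, ED^power, the G statistic
#' and -log10 Fisher p, estimated by simulating unlinked null sites for a
#' haploid cross (per pool: carrier count ~ Binomial(poolSize, 1/2), depth
#' ~ Poisson(meanDepth), alt reads ~ Binomial(depth, carrierFreq)).
#'
#' @slot thresholds named numeric: `delta`, `ed`, `g`, `fisher` (the
#'   Fisher cutoff is on the -log10(p) scale).
#' @slot quantile the upper quantile used (default 0.99).
#' @slot nNullSites number of simulated null sites.
#' @slot poolSize,meanDepth pool model parameters used.
#' @slot edPower exponent applied to ED before taking the quantile.
#' @slot seed seed used for the simulation (NA if inherited).
#' @export
setClass("BsaNullThresholds",
  representation(
    thresholds = "numeric",
    quantile   = "numeric",
    nNullSites = "integer",
    poolSize   = "integer",
    meanDepth  = "numeric",
    edPower    = "numeric",
    seed       = "integer"
  )
)

setValidity("BsaNullThresholds", function(object) {
  msg <- character()
  if (!all(c("delta", "ed", "g", "fisher") %in% names(object@thresholds)))
    msg <- c(msg, "thresholds must be named delta, ed, g, fisher")
  if (object@quantile <= 0 || object@quantile >= 1)
    msg <- c(msg, "quantile must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Gene models parsed from GFF3
#'
#' Gene spans plus exon and CDS parts grouped by gene, as read by
#' [readGeneModels()] from a GFF3 file (1-based closed coordinates,
#' phase column honored, both strands supported).
#'
#' @slot genes `GRanges` of gene spans with a `gene_id` column.
#' @slot exons `GRangesList` of exons, one element per gene.
#' @slot cds `GRangesList` of CDS parts (with `phase`), one element per gene.
#' @export
setClass("BsaGeneModels",
  representation(
    genes = "GRanges",
    exons = "GRangesList",
    cds   = "GRangesList"
  )
)

setValidity("BsaGeneModels", function(object) {
  ids <- object@genes$gene_id
  if (is.null(ids)) return("genes must carry a gene_id column")
  if (!all(names(object@cds) %in% ids))
    return("cds list names must be gene_ids")
  TRUE
})

#' Result of a synthetic haploid cross
#'
#' Holds the marker table, progeny haplotypes (parental origin per marker),
#' phenotypes, bulk membership and pooled allele depths produced by
#' [simulateCross()].
#'
#' @slot config the [BsaSimConfig-class] used.
#' @slot markers `GRanges` of marker sites with `ref`/`alt` columns; the
#'   alt allele is the fruiting parent's allele at every marker.
#' @slot originF logical matrix (progeny x markers); `TRUE` where the
#'   progeny haplotype derives from the fruiting parent.
#' @slot phenotypes character vector (`"fruiting"`/`"non_fruiting"`).
#' @slot pools list of two integer vectors of progeny indices (`F`, `N`).
#' @slot poolCounts integer matrix (markers x 4): refF, altF, refN, altN.
#' @slot causalMarker index of the marker resolved as the causal locus.
#' @export
setClass("BsaSimulation",
  representation(
    config       = "BsaSimConfig",
    markers      = "GRanges",
    originF      = "matrix",
    phenotypes   = "character",
    pools        = "list",
    poolCounts   = "matrix",
    causalMarker = "integer"
  )
)
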