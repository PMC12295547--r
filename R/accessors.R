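#' Construct a synthetic-cross configuration
#'
#' Defaults describe the study conditions emulated by the generator: a
#' ~35 Mb genome in 10 scaffolds, 7021 biallelic SNP markers, 156 haploid
#' progeny from two homozygous parents, two phenotype bulks of 24 strains
#' and pooled sequencing at a mean depth of 68.8x. The causal fruiting
#' locus is fully penetrant by default and sits mid-scaffold05.
#'
#' @param nScaffolds,scaffoldLengths genome geometry (bp per scaffold).
#' @param nMarkers number of biallelic SNP markers genome-wide.
#' @param nProgeny number of haploid progeny strains.
#' @param poolSize strains bulked per phenotype pool.
#' @param meanDepth mean pooled sequencing depth per site (Poisson).
#' @param seqError per-read allele flip probability in [0, 0.5).
#' @param recombRate crossovers per Mb per meiosis.
#' @param causalScaffold,causalPos location of the causal locus; it is
#'   resolved to the nearest marker (one marker is forced onto it).
#' @param penetrance probability a fruiting-allele carrier fruits.
#' @param misclassRate probability of phenotyping a strain into the wrong
#'   class.
#' @param seed integer seed for the whole simulation.
#' @return a validated [BsaSimConfig-class] object.
#' @examples
#' cfg <- bsaSimConfig(nMarkers = 100L, seed = 1L)
#' scaffoldNames(cfg)[1:3]
#' @export
bsaSimConfig <- function(nScaffolds = 10L,
                         scaffoldLengths = rep(3.5e6, nScaffolds),
                         nMarkers = 7021L,
                         nProgeny = 156L,
                         poolSize = 24L,
                         meanDepth = 68.8,
                         seqError = 0.001,
                         recombRate = 0.4,
                         causalScaffold = "scaffold05",
                         causalPos = 1750000,
                         penetrance = 1,
                         misclassRate = 0,
                         seed = 1L) {
  new("BsaSimConfig",
      nScaffolds = as.integer(nScaffolds),
      scaffoldLengths = as.numeric(scaffoldLengths),
      nMarkers = as.integer(nMarkers),
      nProgeny = as.integer(nProgeny),
      poolSize = as.integer(poolSize),
      meanDepth = meanDepth,
      seqError = seqError,
      recombRate = recombRate,
      causalScaffold = causalScaffold,
      causalPos = as.numeric(causalPos),
      penetrance = penetrance,
      misclassRate = misclassRate,
      seed = as.integer(seed))
}

#' @rdname BsaSimConfig-class
#' @export
setMethod("scaffoldNames", "BsaSimConfig", function(x) {
  sprintf("scaffold%02d", seq_len(x@nScaffolds))
})

#' @rdname BsaVariantSet-class
#' @export
setMethod("variantRanges", "BsaVariantSet", function(x) x@variants)

#' @rdname BsaVariantSet-class
#' @export
setMethod("isOriented", "BsaVariantSet", function(x) x@oriented)

#' @describeIn BsaVariantSet-class number of variant records.
#' @export
setMethod("length", "BsaVariantSet", function(x) length(x@variants))

#' @describeIn BsaVariantSet-class subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "BsaVariantSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, variants = x@variants[i])
})

#' @rdname BsaNullThresholds-class
#' @export
setMethod("thresholdValues", "BsaNullThresholds", function(x) x@thresholds)

#' @rdname BsaGeneModels-class
#' @export
setMethod("geneRanges", "BsaGeneModels", function(x) x@genes)

#' @rdname BsaGeneModels-class
#' @export
setMethod("cdsByGene", "BsaGeneModels", function(x) x@cds)

#' @rdname BsaGeneModels-class
#' @export
setMethod("exonsByGene", "BsaGeneModels", function(x) x@exons)

#' @describeIn BsaGeneModels-class number of gene models.
#' @export
setMethod("length", "BsaGeneModels", function(x) length(x@genes))

#' @rdname BsaSimulation-class
#' @export
setMethod("markerRanges", "BsaSimulation", function(x) x@markers)

setMethod("show", "BsaSimConfig", function(object) {
  cat("BsaSimConfig:", object@nScaffolds, "scaffolds,",
      format(sum(object@scaffoldLengths), big.mark = ","), "bp genome\n")
  cat("  markers:", object@nMarkers,
      " progeny:", object@nProgeny,
      " pools: 2 x", object@poolSize, "\n")
  cat("  depth:", object@meanDepth, "x  seqError:", object@seqError,
      " recomb:", object@recombRate, "/Mb\n")
  cat("  causal locus:", object@causalScaffold, "@",
      format(object@causalPos, big.mark = ","),
      " penetrance:", object@penetrance,
      " misclass:", object@misclassRate, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "BsaVariantSet", function(object) {
  cat("BsaVariantSet with", length(object), "sites on",
      length(unique(as.character(seqnames(object@variants)))), "scaffolds\n")
  cat("  oriented:", object@oriented, "\n")
  cat("  samples:", paste(names(object@samples), object@samples,
                          sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BsaNullThresholds", function(object) {
  cat(sprintf("BsaNullThresholds (quantile %.3g, %d null sites, pool %d, depth %.3g)\n",
              object@quantile, object@nNullSites, object@poolSize,
              object@meanDepth))
  t <- object@thresholds
  cat(sprintf("  |dSNP-index| >= %.4f  ED^%g >= %.4f  G >= %.4f  -log10(p) >= %.4f\n",
              t["delta"], object@edPower, t["ed"], t["g"], t["fisher"]))
})

setMethod("show", "BsaGeneModels", function(object) {
  cat("BsaGeneModels with", length(object), "genes\n")
  if (length(object) > 0) {
    cat("  ids:", paste(utils::head(object@genes$gene_id, 5), collapse = ", "),
        if (length(object) > 5) "..." else "", "\n")
  }
})

setMethod("show", "BsaSimulation", function(object) {
  ph <- table(object@phenotypes)
  cat("BsaSimulation:", ncol(object@originF), "markers x",
      nrow(object@originF), "progeny\n")
  cat("  phenotypes:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  cm <- object@markers[object@causalMarker]
  cat("  causal marker:", as.character(seqnames(cm)), "@",
      format(start(cm), big.mark = ","), "\n")
})
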