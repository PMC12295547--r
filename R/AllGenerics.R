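#' @rdname BsaSimConfig-class
#' @param x a `BsaSimConfig`.
#' @export
setGeneric("scaffoldNames", function(x) standardGeneric("scaffoldNames"))

#' @rdname BsaVariantSet-class
#' @param x a `BsaVariantSet`.
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname BsaVariantSet-class
#' @export
setGeneric("isOriented", function(x) standardGeneric("isOriented"))

#' @rdname BsaNullThresholds-class
#' @param x a `BsaNullThresholds`.
#' @export
setGeneric("thresholdValues", function(x) standardGeneric("thresholdValues"))

#' @rdname BsaGeneModels-class
#' @param x a `BsaGeneModels`.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname BsaGeneModels-class
#' @export
setGeneric("cdsByGene", function(x) standardGeneric("cdsByGene"))

#' @rdname BsaGeneModels-class
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname BsaSimulation-class
#' @param x a `BsaSimulation`.
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))
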