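#' @importFrom utils write.table read.delim head
NULL

# centralized 1-based-closed -> BED (0-based half-open) conversion
.bedLines <- function(gr, names = ".", scores = 0) {
  if (!length(gr)) return(character(0))
  sprintf("%s\t%d\t%d\t%s\t%s\t.",
          as.character(seqnames(gr)), start(gr) - 1L, end(gr),
          rep_len(names, length(gr)),
          rep_len(format(scores, trim = TRUE), length(gr)))
}

.fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Run the BSA-seq mapping pipeline end-to-end
#'
#' Reads variants, applies the informative-marker filters, polarizes
#' alleles to the fruiting parent, computes the per-site association
#' statistics, smooths them, calibrates null-simulation thresholds,
#' calls per-method significant regions, intersects them into consensus
#' QTL intervals and (when annotation inputs are given) reports candidate
#' genes and ranked coding variants inside them. All outputs are
#' byte-deterministic given the seed.
#'
#' @param vcf path to the input VCF (parents with GT, pools with AD).
#' @param outDir output directory (created if absent).
#' @param gff,fasta optional gene models and genome for the annotation
#'   stage; both are required when `annotate = TRUE`.
#' @param domains optional TSV of conserved-domain intervals
#'   (columns `gene_id`, `chrom`, `start`, `end`).
#' @param sampleNames named character vector binding the four VCF sample
#'   columns (`parentF`, `parentN`, `poolF`, `poolN`).
#' @param poolSize strains per bulk (used by the null model).
#' @param meanDepth expected pool depth; estimated from the data when
#'   `NULL`.
#' @param criteria a [filterCriteria()] object; by default the depth
#'   window is `[10, 3 x meanDepth]`.
#' @param bandwidth,kernel smoothing parameters (see [smoothTrack()]).
#' @param edPower exponent applied to ED before smoothing.
#' @param nNullSites,quantile null-simulation size and confidence level.
#' @param thresholds optional precomputed [BsaNullThresholds-class]
#'   (e.g. shared across replicate runs of one design); when given, the
#'   null simulation is skipped.
#' @param consensusLevel methods required to support a consensus
#'   interval (4 = full consensus).
#' @param maxGap merge gap for region calling; defaults to `bandwidth`.
#' @param annotate run the gene/effect/candidate stage.
#' @param strict error when the consensus is empty.
#' @param seed integer seed for the null simulation.
#' @return (invisibly) list with `stats` (GRanges), `tally`,
#'   `thresholds`, `regions` (list by method), `consensus` (GRanges),
#'   `genes`, `candidates` (data.frame or NULL) and `paths`.
#' @export
runPipeline <- function(vcf, outDir, gff = NULL, fasta = NULL,
                        domains = NULL,
                        sampleNames = c(parentF = "ParentF",
                                        parentN = "ParentN",
                                        poolF = "PoolF", poolN = "PoolN"),
                        poolSize = 24L, meanDepth = NULL,
                        criteria = NULL, bandwidth = 1e6,
                        kernel = "tricube", edPower = 4,
                        nNullSites = 100000L, quantile = 0.99,
                        thresholds = NULL,
                        consensusLevel = 4L, maxGap = bandwidth,
                        annotate = !is.null(gff), strict = FALSE,
                        seed = 1L) {
  # pre-flight checks before any computation
  for (p in c(vcf, gff, fasta, domains)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (annotate && (is.null(gff) || is.null(fasta)))
    stop("annotation requested but gff/fasta not provided")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  set.seed(seed)

  vs <- readPoolVariants(vcf, sampleNames["parentF"],
                         sampleNames["parentN"], sampleNames["poolF"],
                         sampleNames["poolN"])
  if (length(vs) == 0L) stop("no variants in input VCF")
  mcAll <- mcols(vs@variants)
  obsDepth <- mean(c(mcAll$adF1 + mcAll$adF2, mcAll$adN1 + mcAll$adN2),
                   na.rm = TRUE)
  if (is.null(meanDepth)) meanDepth <- obsDepth
  if (is.null(criteria))
    criteria <- filterCriteria(minPoolDepth = 10L,
                               maxPoolDepth = ceiling(3 * meanDepth))
  flt <- filterVariants(vs, criteria)
  kept <- polarizeVariants(flt$kept)
  if (length(kept) == 0L) stop("no variants survive the filters")
  stats <- siteStatistics(kept, edPower = edPower)

  thr <- if (is.null(thresholds)) {
    nullThresholds(poolSize, meanDepth, nNullSites = nNullSites,
                   quantile = quantile, edPower = edPower)
  } else thresholds
  stopifnot(is(thr, "BsaNullThresholds"))
  tv <- thresholdValues(thr)

  sm <- smoothTrack(stats,
                    cbind(delta = stats$deltaSnpIndex, ed = stats$edPow,
                          g = stats$g, fisher = -log10(stats$fisherP)),
                    bandwidth, kernel)
  tracks <- list(delta_snp_index = abs(sm[, "delta"]), ed = sm[, "ed"],
                 g = sm[, "g"], fisher = sm[, "fisher"])
  cuts <- c(delta_snp_index = unname(tv["delta"]), ed = unname(tv["ed"]),
            g = unname(tv["g"]), fisher = unname(tv["fisher"]))
  regions <- lapply(names(tracks), function(m)
    callRegions(stats, tracks[[m]], cuts[[m]], maxGap = maxGap,
                method = m))
  names(regions) <- names(tracks)
  consensus <- consensusIntervals(regions, consensusLevel)
  if (strict && length(consensus) == 0L)
    stop("no consensus QTL interval at level ", consensusLevel)

  genes <- NULL
  candidates <- NULL
  if (annotate) {
    models <- readGeneModels(gff)
    genome <- readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    domTab <- if (!is.null(domains)) read.delim(domains) else NULL
    hitModels <- list()
    for (i in seq_along(consensus)) {
      chrom <- as.character(seqnames(consensus)[i])
      if (!(chrom %in% unique(as.character(seqnames(geneRanges(models))))))
        next
      hitModels[[i]] <- genesInInterval(models, consensus[i])
    }
    geneIds <- unique(unlist(lapply(hitModels, function(m)
      if (!is.null(m)) geneRanges(m)$gene_id)))
    genes <- geneRanges(models)[geneRanges(models)$gene_id %in% geneIds]
    assign <- variantsInGenes(stats, models)
    inCds <- which(assign$feature == "CDS" & assign$gene_id %in% geneIds)
    if (length(inCds)) {
      eff <- lapply(inCds, function(i) {
        classifyEffect(assign$chrom[i], assign$pos[i],
                       # effect is called on the A/other alleles as REF/ALT
                       assign$ref[i], assign$alt[i], models,
                       assign$gene_id[i], genome)
      })
      mcK <- mcols(kept@variants)
      key <- paste(as.character(seqnames(kept@variants)),
                   start(kept@variants))
      idx <- match(paste(assign$chrom[inCds], assign$pos[inCds]), key)
      annotated <- data.frame(
        assign[inCds, c("chrom", "pos", "ref", "alt", "gene_id",
                        "cdsPos")],
        effect = vapply(eff, `[[`, character(1), "effect"),
        codon = vapply(eff, `[[`, integer(1), "codon"),
        refAa = vapply(eff, `[[`, character(1), "refAa"),
        altAa = vapply(eff, `[[`, character(1), "altAa"),
        gtF = mcK$gtF[idx], gtN = mcK$gtN[idx],
        snpIndexF = stats$snpIndexF[idx],
        snpIndexN = stats$snpIndexN[idx],
        deltaSnpIndex = stats$deltaSnpIndex[idx],
        fisherP = stats$fisherP[idx])
      candidates <- candidateFilter(annotated, domains = domTab)
    } else {
      candidates <- candidateFilter(data.frame(
        chrom = character(0), pos = integer(0), gene_id = character(0),
        effect = character(0), gtF = character(0), gtN = character(0),
        snpIndexF = numeric(0), snpIndexN = numeric(0),
        deltaSnpIndex = numeric(0), fisherP = numeric(0)))
    }
  }

  # ---- outputs ----
  paths <- c(stats = file.path(outDir, "site_stats.tsv"),
             consensus = file.path(outDir, "consensus.bed"),
             log = file.path(outDir, "run_log.txt"))
  statsTab <- data.frame(
    chrom = as.character(seqnames(stats)), pos = start(stats),
    ref = stats$ref, alt = stats$alt,
    snpIndexF = .fmt(stats$snpIndexF), snpIndexN = .fmt(stats$snpIndexN),
    deltaSnpIndex = .fmt(stats$deltaSnpIndex), ed = .fmt(stats$ed),
    edPow = .fmt(stats$edPow), g = .fmt(stats$g),
    fisherP = .fmt(stats$fisherP),
    smoothedAbsDelta = .fmt(tracks$delta_snp_index),
    smoothedEdPow = .fmt(tracks$ed), smoothedG = .fmt(tracks$g),
    smoothedLog10FisherP = .fmt(tracks$fisher))
  write.table(statsTab, paths["stats"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (m in names(regions)) {
    p <- file.path(outDir, sprintf("regions_%s.bed", m))
    writeLines(.bedLines(regions[[m]], names = m,
                         scores = .fmt(regions[[m]]$peakValue)), p)
    paths[paste0("regions_", m)] <- p
  }
  writeLines(.bedLines(consensus,
                       names = sprintf("consensus_level%d", consensusLevel)),
             paths["consensus"])
  if (!is.null(candidates)) {
    paths["candidates"] <- file.path(outDir, "candidates.tsv")
    ct <- candidates
    for (col in c("snpIndexF", "snpIndexN", "deltaSnpIndex", "fisherP"))
      if (col %in% names(ct)) ct[[col]] <- .fmt(ct[[col]])
    write.table(ct, paths["candidates"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  logLines <- c(
    "bsamap run log",
    sprintf("vcf: %s", basename(vcf)),
    sprintf("samples: %s", paste(names(sampleNames), sampleNames,
                                 sep = "=", collapse = " ")),
    sprintf("seed: %d", seed),
    sprintf("pool_size: %d  mean_depth: %s (observed %s)",
            poolSize, .fmt(meanDepth), .fmt(obsDepth)),
    sprintf("filter: min_depth=%s max_depth=%s snps_only=%s informative_parents=%s",
            criteria$minPoolDepth, criteria$maxPoolDepth,
            criteria$requireSnp, criteria$requireInformativeParents),
    sprintf("filter tally: input=%d kept=%d %s", length(vs), length(kept),
            paste(names(flt$tally), flt$tally, sep = "=", collapse = " ")),
    sprintf("smoothing: kernel=%s bandwidth=%s bp  ed_power=%s  max_gap=%s bp",
            kernel, .fmt(bandwidth), .fmt(edPower), .fmt(maxGap)),
    sprintf("null simulation: n=%d quantile=%s%s", thr@nNullSites,
            .fmt(thr@quantile),
            if (is.null(thresholds)) "" else " (precomputed)"),
    sprintf("thresholds: |delta|>=%s ed^%s>=%s G>=%s -log10p>=%s",
            .fmt(tv["delta"]), .fmt(edPower), .fmt(tv["ed"]),
            .fmt(tv["g"]), .fmt(tv["fisher"])),
    sprintf("regions: %s", paste(names(regions),
                                 vapply(regions, length, integer(1)),
                                 sep = "=", collapse = " ")),
    sprintf("consensus (level %d): %d interval(s)", consensusLevel,
            length(consensus)),
    if (length(consensus))
      sprintf("  %s:%d-%d [%s]", as.character(seqnames(consensus)),
              start(consensus), end(consensus),
              vapply(consensus$supportingMethods, paste, character(1),
                     collapse = ",")),
    if (!is.null(candidates))
      sprintf("candidates: %d (top: %s)", nrow(candidates),
              if (nrow(candidates)) paste0(candidates$gene_id[1], " ",
                                           candidates$chrom[1], ":",
                                           candidates$pos[1])
              else "none"))
  writeLines(logLines, paths["log"])
  invisible(list(stats = stats, tally = flt$tally, thresholds = thr,
                 regions = regions, consensus = consensus, genes = genes,
                 candidates = candidates, paths = paths))
}
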