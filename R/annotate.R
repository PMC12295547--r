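#' @importFrom Biostrings readDNAStringSet subseq
#' @importFrom rtracklayer import
NULL

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (1-based closed coordinates, both
#' strands) and groups exon and CDS parts by gene. Exons or CDS parts
#' whose `Parent` is a transcript are resolved to the transcript's gene.
#'
#' @param gffPath path to a GFF3 file.
#' @return a [BsaGeneModels-class].
#' @export
readGeneModels <- function(gffPath) {
  gff <- import(gffPath)
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  geneIds <- as.character(genes$ID)
  mcols(genes) <- DataFrame(gene_id = geneIds)
  tx <- gff[type %in% c("mRNA", "transcript")]
  tx2gene <- structure(vapply(tx$Parent, `[`, character(1), 1),
                       names = as.character(tx$ID))
  toGene <- function(parent) {
    p <- vapply(parent, `[`, character(1), 1)
    ifelse(p %in% names(tx2gene), unname(tx2gene[p]), p)
  }
  grab <- function(what) {
    feat <- gff[type == what]
    gid <- toGene(feat$Parent)
    keepCols <- if (what == "CDS") DataFrame(phase = feat$phase)
                else DataFrame(matrix(nrow = length(feat), ncol = 0))
    mcols(feat) <- keepCols
    lst <- split(feat, factor(gid, levels = geneIds))
    GRangesList(lapply(lst, sort, ignore.strand = TRUE))
  }
  new("BsaGeneModels", genes = sort(genes, ignore.strand = TRUE),
      exons = grab("exon"), cds = grab("CDS"))
}

#' Genes overlapping a genomic interval
#'
#' @param models a [BsaGeneModels-class].
#' @param interval a length-1 `GRanges` (1-based closed).
#' @return a `BsaGeneModels` restricted to genes whose span overlaps the
#'   interval by at least 1 bp, in positional order.
#' @export
genesInInterval <- function(models, interval) {
  stopifnot(is(models, "BsaGeneModels"), length(interval) == 1L)
  chrom <- as.character(seqnames(interval))
  known <- unique(as.character(seqnames(models@genes)))
  if (!(chrom %in% known))
    stop("unknown scaffold in interval: ", chrom)
  keep <- as.character(seqnames(models@genes)) == chrom &
    start(models@genes) <= end(interval) &
    end(models@genes) >= start(interval)
  ids <- models@genes$gene_id[keep]
  new("BsaGeneModels", genes = models@genes[keep],
      exons = models@exons[ids], cds = models@cds[ids])
}

#' Assign variants to gene features
#'
#' Labels each variant with the gene and feature it falls in (`"CDS"`,
#' `"intron"` for positions inside a gene span but outside its CDS, or
#' `"intergenic"`), using 1-based closed coordinates and respecting
#' strand for the CDS-relative offset.
#'
#' @param variants `GRanges` with `ref`/`alt` metadata columns (e.g.
#'   from [siteStatistics()] or `variantRanges()`).
#' @param models a [BsaGeneModels-class].
#' @return `data.frame` with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, `gene_id`, `feature`, `cdsPos` (NA outside CDS).
#' @export
variantsInGenes <- function(variants, models) {
  chrom <- as.character(seqnames(variants))
  pos <- start(variants)
  n <- length(variants)
  geneId <- rep(NA_character_, n)
  feature <- rep("intergenic", n)
  cdsPos <- rep(NA_integer_, n)
  genes <- models@genes
  hits <- suppressWarnings(
    findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)), genes,
                 ignore.strand = TRUE))
  first <- !duplicated(queryHits(hits))
  for (h in which(first)) {
    i <- queryHits(hits)[h]
    gid <- genes$gene_id[subjectHits(hits)[h]]
    geneId[i] <- gid
    cp <- .genomicToCds(models@cds[[gid]], chrom[i], pos[i])
    if (!is.na(cp)) {
      feature[i] <- "CDS"
      cdsPos[i] <- cp
    } else {
      feature[i] <- "intron"
    }
  }
  data.frame(chrom = chrom, pos = pos,
             ref = mcols(variants)$ref, alt = mcols(variants)$alt,
             gene_id = geneId, feature = feature, cdsPos = cdsPos,
             stringsAsFactors = FALSE)
}

# spliced CDS sequence of one gene (transcript orientation)
.splicedCds <- function(cdsParts, genome) {
  parts <- .transcriptOrder(cdsParts)
  pieces <- vapply(seq_along(parts), function(j) {
    chrom <- as.character(seqnames(parts)[j])
    s <- as.character(subseq(genome[[chrom]], start(parts)[j],
                             end(parts)[j]))
    if (as.character(strand(parts)[j]) == "-") .revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon is excluded from the
#' returned protein. A CDS not starting with ATG triggers a warning;
#' internal stop codons and lengths not divisible by three are errors.
#'
#' @param cds a character string or `DNAString` of coding sequence.
#' @return the protein as a single character string.
#' @examples
#' translateCds("ATGTGA")  # "M"
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1] != "ATG")
    warning("CDS does not start with ATG")
  aa <- unname(GENETIC_CODE[codons])
  if (anyNA(aa))
    stop("non-ACGT codon at codon index ", which(is.na(aa))[1])
  stops <- which(aa == "*")
  if (any(stops < length(aa)))
    stop("internal stop codon at codon index ", stops[stops < length(aa)][1])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Classify the coding effect of a variant
#'
#' Splices the gene's CDS parts in transcript order (reverse-complemented
#' on the minus strand), locates the variant's CDS-relative position
#' (CDS position 121 is codon 41, position 1), substitutes the alternate
#' base into its codon and translates both codons with the standard
#' genetic code.
#'
#' @param chrom,pos variant location (1-based).
#' @param refAllele,altAllele single-base alleles on the plus strand (as
#'   in the VCF).
#' @param models a [BsaGeneModels-class].
#' @param geneId gene whose CDS contains the variant.
#' @param genome a named `DNAStringSet` of scaffold sequences.
#' @return list with `effect` (`"synonymous"`, `"missense"`,
#'   `"nonsense"`, `"start_loss"` or `"other"`), `codon`, `refAa`,
#'   `altAa` and `cdsPos`.
#' @examples
#' \dontrun{classifyEffect("scaffold05", 1750000, "T", "G", models,
#'                          "syng02", genome)}
#' @export
classifyEffect <- function(chrom, pos, refAllele, altAllele, models,
                           geneId, genome) {
  cdsParts <- models@cds[[geneId]]
  if (is.null(cdsParts) || !length(cdsParts))
    stop("gene ", geneId, " has no CDS features")
  cdsPos <- .genomicToCds(cdsParts, chrom, pos)
  if (is.na(cdsPos))
    stop("variant ", chrom, ":", pos, " is not inside the CDS of ", geneId)
  genomeBase <- as.character(subseq(genome[[chrom]], pos, pos))
  if (genomeBase != refAllele)
    stop(sprintf("REF mismatch at %s:%d: VCF says %s, genome says %s",
                 chrom, pos, refAllele, genomeBase))
  minus <- as.character(strand(cdsParts)[1]) == "-"
  altTx <- if (minus) .revcomp(altAllele) else altAllele
  cds <- .splicedCds(cdsParts, genome)
  if (nchar(cds) %% 3L != 0L)
    warning("CDS length of ", geneId, " is not divisible by 3; gene flagged")
  cdsPos <- as.integer(cdsPos)
  codon <- (cdsPos - 1L) %/% 3L + 1L
  within <- (cdsPos - 1L) %% 3L + 1L
  refCodon <- substring(cds, (codon - 1L) * 3L + 1L, codon * 3L)
  altCodon <- refCodon
  substring(altCodon, within, within) <- altTx
  refAa <- unname(GENETIC_CODE[refCodon])
  altAa <- unname(GENETIC_CODE[altCodon])
  effect <- if (refAa == altAa) "synonymous"
    else if (altAa == "*") "nonsense"
    else if (codon == 1L && refAa == "M") "start_loss"
    else if (refAa == "*") "other"
    else "missense"
  list(effect = effect, codon = codon, refAa = refAa, altAa = altAa,
       cdsPos = cdsPos)
}

#' Filter and rank candidate causal variants
#'
#' Keeps effect-annotated variants that (a) alter the protein (missense,
#' nonsense or start-loss), (b) have opposite-homozygous parental
#' genotypes, and (c) show pool allele frequencies concordant with the
#' parents (fruiting-pool SNP-index above 1/2, non-fruiting below 1/2 on
#' the polarized orientation). Candidates are ranked by conserved-domain
#' membership (a user-supplied interval annotation, not computed), then
#' |Delta SNP-index| (descending), then Fisher p (ascending), then
#' position.
#'
#' @param annotated `data.frame` of variants with columns `chrom`, `pos`,
#'   `gene_id`, `effect`, `gtF`, `gtN`, `snpIndexF`, `snpIndexN`,
#'   `deltaSnpIndex`, `fisherP`.
#' @param domains optional `data.frame` of conserved-domain intervals
#'   with columns `chrom`, `start`, `end`.
#' @return the kept rows, ranked, with `inDomain` and `rank` columns.
#' @export
candidateFilter <- function(annotated, domains = NULL) {
  stopifnot(is.data.frame(annotated))
  keep <- annotated$effect %in% c("missense", "nonsense", "start_loss") &
    ((annotated$gtF == "hom_ref" & annotated$gtN == "hom_alt") |
     (annotated$gtF == "hom_alt" & annotated$gtN == "hom_ref")) &
    annotated$snpIndexF > 0.5 & annotated$snpIndexN < 0.5
  out <- annotated[keep, , drop = FALSE]
  inDomain <- rep(FALSE, nrow(out))
  if (!is.null(domains) && nrow(out)) {
    for (j in seq_len(nrow(domains))) {
      inDomain <- inDomain | (out$chrom == domains$chrom[j] &
                                out$pos >= domains$start[j] &
                                out$pos <= domains$end[j])
    }
  }
  out$inDomain <- inDomain
  o <- order(-out$inDomain, -abs(out$deltaSnpIndex), out$fisherP,
             out$chrom, out$pos)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-strain genotype-phenotype concordance at a site
#'
#' Fraction of strains whose allele at the site matches the allele
#' expected from their phenotype (fruiting strains carry the fruiting
#' parent's allele), with the 2x2 contingency table for reporting.
#'
#' @param genotypes named character vector per strain: `"F"` (fruiting
#'   parent's allele) or `"N"`.
#' @param phenotypes named character vector per strain: `"fruiting"` or
#'   `"non_fruiting"`. Names must match `genotypes`.
#' @return list with `concordance` (fraction) and `table` (2x2 counts).
#' @export
genotypeConcordance <- function(genotypes, phenotypes) {
  if (!is.null(names(genotypes)) && !is.null(names(phenotypes))) {
    onlyG <- setdiff(names(genotypes), names(phenotypes))
    onlyP <- setdiff(names(phenotypes), names(genotypes))
    if (length(onlyG) || length(onlyP))
      stop("strains present in only one input: ",
           paste(c(onlyG, onlyP), collapse = ", "))
    phenotypes <- phenotypes[names(genotypes)]
  } else if (length(genotypes) != length(phenotypes)) {
    stop("genotypes and phenotypes must cover the same strains")
  }
  expected <- ifelse(phenotypes == "fruiting", "F", "N")
  tab <- table(genotype = factor(genotypes, levels = c("F", "N")),
               phenotype = factor(phenotypes,
                                  levels = c("fruiting", "non_fruiting")))
  list(concordance = mean(genotypes == expected), table = tab)
}
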