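#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet GENETIC_CODE
NULL

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

# random stop-free CDS of nCodons codons (incl. ATG start and TAA stop);
# fixedCodons: named vector, names = codon numbers to pin
.randomCds <- function(nCodons, fixedCodons = NULL) {
  codons <- names(GENETIC_CODE)
  sense <- setdiff(codons, .STOPS)
  body <- sample(sense, nCodons - 2L, replace = TRUE)
  cds <- c("ATG", body, "TAA")
  if (!is.null(fixedCodons))
    cds[as.integer(names(fixedCodons))] <- fixedCodons
  paste(cds, collapse = "")
}

# Geometry of the five synthetic candidate genes tiling the causal locus.
# Gene 2 mirrors the mapped candidate: 7 exons, 6 introns, 2193 bp span,
# 1710 bp CDS, causal SNP at CDS position 121 (codon 41, first base).
.geneLayout <- function(config) {
  cp <- config@causalPos
  causalStart <- cp - 280   # 60 + 80 + 45 + 80 + 15 upstream CDS/intron bases
  g <- list(
    list(id = "syng01", strand = "+", exonW = c(300L, 300L), intronW = 100L),
    list(id = "syng02", strand = "+",
         exonW = c(60L, 45L, 300L, 400L, 400L, 300L, 205L),
         intronW = c(80L, 80L, 80L, 80L, 80L, 83L)),
    list(id = "syng03", strand = "+", exonW = c(450L, 450L), intronW = 120L),
    list(id = "syng04", strand = "-", exonW = c(300L, 303L), intronW = 110L),
    list(id = "syng05", strand = "+", exonW = c(600L, 399L), intronW = 130L)
  )
  span <- function(x) sum(x$exonW) + sum(x$intronW)
  gap <- 200L
  g[[2]]$start <- causalStart
  g[[1]]$start <- causalStart - gap - span(g[[1]])
  at <- causalStart + span(g[[2]]) + gap
  for (i in 3:5) {
    g[[i]]$start <- at
    at <- at + span(g[[i]]) + gap
  }
  scafLen <- config@scaffoldLengths[match(config@causalScaffold,
                                          scaffoldNames(config))]
  if (g[[1]]$start < 1 || at - gap > scafLen)
    stop("causal locus too close to a scaffold edge to place the gene fixture")
  g
}

# exon coordinates (genomic order) for one gene layout entry
.geneExons <- function(gene) {
  k <- length(gene$exonW)
  wGenomic <- if (gene$strand == "-") rev(gene$exonW) else gene$exonW
  iGenomic <- if (gene$strand == "-") rev(gene$intronW) else gene$intronW
  starts <- integer(k)
  at <- gene$start
  for (j in seq_len(k)) {
    starts[j] <- at
    at <- at + wGenomic[j] + if (j < k) iGenomic[j] else 0L
  }
  IRanges(starts, width = wGenomic)
}

# genomic base vector for the whole gene span, embedding the CDS
.geneSequence <- function(gene, cds) {
  k <- length(gene$exonW)
  chunks <- substring(cds, cumsum(c(1L, gene$exonW))[seq_len(k)],
                      cumsum(gene$exonW))
  exons <- .geneExons(gene)
  spanLen <- max(end(exons)) - gene$start + 1L
  seqv <- sample(.BASES, spanLen, replace = TRUE)
  # transcript order: left-to-right on +, right-to-left (revcomp) on -
  ord <- if (gene$strand == "-") rev(seq_len(k)) else seq_len(k)
  for (j in seq_len(k)) {
    piece <- chunks[ord[j]]
    if (gene$strand == "-") piece <- .revcomp(piece)
    rel <- (start(exons)[j] - gene$start + 1L):(end(exons)[j] - gene$start + 1L)
    seqv[rel] <- strsplit(piece, "")[[1]]
  }
  seqv
}

.gffAttr <- function(...) paste(..., sep = ";")

# GFF3 rows (character vector) for one gene
.geneGffLines <- function(gene, chrom) {
  exons <- .geneExons(gene)
  gStart <- min(start(exons)); gEnd <- max(end(exons))
  tid <- paste0(gene$id, ".t1")
  lines <- c(
    paste(chrom, "bsamap", "gene", gStart, gEnd, ".", gene$strand, ".",
          sprintf("ID=%s;Name=%s", gene$id, gene$id), sep = "\t"),
    paste(chrom, "bsamap", "mRNA", gStart, gEnd, ".", gene$strand, ".",
          sprintf("ID=%s;Parent=%s", tid, gene$id), sep = "\t")
  )
  # CDS parts in transcript order for phase bookkeeping
  k <- length(exons)
  tOrd <- if (gene$strand == "-") rev(seq_len(k)) else seq_len(k)
  cum <- 0L
  phase <- integer(k)
  for (j in seq_len(k)) {
    phase[tOrd[j]] <- (3L - cum %% 3L) %% 3L
    cum <- cum + width(exons)[tOrd[j]]
  }
  for (j in seq_len(k)) {
    lines <- c(lines,
      paste(chrom, "bsamap", "exon", start(exons)[j], end(exons)[j], ".",
            gene$strand, ".", sprintf("Parent=%s", tid), sep = "\t"),
      paste(chrom, "bsamap", "CDS", start(exons)[j], end(exons)[j], ".",
            gene$strand, phase[j],
            sprintf("ID=cds:%s;Parent=%s", gene$id, tid), sep = "\t"))
  }
  lines
}

#' Write the synthetic dataset to standard-format files
#'
#' Emits a VCF 4.2 (two parent sample columns with GT, two pool columns
#' with AD and DP), a GFF3 with five multi-exon gene models tiling the
#' causal locus (the causal gene has 7 exons, a 1710 bp CDS and the
#' causal T-to-G SNP at CDS position 121), a genome FASTA consistent with
#' the VCF REF alleles and GFF coordinates, a tab-separated phenotype
#' table, and a conserved-domain annotation track (synthetic) covering
#' CDS positions 61-210 of the causal gene. REF/ALT bases of markers are
#' harmonized with the generated genome; pool allele depths are written
#' exactly as simulated. Output is byte-deterministic given the
#' configuration seed.
#'
#' @param sim a [BsaSimulation-class] from [simulateCross()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths (`vcf`, `gff`, `fasta`,
#'   `phenotypes`, `domains`).
#' @export
writeDataset <- function(sim, dir) {
  stopifnot(is(sim, "BsaSimulation"))
  config <- sim@config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "genome.fa"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             domains = file.path(dir, "domains.tsv"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config@seed + 1L)

  sn <- scaffoldNames(config)
  layout <- .geneLayout(config)
  # pin codon 41 of the causal gene to TCT: CDS 121 is its first base (T)
  cdsSeqs <- lapply(layout, function(g) {
    .randomCds(sum(g$exonW) %/% 3L,
               fixedCodons = if (g$id == "syng02") c("41" = "TCT"))
  })

  # genome: random bases (as indices into .BASES for speed), gene
  # fixtures embedded on the causal scaffold
  genome <- vector("list", length(sn))
  names(genome) <- sn
  for (i in seq_along(sn)) {
    seqi <- sample.int(4L, config@scaffoldLengths[i], replace = TRUE)
    if (sn[i] == config@causalScaffold) {
      for (j in seq_along(layout)) {
        g <- layout[[j]]
        gs <- .geneSequence(g, cdsSeqs[[j]])
        seqi[g$start:(g$start + length(gs) - 1L)] <- match(gs, .BASES)
      }
    }
    genome[[i]] <- seqi
  }

  # harmonize marker REF with the genome; keep ALT distinct from REF
  markers <- sim@markers
  chrom <- as.character(seqnames(markers))
  pos <- start(markers)
  ref <- character(length(markers))
  for (i in seq_along(sn)) {
    idx <- which(chrom == sn[i])
    ref[idx] <- .BASES[genome[[i]][pos[idx]]]
  }
  alt <- mcols(markers)$alt
  clash <- alt == ref
  alt[clash] <- .BASES[(match(ref[clash], .BASES) %% 4L) + 1L]
  if (length(sim@causalMarker) == 1L && !is.na(sim@causalMarker)) {
    # causal marker: genome carries codon-41 "T"; the fruiting allele is G
    alt[sim@causalMarker] <- "G"
  }

  # --- VCF ---
  vcfHeader <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap-simulateCross",
    sprintf("##contig=<ID=%s,length=%d>", sn,
            as.integer(config@scaffoldLengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ParentF", "ParentN", "PoolF", "PoolN", sep = "\t"))
  pc <- sim@poolCounts
  body <- if (length(markers)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t1|1:.:.\t0|0:.:.\t./.:%d,%d:%d\t./.:%d,%d:%d",
            chrom, pos, ref, alt,
            pc[, "refF"], pc[, "altF"], pc[, "refF"] + pc[, "altF"],
            pc[, "refN"], pc[, "altN"], pc[, "refN"] + pc[, "altN"])
  } else character(0)
  writeLines(c(vcfHeader, body), paths["vcf"])

  # --- GFF3 ---
  gffLines <- c("##gff-version 3",
                unlist(lapply(layout, .geneGffLines,
                              chrom = config@causalScaffold)))
  writeLines(gffLines, paths["gff"])

  # --- FASTA (60-column wrap) ---
  baseCodes <- utf8ToInt("ACGT")
  dss <- DNAStringSet(vapply(genome, function(seqi)
    intToUtf8(baseCodes[seqi]), character(1)))
  names(dss) <- sn
  writeXStringSet(dss, paths["fasta"], width = 60L)

  # --- phenotype table ---
  ids <- sprintf("strain%03d", seq_along(sim@phenotypes))
  writeLines(c("strain\tphenotype",
               paste(ids, sim@phenotypes, sep = "\t")),
             paths["phenotypes"])

  # --- synthetic conserved-domain track (CDS 61..210 of the causal gene) ---
  causal <- layout[[2]]
  exons <- .geneExons(causal)
  cdsParts <- GRanges(config@causalScaffold, exons, strand = causal$strand)
  dStart <- .cdsToGenomic(cdsParts, 61L)
  dEnd <- .cdsToGenomic(cdsParts, 210L)
  writeLines(c("gene_id\tchrom\tstart\tend\tname",
               sprintf("%s\t%s\t%d\t%d\tsynDomain", causal$id,
                       config@causalScaffold, min(dStart, dEnd),
                       max(dStart, dEnd))),
             paths["domains"])
  paths
}
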