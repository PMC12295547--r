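# Independent oracles and fixture builders used across the suite.

# Brute-force two-tailed Fisher p: enumerate the full hypergeometric
# support with plain choose() arithmetic (independent of dhyper and of
# the package implementation).
oracleFisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  lo <- max(0L, k - m2); hi <- min(k, m1)
  supp <- lo:hi
  pt <- choose(m1, supp) * choose(m2, k - supp) / choose(N, k)
  obs <- pt[a - lo + 1L]
  min(1, sum(pt[pt <= obs * (1 + 1e-7)]))
}

# G via the entropy decomposition 2(sum n log n - sum r log r
#   - sum c log c + N log N), an algebraically different route.
oracleG <- function(tab) {
  xlx <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  2 * (xlx(tab) - xlx(rowSums(tab)) - xlx(colSums(tab)) + xlx(sum(tab)))
}

# Per-bp brute-force consensus: bp positions covered by >= level methods.
oracleConsensusBp <- function(regionList, level, maxBp) {
  cov <- integer(maxBp)
  for (regs in regionList) {
    hit <- logical(maxBp)
    if (!is.null(regs)) for (i in seq_len(nrow(regs)))
      hit[regs$start[i]:regs$end[i]] <- TRUE
    cov <- cov + hit
  }
  which(cov >= level)
}

# Small fast simulation config for unit tests.
smallSimConfig <- function(seed = 1L, ...) {
  args <- list(nScaffolds = 2L, scaffoldLengths = c(4e5, 4e5),
               nMarkers = 200L, nProgeny = 60L, poolSize = 10L,
               meanDepth = 40, causalScaffold = "scaffold01",
               causalPos = 200000, seed = seed)
  do.call(bsaSimConfig, utils::modifyList(args, list(...)))
}

# Write a small VCF with given data lines (single scaffold header).
writeTestVcf <- function(lines, path = tempfile(fileext = ".vcf"),
                         contigs = c(s1 = 1000000L, s2 = 1000000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ParentF", "ParentN", "PoolF", "PoolN", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

# One VCF data line with GT-only parents and AD/DP pools.
vcfLine <- function(chrom, pos, ref, alt, gtF, gtN, adF, adN) {
  sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s:.:.\t%s:.:.\t./.:%s:%d\t./.:%s:%d",
          chrom, pos, ref, alt, gtF, gtN,
          paste(adF, collapse = ","), sum(adF),
          paste(adN, collapse = ","), sum(adN))
}

# Two-strand gene fixture built in code: gene models (GFF3), a matching
# 2 kb genome (FASTA) and the designed CDS sequences.
# gA (+): exons 101-160, 201-245, 301-600  -> CDS 405 bp
# gB (-): exons 1001-1240, 1321-1482       -> CDS 402 bp
makeGeneFixture <- function(seed = 42L, dir = tempfile()) {
  dir.create(dir)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  mkCds <- function(nCodons)
    paste(c("ATG", sample(sense, nCodons - 2L, replace = TRUE), "TAA"),
          collapse = "")
  cdsA <- mkCds(135L)  # 405 nt
  cdsB <- mkCds(134L)  # 402 nt
  genome <- sample(bases, 2000L, replace = TRUE)
  put <- function(genome, at, s) {
    genome[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    genome
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome <- put(genome, 101L, substr(cdsA, 1, 60))
  genome <- put(genome, 201L, substr(cdsA, 61, 105))
  genome <- put(genome, 301L, substr(cdsA, 106, 405))
  genome <- put(genome, 1321L, rc(substr(cdsB, 1, 162)))    # tx exon 1
  genome <- put(genome, 1001L, rc(substr(cdsB, 163, 402)))  # tx exon 2
  fasta <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(dss) <- "s1"
  Biostrings::writeXStringSet(dss, fasta, width = 60L)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
    "s1\ttest\tgene\t101\t600\t.\t+\t.\tID=gA;Name=gA",
    "s1\ttest\tmRNA\t101\t600\t.\t+\t.\tID=gA.t1;Parent=gA",
    "s1\ttest\texon\t101\t160\t.\t+\t.\tParent=gA.t1",
    "s1\ttest\tCDS\t101\t160\t.\t+\t0\tID=cds:gA;Parent=gA.t1",
    "s1\ttest\texon\t201\t245\t.\t+\t.\tParent=gA.t1",
    "s1\ttest\tCDS\t201\t245\t.\t+\t0\tID=cds:gA;Parent=gA.t1",
    "s1\ttest\texon\t301\t600\t.\t+\t.\tParent=gA.t1",
    "s1\ttest\tCDS\t301\t600\t.\t+\t0\tID=cds:gA;Parent=gA.t1",
    "s1\ttest\tgene\t1001\t1482\t.\t-\t.\tID=gB;Name=gB",
    "s1\ttest\tmRNA\t1001\t1482\t.\t-\t.\tID=gB.t1;Parent=gB",
    "s1\ttest\texon\t1001\t1240\t.\t-\t.\tParent=gB.t1",
    "s1\ttest\tCDS\t1001\t1240\t.\t-\t0\tID=cds:gB;Parent=gB.t1",
    "s1\ttest\texon\t1321\t1482\t.\t-\t.\tParent=gB.t1",
    "s1\ttest\tCDS\t1321\t1482\t.\t-\t0\tID=cds:gB;Parent=gB.t1"), gff)
  list(gff = gff, fasta = fasta, genome = dss, cdsA = cdsA, cdsB = cdsB)
}

md5OfFiles <- function(paths) unname(tools::md5sum(sort(paths)))
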