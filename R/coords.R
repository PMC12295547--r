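# Shared CDS <-> genome coordinate arithmetic. GFF coordinates are
# 1-based closed; CDS positions are 1-based along the spliced transcript
# (position 1 = first base of the start codon).

.transcriptOrder <- function(cdsParts) {
  minus <- as.character(strand(cdsParts)[1]) == "-"
  o <- order(start(cdsParts), decreasing = minus)
  cdsParts[o]
}

# genomic position of a 1-based spliced-CDS coordinate
.cdsToGenomic <- function(cdsParts, cdsPos) {
  parts <- .transcriptOrder(cdsParts)
  w <- width(parts)
  ends <- cumsum(w)
  j <- which(cdsPos <= ends)[1]
  if (is.na(j)) stop("CDS position beyond spliced CDS length")
  off <- cdsPos - c(0, ends)[j] - 1L   # 0-based offset within part j
  if (as.character(strand(parts)[j]) == "-")
    end(parts)[j] - off
  else
    start(parts)[j] + off
}

# spliced-CDS coordinate of a genomic position, NA if not in the CDS
.genomicToCds <- function(cdsParts, chrom, pos) {
  parts <- .transcriptOrder(cdsParts)
  w <- width(parts)
  before <- c(0, cumsum(w))
  for (j in seq_along(parts)) {
    if (as.character(seqnames(parts)[j]) != chrom) next
    if (pos < start(parts)[j] || pos > end(parts)[j]) next
    off <- if (as.character(strand(parts)[j]) == "-")
      end(parts)[j] - pos else pos - start(parts)[j]
    return(as.integer(before[j] + off + 1L))
  }
  NA_integer_
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
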