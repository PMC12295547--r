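mkSites <- function(pos, chrom = "s1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
}

test_that("region calling finds runs, merges gaps and handles edge cases", {
  pos <- seq(1000, 30000, by = 1000)
  v <- rep(0, length(pos))
  expect_length(callRegions(mkSites(pos), v, threshold = 1), 0L)
  # one isolated significant site
  v1 <- v; v1[10] <- 5
  r1 <- callRegions(mkSites(pos), v1, threshold = 1)
  expect_length(r1, 1L)
  expect_equal(GenomicRanges::start(r1), pos[10])
  expect_equal(GenomicRanges::end(r1), pos[10])
  expect_equal(r1$peakPos, pos[10])
  # threshold tie counts as significant
  vt <- v; vt[3] <- 1
  expect_length(callRegions(mkSites(pos), vt, threshold = 1), 1L)
  # two runs 5 kb apart merge under a 10 kb gap, split under 2 kb
  v2 <- v; v2[c(1, 2, 3, 9, 10)] <- 5   # runs end 3000, restart 9000
  merged <- callRegions(mkSites(pos), v2, threshold = 1, maxGap = 10000)
  expect_length(merged, 1L)
  expect_equal(c(GenomicRanges::start(merged), GenomicRanges::end(merged)),
               c(1000, 10000))
  split <- callRegions(mkSites(pos), v2, threshold = 1, maxGap = 2000)
  expect_length(split, 2L)
  expect_equal(split$nSites, c(3L, 2L))
})

test_that("region calling is invariant to pre-sorting site permutations", {
  set.seed(40)
  pos <- sort(sample.int(1e5, 60))
  v <- runif(60, 0, 10)
  base <- callRegions(mkSites(pos), v, threshold = 7, maxGap = 5000)
  perm <- sample.int(60)
  o <- order(pos[perm])
  again <- callRegions(mkSites(pos[perm][o]), v[perm][o], threshold = 7,
                       maxGap = 5000)
  expect_identical(as.data.frame(base), as.data.frame(again))
})

test_that("consensus is the genomic intersection of the four methods", {
  regs <- function(s, e) GenomicRanges::GRanges("s1",
    IRanges::IRanges(s, e))
  four <- list(delta = regs(40000, 56000), ed = regs(45000, 60000),
               g = regs(44000, 55000), fisher = regs(45000, 58000))
  cons <- consensusIntervals(four, 4)
  expect_length(cons, 1L)
  expect_equal(GenomicRanges::start(cons), 45000)
  expect_equal(GenomicRanges::end(cons), 55000)
  expect_setequal(cons$supportingMethods[[1]],
                  c("delta", "ed", "g", "fisher"))
  # one empty method empties the full consensus
  four$ed <- GenomicRanges::GRanges()
  expect_length(consensusIntervals(four, 4), 0L)
  # identical regions are returned unchanged
  same <- list(a = regs(100, 200), b = regs(100, 200),
               c = regs(100, 200), d = regs(100, 200))
  cons2 <- consensusIntervals(same, 4)
  expect_equal(c(GenomicRanges::start(cons2), GenomicRanges::end(cons2)),
               c(100, 200))
  expect_error(consensusIntervals(four, 5), "consensusLevel")
  expect_error(consensusIntervals(four, 0), "consensusLevel")
})

test_that("consensus equals a brute-force per-bp intersection", {
  set.seed(41)
  for (rep in 1:10) {
    regionList <- lapply(1:4, function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      s <- sort(sample.int(1900, k))
      data.frame(start = s, end = pmin(s + sample.int(300, k), 2000))
    })
    grs <- lapply(regionList, function(r) {
      if (is.null(r)) GenomicRanges::GRanges()
      else GenomicRanges::GRanges("s1", IRanges::IRanges(r$start, r$end))
    })
    names(grs) <- paste0("m", 1:4)
    for (level in c(2, 4)) {
      cons <- consensusIntervals(grs, level)
      got <- integer(0)
      for (i in seq_along(cons))
        got <- c(got, GenomicRanges::start(cons)[i]:GenomicRanges::end(cons)[i])
      expect_identical(sort(got),
                       oracleConsensusBp(regionList, level, 2000L))
    }
  }
})

test_that("gene overlap queries honor the 1 bp rule and unknown scaffolds", {
  fix <- makeGeneFixture(seed = 43L)
  models <- readGeneModels(fix$gff)
  expect_length(models, 2L)
  hit <- genesInInterval(models, GenomicRanges::GRanges("s1",
    IRanges::IRanges(550, 1100)))
  expect_setequal(geneRanges(hit)$gene_id, c("gA", "gB"))
  # gene straddling the interval edge is included
  edge <- genesInInterval(models, GenomicRanges::GRanges("s1",
    IRanges::IRanges(600, 700)))
  expect_equal(geneRanges(edge)$gene_id, "gA")
  desert <- genesInInterval(models, GenomicRanges::GRanges("s1",
    IRanges::IRanges(1600, 1900)))
  expect_length(desert, 0L)
  expect_error(genesInInterval(models, GenomicRanges::GRanges("sX",
    IRanges::IRanges(1, 10))), "unknown scaffold")
})

test_that("variants are assigned to CDS, intron and intergenic features", {
  fix <- makeGeneFixture(seed = 44L)
  models <- readGeneModels(fix$gff)
  gr <- GenomicRanges::GRanges("s1",
    IRanges::IRanges(c(130, 170, 601, 1100, 1482), width = 1),
    ref = "A", alt = "G")
  out <- variantsInGenes(gr, models)
  expect_equal(out$feature, c("CDS", "intron", "intergenic", "CDS", "CDS"))
  expect_equal(out$gene_id, c("gA", "gA", NA, "gB", "gB"))
  expect_equal(out$cdsPos[1], 30L)       # plus strand: offset into exon 1
  expect_equal(out$cdsPos[5], 1L)        # minus strand: CDS starts at 1482
  expect_equal(out$cdsPos[4], 162L + 141L)  # second tx exon, 1240 - 1100 + 1
})

test_that("effect classification agrees with full-CDS translation on both strands", {
  fix <- makeGeneFixture(seed = 45L)
  models <- readGeneModels(fix$gff)
  genome <- fix$genome
  cdsSeqs <- list(gA = fix$cdsA, gB = fix$cdsB)
  strandOf <- list(gA = "+", gB = "-")
  set.seed(45)
  for (gid in c("gA", "gB")) {
    parts <- cdsByGene(models)[[gid]]
    cds <- cdsSeqs[[gid]]
    for (cdsPos in sort(sample.int(nchar(cds) - 3L, 40))) {
      gpos <- bsamap:::.cdsToGenomic(parts, cdsPos)
      refBase <- as.character(Biostrings::subseq(genome[["s1"]], gpos, gpos))
      altBase <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
      eff <- classifyEffect("s1", gpos, refBase, altBase, models, gid,
                            genome)
      # oracle: mutate the full CDS (transcript orientation) and translate
      altTx <- if (strandOf[[gid]] == "-")
        bsamap:::.revcomp(altBase) else altBase
      mutCds <- cds
      substring(mutCds, cdsPos, cdsPos) <- altTx
      refProt <- translateCds(cds)
      mutProt <- tryCatch(suppressWarnings(translateCds(mutCds)),
                          error = function(e) "INTERNAL_STOP")
      codon <- (cdsPos - 1) %/% 3 + 1
      expect_equal(eff$codon, codon)
      if (identical(mutProt, "INTERNAL_STOP")) {
        expect_equal(eff$effect, "nonsense")
      } else if (identical(refProt, mutProt)) {
        expect_equal(eff$effect, "synonymous")
      } else if (codon == 1) {
        expect_equal(eff$effect, "start_loss")
      } else {
        expect_equal(eff$effect, "missense")
        expect_equal(substring(mutProt, codon, codon), eff$altAa)
      }
    }
  }
})

test_that("effect classification validates REF against the genome", {
  fix <- makeGeneFixture(seed = 46L)
  models <- readGeneModels(fix$gff)
  gpos <- bsamap:::.cdsToGenomic(cdsByGene(models)[["gA"]], 10L)
  refBase <- as.character(Biostrings::subseq(fix$genome[["s1"]], gpos, gpos))
  wrong <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  expect_error(classifyEffect("s1", gpos, wrong, refBase, models, "gA",
                              fix$genome), "REF mismatch")
  expect_error(classifyEffect("s1", 1800, "A", "G", models, "gA",
                              fix$genome), "not inside the CDS")
})

test_that("CDS translation applies the standard code and its guards", {
  expect_equal(translateCds("ATGTGA"), "M")
  expect_equal(substring(translateCds("ATGGCTTAA"), 2, 2), "A")
  # wobble: TCT and TCA both encode Ser
  expect_equal(translateCds("ATGTCTTAA"), translateCds("ATGTCATAA"))
  set.seed(47)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds1710 <- paste(c("ATG", sample(sense, 568, TRUE), "TGA"),
                   collapse = "")
  expect_equal(nchar(cds1710), 1710)
  expect_equal(nchar(translateCds(cds1710)), 569)
  expect_error(translateCds("ATGTA"), "divisible by 3")
  expect_error(translateCds("ATGTAAGCTTGA"), "internal stop codon at codon index 2")
  expect_warning(translateCds("CTGTGA"), "ATG")
})

test_that("candidate filtering applies the three keep rules and domain ranking", {
  tab <- data.frame(
    chrom = "s1", pos = c(100, 200, 300, 400, 500),
    gene_id = paste0("g", 1:5),
    effect = c("missense", "synonymous", "missense", "missense",
               "nonsense"),
    gtF = c("hom_alt", "hom_alt", "hom_alt", "het", "hom_ref"),
    gtN = c("hom_ref", "hom_ref", "hom_ref", "hom_ref", "hom_alt"),
    snpIndexF = c(0.98, 0.98, 0.52, 0.97, 0.90),
    snpIndexN = c(0.02, 0.02, 0.48, 0.03, 0.10),
    deltaSnpIndex = c(0.96, 0.96, 0.04, 0.94, 0.80),
    fisherP = c(1e-20, 1e-20, 0.5, 1e-18, 1e-10))
  out <- candidateFilter(tab)
  # synonymous excluded (rule a), het parent excluded (rule b)
  expect_setequal(out$pos, c(100, 300, 500))
  expect_equal(out$pos[1], 100)   # strongest |delta| first
  expect_true(all(out$snpIndexF > 0.5 & out$snpIndexN < 0.5))
  # fully discordant pools (indices on the wrong sides) are excluded
  tab2 <- tab[3, ]; tab2$snpIndexF <- 0.48; tab2$snpIndexN <- 0.52
  expect_equal(nrow(candidateFilter(tab2)), 0L)
  # domain membership outranks raw |delta|
  dom <- data.frame(chrom = "s1", start = 450, end = 550)
  out2 <- candidateFilter(tab, domains = dom)
  expect_equal(out2$pos[1], 500)
  expect_true(out2$inDomain[1])
})

test_that("genotype-phenotype concordance counts matches and mismatches", {
  phen <- rep(c("fruiting", "non_fruiting"), c(74, 82))
  names(phen) <- sprintf("s%03d", seq_along(phen))
  geno <- ifelse(phen == "fruiting", "F", "N")
  names(geno) <- names(phen)
  perfect <- genotypeConcordance(geno, phen)
  expect_equal(perfect$concordance, 1.0)
  expect_equal(as.integer(perfect$table), c(74L, 0L, 0L, 82L))
  one <- geno; one[1] <- "N"
  expect_equal(genotypeConcordance(one, phen)$concordance, 155 / 156)
  set.seed(48)
  shuffled <- genotypeConcordance(geno, setNames(sample(phen), names(phen)))
  expect_lt(abs(shuffled$concordance - 0.5), 0.15)
  expect_error(genotypeConcordance(geno[-1], phen), "s001")
})
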