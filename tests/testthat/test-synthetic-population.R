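test_that("marker generation yields distinct, fully informative sites", {
  set.seed(1)
  cfg <- bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 1e5,
                      nMarkers = 10L, nProgeny = 20L, poolSize = 5L,
                      causalScaffold = "scaffold01", causalPos = 50000)
  par <- generateParents(cfg)
  m <- par$markers
  expect_length(m, 10L)
  expect_true(all(GenomicRanges::start(m) >= 1 &
                    GenomicRanges::start(m) <= 1e5))
  expect_false(anyDuplicated(GenomicRanges::start(m)) > 0)
  mc <- S4Vectors::mcols(m)
  expect_true(all(mc$ref %in% c("A", "C", "G", "T")))
  expect_true(all(mc$alt %in% c("A", "C", "G", "T")))
  expect_true(all(mc$ref != mc$alt))
  expect_equal(GenomicRanges::start(m)[par$causalMarker], 50000)
})

test_that("an empty marker table is valid and degenerate", {
  cfg <- bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 1e5,
                      nMarkers = 0L, nProgeny = 20L, poolSize = 5L,
                      causalScaffold = "scaffold01", causalPos = 50000)
  par <- generateParents(cfg)
  expect_length(par$markers, 0L)
  expect_true(is.na(par$causalMarker))
  expect_error(assignPhenotypes(matrix(logical(0), nrow = 5), cfg,
                                par$causalMarker),
               "causal locus")
})

test_that("impossible marker density is a configuration error", {
  expect_error(bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 5,
                            nMarkers = 10L, nProgeny = 10L, poolSize = 2L,
                            causalScaffold = "scaffold01", causalPos = 3),
               "more markers")
})

test_that("meiosis without recombination is clonal per chromosome", {
  cfg <- bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 1e6,
                      nMarkers = 50L, nProgeny = 20L, poolSize = 5L,
                      recombRate = 0, causalScaffold = "scaffold01",
                      causalPos = 5e5)
  set.seed(2)
  par <- generateParents(cfg)
  origins <- replicate(200, simulateMeiosis(par$markers, cfg))
  constant <- apply(origins, 2, function(o) all(o) || all(!o))
  expect_true(all(constant))
  fracF <- mean(apply(origins, 2, all))
  expect_gt(fracF, 0.35)  # each parent with probability 1/2
  expect_lt(fracF, 0.65)
})

test_that("a forced crossover splits parental origin at the breakpoint", {
  cfg <- bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 1e6,
                      nMarkers = 40L, nProgeny = 20L, poolSize = 5L,
                      causalScaffold = "scaffold01", causalPos = 5e5)
  set.seed(3)
  par <- generateParents(cfg)
  o <- simulateMeiosis(par$markers, cfg,
                       crossovers = list(scaffold01 = 500000.5),
                       startFrom = c(scaffold01 = "F"))
  pos <- GenomicRanges::start(par$markers)
  expect_true(all(o[pos <= 5e5]))
  expect_true(all(!o[pos > 5e5]))
})

test_that("dense crossovers decouple markers per the Haldane expectation", {
  cfg <- bsaSimConfig(nScaffolds = 1L, scaffoldLengths = 4e5,
                      nMarkers = 20L, nProgeny = 20L, poolSize = 5L,
                      recombRate = 150,  # 60 expected crossovers
                      causalScaffold = "scaffold01", causalPos = 2e5)
  set.seed(4)
  par <- generateParents(cfg)
  origins <- t(replicate(2000, simulateMeiosis(par$markers, cfg)))
  freq <- colMeans(origins)
  expect_true(all(abs(freq - 0.5) < 5 * sqrt(0.25 / 2000)))
  # adjacent-marker origin correlation = exp(-2 * lambda) under a
  # no-interference crossover process (1 - 2r, Haldane)
  pos <- GenomicRanges::start(par$markers)
  expected <- exp(-2 * cfg@recombRate * diff(pos) / 1e6)
  adjCor <- vapply(seq_len(ncol(origins) - 1), function(j)
    cor(origins[, j], origins[, j + 1]), numeric(1))
  expect_lt(max(abs(adjCor - expected)), 0.1)
  # well-separated markers (lambda >= 3) are essentially independent
  far <- expected < 0.01
  expect_true(any(far))
  expect_lt(max(abs(adjCor[far])), 0.1)
})

test_that("full penetrance maps phenotype exactly to the causal allele", {
  cfg <- smallSimConfig(seed = 5L)
  sim <- simulateCross(cfg)
  carrier <- sim@originF[, sim@causalMarker]
  expect_identical(sim@phenotypes,
                   ifelse(carrier, "fruiting", "non_fruiting"))
})

test_that("phenotype counts fit 1:1 at the expected chi-square pass rate", {
  set.seed(6)
  pass <- logical(300)
  for (i in seq_along(pass)) {
    carriers <- stats::rbinom(1, 156, 0.5)
    res <- segregationChiSquare(c(carriers, 156 - carriers), c(1, 1))
    pass[i] <- res$pValue > 0.05
  }
  expect_gte(mean(pass), 0.90)
  expect_lte(mean(pass), 0.99)
})

test_that("total misclassification destroys genotype-phenotype coupling", {
  cfg <- smallSimConfig(seed = 7L, misclassRate = 0.5, nProgeny = 500L)
  sim <- simulateCross(cfg)
  carrier <- sim@originF[, sim@causalMarker]
  fruit <- sim@phenotypes == "fruiting"
  expect_lt(abs(cor(carrier, fruit)), 0.15)
})

test_that("pool construction samples disjointly and errors when short", {
  set.seed(8)
  phen <- rep(c("fruiting", "non_fruiting"), c(74, 82))
  pools <- buildPools(phen, 24)
  expect_length(pools$F, 24)
  expect_length(pools$N, 24)
  expect_length(intersect(pools$F, pools$N), 0)
  expect_true(all(phen[pools$F] == "fruiting"))
  expect_error(buildPools(phen, 0), "positive")
  expect_error(buildPools(rep(c("fruiting", "non_fruiting"), c(24, 100)),
                          30), "fruiting.*30|30.*fruiting")
})

test_that("pooled reads follow the binomial sequencing model", {
  set.seed(9)
  # fixed pool, no error: all reads carry alt
  r <- simulatePoolReads(rep(24L, 50), 24, 68.8, seqError = 0)
  expect_true(all(r[, "ref"] == 0))
  # p = 0 with 1% error: alt fraction within 3 binomial SE at ~1e6 reads
  r0 <- simulatePoolReads(rep(0L, 15000), 24, 68.8, seqError = 0.01)
  nReads <- sum(r0)
  frac <- sum(r0[, "alt"]) / nReads
  expect_gt(nReads, 1e6)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / nReads))
  # p = 1/2, no error: symmetric
  rh <- simulatePoolReads(rep(12L, 20000), 24, 68.8, seqError = 0)
  expect_lt(abs(sum(rh[, "alt"]) / sum(rh) - 0.5), 0.005)
})

test_that("causal-marker pool frequencies are fixed before sequencing noise", {
  sim <- simulateCross(smallSimConfig(seed = 10L))
  altF <- sum(sim@originF[sim@pools$F, sim@causalMarker])
  altN <- sum(sim@originF[sim@pools$N, sim@causalMarker])
  expect_equal(altF, length(sim@pools$F))
  expect_equal(altN, 0)
})

test_that("emitted files are standard, consistent and round-trip exactly", {
  sim <- simulateCross(smallSimConfig(seed = 11L))
  d <- tempfile()
  paths <- writeDataset(sim, d)
  # VCF data-line count equals the marker count
  vcfLines <- readLines(paths["vcf"])
  dataLines <- vcfLines[!startsWith(vcfLines, "#")]
  expect_length(dataLines, length(sim@markers))
  # REF at each site matches the FASTA base (1-based)
  genome <- Biostrings::readDNAStringSet(paths["fasta"])
  f <- strsplit(dataLines, "\t")
  refOk <- vapply(f, function(x)
    as.character(Biostrings::subseq(genome[[x[1]]], as.integer(x[2]),
                                    as.integer(x[2]))) == x[4],
    logical(1))
  expect_true(all(refOk))
  # re-reading reproduces the allele-depth matrix exactly
  vs <- readPoolVariants(paths["vcf"])
  mc <- S4Vectors::mcols(variantRanges(vs))
  expect_identical(cbind(mc$adF1, mc$adF2, mc$adN1, mc$adN2),
                   unname(sim@poolCounts))
  # GFF parses and a gene overlaps the causal locus
  models <- readGeneModels(paths["gff"])
  causal <- GenomicRanges::GRanges("scaffold01",
                                   IRanges::IRanges(200000, 200000))
  expect_gte(length(geneRanges(genesInInterval(models, causal))), 1L)
  # phenotype table round-trips
  ph <- read.delim(paths["phenotypes"])
  expect_identical(ph$phenotype, sim@phenotypes)
  unlink(d, recursive = TRUE)
})

test_that("a fixed seed reproduces byte-identical output files", {
  sim1 <- simulateCross(smallSimConfig(seed = 12L))
  sim2 <- simulateCross(smallSimConfig(seed = 12L))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeDataset(sim1, d1)
  p2 <- writeDataset(sim2, d2)
  expect_identical(md5OfFiles(p1), md5OfFiles(p2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("null markers have pooled allele frequency 1/2 in both bulks", {
  # unlinked limit checked directly on the sampling model
  set.seed(13)
  carriers <- stats::rbinom(10000, 24, 0.5)
  r <- simulatePoolReads(carriers, 24, 68.8, seqError = 0)
  frac <- sum(r[, "alt"]) / sum(r)
  se <- sqrt(0.25 / sum(r))  # conservative binomial SE at p = 1/2
  expect_lt(abs(frac - 0.5), 3 * (se + 0.5 / sqrt(10000) / sqrt(24)))
})
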