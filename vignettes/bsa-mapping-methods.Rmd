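---
title: "Mapping a binary trait in a haploid fungal cross with bsamap"
author: "bsamap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a binary trait in a haploid fungal cross with bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The mapping problem

Many agaricomycetes can be propagated as *monokaryons*: strains whose
hyphal cells carry a single haploid nucleus, obtained by germinating
individual basidiospores. Some monokaryons of species such as the enoki
mushroom (*Flammulina filiformis*) form fruiting bodies without mating —
*monokaryotic fruiting* — and because the strains are haploid, both
dominant and recessive alleles of a fruiting-control gene are directly
visible in the phenotype. Crossing a fruiting with a non-fruiting
homozygous parent and collecting basidiospore progeny yields a haploid
F1 population in which a single fully penetrant causal locus segregates
1:1.

`bsamap` implements bulked segregant analysis by sequencing (BSA-seq)
for exactly this design. Two bulks of progeny — one per phenotype class —
are pool-sequenced, and at every informative SNP the two pools' allele
depths are compared. Markers unlinked to the causal locus have expected
pooled allele frequency 1/2 in both bulks; markers linked to it are
enriched for the fruiting parent's allele in the fruiting bulk and
depleted in the other.

## The association statistics

Let a site be *polarized* so that "allele A" is the fruiting parent's
allele, and let the pools have read counts $(a_F, d_F - a_F)$ and
$(a_N, d_N - a_N)$ for (A, non-A). The per-site statistics are:

* **SNP-index** per pool: $\widehat{p}_F = a_F / d_F$,
  $\widehat{p}_N = a_N / d_N$.
* **$\Delta$(SNP-index)**: $\widehat{p}_F - \widehat{p}_N$, in $[-1, 1]$,
  near $+1$ at a fully penetrant causal locus.
* **Euclidean distance (ED)**:
  $\sqrt{(\widehat{p}_F-\widehat{p}_N)^2 + ((1-\widehat{p}_F)-(1-\widehat{p}_N))^2}
  = \sqrt{2}\,|\Delta|$, raised to the 4th power before smoothing to
  sharpen peaks (the power is a parameter, `edPower`).
* **G statistic**: the likelihood-ratio statistic
  $G = 2\sum_{n>0} n \ln(n/\hat e)$ over the four cells of the
  pool-by-allele table, with $\hat e$ the independence expectation; no
  continuity correction, zero cells contribute zero.
* **Fisher exact test**: exact two-tailed p, summing all hypergeometric
  outcomes at fixed margins whose point probability does not exceed the
  observed one. The implementation exploits the log-concavity of the
  hypergeometric pmf: the rejected outcomes form two tails whose
  boundaries are located by binary search and summed with `phyper`, so
  the computation stays exact (and fast) at arbitrary depth.

## Smoothing, thresholds, and consensus intervals

Site-level statistics at ~70x pooled depth are noisy. Each track is
smoothed along the genome with a tricube kernel,
$w(d) = (1-(d/h)^3)^3$ for $|d| \le h$, with a common default bandwidth
$h$ of 1 Mb; scaffolds are never mixed and an isolated site keeps its
raw value. One smoothing convention for all four methods was preferred
over four method-specific historical conventions; bandwidth and kernel
are parameters.

Significance cutoffs come from a null simulation that is specific to a
*haploid* cross: for each pool the number of fruiting-allele carriers
among the `poolSize` (default 24) bulked strains is
Binomial(poolSize, 1/2) — the pool allele-frequency granularity is 1/24,
unlike the diploid QTL-seq setting — then depth is
Poisson(`meanDepth`, default 68.8, floored at one read so the
statistics stay defined) and allele reads are binomial at the carrier
frequency. The 99th percentile of each statistic (|Δ|, ED⁴, G, and
−log10 Fisher p) over ≥100,000 such sites is the threshold; a site
exactly at the cutoff counts as significant. Thresholds are estimated
from raw (unsmoothed) null statistics and applied to the smoothed
tracks: smoothing shrinks noise away from a QTL, so region calls away
from real signal become conservative while the null calibration itself
remains interpretable site-wise (the type-I tests in the suite check
exactly that raw-vs-raw 1% property). Thresholding smoothed Fisher
significance on the simulated −log10(p) quantile keeps all four methods
on the same calibrated footing; a Bonferroni cut can be imposed by
passing a `BsaNullThresholds` object with the desired cutoff.

Per method, maximal runs of consecutive significant markers form
regions; runs separated by at most `maxGap` bp (default: the smoothing
bandwidth, so a marker desert narrower than the kernel cannot split a
QTL) are merged, and region boundaries are the outermost significant
marker positions — marker-supported spans, not threshold-crossing
interpolations. The final QTL interval is the genomic intersection of
the four methods' regions (`consensusLevel = 4`); any method without an
overlapping region empties the full consensus. Region BED files are
0-based half-open; all reports quote 1-based closed coordinates; the
conversion is centralized and tested.

## Candidate genes and coding variants

Genes whose span overlaps a consensus interval by at least 1 bp are
candidates. Variants inside their CDS are classified by splicing the
CDS parts in transcript order (reverse-complemented on the minus
strand; both strands fully supported), locating the CDS-relative
position (CDS position 121 is codon 41, position 1), mutating the codon
and translating with the standard genetic code. Candidates must (a)
alter the protein, (b) have opposite-homozygous parents, and (c) show
pool indices on the parent-concordant sides of 1/2; they are ranked by
conserved-domain membership first, then |Δ(SNP-index)|, Fisher p and
position. Domain membership is a user-supplied interval annotation, not
a computation — it derives from external protein-domain databases — and
it is the discriminating key among perfectly linked coding variants,
which pooled read counts alone cannot distinguish. Per-strain
genotype-phenotype concordance (`genotypeConcordance`) supports the
follow-up validation step in which individual strains are genotyped at
the top candidate.

## The synthetic cross generator

No sequencing data accompany the study design this package addresses,
so a first-class simulator (`simulateCross` + `writeDataset`) generates
the whole input set: VCF 4.2 (parents as GT, pools as AD/DP), GFF3,
FASTA and a phenotype TSV that round-trip through the package's own
readers. Its defaults are the study conditions: 156 haploid progeny
from two fully homozygous parents, bulks of 24 strains, 7021 biallelic
SNP markers, mean pooled depth 68.8x, a single fully penetrant causal
locus.

Choices the design left open, fixed once here:

* **Genome geometry**: 10 scaffolds x 3.5 Mb (~35 Mb), markers uniform
  at random; scaffold-level mapping at this scale, with no claim about
  any real assembly.
* **Recombination**: crossovers are Poisson per scaffold
  (no interference, Haldane-consistent) at 0.4 crossovers/Mb/meiosis —
  about 40 kb/cM, a typical agaricomycete map density giving ~14
  crossovers per meiosis genome-wide.
* **Sequencing**: per-site depth is Poisson (shotgun coverage variance)
  rather than fixed; per-read allele flips at `seqError` = 0.001,
  Illumina-like.
* **Phenotyping**: `penetrance` (default 1) and `misclassRate`
  (default 0) are first-class parameters because scoring
  primordia-only strains as "fruiting" is a judgment a user may want to
  stress-test.
* **Annotation fixture**: five multi-exon genes tile the causal locus;
  the causal gene mirrors the mapped candidate's architecture (2193 bp
  span, 7 exons, 1710 bp CDS encoding 569 aa) with the causal T→G SNP
  at CDS position 121 pinned to codon 41 `TCT`, so the coding change is
  Ser→Ala. One neighbour gene is on the minus strand to exercise the
  annotator. A synthetic conserved-domain track covering CDS 61–210 of
  the causal gene is emitted alongside.

What the simulator does **not** emulate: read-level errors correlated
along reads, mapping artifacts and repeat-induced depth excursions,
segregation distortion, InDel markers, or polygenic architectures.
Passing tests therefore demonstrate correctness of the statistical
machinery under the declared sampling model, not robustness to every
real-data pathology; the depth-window filter (default [10, 3x mean])
is the main guard against the repeat/collapse failure mode.

## Numerical and degenerate-input conventions

* Sites with zero or missing depth in either pool are filtered (the
  SNP-index is undefined there), tallied under
  `missing_or_zero_depth`; each rejected record counts under its first
  failing rule so kept + tally = input, exactly.
* Phased (`0|0`) and unphased (`0/0`) genotypes are treated identically
  — phase is meaningless for homozygous haploid-derived calls. Haploid
  single-allele calls (`0`, `1`) are accepted.
* InDels and multiallelic records are retained by the reader but
  flagged, and excluded from association by default
  (`requireSnp = TRUE`).
* Polarizing an already-oriented set is a no-op; polarization preserves
  total depth per site.
* G on a table with a zero row (a zero-depth pool) is an error in the
  scalar interface; upstream filtering prevents it in tracks.
* Ties at a threshold count as significant (deterministic and
  documented).
* The Fisher tie comparison uses the customary 1 + 1e-7 relative slack
  against floating-point equality.
* Byte-determinism: every output (simulated dataset and pipeline
  report) is reproducible byte-for-byte from config + seed; logs
  record thresholds, tallies and seeds, and contain no timestamps.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run a reduced cross (2 scaffolds x 400 kb, 200 markers, 60
progeny, bulks of 10, 40x) chosen so each end-to-end run takes a few
seconds while still containing every structural feature (two scaffolds,
all five genes, both strands). Full study-scale conditions (156
progeny, bulks of 24, 7021 markers, 68.8x) are exercised by the
acceptance tests: a 100,000-site null calibration with a fresh
100,000-site type-I check, and 50 replicate end-to-end crosses for
parameter recovery; `scripts/acceptance.R` repeats the same analyses
with 20 replicate crosses. Manhattan-style plots of raw and smoothed
tracks can be drawn from the `site_stats.tsv` output; both modes are
written precisely because published figures rarely state which one they
show.

## Known limitations

* The consensus interval under the default 1 Mb bandwidth is far wider
  than a fine-mapped interval from real data with local marker density;
  resolution here is driven by the simulated recombination rate and
  bandwidth, not by the method.
* The null model assumes balanced 1:1 sampling into bulks; strong
  segregation distortion would shift the carrier distribution away from
  Binomial(n, 1/2).
* Conserved-domain evidence is consumed, never computed.
* The CLI (`inst/scripts/bsamap.R`) is a thin convenience wrapper; the
  R functions are the supported interface.
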