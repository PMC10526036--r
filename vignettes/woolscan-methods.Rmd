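---
title: "Methods: composite selection-signature scanning with woolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite selection-signature scanning with woolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Artificial selection on a quantitative trait — here, wool fineness in sheep
— leaves localized footprints in the genome: the selected population shows
elevated differentiation from an unselected contrast population (high Fst),
depressed nucleotide diversity (low pi), and unusually long stretches of
haplotype homozygosity around the favored allele. No single statistic is
reliable on its own at modest sample sizes, so the scan implemented here
combines three, each computed in genomic windows, and intersects their
candidate gene sets. The design assumes two cohorts of resequenced diploids
(a fine/semi-fine-wool group "F" of 10 animals and a coarse-wool group "C"
of 18, mirroring the eight-breed panel the scan was built around) with
phased genotypes in a multi-sample VCF.

## The three statistics

**Weir–Cockerham Fst.** Per site, the r = 2 variance-components estimator
(Weir & Cockerham 1984) with observed heterozygosity: the
between-population component $a$ and total $a + b + c$ are computed from
sample sizes, allele frequencies and heterozygote frequencies of the two
groups. Windows aggregate as a ratio of sums,
$F_{ST}^{win} = \sum_s a_s / \sum_s (a_s + b_s + c_s)$, the standard
weighted estimate. Sites monomorphic across both groups, or with fewer than
two genotyped diploids in either group, are undefined and excluded. Small
negative values are legitimate (the estimator is unbiased around zero) and
are *not* clamped; anything outside $[-0.05, 1]$ would indicate a defect.

**Nucleotide diversity and the pi ratio.** Per site,
$\pi = 2 c_0 c_1 / (n(n-1))$ — the fraction of distinct sequence pairs
differing at the site, from non-missing allele counts. Windows divide the
summed site values by the window length in bp (the convention of the
standard windowed-pi tools; a per-SNP normalization is available by flag).
The scan statistic is the ratio oriented *contrast over target*,
$\theta_\pi\text{-ratio} = \pi_{contrast} / \pi_{target}$, so a swept
(diversity-depleted) target group produces a large ratio and both scan
directions can take the upper tail. Windows where the target diversity is
exactly zero but the contrast is positive are the strongest possible signal
and rank above all finite ratios (an `Inf` sentinel); windows with zero
diversity in both groups carry no information and are dropped from ranking.

**XP-EHH.** For a core SNP, EHH at extension $k$ is the probability that
two haplotypes drawn from the group are identical over all sites from the
core out to $k$ (core included); it starts at 1 and decays. The integral of
the curve against physical distance, iHH, is accumulated per side while the
proximal EHH is at least the cutoff (default 0.05), including the first
segment crossing below it. The score is
$\ln(\text{iHH}_{target}/\text{iHH}_{ref})$, standardized genome-wide to a
z score; positive z means long haplotypes — a sweep — in the target group.
Window values (50 kb windows sliding by 20 kb) are plain means of the z of
covered SNPs.

Numerical and convention choices for XP-EHH, made once and exposed as
arguments:

* **Unconditional EHH.** EHH is computed over all group haplotypes,
  unconditional on the core allele. The cross-population statistic
  contrasts *populations*, not alleles, and conditioning on the core allele
  would leave near-empty classes in 20-haplotype groups.
* **Physical distance.** No genetic map is assumed; integration is in bp.
* **Genome-wide normalization.** z-scores use the population (denominator
  $n$) standard deviation over all scored SNPs; no allele-frequency binning
  is applied (none is defensible at these SNP counts), though the scan
  structure accepts one.
* **Missing data.** A haplotype that reaches a missing call during
  extension stops counting as homozygous with any other haplotype from that
  point (each missing call acts as a private allele). The alternative —
  dropping the haplotype and shrinking the pair denominator mid-traversal —
  can make EHH increase with distance, which breaks both the monotonicity
  invariant and the integral's interpretation. Haplotypes missing at the
  core are excluded before the scan; cores with fewer than two defined
  haplotypes or a zero iHH in either group are skipped.
* **Edge handling.** If the chromosome end is reached while EHH is still at
  or above the cutoff, integration stops at the last site and the score is
  flagged (`edge_flag`), so edge-inflated scores can be audited.

## From windows to candidate genes

Selection is rank-based: exactly $\lfloor 0.05 N \rfloor$ windows with the
largest values, ties at the boundary broken by genomic order, so counts are
deterministic no matter how flat the statistic is. The Fst and pi-ratio
tracks (same non-overlapping 50 kb grid) are intersected window-wise; the
SNPs inside joint windows are the Fst-and-ratio candidates. XP-EHH
candidates are the scored SNPs inside its own top windows. Each candidate
SNP is flanked by 50 kb on both sides (clipped to the chromosome),
overlapping or book-ended intervals are merged, and genes overlapping a
merged region by at least 1 bp (closed intervals) are collected. The final
candidate list is the two-way intersection of the Fst-and-ratio gene set
with the XP-EHH gene set, per direction. The flank is applied to candidate
SNPs, taken literally; applying it to whole windows instead would only
widen regions already several windows long.

## Quality control

Three rules in a fixed order: genotypes with depth below 3 reads are set
missing ("depth above 2", read per genotype since the fixture VCFs carry
FORMAT/DP; a site-mean mode is available); sites with a missing fraction of
10% or more are dropped; sites with minor allele frequency at or below 5%
(over non-missing alleles) are dropped, which also removes monomorphic
sites. The boundary conventions (mask when depth < 3, drop when missingness
>= 0.10, keep when MAF > 0.05) are documented on the function and
configurable.

One subtlety is worth stating because it is provable rather than a bug:
with genotype-level depth masking, *tightening* the depth threshold can
rescue a site that the MAF rule would otherwise drop, because masking a
reference-carrying genotype shifts the allele frequency computed on the
remaining alleles (2 alt alleles among 40 is exactly 0.05 and fails; among
38 it passes). Retained-site counts are therefore monotone in the
missingness and MAF thresholds, and in the depth threshold under site-level
filtering, but not strictly monotone in the genotype-level depth threshold.
The test suite pins this corner explicitly.

## Population structure

PCA standardizes each genotype column by centering at $2\hat p$ and scaling
by $\sqrt{2\hat p(1-\hat p)}$, zeroing missing entries after centering
(mean imputation), and eigendecomposes the sample covariance; variance
fractions are eigenvalues over their trace. LD pruning (25-SNP windows,
step 5, remove one of each pair with $r^2 > 0.05$) is the caller's job
before PCA, matching standard practice; the removal rule — largest
offending $r^2$ first, later member removed, ties to the lowest index pair
— is fixed for determinism rather than copying any one tool's heuristic.
The neighbor-joining tree runs on $1 - \mathrm{IBS}$ allele-sharing
distances (the distance the source software is not explicit about; IBS is
the least-assuming choice for closely related breeds). NJ itself is the
classic Saitou–Nei agglomeration with deterministic tie-breaking; negative
branch lengths, which arise from non-additive noise, are clamped to zero
with the deficit moved to the sibling branch so path lengths are preserved
as far as possible. Additive matrices are recovered exactly.

## Enrichment

Candidate gene sets are tested term-by-term with the one-sided (upper-tail)
hypergeometric probability, accumulated in log space. The background is the
set of genes carrying at least one term in the supplied map — web-tool
backgrounds are version-dependent and irreproducible, so the map *is* the
universe. Raw p < 0.05 is the headline significance rule, matching the
scan's original usage; Benjamini–Hochberg q-values are reported alongside
but do not drive the flag.

## The simulator

The generator is the package's study-condition stand-in for resequencing
data that are not publicly deposited. Its defaults are the study design:
10 + 18 diploids in groups F and C, two 2 Mb chromosomes, mean SNP spacing
500 bp (about 4,000 SNPs per chromosome), Balding–Nichols drift
$F = 0.05$ per population around an ancestral frequency
$p \sim \mathrm{Beta}(0.8, 0.8)$, per-genotype Poisson depth with mean 8
(the study's ~7.6x coverage, rounded; zero draws promoted to one read), and
REF/ALT pairs drawn with a 2:1 transition bias so the raw ts/tv ratio sits
near 2, where genome-wide SNP sets land. A sweep is planted by copying one
founder haplotype onto `round(0.95 * n)` of the target group's haplotypes
across a +/- 75 kb span — a hard, recent sweep at high carrier frequency,
the regime all three statistics are designed to catch.

What the simulator deliberately does **not** model: recombination and
mutation as genealogical processes (haplotypes are independent Bernoulli
draws given population frequencies, so background LD is near zero),
within-group breed structure (the eight breed labels are cosmetic; both
groups are exchangeable populations), soft or old sweeps, and
sequencing-read errors. Passing the recovery tests therefore shows the
pipeline detects the planted signal against drift noise at the study's
sample sizes — not that it would have the same power against real
background LD, demographic structure, or soft sweeps. The near-zero
background LD also means LD pruning removes less here than it would on
real data.

Every random draw flows from a single integer seed; equal seeds give
byte-identical datasets, and the end-to-end scan is deterministic (the
summary JSON is byte-stable across reruns).

## Problem sizes and degenerate inputs

The bundled analyses and tests run at the study scale: 28 diploids, two
2 Mb chromosomes (~8,000 simulated SNPs, ~6,500 after QC), 80 windows on
the 50 kb grid — large enough that the top-5% rule keeps 4 windows per
track, small enough that a full scan takes seconds. Top-fraction selection
refuses grids where $\lfloor 0.05 N \rfloor < 1$; a 20-window chromosome is
the practical minimum, and single-window-per-track selections (N < 40)
make the joint Fst-and-ratio intersection fragile. Windows with no defined
Fst site, cores with degenerate haplotype sets, and ratio windows with no
diversity in either group are all dropped rather than imputed; empty
candidate sets propagate as empty gene lists and a skipped enrichment
rather than errors.

## Known limitations

* XP-EHH uses physical distance; on real data with variable recombination,
  bp-integrated iHH conflates map length with haplotype length.
* The two-way Venn (Fst-and-ratio vs XP-EHH) follows the source design; a
  three-way intersection treating the ratio as its own arm would be
  stricter.
* Term enrichment inherits every bias of the supplied gene-term map;
  with the fixture's 20-term pool the test is exact but the universe is
  tiny, so p-values near 0.05 should not be over-read.
* The hand-rolled VCF reader/writer pair targets the GT:DP phased subset
  of VCF 4.2 the scan needs (via vcfR for parsing); exotic FORMAT fields
  are ignored rather than interpreted.
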