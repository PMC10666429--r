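---
title: "Methods: heterozygosity, kinship, ROH inbreeding and founder-event dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity, kinship, ROH inbreeding and founder-event dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohkin)
```

`rohkin` analyses small cohorts of deeply sequenced whole genomes — the
setting of population isolates, where a handful of high-coverage genomes
(n ≈ 6–10) can already say a great deal about diversity, relatedness and
demographic history because millions of SNP markers compensate for the
small sample. This vignette describes the statistical machinery, the
choices behind its defaults, and what the synthetic-data validation does
and does not demonstrate.

## Genotype data and filtering

The unit of analysis is a matrix of diploid genotype codes (0 hom-ref,
1 het, 2 hom-alt, NA missing) over autosomal biallelic SNPs identified by
(chrom, pos, ref, alt), with 1-based inclusive coordinates throughout.
`load_vcf()` supports two site-filter criteria typical of CASAVA-style
per-sample callsets:

* **basic** — biallelic SNPs with QUAL > 30;
* **advanced** — additionally FILTER = PASS and a per-genotype depth-used
  (FMT/DPU) > 10. The depth rule acts per genotype (failing genotypes
  become missing) rather than per site, because DPU is a FORMAT field;
  for single-sample input the distinction is moot, but merged cohorts
  need the per-genotype rule.

Multiallelic records and indels are dropped, not split: per-sample SNV
callsets list biallelic SNPs, and splitting would fabricate sites the
caller never reported.

`merge_cohort()` builds a cohort by union-of-sites: every sample is NA at
sites absent from its own callset. This is the crucial mechanism of the
merged analysis — a site called in only some samples becomes a
partially-missing site, so per-sample missing rates of ~0.5 after merging
are normal and informative, not a QC failure.

`apply_qc()` filters in a fixed order: per-sample missingness (`mind`),
then per-site missingness (`geno`), then the Hardy–Weinberg exact test
(`hwe`), mirroring conventional practice; the order matters because the
site missing rates are recomputed over surviving samples. With n = 8 and
`geno_max = 0.1`, every surviving site has call rate exactly 1, since
7/8 = 0.875 < 0.9 — the merged-and-filtered matrix is the complete-case
SNP set. Two deliberate conventions:

* The `mind` ceiling of 0.1 is a *single-sample* QC notion. On a
  union-merged cohort it would remove every sample, so the pipeline's
  merged-stage default disables it (`mind_max = 1`) and applies site
  missingness plus HWE only. `apply_qc()` itself keeps the full default
  for callers who want the sample filter.
* The HWE test needs cohort genotype counts; a single-sample test is
  degenerate and skipped with a message.

The HWE test is the two-sided exact test: conditional on the observed
allele counts, the heterozygote count has probability proportional to
`n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa`, and the p-value sums the
probabilities of all configurations no more probable than the observed
one. This is the standard convention of SNP QC toolchains; the test suite
checks it against exhaustive enumeration for all configurations with up
to 40 alleles.

## Heterozygosity and the merge effect

Per-sample SNP heterozygosity `H` is the fraction of heterozygous calls
among non-missing genotypes at the variant sites present in the matrix.
There is no monomorphic-genome denominator: per-sample callsets contain
only the sample's variant sites, which is why single genomes show
H ≈ 0.6 while genome-wide heterozygosity (including monomorphic
positions) would be two orders of magnitude smaller. Estimates defined
this way are known to depend on how the site set was ascertained; the
package reports the convention rather than "correcting" it, and
`het_by_call_rate()` makes the ascertainment visible: in a merged cohort,
sites are binned by the number of samples with a call, and the
heterozygous fraction per bin typically *decreases* with call rate —
private variants are young and disproportionately heterozygous, so
complete-case filtering lowers cohort H. An identity links the pieces:
overall H across the merged matrix equals the call-weighted mean of the
bin heterozygosities.

Minor allele frequencies use called genotypes only (denominator 2 ×
called samples at the site), so with eight samples the achievable grid is
0, 1/16, …, 1/2 and a large spike at maf < 1/16 signals abundant rare
variation.

Summary tables use the median / IQR / mean / SD convention with type-7
(linear interpolation) quantiles and the n−1 SD (reported as 0 for a
single value); the quantile type is a documented choice, as published
tables rarely state theirs.

## KING kinship from concordance counts

For a pair (i, j), `pair_counts()` tallies, over markers non-missing in
both: each sample's heterozygote count `N_Aa`, the both-heterozygous
count `N_Aa,Aa`, and the opposite-homozygote count `N_AA,aa`. The
within-family estimator is

φ̂ = (N_Aa,Aa − 2 N_AA,aa) / (N_Aa(i) + N_Aa(j)),

and the robust (between-family) estimator rescales by the *smaller* of
the two heterozygosity rates to guard against inflation when individual
allele-frequency distributions differ:

φ̂ = (N_Aa,Aa − 2 N_AA,aa) / (2 N_Aa(i)) + 1/2 − (N_Aa(i) + N_Aa(j)) / (4 N_Aa(i)),

with i the lower-heterozygosity individual. When the rates tie the two
estimators coincide algebraically, and the within-family form is used as
the deterministic tie-break; the relabeling makes the estimate symmetric
in the pair. Relatedness is R = 2φ̂ (the IBD identity 2φ = π₁/2 + π₂);
negative estimates are reported untruncated and flagged rather than
clamped at zero, since truncation conventions vary across tools.

`kinship_matrix()` exposes two marker-set modes because they answer
different questions on merged data: `"pairwise"` uses, per pair, the
markers shared by the two samples (estimates invariant to adding further
samples to the cohort), while `"complete-case"` (the default) uses the
markers called in every sample, matching the post-filter cohort analysis.
On data without missingness they coincide. No maf filtering or LD pruning
is applied anywhere — the estimators are designed to work on the full
marker set.

## ROH detection

`call_roh()` implements the classic sliding-window dialect: 50-SNP
windows are scored homozygous if they contain ≤ 1 heterozygous and ≤ 5
missing calls; a SNP is supported if ≥ 5% of the windows overlapping it
are homozygous; maximal stretches of consecutive supported SNPs — broken
where the gap between adjacent SNPs exceeds 1000 kb — become runs, with
boundaries at the outermost supported homozygous SNPs; and a run is
emitted if it has ≥ 100 SNPs, spans at least the minimum length, and does
not exceed 50 kb/SNP. Missing genotypes inside a run count toward the
window allowance but never break the run. A second preset (`"ref20"`,
25-SNP minimum, 100 kb gap) matches the settings used in comparative
inbreeding studies of European isolates; run length is the inclusive bp
span divided by 1000, a convention fixed here because report rounding is
rarely documented. Only windows fully inside a chromosome are counted, so
calls within one window of a chromosome end may differ marginally from
implementations with edge-window heuristics.

`sweep_roh()` evaluates NROH, SROH and AVROH over a grid of minimum
lengths (default 0.1–5 Mb in 0.1 Mb steps). Window support does not
depend on the minimum length, so the sweep calls once at the smallest
grid value and post-filters by length — provably identical to re-calling
at every grid point, which the tests verify directly.

## Inbreeding and founder-event dating

`f_roh()` computes F_ROH>x = ΣL_ROH>x / L_aut with
L_aut = 2,881,033.286 kb, the summed GRCh37 autosome lengths (the
per-chromosome vector ships with the package), and
R_ROH>x = 2·F_ROH>x, the parental relatedness implied by offspring
inbreeding when common ancestors are themselves non-inbred. Per-sample
values are doubled first and medians taken afterwards; the aggregation
order only moves the third decimal, but it is fixed and documented.
`match_r_to_roh()` finds the minimum length x* where kinship-derived R
meets R_ROH>x: a small x* attributes the observed relatedness to deep
evolutionary (bottleneck) sharing, a large one to recent family
structure.

The bottleneck detector works in the NROH-versus-SROH plane. With SROH
in Mb, the diagonal NROH = SROH is the locus where runs average 1 Mb;
`deviation_profile()` computes the signed vertical deviation
d = SROH_Mb − NROH per sample per grid length. The profile's
`l_min` (smallest length at which all samples fall below the diagonal)
and `l_max` (length maximizing the median deviation) mark the start and
peak of the bottleneck/consanguinity signal. Vertical deviation was
chosen as it reads directly off the plot's axes; the deviation table is
returned, so a perpendicular-distance variant is a one-line
transformation for anyone who prefers it. The median across samples
defines `l_max` (robust for n = 8), with per-sample argmax lengths also
reported.

`date_length()` converts lengths to time: autozygous segment lengths from
an ancestor g generations back are approximately exponential with mean
100/(2g) cM, so ĝ = 100 cM / (2L), years back t = 26.9·ĝ (human
generation time 26.9 y), and calendar year = reference year − t. The map
is fixed at 1 cM/Mb by default (configurable), consistent on both the
simulation and analysis side. The reference year defaults to 1960 — a
birth-year convention for cohorts sampled around 2012 — and reports can
carry both 1960 and 2012, which simply shift the calendar scale by 52
years. Dates are reported unrounded.

## The synthetic-data generator

Because the genomes this class of analysis targets are access-restricted,
validation runs on synthetic cohorts with known truth
(`simulate_cohort()`):

* **Genome**: a few chromosomes of tens of Mb with uniformly scattered
  SNP sites (defaults: 3 × 80 Mb at 0.5 SNP/kb) — scaled down from the
  ~2881 Mb / ~3.5M-SNP real setting so that a full pipeline run takes
  seconds. Sites are in linkage equilibrium apart from pedigree descent
  and planted tracts, keeping every oracle analytic.
* **Genotypes**: either the `"het"` model (direct control of per-sample
  heterozygosity, default 0.6 at variant sites, emulating the observed
  single-genome value) or the `"freq"` model (founder haplotypes from a
  per-site allele frequency, HWE within founders).
* **Pedigree gene drop**: transmission with Haldane recombination
  (Poisson crossovers, no interference, 1 cM/Mb) or fully unlinked
  segregation. Founder-allele labels are tracked, so the truth records
  both pedigree-expected and realized kinship; parent–offspring realized
  kinship is exactly 1/4, and sibling variation around 1/4 reflects
  recombination.
* **Autozygosity**: per-sample Poisson counts of non-overlapping tracts
  with exponential lengths of mean 100/(2·founder_g) cM, overwriting
  genotypes with frequency-weighted homozygotes. Lengths are drawn before
  placement and rejection acts on positions only (longest first), so the
  emitted length distribution stays exponential even at high tract load;
  an unplaceable load is an error, not a silent truncation.
* **Noise**: uniform genotype-code miscalls at `error_rate`, missingness
  at `missing_rate`, Gaussian site QUAL with a configurable low-QUAL
  fraction (default 5% below the QUAL 30 threshold), Poisson per-genotype
  depth with mean 37 (the coverage regime where short-ROH calling is
  reliable).

A single master seed drives one deterministic stream; identical
specifications reproduce cohorts, VCFs and pipeline outputs byte for
byte. `make_private_shared_cohort()` additionally generates the
private/shared two-stratum structure (defaults: private variants 80%
heterozygous, shared 30%) that reproduces the call-rate heterozygosity
gradient of merged cohorts.

**What passing tests show — and don't.** The generator validates the
estimators under their own assumptions: exchangeable sites, no LD beyond
pedigree and planted tracts, uniform recombination, error independent of
genotype. Real genomes violate all of these to some degree (LD structure,
recombination hotspots, caller-correlated errors, a frequency spectrum
shaped by demography), so recovery of g₀ within 10% on synthetic cohorts
bounds estimator error, not the historical uncertainty of a real dating,
which is dominated by the 1 cM/Mb approximation, the generation-time
constant and the exponential-length idealization.

## Problem sizes and numerical choices

The test suite validates at sizes chosen to make sampling error small
relative to the tested tolerances while keeping a full run around a
minute: kinship oracles at ≥50k unlinked sites (mean φ̂ within ±0.02 of
pedigree expectations), tract-length
recovery from ~800 pooled segments per founder generation
(g₀ ∈ {25, 50, 100} recovered within 10%), and the deviation profile on
an 8-sample, 660 Mb, 660k-site founder cohort (l_max lands on the grid
point 1.0 Mb, inside the 0.6–1.6 Mb band around the expected 1 cM mean).
Degenerate inputs have defined behavior throughout: monomorphic sites
give HWE p = 1; zero-heterozygote pairs are flagged, not dropped; samples
with no ROH contribute zero rows to sweeps and F_ROH = 0; an
all-on-diagonal deviation profile reports l_min/l_max as undefined with
diagnostics. Grid lookups match with a 1e-6 kb tolerance to absorb
floating-point Mb-to-kb conversion.

## Known limitations

* The ROH caller is the window dialect only; HMM/likelihood callers and
  phased-IBD methods are out of scope, as are sex chromosomes, indels
  and structural variation.
* π₁/π₂ IBD-state probabilities are not estimated; R = 2φ̂ is reported
  with the identity documented.
* Heterozygosity is SNP heterozygosity over ascertained variant sites;
  genome-wide H would require all-sites calls.
* Dating assumes a single founder/bottleneck pulse; continuous or
  multiple admixture/bottleneck histories fold into one effective signal.
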