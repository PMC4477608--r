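---
title: "breedscan: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breedscan: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

# The problem

Strong artificial selection and breed bottlenecks leave dog genomes with
megabase-scale haplotypes and extreme allele-frequency differentiation
between breeds. When one such region associates with two phenotypes — here
ear carriage and body mass — the question is whether one variant affects
both traits (pleiotropy) or whether distinct, tightly linked variants each
control one trait. `breedscan` implements the analysis chain for answering
that question from two data types: an across-breed association panel
(samples genotyped on an array, phenotypes assigned at the breed level) and
pooled resequencing of the candidate interval (read counts, not genotypes,
from pools of individuals).

This vignette documents the statistical models, every tunable that matters,
the synthetic-data generator that stands in for the unavailable raw data,
and the design decisions taken where the methods left genuine freedom.

# Across-breed association with breed permutations

Phenotypes are breed averages: every sample of a breed carries the same
trait value (ear code prick = 1, intermediate = 2, drop = 3, a quantitative
coding of an ordered morphological series; or breed-average sex-averaged
mass in kg). The per-SNP statistic is the 1-df score statistic

$$\chi^2 = n\,r^2,$$

with $r$ the Pearson correlation between allele dosage (0/1/2) and trait
over the $n$ non-missing samples. Because samples within a breed are
phenotypically identical and genetically correlated, asymptotic p-values
are anticonservative; significance therefore comes from **breed
permutations**: breed-level trait values are shuffled among breeds,
broadcast back to samples, and all SNP statistics recomputed. With $P$
permutations,

* `EMP1` (pointwise) $= (1 + \#\{\text{perm stat} \ge \text{obs}\})/(P+1)$,
* `EMP2` (genome-wide) counts permutations whose *maximum* statistic over
  all SNPs reaches the SNP's observed value — the max-statistic correction
  for multiplicity.

Ties count toward the permutation (conservative); the `+1` smoothing gives
the floor $1/(P+1)$, so the default $P = 1000$ supports genome-wide
p-values down to 0.001. Breeds are put in a canonical (sorted) order before
permuting so results are invariant to sample ordering. A zero-variance
trait yields statistic 0 at every SNP (hence `EMP = 1`); a monomorphic SNP
yields `NA` — "no signal" and "not testable" are kept distinct.

Worth knowing: with only two breeds, swapping the two trait values flips
the sign of $r$ and leaves $r^2$ unchanged, so every permutation ties the
observed statistic and `EMP1 = 1`. The permutation design needs at least
three breeds to be informative, and many to be powerful.

The accompanying `kruskal_wallis_mass_by_ear()` runs the tie-corrected
Kruskal–Wallis test of breed-average mass across ear classes **at the breed
level** (one observation per breed, $n = 46$ in the shipped panel). The
breed-level reading reproduces the published statistic exactly
(H = 0.224); a sample-level variant would pseudo-replicate breed values and
is deliberately not offered.

Among-breed differentiation uses the unweighted Nei-style estimator
$F_{ST} = (H_T - H_S)/H_T$ with $H_T = 2\bar p(1-\bar p)$, $\bar p$ the
unweighted mean of breed allele frequencies and $H_S$ the mean within-breed
expected heterozygosity. Unweighted means keep large panels from dominating
$\bar p$; the screen defaults (F_ST > 0.55, overall MAF > 0.15, both
strict) select the strongly differentiated, common SNPs whose maximal
consecutive runs mark candidate selection targets.

# The pooled SNP caller

Pool-seq replaces genotypes with read fractions. The caller operates on
QC-passing reference/non-reference counts per (site, pool):

1. **Base filtering** (in the pileup parser): bases with phred < 20 are
   dropped; read-start/end markers and indel runs are stripped; deletions
   (`*`) and `N` count as neither allele. Only the dominant non-reference
   base is tracked (biallelic model); tertiary-allele reads are reported in
   an `other` column and excluded from frequencies. How the original
   analysis treated multi-allelic sites is unknown; this choice is
   explicit and visible in the output.
2. **Variable-site screen**: a site is variable iff minor-allele reads,
   summed over all pools, strictly exceed 10 % of summed reads — "> 10 %"
   is read strictly, so 100/1000 does not qualify and 110/1000 does. The
   screen runs on QC-passing reads (the quality filter sits upstream).
3. **Classification**: sequence-capture pools with depth < 100
   (about 2 % of their average coverage) are `missing`; otherwise the
   majority allele's fraction is compared to a fixation cutoff from the
   tier set {0.70, 0.90, 0.99} — fraction ≥ cutoff ⇒ fixed for that
   allele, else `polymorphic`. Whole-genome pools at ~6–8× cannot support
   fractional cutoffs: they are `missing` at zero depth and fixed only
   when *all* reads agree. Fixation is ≥ (not >) the cutoff so that a pool
   with exactly 99 % support passes the 99 % tier; monotonicity follows:
   the fixed-call set at a strict cutoff is a subset of the set at any
   looser cutoff, and the test suite asserts this end-to-end on fuzzed
   counts.

One SC pool (the ESS analogue) had markedly lower, more variable coverage.
Its calls are accepted only where the other pool with the same phenotype
(WEI analogue) could also be called: `apply_ess_rule()` sets the
low-coverage pool to `missing` wherever the partner is `missing`, so that
phenotype class is never represented by the unreliable pool alone.

# Candidate SNPs and the consistency filter

A site is a **trait candidate** iff the pools of one phenotype class are
all fixed for one allele and the pools of the opposite class for the other
(ear: drop vs non-drop; mass: small vs large). Any polymorphic pool blocks.
A missing pool also blocks, with one exception: the designated low-coverage
pool may be missing when another pool of its phenotype class is
informative — this is the only reading under which the low-coverage masking
rule has any effect, since a hard missing-blocks rule would discard every
masked site outright. Both behaviours are available (`low_cov_pool = NULL`
gives the hard rule).

Candidates are then vetted against the WGS pools
(`wgs_consistency_filter()`): a candidate is rejected iff some WGS pool
with an informative label is fixed — by the all-reads rule — for the allele
inconsistent with the candidate's orientation. Mixed-ear pools are
uninformative for ear; every WGS pool is informative for mass (all large);
the wolf pool counts as large and non-drop, the wild-type phenotype.
Missing or polymorphic WGS calls never reject: absence of evidence is not
inconsistency. The test suite checks this operation against a full
enumeration of (trait × orientation × pool label × call).

**Dog–wolf fixed differences** pool all dog reads (SC + WGS) against the
wolf pool; a site qualifies at > 3000× total dog depth, > 3× wolf depth,
differing majority alleles and ≤ 1 % discordant reads on each side. At a
wolf pool of mean 7.5×, the Poisson lower tail (depth ≤ 3) makes a
fraction of true sites undetectable — a property of the published
thresholds, reported as such. Cluster density is reported as interval span
(kb, 1-based inclusive) per SNP, with a two-sided Fisher's exact test on
the 2×2 table of SNP-bp versus non-SNP-bp inside and outside the cluster.
Base pairs as the unit of trials is a modelling convention (the original
table construction is not documented); the p-value is descriptive.

# Read-depth CNV scan

Coverage is summarised in non-overlapping 100 bp windows. Per pool, window
depth is divided by the pool's mean over all windows (removing library
size); per window, these relative depths are divided by their cross-pool
mean, so normalized values average exactly 1 in every covered window.

Flagging uses a **leave-one-out twofold rule** by default: a pool deviates
when its relative depth exceeds twice the mean of the other pools'
relative depths (or falls below half of it, or is zero while another pool
has coverage). The naive alternative — thresholding the normalized value at
2.0 — fails its own purpose with few pools: a true 2.5-fold duplication in
one of five pools has normalized depth $2.5/((2.5+4)/5) = 1.92 < 2$, which
the leave-one-out comparison correctly resolves (2.5 vs 1.0). The
normalized-threshold rule remains available (`rule = "normalized"`).
Adjacent flagged windows merge into regions, and each region is annotated
with whether its deviating-pool set coincides with one side of the ear or
size contrast among the scanned pools — a programmatic phenotype-consistency
report standing in for manual browser inspection. Pool means (not medians)
define relative depth, matching "relative to the average coverage".

# EM haplotype phasing and linkage disequilibrium

Over a small SNP panel ($L \le 20$; practical instances use ~15),
haplotype frequencies are estimated by expectation–maximization under
random mating. A sample's likelihood is $\sum f_a f_b$ over *ordered*
compatible haplotype pairs (which absorbs the heterozygote factor 2);
missing genotypes enlarge the compatible set (marginalization). The E-step
weights each pair by current frequencies; the M-step sets frequencies to
expected counts over $2n$ chromosomes. The log-likelihood is recorded per
iteration and asserted non-decreasing; convergence is a gain below `tol`
(default 1e-8). Initialization is uniform over the haplotypes appearing in
any compatible pair; the most probable *unordered* pair is assigned per
sample, ties broken lexicographically (a lone double heterozygote splits
0.5/0.5 between AB/ab and Ab/aB and is assigned the lexicographically
smaller resolution — the tie is reported via the posterior). The
assignment confidence floor defaults to 0 (assign whenever possible;
all-missing samples are never assigned), since the original criterion for
leaving samples unassigned is not documented; `min_posterior` exposes it.
Against an independent exhaustive-likelihood oracle (simplex grid search
plus Nelder–Mead refinement on 2-SNP instances) the EM frequencies agree to
well under 1e-3.

Breed haplotype tables count each assigned sample's two haplotypes;
haplotypes above 1.5 % overall frequency are named in decreasing-frequency
order and the remainder pooled as "Other". Counts come from best-guess
pairs, not frequency-weighted expectations, matching "assigning the most
probable pair".

LD between SNPs $i, j$ is computed from the estimated haplotype
frequencies: $D = p_{AB} - p_A p_B$,
$|D'| = |D| / D_{max}$ with $D_{max} = \min(p_A p_b, p_a p_B)$ for
$D > 0$ and $\min(p_A p_B, p_a p_b)$ otherwise, and
$r^2 = D^2 / (p_A p_a p_B p_b)$. Algebraically $r^2 \le |D'| \le 1$;
the suite fuzzes 10,000 frequency vectors against these invariants. The
signature that distinguishes linkage from pleiotropy is reproduced on the
generator's two-block truth: |D′| is high both within and between blocks
(no recombinants) while between-block r² is low (the ear and mass alleles
ride different haplotypes).

# Selective sweep scan

Genome windows (default 40 kb) summarise pooled site frequencies: dog
heterozygosity is the mean of $2p(1-p)$ over variable sites using the
combined-dog read-fraction frequency, and dog–wolf F_ST is the per-site
$(H_T - H_S)/H_T$ for the frequency pair, averaged over sites
(mean-of-ratios). The estimator inherited by the original analysis is not
specified; both aggregation modes are shipped (`fst_aggregate = "ratio"`
gives ratio-of-sums) and a per-bp heterozygosity mode is available, because
the choices differ on real data. Windows without variable sites report
heterozygosity 0 and F_ST `NA`; negative per-site estimates are kept, with
a clamped copy alongside.

Outlier calling computes genome-wide percentile thresholds (linear
interpolation) and jointly flags windows **strictly** below the low
heterozygosity percentile (default 1 %) and strictly above the high F_ST
percentile (default 99 %); adjacent flags merge. Strict inequalities make
the scan well-behaved under ties — identical windows can never flag
themselves. Requesting percentiles finer than the window count is an
error.

# The synthetic-data generator

`sim_config()` encodes the emulated study design, and its defaults are the
study conditions:

* **Pools**: five single-breed SC pools at mean depths 4748/4910/5182/4305/
  1990× (two small non-drop, one large non-drop, two large drop breeds) and
  six 12-sample WGS pools at 6.1–8.1× — one wolf, two drop, one non-drop,
  two mixed — mirroring the published pool table.
* **Causal architecture**: three founder haplotypes over the causal SNPs —
  D (non-reference at all 7 ear-block SNPs), S (non-reference at all 8
  mass-block SNPs), L (neither) — with blocks at 11.02–11.08 Mb and
  11.34–11.43 Mb of a 3 Mb region, disjoint and ordered 5′→3′. Drop
  breeds are centred on D, small breeds on S, other dogs and the wolf on
  L. Between-block recombination defaults to 0.5 % per transmission,
  matching the observed rarity of recombinants.
* **Drift**: breed haplotype and background allele frequencies are beta/
  Dirichlet-distributed around their targets with concentration
  `drift_strength` (default 50; `Inf` is exact), the one-parameter stand-in
  for bottleneck drift that creates the high-F_ST structure the analyses
  assume. Background ancestral frequencies are uniform on (0.05, 0.95).
* **Reads**: per site and pool, depth ~ Poisson(mean depth) and
  non-reference reads ~ Binomial(depth, $f(1-e) + (1-f)e$) with symmetric
  per-read error $e$ (default 0.002 — no error estimate is published, so
  the default is a typical post-QC Illumina substitution rate and is
  exposed in the config). The estimator bias $e(1-2f)$ is asserted in the
  tests. Planted dog–wolf sites are fixed non-reference in all dog breeds
  and reference in the wolf, clustered in a 26.7 kb interval.
* **Mass model**: breed mass = log-normal baseline (25 kg, σ = 0.15 on the
  log scale — spanning ~15–40 kg, a realistic breed range) plus −8 kg per
  design copy of S, so small breeds land near 9 kg.

The generator writes standard formats (six-column mpileup-like text via
`write_pool_pileup()`, genotype/truth TSVs), and identical configurations
reproduce byte-identical outputs.

Two auxiliary generators support the genome-scale scans, where simulating
reads would be pointless overhead: `simulate_depth_windows()` draws
Poisson window coverage for the CNV scan (CNVs planted by deterministic
fold-scaling via `plant_cnv()`), and `simulate_sweep_frequencies()` draws
site frequencies for the sweep scan. The sweep generator's neutral
condition is **dog = wolf frequencies** (per-site F_ST exactly 0), with
optional Balding–Nichols beta divergence (`divergence` = beta
concentration; expected per-population F_ST ≈ 1/(1 + divergence)). The
identical-frequencies default is what makes planted-sweep recovery exact
rather than probabilistic: empirical percentile thresholds always leave
~1 % of windows in each marginal tail, and with any continuous neutral
F_ST distribution the two tails intersect by chance in a few percent of
simulated genomes; with neutral F_ST identically zero, the strict
inequality at the percentile excludes all neutral windows
deterministically. Swept windows push dog frequencies to 0.995 and leave
the wolf at the ancestral value.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: sequence-level artefacts (mapping error,
reference bias, PCR duplicates), overdispersed coverage
(capture-efficiency waves, GC bias), indels and multi-allelic sites,
linkage among background SNPs (they drift independently), pedigree
structure within breeds, and genuine wolf–dog divergence history. The
pipeline's robustness to those belongs to the upstream QC tools it assumes
(aligner, duplicate marking, realignment).

# Problem sizes and runtime

The shipped tests and the acceptance script run the chain at deliberately
modest sizes — 200-SNP regions for end-to-end candidate recovery, 2000 SNPs
× 200 permutations for the permutation-calibration check, 10,000 fuzzed
vectors for LD invariants, 1000 windows for sweep recovery, 30,000 windows
for the CNV scan — chosen so the whole suite completes in a few minutes on
one CPU while keeping every binomial/Poisson concentration bound
comfortably inside its 3–4σ test tolerance.

# Known limitations

* The caller is biallelic by construction; a genuinely triallelic site
  surfaces only through the `other` count.
* WGS pools at ~7× cannot distinguish "fixed" from "the minor allele was
  unsampled"; the all-reads rule trades sensitivity for specificity, and
  the dog–wolf wolf-depth floor (> 3×) leaves a Poisson-tail fraction of
  true fixations undetected.
* EM phasing enumerates compatible pairs and is exponential in
  heterozygous panel length; it is intended for panels of ~15 SNPs, not
  chromosome-scale phasing.
* The breed-permutation null preserves breed structure but not
  relatedness *between* breeds; clade-driven associations survive it.
* `EMP2` calibrates family-wise error for the SNP set actually tested;
  candidate SNP panels (as opposed to genome-wide arrays) make it
  panel-wide, not genome-wide, significance.
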