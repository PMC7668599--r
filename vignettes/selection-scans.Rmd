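---
title: "Methods: multi-method selection-signature scans from SNP-array genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method selection-signature scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsel)
```

`snpsel` implements the design used in breed-comparison studies of
livestock: detect genomic regions under putative selection by combining a
per-SNP differentiation scan (F~ST~), extended-homozygosity evidence (ROH
islands), and optionally an externally computed haplotype-based scan, and
report regions supported by at least two methods. This vignette explains
the statistical models behind each stage, the tunable parameters and the
reasoning behind their defaults, the numerical conventions, what the
synthetic-data generators do and do not emulate, and the package's known
limitations.

## Data model and coordinates

Genotypes live in a `genotype_dataset`: a samples x SNPs integer matrix of
ALT-allele counts (0/1/2, `NA` = missing call) with a sample sheet
(`sample_id`, `population`) and a SNP map (`snp_id`, `chromosome`,
`position_bp`, alleles). SNPs are kept sorted with strictly increasing
positions within a chromosome; duplicate positions are collapsed at
construction. All interval quantities (ROH, islands, windows, regions) are
**1-based, inclusive** per the PLINK `.map` convention, with
`length = end - start + 1`; BED exports convert to 0-based half-open and
are round-trip tested. In PLINK binary files the `.bim` A1 allele is the
counted ALT allele, so binary round trips are lossless; text `.ped` files
do not declare allele roles, so the text reader assigns REF/ALT
alphabetically.

## Quality control

`apply_qc()` fixes the filter order to match PLINK's semantics: samples
first (`--mind` 0.1 default: drop samples missing >10% of calls), then
SNPs (`--geno` 0.1 on the surviving samples), then non-autosomes (cattle
autosomes are 1-29), then optionally MAF. The minor allele is defined per
SNP from observed counts on post-sample-filter data, and a MAF exactly at
the threshold is kept (the filter removes frequencies strictly *below*
`min_maf`). Two marker sets are conventional: an LD-pruned set without a
MAF filter for diversity statistics, and a MAF>=0.05 unpruned set for the
F~ST~ scan — the F~ST~ tail is sensitive to rare alleles, so the scan set
keeps a permissive threshold rather than none at all.

LD pruning (`ld_prune()`) replays `--indep-pairwise W S r2` greedily:
windows of `W` SNPs advanced by `S`; while any retained pair in a window
has dosage r^2^ above the threshold, one SNP of the first offending pair
(in index order) is removed. Which SNP to drop is not specified anywhere
in the original tooling's documentation, so the package fixes a
deterministic tie-break: higher missingness first, then the later SNP.
r^2^ is the squared Pearson correlation of unphased genotype dosages over
jointly non-missing samples (pairwise-complete), the standard
composite-LD measure for unphased data.

## Diversity statistics

Per locus with `n` typed samples and ALT frequency `p`:
H~O~ = fraction heterozygous, and Nei's unbiased expected heterozygosity
uH~E~ = (2n/(2n-1)) * 2p(1-p), which dominates the plain 2p(1-p) for every
finite `n`. The population inbreeding coefficient is the **ratio of
means**, uF~IS~ = 1 - mean(H~O~)/mean(uH~E~): the alternative (mean of
per-locus ratios) is unstable at nearly monomorphic loci, and the
ratio-of-means form has the conventional sign behaviour (negative =
heterozygote excess). Its 95% CI is a percentile bootstrap over loci
(default 1000 replicates, explicit seed) — locus resampling because loci,
not individuals, are the exchangeable units for a genome-wide mean.
Standard errors on the means are across-locus SEs and are labelled as
such.

Rarefied allelic richness per locus is the expected number of distinct
alleles in a subsample of `g` allele copies,
A~R~ = sum over alleles of 1 - C(2N - n~a~, g)/C(2N, g), computed through
`lchoose` for stability. `g = "auto"` uses twice the smallest
per-population typed sample size over all loci (e.g. 50 copies for a
25-sample population), so all populations are rarefied to a common,
attainable depth; A~R~ is monotone non-decreasing in `g`, and `g = 2N`
returns the observed allele count.

## Runs of homozygosity

`detect_roh()` implements the window-free *consecutive runs* method. Per
sample and chromosome, a run is a maximal stretch of consecutive SNPs
containing at most one heterozygous and at most one missing call, with no
adjacent-SNP gap above `max_gap_bp` (default 1 Mb, the cited
implementation's default; the gap cap prevents runs from leaping across
assay deserts). A run may neither start nor end on a heterozygous or
missing call; when a second heterozygote would enter, the run is
terminated before it and scanning resumes after it, so the breaking call
belongs to no run. The one-het/one-miss allowance avoids fragmenting long
runs (>8 Mb) on array noise. Runs shorter than `min_length_bp` (1 Mb for
ROH statistics) or with fewer than `min_snps` SNPs are discarded.

`min_snps` defaults to the false-positive rule
l = ceil( ln(alpha/(n~s~ n~i~)) / ln(1 - het) ) with alpha = 0.05,
n~s~ SNPs, n~i~ individuals and het the mean observed heterozygosity of
the dataset (all populations pooled): l is the run length at which the
expected number of chance runs genome-wide drops below alpha. The het
actually used is always an explicit, reported parameter, because the rule
is extremely sensitive to it (at array scale, het 0.36 gives l = 42).

F~ROH~ divides the summed ROH length per animal by the autosomal array
coverage (default 2.51 Gb for the bovine HD array). Length-class
summaries use the conventional disjoint classes 1-2, 2-4, 4-8, 8-16,
>=16 Mb and cumulative classes >1 ... >16 Mb.

**Islands.** For island calling the detector is re-run as a second
configured pass with `min_length_bp = 0.3 Mb` (islands are short,
population-shared homozygosity, not individual inbreeding). Per SNP, the
incidence is the fraction of the population's samples whose qualifying
segment covers it; islands are maximal runs of consecutive SNPs with
incidence strictly above 0.5 ("more than 50%" — exactly half does not
qualify), flagged *strongest* above 0.7. Island coordinates are the bp of
the first and last SNP of the run, so islands within a population never
overlap.

## Weir-Cockerham F~ST~ and sweep windows

`wc_fst_pair()` computes the 1984 two-population variance-components
estimator per SNP from sample sizes, ALT frequencies and observed
heterozygote frequencies: theta = a/(a+b+c). Negative per-SNP estimates
are retained (they are part of the estimator's sampling distribution and
truncation would bias means); SNPs monomorphic across both populations
(zero denominator) or typed in fewer than 2 samples in either population
are flagged undefined and excluded from all aggregates. Two genome-wide
aggregates are reported because the field's tooling prints both: the
arithmetic mean of per-SNP theta and the ratio of sums sum(a)/sum(a+b+c)
(the weighted estimator; less noisy, and the one compared against
simulation targets). theta is invariant to swapping the populations and
to relabelling REF/ALT, which the tests assert.

The scan's selection rule takes the top 0.1% of defined per-SNP values:
k = ceil(0.001 * N) records, with all records tied at the threshold value
included (so output may exceed k). Candidate windows put 0.2 Mb on each
side of every selected SNP, clip to chromosome bounds, and merge
overlapping or bookended windows.

## LD-based effective population size

`binned_r2()` computes dosage r^2^ for same-chromosome SNP pairs with MAF
strictly above 0.05, binned by physical distance (default 20 log-spaced
bins, 50 kb-10 Mb; log spacing gives near-uniform coverage of time
depths). Bins over the pair cap (10^6^) are represented by a seeded
uniform subsample. The unphased sampling correction subtracts 1/n from
each bin mean (1/(2n) if phased haplotypes are supplied).

`ne_from_r2()` converts each bin: physical midpoint -> genetic distance
`d` via a uniform map density (default 1 cM/Mb, the cattle genome-wide
average) -> recombination fraction `c` via a mapping function -> time
depth t = 1/(2c) -> N~E~(t) = (1/(4c)) (1/r^2^~adj~ - alpha) with
alpha = 2.2 adjusting for mutation. Three mappings are provided and the
choice is recorded in the result's metadata: `sved_feldman`
(c = d/(1+2d), the default, matching the settings used with the field's
LD-N~E~ tool), `haldane` (c = (1-e^{-2d})/2) and `linear` (c = d); they
agree to first order for d below a few cM. Bins whose corrected r^2^ is
non-positive, or that would give negative N~E~ (1/r^2^~adj~ < alpha), are
excluded with a warning.

The N~E~-changing ratio (`nec_slopes()`) is the slope between adjacent
trajectory points normalised by the median of the 50 most recent
estimates; strongly negative values flag episodes of accelerated decline.

## Imported scans, q-values and consensus

Haplotype-based statistics (e.g. hapFLK) are consumed as externally
computed per-SNP p-value tables, never recomputed. `storey_qvalues()`
estimates the null proportion pi0 by the smoother method (spline through
pi0(lambda) on lambda = 0.05 ... 0.95, evaluated at 0.95) and falls back
to pi0 = 1 — exactly Benjamini-Hochberg, bit-for-bit equal to
`stats::p.adjust(..., "BH")` — for vectors shorter than 100 p-values or
when the smoother misbehaves. `regions_from_pvalues()` seeds regions at
-log10 p > 3 with q <= 0.05, extends each seed across consecutive SNPs
with -log10 p > 1 (the source analyses never define region boundaries;
the 10^-1^ extension threshold is this package's documented, configurable
convention — precomputed region tables are also accepted verbatim), and
flags regions containing a SNP with -log10 p > 5 as strongest.

`consensus_regions()` applies the ">= 2 distinct methods" rule by a sweep
line over interval endpoints: a consensus core is a maximal interval
covered everywhere by at least `min_methods` distinct method labels; the
reported region is the union extent of the intervals contributing to that
core (the conservative envelope, since per-method boundary conventions
differ), with the core(s) also reported. Regions whose union extents
overlap are merged so reported regions are disjoint — this makes the
operation idempotent — and each merged region keeps the list of its
covered cores. Single-method intervals appear in a separate unsupported
table. Gene annotation reports any >= 1 bp overlap between a region and a
gene interval (BED or GFF3 `gene` features), matching the "entirely or in
part within" convention; reciprocal-overlap fractions are deliberately
not required.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and a seed, and
their defaults are the study conditions under which the package's
properties are validated.

* `simulate_populations()` draws Balding-Nichols structure: ancestral
  frequencies uniform on [0.05, 0.95], population frequencies
  Beta-distributed with variance F p(1-p), genotypes Binomial(2, p). It
  matches a *target* F~ST~ (0.09 by default, the differentiation scale of
  closely related breeds) and Hardy-Weinberg within populations; it does
  not model demography, admixture or linkage. Default genome: 3 x 50 Mb,
  keeping full-pipeline runs fast.
* `plant_autozygous_segments()` rewrites a sample's genotypes homozygous
  (alleles drawn by population frequency) inside chosen intervals. This
  creates detectable runs, not true identity-by-descent. With
  `delimit_flanks = k` the k SNPs flanking each interval are forced
  heterozygous in the carrier: without delimiting, chance homozygosity at
  the flanks extends any allowance-honouring detector's run a few SNPs
  past the planted edge, so the *true* boundary is only defined up to
  that chance extension. Boundary-recovery studies therefore use
  delimited planting (k = 2, one more than the het allowance), under
  which the detector recovers every planted segment exactly.
* `plant_differentiated_region()` redraws one population's genotypes from
  frequencies shifted by a constant (clipped to [0.01, 0.99]) inside a
  region, the ground truth for the top-0.1% rule.
* `simulate_wf_ld()` is a discrete-generation Wright-Fisher population
  with random mating (selfing allowed) on one chromosome; gametes
  recombine at Poisson crossover points uniform on the genetic map.
  Initial frequencies are uniform on [0.1, 0.9] and no new mutations
  arise, so SNPs fixed by drift are dropped and counted. 400 generations
  (4N for the default N = 100) lets LD reach drift-recombination
  equilibrium at the time depths examined.

**A mapping subtlety.** Because the simulator's crossovers are a Poisson
process, its true recombination fraction between two sites follows
Haldane's map function. N~E~-recovery studies on simulated data therefore
invert with `mapping = "haldane"`; using the Sved-Feldman default there
would inflate recovered N~E~ by the ratio (1+2d), roughly 5-20% at the
distances examined. For real array data the default remains
`sved_feldman`. The recovered value for a replicate is summarised as the
mean N~E~ over bins with time depths 5-20 generations, the range where a
50 cM / 2000 SNP design has dense pair coverage.

## Validation performed by the test suite

The suite (and nothing outside it) establishes: exact equivalence of the
ROH detector with a naive exhaustive scanner on 200 random datasets;
recovery of all planted (delimited) autozygous segments with zero
spurious calls over 100 replicates; per-SNP theta equal to an
independently coded transcription of the 1984 formulas to 10^-12^ on 1000
random configurations; the weighted F~ST~ estimate within [0.08, 0.10] in
at least 95% of 50 Balding-Nichols replicates at F = 0.09 (50,000 SNPs,
30+30 samples); island calling at carrier fraction 0.6 for 6/10 carriers
and silence at 5/10; top-fraction size and tie behaviour against a
sort-based oracle; N~E~ recovery within [50, 200] for the recent bins in
at least 90% of 20 Wright-Fisher replicates at true N = 100; the
minimum-SNP formula's reference value (42) and monotonicities; bit-exact
BH equality of q-values at pi0 = 1; and an independent coverage recount
of every consensus core over 500 random interval sets. Problem sizes are
the study-design sizes quoted above; passing them demonstrates
correctness of the implementations on data satisfying the generators'
assumptions, not robustness to array artefacts (clustering failures,
batch effects, map errors) that real data contain.

## Known limitations

* Two-population theta only; no r > 2 multi-population estimator and no
  F~ST~ confidence intervals.
* The haplotype-based scan statistic itself is out of scope by design;
  only its per-SNP p-values are consumed.
* Uniform cM/Mb map only; no recombination-map input, no X chromosome.
* LD pruning and ROH detection are O(window^2) and O(n) per sample
  respectively in pure R: sized for array-scale data at tens of
  thousands of SNPs per analysis batch, not whole-genome sequence.
* The text-PLINK reader's alphabetical REF/ALT assignment can flip dosage
  coding relative to an external caller's convention; use binary PLINK
  when allele roles matter. All package statistics are invariant to the
  flip except signed dosage itself.
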