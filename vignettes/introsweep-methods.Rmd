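---
title: "Methods: depth-based CNV calling, introgression detection and selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-based CNV calling, introgression detection and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

introsweep implements the window-based population-genomic procedures used to
dissect crop resequencing panels — wheat-style panels of wild progenitors,
landraces and modern varieties — into copy-number variation, alien
introgression, and footprints of domestication and improvement selection.
This vignette explains each model and procedure, the knobs that matter, and
the choices made where the method description leaves the design open.

## Coordinates and containers

Every interval in the package is 0-based, half-open (`[start, end)`,
BED-native). VCF is the only 1-based surface; `read_vcf()`/`write_vcf()` do
the conversion and nothing else does. Genotypes live in a `geno_matrix`: a
sites tibble (chromosome, position, alleles, total depth, multiallelic flag)
plus an integer matrix of alt-allele dosages (0/1/2, `NA` missing). All other
results are plain tibbles, so stages chain with the pipe.

## Site filters

`filter_sites()` keeps a biallelic site when its total depth is strictly
between `dp_min` = 240 and `dp_max` = 2200, its missing rate is strictly
below 0.1, and the per-population minor-allele-frequency criterion holds
(default threshold 0.05, with per-population overrides such as 0.2 for a
very small diploid-progenitor panel, where 5 accessions make lower
frequencies unobservable anyway). The depth bounds assume a ~93-accession
panel at ~30x summed coverage; for other panel sizes scale them with
`site_filter_rules()`.

Two choices deserve a note:

* **MAF scope.** "MAF at least 0.05 for each population" read conjunctively
  removes every fixed inter-population difference — exactly the sites that
  drive Fst and sweep contrasts. The scope is therefore a flag
  (`maf_scope`), defaulting to the permissive `"any"` reading (at least one
  population passes); `"all"` gives the conjunctive reading.
* **Rule order.** Rules apply in a fixed order (biallelic, depth, missing,
  MAF) so the per-rule removal counts are mutually exclusive and reproduce
  across runs; their sum plus survivors always equals the input.

## Read-depth CNV calling

Depth is summarised in 1000-bp windows on a 500-bp step. Each accession's
raw window depth is divided by its own median window depth, putting the
diploid background at 1; no GC correction is applied at this scale. The
median is robust but needs enough windows to be a stable baseline — a few
hundred windows or more is recommended (tiny tracks are accepted for
testing convenience).

A window is deletion evidence when its normalized depth is strictly below
0.25 and duplication evidence strictly above 1.75. Evidence is chained with
the five-of-seven rule: a window is *seeded* when it lies in at least one
run of 7 consecutive windows holding at least 5 same-kind flags; each
maximal seeded run, trimmed to its outermost flagged windows, becomes one
call. This is the most literal reading of "five of seven or more
consecutive windows"; both numbers are arguments (`min_hits`, `span`) since
other chaining semantics are defensible. Adjacent calls merge when the gap
is strictly under 20% of their combined length, re-evaluating after every
merge until a fixed point; merging is left-to-right, and a property test
confirms the fixed point is order-insensitive for non-pathological inputs
by checking against an enumerator that restarts after every merge.

Cross-accession CNV regions (CNVRs) form by single linkage over the
"strictly more than 50% reciprocal overlap" relation, after removing calls
that touch known introgressions (their deletion-like signal is not copy
number). The representative interval is the largest member call, ties
broken by smaller start.

**RFD.** For a CNVR with carrier frequencies `f_a`, `f_b` in two population
groups, the relative frequency difference is `|f_a - f_b|` — the source
description never writes the formula, and the absolute difference is the
simplest statistic in `[0, 1]` matching the described use (a chr1D deletion
moving from ~0.8 in landraces to ~0.2 in varieties scores 0.6). The
selection threshold is the empirical top-1% quantile of the observed RFD
values, never a constant.

## Window diversity statistics

Per site with `n` called alleles and alt frequency `p`, the unbiased
heterozygosity is `(n/(n-1)) * 2p(1-p)`; window pi sums this over sites and
divides by the *physical* window length. Callable-length correction is out
of reach without per-base masks, so absolute pi values are comparable only
within a run — which is all the pi-ratio scan needs. The convention makes
pi invariant to adding monomorphic records, and the estimator equals the
exhaustive mean-pairwise-difference computation exactly for fully-called
data (a property the test suite checks by enumeration).

Fst is Hudson's ratio of sums, `1 - sum(Hw)/sum(Hb)` with
`Hb = pa(1-pb) + pb(1-pa)`, using only sites where both populations have at
least two called alleles; windows with fewer than 20 usable SNPs are
reported missing because the estimator's variance explodes on sparse
windows. Negative values are reported, not clipped. Hudson's form was
chosen over Weir-Cockerham for its ratio-of-sums stability and its clean
expectation under the Balding-Nichols generator (`E[Fst] = F`), which the
acceptance suite verifies at F = 0.15.

dxy between two accessions is the expected per-bp difference between one
haplotype drawn from each (`px(1-py) + py(1-px)` per site, `p = dosage/2`),
with pair-missing sites excluded from the numerator only — matching the pi
denominator convention.

`pi_by_gene_distance()` bins sites by distance to the nearest gene base
(0 inside genes, boundary bases included) and divides the per-bin diversity
sum by the exact number of genomic bases at that distance, computed in
closed form from the merged gene intervals, so the profile is a per-bp
quantity comparable across bins.

## Sweep scanning

The scan statistic is `ln(pi_progenitor / pi_derived)` per non-overlapping
100-kb window; windows where either pi is missing or the denominator is 0
are dropped and tallied. The selection threshold is the empirical 99%
quantile (type-7 linear interpolation) of the non-missing values, with
*strict* exceedance so threshold ties never inflate the selection.
Published genome-wide thresholds for such scans (e.g. ln-ratio cut-offs
near 3.95, 4.29 and 2.41 for wild-to-landrace and landrace-to-variety
comparisons) are realized quantiles of a particular panel; the package
always recomputes the quantile from its input. Selected windows under
200 kb apart (strict) merge into sweep regions; merging treats a
chromosome as one unit (arms are not split, the simplest defensible
reading).

## Introgression detection

An alien segment shows two signals at once: reads fail to map (a large
deleted CNV) and the reads that do map are unusually divergent from the
reference. Divergent-site ratios (divergent sites / covered bp) on a
non-overlapping 50-kb grid are standardized per accession against that
accession's genome-wide mean and sample (n-1) standard deviation, pooling
chromosomes; a window is a candidate when `z > 1.644853627`, the one-sided
normal critical value at alpha = 0.05 (`qnorm(0.95)`). A deleted CNV of at
least 500 kb (10 windows) becomes an introgression segment when strictly
more than half of its windows — membership decided by window midpoint, as
partial-window handling is unstated — are candidates. Only deletions seed
calls; duplications carry no mapping-failure signal. The null candidate
rate is ~alpha by construction, which the acceptance suite checks
(4-6% across 50 null simulations).

Per-population summaries use union lengths of carried segments; "shared"
between two populations is formalized as pairs of population-union
intervals with at least 50% reciprocal overlap (no procedure is given in
the method description, so the package states its own and keeps it
configurable). QTL co-localization expands point anchors by 2 Mb each way
(clamped at chromosome ends) before intersecting. Donor ranking sorts
candidate donor panels by ascending mean dxy over the segment and assigns
the best only when it undercuts the runner-up by a 20% relative margin —
deliberately conservative, mirroring the observation that most real
introgressions cannot be assigned a reliable origin.

## Haploblocks

Upstream LD-block finders cap block length, leaving sub-10-kb gaps between
blocks that are really one structure; `merge_blocks()` merges strictly
under 10 kb, transitively. Within a block, accessions cluster by the
proportion of mismatching genotypes over co-called sites, average-linkage,
cut at 0.1 (members of one haplotype differ at under ~10% of sites);
accessions with over 20% missing data in the block stay unclustered, and
blocks with fewer than 20 SNPs are skipped. The cut and linkage are
formalizations of what is visually a tree-inspection step, and both are
arguments. Each cluster is assigned a donor by the same margin rule as
segments; a block is labelled with the single agreeing donor, `"mix"` when
two or more donors appear among its clusters, `"unknown"` when nothing is
assignable.

## The synthetic-data generator

`sim_config()` + `simulate_genotypes()` / `simulate_depth()` /
`simulate_divergent_sites()` generate exactly the signals the detectors
consume, so every stage can be benchmarked against a planted truth
(`write_truth()`):

* **Genotypes** follow the Balding-Nichols model: ancestral frequency
  `p ~ Uniform(0.05, 0.95)` per site, population frequency
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `F p(1-p)`; equal to
  `p` at F = 0), diploid genotypes `Binomial(2, p_pop)`, missing genotypes
  at 2% by default. The model was chosen as the simplest generator with a
  tunable Fst; there is no linkage or coalescent machinery, so LD-related
  behaviour of real data is *not* emulated and haplotype structure is
  imposed directly where needed.
* **Sweeps** shrink a target population's expected heterozygosity by a
  factor `pi_reduction`, solving `p'(1-p') = p(1-p)/k` toward the nearer
  fixation boundary.
* **Depth** is Poisson per 1000-bp window at rate `lambda * c/2`, with
  `c = 2` outside events and the planted copy number inside; `lambda = 30`
  emulates ~30x coverage. Windows are drawn independently, ignoring the
  50% overlap correlation of real sliding windows — conservative for the
  caller, which then sees *less* correlated evidence than real data.
* **Introgressions** collapse mapped coverage (covered fraction 0.8 to
  0.2; window copy number 0 by default, since a mapping-failure signal the
  deletion threshold can see is the point of the two-signal design) and
  multiply the background divergent-site rate `r0 = 0.001`/bp by
  `divergence_fold`, clamped at 1 with a warning.

Determinism: a fixed `sim_config()` (including its seed) yields
byte-identical outputs; the three generators use distinct streams derived
from the seed so they can run in any order.

Because the generator has no linkage, no repeat content and no read-level
error, a passing benchmark says the *rules* are implemented correctly and
are recoverable under idealized noise — not that the thresholds are optimal
for any particular real genome.

## Benchmark problem sizes

The acceptance suite (and `scripts/acceptance.R`) uses desk-scale versions
of the study design, chosen so every run finishes in about a minute while
keeping each check statistically meaningful: 1000 random flag tracks of up
to 30 windows for the CNV rule enumerator; a 100-Mb genome with 20
accessions and six planted introgressions of 0.5-2 Mb (fold 10, r0 = 0.001,
lambda = 30); 50 null tracks of 1000 windows for Z calibration; 500 random
5-site matrices for the pi oracle; 20 replicates of 2 x 50 diploids at 2000
SNPs for Fst recovery; a 1-Mb, 30-fold sweep on a 100-Mb genome (1000
windows, so the planted sweep is exactly the top 1%) plus 20 null seeds;
and 100 copied-haplotype blocks at F = 0.4 between donor populations —
strong differentiation chosen to represent clearly distinct wild
populations, the regime in which a 20%-margin donor rule is meant to
operate.

## Known limitations

* No breakpoint refinement below window resolution; CNV genotypes are
  carrier/non-carrier only.
* pi uses physical length, so absolute values are not comparable across
  datasets with different callable fractions.
* The Z test assumes an approximately normal null for divergent-site
  ratios; heavy-tailed real coverage can inflate candidates (the
  conventional one-sided alpha = 0.05 absorbs some of this, and the
  critical value is configurable).
* Haploblock detection itself (LD blocks) is upstream and consumed as an
  interval list.
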