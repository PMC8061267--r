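---
title: "Methods: models, filters and design choices in stockscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and design choices in stockscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockscan)
```

`stockscan` is a post-genotyping inference chain for RAD-seq studies of
stocked freshwater fish: it takes phased diploid genotypes with read depths
and a population map, and produces diversity statistics, differentiation
and boundary analyses, microhaplotype co-ancestry, and a windowed genome
scan. This vignette records the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## The synthetic metapopulation generator

Every stage is exercised against `simulate_metapopulation()`, which builds
a stocked metapopulation with complete ground truth. Its defaults describe
the study system the package targets: two deeply diverged post-glacial
lineages whose populations sit at pairwise differentiation of about 0.07
between lineages and about 0.04 within (the survey scale this package is
built around reports 0.07 between states and 0.03–0.05 within), populations
nested in drainages that act as spatial blocks, and one heavy stocking pulse
in which two thirds of a recipient population are hybrids carrying on
average 46% source ancestry — a population mean of 31% non-native ancestry.

Model components, each chosen once as the realistic option and then left
alone:

* **Frequencies.** A hierarchical Balding–Nichols model: lineage-level
  frequencies are beta draws around a shared ancestral frequency, and
  population frequencies are beta draws around their lineage frequency with
  parameter `F_within`. `F_between` and `F_within` are *target realized
  pairwise theta levels*: because the two drift layers compound, the
  internal lineage-level parameter is `(F_between - F_within) /
  (1 - F_within)`, which makes the expected between-lineage pairwise theta
  equal `F_between`. The closed-form structure of this model (rather than a
  coalescent) is what lets the tests check realized theta against the known
  simulated frequencies.
* **Ancestral spectrum.** Tag-level minor-allele frequencies follow a
  neutral-like 1/x density on [0.01, 0.5]. This reproduces survey-scale
  heterozygosity (about 0.17 before filtering) and, critically, keeps
  mid-frequency loci rare — the frequency region where the HDplot *H*
  criterion is intrinsically noisy.
* **Within-tag structure.** The SNPs of one 140-bp RAD tag share a
  genealogy, so the model is tag-level throughout: one ancestral frequency
  and one Balding–Nichols draw per tag (plus a small per-SNP logit jitter,
  shared across populations, for mutation-age differences), and gamete
  haplotypes drawn by a common-uniform threshold per tag — the allele at
  SNP *s* is `u < p_s` with a single `u` per gamete — giving complete
  within-tag linkage (|D'| = 1), the no-recombination limit. This yields
  realistic few-allele microhaplotypes and properly correlated per-SNP
  HDplot statistics within a tag.
* **Stocking pulses.** A pulse converts a fraction `1 - fraction_pure_native`
  of the recipient individuals into hybrids; each hybrid haplotype at each
  tag descends from the source population with probability `p_adm`.
  Realized (not expected) ancestry fractions are recorded per individual.
* **Paralogs.** A collapsed duplicate is a second, hidden locus with its own
  genotypes (off-centre frequency, uniform on 0.2–0.8) whose reads merge
  onto the visible tag. This one mechanism produces both HDplot axes:
  apparent heterozygote excess (*H*) and skewed heterozygote allele balance
  (*D*).
* **Reads.** Depth is Poisson(`mean_depth`, default 40); a clean
  heterozygote's allele reads are Binomial(depth, 1/2).
* **Geometry.** Planar coordinates with lineages far apart and drainages as
  blocks; Monmonier needs geometry only, so no geographic projection is
  modelled.
* **Genome.** 24 chromosomes. The default chromosome length (1.7 Mb) is a
  desk-scale choice pinned by the genome-scan design target of roughly 10
  loci per 500-kb window given the ~800 tags that survive filtering; real
  percid chromosomes are ~20x longer, with proportionally more markers.
* **Determinism.** All randomness flows from the single integer seed through
  R's default generator in one documented stream order (map, frequencies,
  haplotypes per population, admixture, paralogs, coordinates).

What the generator does *not* emulate: genotyping error and allelic dropout,
missing data patterns (missingness enters tests by deletion), recombination
within tags, selection, overlapping generations, and real drift LD within
populations (individuals are drawn independently from fixed frequencies, so
the LD effective-size estimate on simulated populations is correctly
"Infinite"; finite-size behaviour is validated against a forward
Wright–Fisher simulation instead). Passing tests therefore demonstrate the
statistical machinery, not robustness to every artifact of real RAD data.

## Filtering

The filter order is fixed: individuals (> 80% genotyped), then SNPs (> 80%
genotyped and minor-allele count ≥ 3, recomputed once after the individual
pass — not iterated to convergence), then HDplot, then two branches — the
single-SNP dataset (highest-MAF SNP per tag, ties to the first SNP, then
the F_IS ≤ 0.5 screen) and the microhaplotype dataset (built from the
*pre*-one-SNP whitelist, then the ≤ 10 alleles and F_IS screens).

HDplot decisions worth recording:

* *D* is the binomial z-score of pooled heterozygote reads,
  `(sum(ref) - sum(alt)) / sqrt(total)`; a tag is removed when **any** of
  its SNPs has *H* > 0.5 or |*D*| > 7, because collapsed duplication is a
  property of the tag, not of one SNP.
* Loci with no heterozygote have undefined *D* and pass that criterion by
  convention.
* Retention is `-7 <= D <= 7`: loci with *balanced* read ratios are kept and
  extreme deviations removed, the standard reading of the method.
* The per-locus F_IS used by the filter is computed globally (over all
  individuals), with the small-sample `2n/(2n-1)` correction in the
  denominator.

The upstream loose pre-filters sometimes applied at genotype export (SNP
present in > 5% of individuals, MAF > 0.005) are available as optional
flags but default off — synthetic data does not need them.

## Diversity and effective size

Per locus: `Ho = n_het/n`; unbiased `He = (2n/(2n-1))(1 - sum p^2)`;
rarefied allelic richness at `g` gene copies via the hypergeometric
missing-allele probability. `g` defaults to the smallest per-locus copy
count so every locus supports the rarefaction; requesting more is an error
rather than a silent extrapolation. F_IS is the multilocus ratio of means
`1 - mean(Ho)/mean(He)` over polymorphic loci — more robust than averaging
per-locus ratios, whose denominators can be tiny. Headline Ho/He averages
include all retained loci; polymorphic-only averages are also returned,
since conventions differ.

The LD effective size uses Burrows' composite disequilibrium estimated from
genotype doses (`Delta = cov(x, y)/2`, sample covariance), squared
correlation `r^2 = Delta^2 / (p(1-p)q(1-q))`, loci below `pcrit = 0.05`
minor-allele frequency excluded, and **only inter-chromosomal pairs** so
physical linkage cannot inflate the drift signal. The sampling expectation
`1/S + 3.19/S^2` (S ≥ 30; the small-S variant otherwise) is subtracted and
the closed form `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')` applied;
non-positive drift signal reports "Infinite", and the parametric 95% CI
treats the pair count as chi-squared degrees of freedom. A locus cap
(default 2,000, seeded subsample) keeps the O(L^2) pair computation
tractable; loci with any missing genotype in the focal population are
excluded so all pairs share one S. No correction is applied for the ~7%
downward bias expected from mixed-cohort samples.

## Differentiation and AMOVA

Weir–Cockerham variance components a (among populations), b (among
individuals within populations), c (within individuals) are computed per
locus with the unequal-sample-size moment estimators and combined as the
ratio of sums, `theta = sum(a)/sum(a+b+c)`; zero-variance loci drop out of
both sums, and negative multilocus estimates are reported as-is.

The pairwise permutation test permutes *individuals* between the two labels
(sample sizes preserved) and uses the add-one p-value
`(1 + #[theta_perm >= theta_obs])/(1 + n_perm)`; 10,000 permutations and
the Bonferroni level 0.0001 are the defaults. The permutation engine is
vectorised over batches of label assignments via matrix products, which is
what makes 10,000 x 28 pairs affordable.

AMOVA is a gene-copy-level nested ANOVA under the allele-mismatch distance
(for biallelic copies this coincides exactly with the indicator-variable
sums of squares). Degrees of freedom follow the copy nesting
(`G-1`, `P-G`, `2N-P`); unequal-size coefficients n', n'', n''' convert
mean squares to components; negative components are retained (with a
footnote) rather than truncated, and percent-of-variation is
component/total. Loci with missing genotypes contribute sums of squares
from observed copies only, while df and coefficients use the design sizes —
exact on complete data, a documented approximation otherwise. Running the
same engine with "groups" = populations and "populations" = individuals
reproduces the Weir–Cockerham multilocus theta to machine precision, an
internal-consistency check the tests assert at 1e-9.

Nei's `D_A = 1 - (1/L) sum sqrt(x_a y_a)` feeds an `ape::nj` dendrogram;
bootstraps resample whole RAD tags (not SNPs) when tags carry several SNPs,
avoiding intra-tag pseudo-replication, and node support counts bipartitions
in replicate trees. D_A does not always satisfy the triangle inequality;
nothing here assumes it does.

## Boundary detection

Edwards' distance `sqrt(1 - (1/L) sum sqrt(x_a y_a))` between populations
is rescaled by classical PCoA retaining only axis 1 (the rescaled distance
is the absolute score difference), suppressing off-axis noise before
boundary tracing. The connectivity network is a Delaunay triangulation
(Bowyer–Watson, implemented in the package). Monmonier runs seed at the
largest uncrossed edge distance above the threshold and extend in both
directions through the triangle dual, always crossing the admissible
neighbouring edge of maximal distance, stopping at the hull, an
already-crossed edge, or when no admissible edge remains. Ties break to the
lowest edge index, so results are deterministic. The default threshold is
the third quartile of the network's edge distances — the source value used
in the original analyses is not published, so ours is documented rather
than claimed identical; it is exposed as a parameter, and a relaxation pass
(threshold reduced by 5%) probes shallower structure. A run whose seed edge
falls below the threshold is reported as the convergence point.

## Co-ancestry painting and ancestry EM

For each individual and each tag where it is genotyped, each of its two
haplotype alleles donates one unit of co-ancestry, split equally among the
other individuals whose nearest haplotype (Hamming distance over the tag's
SNPs, better of their two alleles) attains the minimum. Rows therefore sum
to exactly twice the tags used — a conservation law the tests assert — and
the matrix need not be symmetric. This is a faithful-in-spirit variant of
chromosome-painting co-ancestry for RAD data; the original tool's
additional normalisations are deliberately not reproduced, so absolute
scales differ from published co-ancestry tables (which the package
reproduces only as printed-column arithmetic). Painting operates within
tags, so phase across tags is not required. The individual dendrogram is
average-linkage clustering on the symmetrised matrix (max-minus
dissimilarity) — plumbing in place of an MCMC population-configuration
sampler, sufficient for lineage- and population-level recovery.

Supervised ancestry EM treats each gene copy as an independent draw from a
mixture of K reference panels; E-step responsibilities are proportional to
`q_k p_k`, the M-step averages them, convergence is `max |dq| < 1e-6` or
500 iterations, and the log-likelihood is non-decreasing (asserted on
traces). Reference panels should be allele frequencies of the candidate
source pools; for lineage-ancestry questions, pooled lineage frequencies
estimated from labelled samples are the natural panels.

Tukey's HSD for intra- vs inter-basin co-ancestry uses the one-way ANOVA
mean square with the Tukey–Kramer unequal-n adjustment (basin sets are
always unbalanced) and the studentized range distribution, at alpha =
0.001.

## Genome scan

Per-locus multi-population theta feeds windows of 500 kb tiled from
coordinate 1 of each chromosome at 100-kb steps (half-open intervals, so a
boundary locus belongs to the lower window only). Within a window, loci are
weighted `exp(-d^2/(2 sigma^2))` by distance to the centre with
`sigma = window/4` (±2 sigma spans the window); sigma is exposed because
the weighting scale is a convention, not a published constant. The
significance test deliberately uses the **plain** window mean: the null
resamples `n` loci from the genome without replacement (vectorised
rejection sampling; with-replacement fallback only when a window exceeds
the pool) and compares average differentiation, so the weighted mean is
reported but not tested. Stage one is 1,000 replicates; windows past the
empirical 90th percentile are re-tested with 10,000 fresh draws (draws are
not reused across stages), and a window is significant when its mean
exceeds the 99th percentile and it holds at least two loci — the minimum
that avoids single-locus artifacts while catching short, dense regions.
Contiguous significant windows merge into regions (BED export is 0-based
half-open). Windows restart at coordinate 1 per chromosome rather than at
the first locus; with uniformly placed tags the difference is one window at
most.

## Problem sizes and numerical notes

The default scenario is 1,000 tags (~5,400 SNPs, ~800 surviving tags), 8
populations of 30, chosen so a full simulate-to-scan pass runs in seconds
and the whole test suite in a few minutes on one core. Co-ancestry
clustering recovery is tested at 2,500 tags with 15 individuals per
population: painting contrast scales with marker count (the survey-scale
microhaplotype panel is ~17,500 tags), and 2,500 is the smallest size at
which two-lineage recovery (≥ 95% agreement) and population-level
clustering (adjusted Rand ≥ 0.7) are stable. The Wright–Fisher oracle for
the LD-Ne check uses N = 100, six generations of drift with free
recombination, samples of 50 and 2,000 unlinked loci. Statistical-power
checks (implanted 1-Mb divergent region, F_ST permutation power) use 5,000
locus records on 24 chromosomes and the full two-stage bootstrap.

Degenerate inputs are handled explicitly rather than silently: empty
datasets after filtering, loci with no heterozygotes (undefined D), g
exceeding available gene copies, degenerate PCoA configurations (first
eigenvalue ≤ 0), networks with no edge above the Monmonier threshold, and
zero-variance Tukey groups (exact mean comparison, p in {0, 1}).

## Known limitations

* AMOVA with missing genotypes mixes observed-copy sums of squares with
  design-size coefficients; heavy, non-random missingness would bias
  components.
* The painting scale is not comparable to published co-ancestry magnitudes
  (different normalisation); only patterns and contrasts are.
* The LD-Ne parametric CI treats all inter-chromosomal pairs as independent
  comparisons, which understates uncertainty when many pairs share loci —
  the cited estimator's convention, kept for comparability.
* The supervised EM assumes reference panels are correctly specified;
  mis-specified panels (a sister population standing in for the true
  source) bias ancestry estimates upward, which is visible in the tests'
  fixture choices.
* Monmonier's threshold default (third quartile) is a convention; very flat
  distance distributions can leave no admissible edge, which is reported as
  immediate convergence, not an error.
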