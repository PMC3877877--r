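---
title: "Models and methods behind gendiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gendiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendiv)
```

gendiv analyzes multi-individual SNV tables: it computes diversity and
differentiation statistics, finds runs of exceptional SNVs without genomic
windows, paints admixed genomes over source populations, builds
genotype-distance trees, and ranks gene sets and pathways. This vignette
explains the models, the tunable parameters, and the design choices made
where more than one defensible option existed.

## The SNV table formats

A `gd_snp` table has one row per biallelic SNV: chromosome, 1-based
position, reference and variant alleles, a site quality (`-1` when absent),
then four columns per individual -- reference-read count, variant-read
count, genotype, genotype quality. A `gd_genotype` table carries only the
genotype column. Genotypes count copies of the **reference** allele (2 =
homozygous reference, 0 = homozygous variant, -1 = uncalled). Analyses
append named numeric columns after the sample block, so pipelines compose
by chaining columns, and the writer round-trips its own output
byte-identically.

The header dialect (`#format`, `#individual <name> <first_column>`,
`#column <name> <index>`) is this package's own fixed convention; the
format family predates it without a published literal header. Duplicate
(chrom, pos) rows are rejected at parse time because every downstream
statistic assumes unique sites. VCF conversion requires GT and takes AD/GQ
when present (`-1` placeholders otherwise); multi-allelic rows are skipped
and counted, since the table model is strictly biallelic.

Depth filtering is per individual: a member with a `-1` read count fails an
active depth threshold (the conservative reading -- an unknown depth cannot
certify a pass). Whether a population-mean rule would be preferable is
unknowable from the format alone; the per-individual rule is stricter and
simpler to reason about.

## Diversity and differentiation

With `a` reference alleles among `n` called alleles at a site, the per-site
nucleotide diversity is the mean pairwise difference
$\pi_{site} = 2a(n-a)/(n(n-1))$, summed over sites. Watterson's
$\theta_W$ counts segregating sites, each scaled by the harmonic number
$a_n = \sum_{i=1}^{n-1} 1/i$ evaluated at **that site's** called-allele
count; with missing genotypes, `n` varies across sites, and the per-site
harmonic factor is the natural generalization of the fixed-n textbook form.
Both are sums; an optional sequence length `L` reports per-bp values, since
conventions differ on normalization.

Three F_ST estimators are available, selectable per call:

* **wright** -- the original definition: the variance of the two allele
  frequencies over its limiting value $\bar p(1-\bar p)$, defined as 0 when
  the mean frequency is degenerate. Always in [0, 1].
* **reich** -- the unbiased moment estimator: with
  $h_i = a_i(n_i-a_i)/(n_i(n_i-1))$,
  $N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2$ and $D = N + h_1 + h_2$,
  the per-SNV score is $N/D$ (negative values possible and reported).
  It behaves well at small sample sizes and is the default. It needs two
  called alleles per population; sites failing that are unscoreable.
* **weir_cockerham** -- the 1984 two-population variance-components
  estimator from genotype data (it needs observed heterozygosity, so it is
  genotype-mode only).

Overall values are **ratios of sums** of the per-site components (for
Reich, $\sum N / \sum D$), never means of per-site ratios: low-information
sites would otherwise dominate. Allele counts come from genotypes by
default (a = reference copies over called members, n = 2 x called members)
or from summed read counts in `"reads"` mode for pooled samples.

The locus-specific branch length isolates which lineage moved:
$LSBL_A = (F_{AB} + F_{AC} - F_{BC})/2$. It is additive
($LSBL_A + LSBL_B = F_{AB}$) and negative values are reported unclamped --
clamping would destroy additivity.

## Window-free sweep intervals

Scanning for sweeps with fixed windows forces several arbitrary choices
(window size, overlap, merging). Instead, a single **shift value** is
subtracted from every per-SNV score and the finder reports all
maximal-scoring subsequences of the shifted scores: runs with positive
total whose every proper sub-run scores strictly less, contained in no
longer run with that property. The implementation is the linear-time stack
algorithm; the test suite checks it against a quadratic brute-force
maximality oracle. Interval coordinates are the first and last member-SNV
positions -- SNV-bounded, not round-number window edges.

Choosing the shift at, say, the 90th percentile of the scores
(`percentile_shift()`, linear interpolation between order statistics)
leaves at least 90% of shifted scores non-positive, so reported runs sit in
the top decile on average. Raising the shift shortens intervals: the
longest interval and the best score are non-increasing, and every interval
found at a higher shift nests inside one found at a lower shift. The
*number* of intervals usually falls too, but not monotonically -- a higher
shift can split one long run into several short ones (scores `c(1, 0.2, 1)`
at shifts 0.5 and 0.7), so only the length and score monotonicities are
asserted as invariants.

Significance is empirical: scores are shuffled (genome-wide by default;
`within_chrom = TRUE` restricts permutations to chromosomes, both readings
being defensible since scores are exchangeable only genome-wide under the
strictest null), the best interval score of each shuffle is recorded, and
an observed interval's p is `(1 + #{best >= observed}) / (n_shuffles + 1)`
-- the +1 correction keeps p away from 0. Independence of scores is
assumed; linked SNVs violate it, which is why AIM-style spacing matters
upstream.

The worked pooled-counts example: a SNV where all 30 reads carry one allele
has homozygosity $(r^2+v^2)/(r+v)^2 = 1$; at shift 0.9 each such SNV
contributes 0.1, so a 10-SNV run totals 1.0 and a 100-SNV run 10.0 and
outranks it -- SNV-dense regions are preferred rather than penalized.

## Admixture painting

For 2 (or 3) source populations there are 3 (or 6) **interval genotypes**:
unordered pairs (i, j) saying which source each chromosome copy came from.
Given source reference-allele frequencies $p_i$ at a SNV, the genotype
likelihoods follow the random-sampling product rule (e.g. a
homozygous-reference genotype has probability $p_i^2$ under (i,i) and
$p_i p_j$ under (i,j)); log-likelihoods are added along a segment. The
painting maximizes the summed emission log-likelihood minus
$\lambda \times$ (number of state switches) over all state sequences by
dynamic programming with backtracking. Ties prefer staying in the previous
state, then the lowest state index, making output deterministic.

Parameters that matter:

* **switch penalty** $\lambda$ (nats per switch, default 1): larger values
  give fewer, longer runs of constant interval genotype. The segment count
  is non-increasing in $\lambda$ (a test asserts this). Values of roughly
  0.5-10 span the useful range; because the scale depends on the log base
  and on marker density, proportions should be read across a $\lambda$
  grid, not at one value.
* **AIM selection**: painting is most informative at SNVs with high F_ST
  between the sources (`select_aims()`, e.g. retain F_ST > 0.4) and with a
  minimum spacing to approximate independence.
* **frequency clamping**: source frequencies are clamped into
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2n+2)$ at a site
  with n called source alleles, preventing $-\infty$ emissions from finite
  samples; a site with no source data collapses to the uninformative 0.5.

Missing genotypes emit nothing and consume no switch. Chromosomes are
painted independently. For bp accounting, segment boundaries are placed at
the midpoint between the flanking SNVs of a switch; SNV-position bounds are
reported alongside. Ancestry proportions credit (i,i) spans wholly to
source i and (i,j) spans half to each, and are reported both bp-weighted
and SNV-count-weighted, the two defensible conventions.

The model deliberately ignores haplotype phase, recombination maps and
time-since-admixture -- it is the simple, fast alternative for data sets
that cannot support richer models.

## Genotype-distance trees

For each pair of individuals, the informative sites are those where both
genotypes are called (and, with read data, both depths reach `min_depth`);
the distance is the number of genotypic differences divided by the number
of informative sites. "Difference" is read literally -- any unequal pair of
called genotypes counts 1 -- with `allele_sharing = TRUE` offering the
half-weight alternative (het vs hom = 0.5) as an interpretation. Trees are
standard neighbor joining (via ape) with negative branch lengths clamped to
0; tests confirm exact recovery of additive matrices.

## Gene sets and pathways

Category enrichment uses the two-tailed Fisher exact test (the sum of
hypergeometric outcomes no more probable than the observed table), ranking
categories by the fraction of their genes present in the input and then by
p -- the ranking is by effect first, significance second, and both
enrichment and depletion directions are labelled.

Pathway disruption treats a pathway as a directed graph. Sources are nodes
with no incoming edge, sinks nodes with no outgoing edge, both recomputed
after any deletion. The metrics are the count and mean edge-length of
simple source-to-sink paths (at least one edge; cycles terminate naturally
under the simple-path constraint; a cap, default 1e6 paths, turns
exponential blowup into an explicit error). Ranking compares each pathway
with and without the nodes carrying the input genes, ordered by
|change in mean length| then |change in path count|; a pathway left with no
path contributes mean length 0 to the difference, so total disconnection
registers as maximal change rather than as missing data.

Category clustering is single-linkage with the shared-gene fraction
$|A \cap B| / \min(|A|, |B|)$: the min-denominator makes a small category
nested in a large one link at any threshold its overlap warrants, which
Jaccard would dilute. Cluster count is non-decreasing in the threshold.

## The synthetic-data generator

`simulate_populations()` draws ancestral frequencies Uniform(0.05, 0.95)
and population frequencies from the Balding-Nichols Beta model with drift
parameter F per population -- the simplest standard model with a single
differentiation knob (F = 0 gives identical populations; F around 0.6
yields many near-fixed differences suitable as AIMs). Genotypes are
Binomial(2, p); pooled read counts are Poisson depth with per-read error.
`simulate_admixed()` tiles each chromosome copy with Exponential-length
ancestry tracts (memoryless, matching the run-length structure the DP
assumes) and records the realized diploid interval genotypes as ground
truth.

What the generator does **not** emulate: linkage disequilibrium beyond
tract structure, mutation-model detail, allele-frequency spectra of real
demographies, mapping artifacts, or genotyping error correlated with
depth. Passing recovery tests on these fixtures therefore demonstrates
algorithmic correctness (the DP finds the optimum; estimators match their
closed forms) and sane behavior at realistic parameter scales -- not
field-readiness for any particular organism.

Test problem sizes are chosen to keep the suite quick at desk scale while
leaving the checks meaningful: 1,000 random vectors (length <= 50) for the
segment-finder oracle, 200 painting instances (up to 10 SNVs with 2
sources, up to 7 with 3 -- the 6-state space grows as $6^n$), 500 random
count configurations for the Reich oracle, 200 no-drift replicates for the
null F_ST check, 100 random trees for NJ recovery, exhaustive 2x2 tables
to N = 40 for Fisher, and a 40 Mb, 6,000-SNV genome for the 70/30
admixture-recovery experiment.

## Numerical choices and degenerate inputs

* Equal-score intervals rank leftmost-first, then shortest; painting ties
  prefer no-switch, then the lowest state; NJ ties follow ape's fixed
  order. All outputs are deterministic given the seed.
* Wright F_ST is defined 0 at degenerate mean frequency; Reich leaves
  sites with fewer than two called alleles per population unscored (count
  attached as an attribute) rather than guessing.
* `homozygosity_score`, `allele_frequency` and `nucleotide_diversity`
  raise errors on empty counts instead of returning NaN.
* Empty inputs are legal where a sensible empty output exists (an empty
  score vector yields no intervals; an empty gd body parses to an empty
  table) and errors where silence would hide a mistake (a population with
  no called alleles anywhere, a pair with no informative site).

## Known limitations

Per-SNV statistics assume unlinked, independently scored sites; the
shuffle null and the painting likelihood both inherit that assumption.
The painting reports hard state assignments, not posterior uncertainty.
Pathway metrics depend on the curated graph topology and treat all edges
equally. The Weir-Cockerham implementation covers the two-population,
two-allele case only.
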